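#' Configuration of the TDGL phase-field model
#'
#' Collects every term of the total free energy
#' `F = f_bulk + f_grad + f_elastic + f_elec` and the numerical settings of
#' the semi-implicit Fourier-spectral gradient flow
#' `dP_i/dt* = -(1/alpha0) dF/dP_i`, where `t*` is the reduced time into
#' which the (unprinted) kinetic coefficient is folded and `alpha0` is a
#' fixed energy-scale normalizer.
#'
#' Gradient energy: `f_grad = 1/2 [G11 sum_i (dP_i/dx_i)^2 +
#' G44 sum_{i != j} (dP_i/dx_j)^2]` (the printed `G12/G110 = 0` removes the
#' cross term), giving a per-component Fourier kernel
#' `K_i(k) = G11 k_i^2 + G44 sum_{j != i} k_j^2` that is treated fully
#' implicitly.
#'
#' Electrostatic energy: `f_elec = -(E_appl + E_RF) . P - 1/2 E_dep . P`,
#' with `E_dep` the bound-charge depolarization field (only when
#' `electrostatic_mode = "depolarization"`).
#'
#' Elastic energy: periodic microelasticity with eigenstrain
#' `eps0_ij = Q_ijkl P_k P_l` under zero mean stress and homogeneous cubic
#' stiffness obtained by inverting the compliances. Off by default: the
#' shipped compliance set is not positive definite (`s11 + 2 s12 < 0`), so
#' default evolutions run without the elastic term; switch `elastic_on` for
#' the microelasticity code path.
#'
#' @param material Material id for the bulk Landau coefficients.
#' @param temperature Temperature in K.
#' @param dt Dimensionless time step (default 0.05; see
#'   [tdgl_stability_dt()]).
#' @param alpha0 Energy-scale normalizer in C^-2 m^2 N (default 1e7).
#' @param G110 Gradient coefficient scale, C^-2 m^4 N.
#' @param g11_ratio,g12_ratio,g44_ratio Ratios G11/G110, G12/G110, G44/G110.
#' @param Q Electrostrictive constants `c(Q11, Q12, Q44)` (m^4/C^2).
#' @param s Compliances `c(s11, s12, s44)` (m^2/N).
#' @param elastic_on Include the microelasticity term (default FALSE).
#' @param electrostatic_mode `"depolarization"` (default; the bound-charge
#'   field that penalizes charged walls and stabilizes multidomain
#'   states) or `"off"` (for oracle tests).
#' @param eps_b Background relative permittivity for the depolarization
#'   solve (default 45).
#' @param kzero_mode `"short"` (no macroscopic depolarization; default) or
#'   `"open"` (mean polarization is depolarized too).
#' @param applied_field Length-3 applied field, V/m.
#' @param defect_field Static random-field array (shape x 3, V/m) from
#'   [make_defect_field()], or NULL.
#' @return A `tdgl_config` object.
#' @export
tdgl_config <- function(material = "btz", temperature = 298,
                        dt = 0.05, alpha0 = 1e7,
                        G110 = 7.04e-11, g11_ratio = 1.5,
                        g12_ratio = 0, g44_ratio = 0.75,
                        Q = c(Q11 = 0.1, Q12 = -0.034, Q44 = 0.029),
                        s = c(s11 = 9.1e-12, s12 = -3.2e-10,
                              s44 = 8.2e-10),
                        elastic_on = FALSE,
                        electrostatic_mode = c("depolarization", "off"),
                        eps_b = 45,
                        kzero_mode = c("short", "open"),
                        applied_field = c(0, 0, 0),
                        defect_field = NULL) {
  electrostatic_mode <- match.arg(electrostatic_mode)
  kzero_mode <- match.arg(kzero_mode)
  stopifnot(dt > 0, alpha0 > 0, G110 > 0, eps_b > 1,
            length(applied_field) == 3L, length(Q) == 3L, length(s) == 3L)
  if (g12_ratio != 0) {
    stop("only G12/G110 = 0 is supported (cross-gradient terms absent); ",
         "got ", g12_ratio, call. = FALSE)
  }
  coeffs <- coefficients_at(material, temperature)
  stiff <- if (elastic_on) {
    cubic_stiffness_from_compliance(s[[1]], s[[2]], s[[3]])
  } else NULL
  structure(
    list(material = landau_material(material)$material_id,
         temperature = temperature, coeffs = coeffs,
         dt = dt, alpha0 = alpha0,
         G11 = g11_ratio * G110, G12 = g12_ratio * G110,
         G44 = g44_ratio * G110, G110 = G110,
         Q = unname(Q), s = unname(s), stiffness = stiff,
         elastic_on = elastic_on,
         electrostatic_mode = electrostatic_mode, eps_b = eps_b,
         kzero_mode = kzero_mode,
         applied_field = applied_field, defect_field = defect_field),
    class = "tdgl_config")
}

EPS0 <- 8.8541878128e-12  # vacuum permittivity, F/m

#' Cubic stiffness tensor from compliances
#'
#' Inverts the Voigt cubic compliance matrix analytically:
#' `c11 = (s11 + s12)/d`, `c12 = -s12/d`, `c44 = 1/s44` with
#' `d = (s11 - s12)(s11 + 2 s12)`. Errors when the inversion is
#' ill-conditioned (|d| below 1e-6 * s11^2).
#'
#' @param s11,s12,s44 Compliances in m^2/N.
#' @return Named list `c11`, `c12`, `c44` (N/m^2).
#' @export
cubic_stiffness_from_compliance <- function(s11, s12, s44) {
  d <- (s11 - s12) * (s11 + 2 * s12)
  if (!is.finite(d) || abs(d) < 1e-6 * max(abs(c(s11, s12)))^2 ||
      s44 == 0) {
    stop("compliance matrix is ill-conditioned; cannot form the stiffness ",
         "tensor (d = ", format(d), ")", call. = FALSE)
  }
  list(c11 = (s11 + s12) / d, c12 = -s12 / d, c44 = 1 / s44)
}

# k-space machinery -----------------------------------------------------

fft_freqs <- function(n, spacing) {
  2 * pi * c(0:(n / 2 - 1), seq(-n / 2, -1)) / (n * spacing)
}

# Full-grid arrays of k components (always 3; k3 = 0 in 2D), |k|^2, and the
# per-component implicit gradient kernels.
spectral_setup <- function(grid, config = NULL) {
  shp <- grid$shape
  ax <- lapply(shp, fft_freqs, spacing = grid$spacing)
  karr <- vector("list", 3L)
  if (grid$dimensions == 2L) {
    karr[[1]] <- array(rep(ax[[1]], times = shp[2]), dim = shp)
    karr[[2]] <- array(rep(ax[[2]], each = shp[1]), dim = shp)
    karr[[3]] <- array(0, dim = shp)
  } else {
    karr[[1]] <- array(rep(ax[[1]], times = shp[2] * shp[3]), dim = shp)
    karr[[2]] <- array(rep(rep(ax[[2]], each = shp[1]), times = shp[3]),
                       dim = shp)
    karr[[3]] <- array(rep(ax[[3]], each = shp[1] * shp[2]), dim = shp)
  }
  ksq <- karr[[1]]^2 + karr[[2]]^2 + karr[[3]]^2
  out <- list(karr = karr, ksq = ksq)
  if (!is.null(config)) {
    out$Kgrad <- lapply(1:3, function(i) {
      config$G11 * karr[[i]]^2 + config$G44 * (ksq - karr[[i]]^2)
    })
  }
  out
}

ifft_re <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

# Analytic gradient of the bulk Landau polynomial, vectorized over arrays.
bulk_energy_grad <- function(P1, P2, P3, co) {
  g <- function(a, b, c) {
    2 * co$alpha1 * a + 4 * co$alpha11 * a^3 +
      2 * co$alpha12 * a * (b^2 + c^2) +
      6 * co$alpha111 * a^5 +
      co$alpha112 * (4 * a^3 * (b^2 + c^2) + 2 * a * (b^4 + c^4)) +
      2 * co$alpha123 * a * b^2 * c^2
  }
  list(g(P1, P2, P3), g(P2, P1, P3), g(P3, P1, P2))
}

# Voigt eigenstrain (engineering shears) from electrostriction.
eigenstrain_voigt <- function(P1, P2, P3, Q) {
  Q11 <- Q[1]; Q12 <- Q[2]; Q44 <- Q[3]
  list(Q11 * P1^2 + Q12 * (P2^2 + P3^2),
       Q11 * P2^2 + Q12 * (P1^2 + P3^2),
       Q11 * P3^2 + Q12 * (P1^2 + P2^2),
       Q44 * P2 * P3, Q44 * P1 * P3, Q44 * P1 * P2)
}

# Periodic microelasticity at zero mean stress: returns the domain-averaged
# elastic energy density and the elastic driving force -sigma : d(eps0)/dP.
elastic_solution <- function(P1, P2, P3, config, sp) {
  st <- config$stiffness
  c11 <- st$c11; c12 <- st$c12; c44 <- st$c44
  Q <- config$Q
  e0 <- eigenstrain_voigt(P1, P2, P3, Q)
  # eigenstress (Voigt, engineering shears)
  s0 <- list(c11 * e0[[1]] + c12 * (e0[[2]] + e0[[3]]),
             c11 * e0[[2]] + c12 * (e0[[1]] + e0[[3]]),
             c11 * e0[[3]] + c12 * (e0[[1]] + e0[[2]]),
             c44 * e0[[4]], c44 * e0[[5]], c44 * e0[[6]])
  s0h <- lapply(s0, stats::fft)
  kn <- sqrt(sp$ksq)
  nz <- kn > 0
  n1 <- ifelse(nz, sp$karr[[1]] / kn, 0)
  n2 <- ifelse(nz, sp$karr[[2]] / kn, 0)
  n3 <- ifelse(nz, sp$karr[[3]] / kn, 0)
  dim(n1) <- dim(n2) <- dim(n3) <- dim(kn)
  # traction t = sigma0_hat . n  (tensor shears = engineering values here
  # because sigma4 = c44*gamma4 is already the tensor shear stress)
  t1 <- s0h[[1]] * n1 + s0h[[6]] * n2 + s0h[[5]] * n3
  t2 <- s0h[[6]] * n1 + s0h[[2]] * n2 + s0h[[4]] * n3
  t3 <- s0h[[5]] * n1 + s0h[[4]] * n2 + s0h[[3]] * n3
  # acoustic tensor A(n), symmetric 3x3 per k
  cp <- c12 + c44
  ch <- c11 - c12 - 2 * c44
  A11 <- c44 + cp * n1^2 + ch * n1^2
  A22 <- c44 + cp * n2^2 + ch * n2^2
  A33 <- c44 + cp * n3^2 + ch * n3^2
  A12 <- cp * n1 * n2
  A13 <- cp * n1 * n3
  A23 <- cp * n2 * n3
  # closed-form symmetric inverse via cofactors
  C11 <- A22 * A33 - A23^2
  C12 <- A13 * A23 - A12 * A33
  C13 <- A12 * A23 - A13 * A22
  C22 <- A11 * A33 - A13^2
  C23 <- A12 * A13 - A11 * A23
  C33 <- A11 * A22 - A12^2
  det <- A11 * C11 + A12 * C12 + A13 * C13
  scale <- max(abs(c(c11, c12, c44)))
  if (any(nz & abs(det) < 1e-9 * scale^3)) {
    stop("acoustic tensor is singular for some wave direction; elastic ",
         "solve is ill-conditioned with these moduli", call. = FALSE)
  }
  det[!nz] <- 1
  X1 <- (C11 * t1 + C12 * t2 + C13 * t3) / det
  X2 <- (C12 * t1 + C22 * t2 + C23 * t3) / det
  X3 <- (C13 * t1 + C23 * t2 + C33 * t3) / det
  X1[!nz] <- 0; X2[!nz] <- 0; X3[!nz] <- 0
  # strain fluctuation, Voigt engineering: eps_v = sym(n (x) X)
  ef <- list(ifft_re(n1 * X1), ifft_re(n2 * X2), ifft_re(n3 * X3),
             ifft_re(n2 * X3 + n3 * X2),
             ifft_re(n1 * X3 + n3 * X1),
             ifft_re(n1 * X2 + n2 * X1))
  ebar <- vapply(e0, mean, numeric(1))  # zero mean stress => mean strain
  delta <- lapply(1:6, function(v) ebar[v] + ef[[v]] - e0[[v]])
  sig <- list(c11 * delta[[1]] + c12 * (delta[[2]] + delta[[3]]),
              c11 * delta[[2]] + c12 * (delta[[1]] + delta[[3]]),
              c11 * delta[[3]] + c12 * (delta[[1]] + delta[[2]]),
              c44 * delta[[4]], c44 * delta[[5]], c44 * delta[[6]])
  energy <- 0.5 * mean(sig[[1]] * delta[[1]] + sig[[2]] * delta[[2]] +
                       sig[[3]] * delta[[3]] + sig[[4]] * delta[[4]] +
                       sig[[5]] * delta[[5]] + sig[[6]] * delta[[6]])
  Q11 <- Q[1]; Q12 <- Q[2]; Q44 <- Q[3]
  force <- list(
    -(2 * P1 * (Q11 * sig[[1]] + Q12 * (sig[[2]] + sig[[3]])) +
        Q44 * (sig[[5]] * P3 + sig[[6]] * P2)),
    -(2 * P2 * (Q11 * sig[[2]] + Q12 * (sig[[1]] + sig[[3]])) +
        Q44 * (sig[[4]] * P3 + sig[[6]] * P1)),
    -(2 * P3 * (Q11 * sig[[3]] + Q12 * (sig[[1]] + sig[[2]])) +
        Q44 * (sig[[4]] * P2 + sig[[5]] * P1)))
  list(energy = energy, force = force)
}

#' Depolarization field of a periodic polarization field
#'
#' Spectral solution of the bound-charge Poisson problem: the longitudinal
#' projection `E_dep(k) = -(k . P(k)) k / (eps0 eps_b |k|^2)`. Under the
#' short-circuit convention (default) the k = 0 mode is zero, i.e. there is
#' no macroscopic depolarization; `kzero_mode = "open"` depolarizes the mean
#' polarization too.
#'
#' @param field A `polarization_field`.
#' @param eps_b Background relative permittivity.
#' @param kzero_mode `"short"` or `"open"`.
#' @return Array (shape x 3) of the depolarization field, V/m.
#' @export
depolarization_field <- function(field, eps_b = 45,
                                 kzero_mode = c("short", "open")) {
  kzero_mode <- match.arg(kzero_mode)
  sp <- spectral_setup(field$grid)
  Ph <- lapply(1:3, function(i) stats::fft(field_component(field$P, i)))
  kdotP <- sp$karr[[1]] * Ph[[1]] + sp$karr[[2]] * Ph[[2]] +
    sp$karr[[3]] * Ph[[3]]
  denom <- sp$ksq
  denom[denom == 0] <- Inf
  pref <- -kdotP / (EPS0 * eps_b * denom)
  E <- array(0, dim = c(field$grid$shape, 3L))
  for (i in 1:3) {
    Ei <- ifft_re(pref * sp$karr[[i]])
    if (kzero_mode == "open") {
      Ei <- Ei - mean(field_component(field$P, i)) / (EPS0 * eps_b)
    }
    E <- set_field_component(E, i, Ei)
  }
  E
}

check_defect_field <- function(config, grid) {
  df <- config$defect_field
  if (is.null(df)) return(NULL)
  if (!identical(dim(df), c(grid$shape, 3L))) {
    stop("defect field shape ", paste(dim(df), collapse = "x"),
         " does not match grid ", paste(grid$shape, collapse = "x"),
         call. = FALSE)
  }
  df
}

#' Total free energy of a polarization field
#'
#' Domain-averaged free-energy density with a per-term breakdown: bulk
#' Landau polynomial, gradient energy (spectral derivatives), periodic
#' microelasticity at zero mean stress (if enabled), and electrostatic
#' energy `-(E_appl + E_RF) . P - 1/2 E_dep . P`.
#'
#' @param field A `polarization_field`.
#' @param config A [tdgl_config()].
#' @return List `total`, `bulk`, `gradient`, `elastic`, `electrostatic`
#'   (J/m^3, domain-averaged).
#' @export
total_free_energy <- function(field, config) {
  stopifnot(inherits(field, "polarization_field"),
            inherits(config, "tdgl_config"))
  grid <- field$grid
  df <- check_defect_field(config, grid)
  P1 <- field_component(field$P, 1)
  P2 <- field_component(field$P, 2)
  P3 <- field_component(field$P, 3)
  e_bulk <- mean(bulk_energy(cbind(as.vector(P1), as.vector(P2),
                                   as.vector(P3)), config$coeffs))
  sp <- spectral_setup(grid, config)
  n2 <- n_cells(grid)^2
  e_grad <- 0
  for (i in 1:3) {
    Ph <- stats::fft(list(P1, P2, P3)[[i]])
    e_grad <- e_grad + 0.5 * sum(sp$Kgrad[[i]] * Mod(Ph)^2) / n2
  }
  e_elast <- if (config$elastic_on) {
    elastic_solution(P1, P2, P3, config, sp)$energy
  } else 0
  Eap <- config$applied_field
  e_elec <- -(Eap[1] * mean(P1) + Eap[2] * mean(P2) + Eap[3] * mean(P3))
  if (!is.null(df)) {
    e_elec <- e_elec - mean(field_component(df, 1) * P1 +
                            field_component(df, 2) * P2 +
                            field_component(df, 3) * P3)
  }
  if (config$electrostatic_mode == "depolarization") {
    Ed <- depolarization_field(field, config$eps_b, config$kzero_mode)
    e_elec <- e_elec - 0.5 * mean(field_component(Ed, 1) * P1 +
                                  field_component(Ed, 2) * P2 +
                                  field_component(Ed, 3) * P3)
  }
  list(total = e_bulk + e_grad + e_elast + e_elec,
       bulk = e_bulk, gradient = e_grad, elastic = e_elast,
       electrostatic = e_elec)
}

# largest single-domain Ps among T/O/R at the config temperature (0 if
# paraelectric); used for divergence guards and default thresholds
max_landau_ps <- function(coeffs) {
  max(vapply(c("T", "O", "R"),
             function(ph) minimize_phase(ph, coeffs)$total_Ps, numeric(1)))
}

#' Stability bound on the dimensionless TDGL time step
#'
#' The gradient (and optional depolarization) operator is implicit, so the
#' step is limited by the explicitly treated bulk term: a forward-Euler step
#' on `dP/dt* = -f'(P)/alpha0` is linearly stable for
#' `dt < 2 alpha0 / Lmax`, with `Lmax` the largest absolute eigenvalue of
#' the bulk Hessian over the relevant polarization range (sampled over the
#' 26 variant directions up to 1.2x the largest single-domain Ps).
#'
#' @param config A [tdgl_config()].
#' @return The bound on `dt` (dimensionless).
#' @export
tdgl_stability_dt <- function(config) {
  co <- config$coeffs
  pmax <- max(max_landau_ps(co), 0.05)
  dirs <- as.matrix(enumerate_variants()[, c("x", "y", "z")])
  lmax <- 0
  h <- 1e-5
  for (s in seq(0, 1.2 * pmax, length.out = 13)) {
    pts <- dirs * s
    for (r in seq_len(nrow(pts))) {
      P <- pts[r, ]
      H <- matrix(0, 3, 3)
      for (i in 1:3) for (j in i:3) {
        ei <- ej <- c(0, 0, 0); ei[i] <- h; ej[j] <- h
        H[i, j] <- H[j, i] <-
          (bulk_energy(P + ei + ej, co) - bulk_energy(P + ei - ej, co) -
           bulk_energy(P - ei + ej, co) + bulk_energy(P - ei - ej, co)) /
          (4 * h^2)
      }
      lmax <- max(lmax, max(abs(eigen(H, symmetric = TRUE,
                                      only.values = TRUE)$values)))
    }
  }
  2 * config$alpha0 / lmax
}

#' Evolve a polarization field by the TDGL equation
#'
#' Semi-implicit Fourier-spectral integration of the reduced gradient flow
#' `dP_i/dt* = -(1/alpha0) dF/dP_i`: the linear gradient kernel (and, when
#' electrostatics is on, the linear longitudinal depolarization operator,
#' via a Sherman-Morrison solve per wavevector) is implicit; the nonlinear
#' bulk, elastic and static-field driving forces are explicit. Deterministic
#' for fixed inputs.
#'
#' @param field A `polarization_field`.
#' @param config A [tdgl_config()].
#' @param steps Number of time steps.
#' @param check_every Divergence-check interval (steps); any `|P|` exceeding
#'   10x the largest Landau minimum aborts with advice to reduce `dt`.
#' @param energy_every If > 0, report the energy breakdown every that many
#'   steps via `message()`.
#' @return The evolved `polarization_field` (`step_count` incremented).
#' @export
evolve <- function(field, config, steps, check_every = 50L,
                   energy_every = 0L) {
  stopifnot(inherits(field, "polarization_field"),
            inherits(config, "tdgl_config"), steps >= 0)
  grid <- field$grid
  df <- check_defect_field(config, grid)
  sp <- spectral_setup(grid, config)
  a <- config$dt / config$alpha0
  denom <- lapply(1:3, function(i) 1 + a * sp$Kgrad[[i]])
  depol <- config$electrostatic_mode == "depolarization"
  if (depol) {
    kn <- sqrt(sp$ksq)
    nz <- kn > 0
    nvec <- lapply(1:3, function(i) {
      out <- ifelse(nz, sp$karr[[i]] / kn, 0)
      dim(out) <- dim(kn)
      out
    })
    b <- a / (EPS0 * config$eps_b)
    # Sherman-Morrison: (D + b n n^T)^-1 v = D^-1 v - b (n.D^-1 v)/(1 + b n.D^-1 n) D^-1 n
    sm_den <- 1 + b * (nvec[[1]]^2 / denom[[1]] + nvec[[2]]^2 / denom[[2]] +
                       nvec[[3]]^2 / denom[[3]])
  }
  P1 <- field_component(field$P, 1)
  P2 <- field_component(field$P, 2)
  P3 <- field_component(field$P, 3)
  Eap <- config$applied_field
  co <- config$coeffs
  p_guard <- 10 * max(max_landau_ps(co), 0.05)
  for (step in seq_len(steps)) {
    fb <- bulk_energy_grad(P1, P2, P3, co)
    f1 <- fb[[1]] - Eap[1]
    f2 <- fb[[2]] - Eap[2]
    f3 <- fb[[3]] - Eap[3]
    if (config$elastic_on) {
      # elastic_solution returns the dF/dP contribution -sigma : d(eps0)/dP
      fe <- elastic_solution(P1, P2, P3, config, sp)$force
      f1 <- f1 + fe[[1]]; f2 <- f2 + fe[[2]]; f3 <- f3 + fe[[3]]
    }
    if (!is.null(df)) {
      f1 <- f1 - field_component(df, 1)
      f2 <- f2 - field_component(df, 2)
      f3 <- f3 - field_component(df, 3)
    }
    r1 <- stats::fft(P1) - a * stats::fft(f1)
    r2 <- stats::fft(P2) - a * stats::fft(f2)
    r3 <- stats::fft(P3) - a * stats::fft(f3)
    if (!depol) {
      P1 <- ifft_re(r1 / denom[[1]])
      P2 <- ifft_re(r2 / denom[[2]])
      P3 <- ifft_re(r3 / denom[[3]])
    } else {
      d1 <- r1 / denom[[1]]; d2 <- r2 / denom[[2]]; d3 <- r3 / denom[[3]]
      ndv <- nvec[[1]] * d1 + nvec[[2]] * d2 + nvec[[3]] * d3
      corr <- b * ndv / sm_den
      u1 <- d1 - corr * nvec[[1]] / denom[[1]]
      u2 <- d2 - corr * nvec[[2]] / denom[[2]]
      u3 <- d3 - corr * nvec[[3]] / denom[[3]]
      if (config$kzero_mode == "open") {
        u1[1] <- r1[1] / (denom[[1]][1] + b)
        u2[1] <- r2[1] / (denom[[2]][1] + b)
        u3[1] <- r3[1] / (denom[[3]][1] + b)
      }
      P1 <- ifft_re(u1); P2 <- ifft_re(u2); P3 <- ifft_re(u3)
    }
    if (step %% check_every == 0L || step == steps) {
      pmax_now <- max(abs(P1), abs(P2), abs(P3))
      if (!is.finite(pmax_now) || pmax_now > p_guard) {
        stop("TDGL evolution diverged (|P| > 10x the largest Landau ",
             "minimum); reduce dt below the bound from ",
             "tdgl_stability_dt()", call. = FALSE)
      }
    }
    if (energy_every > 0L && step %% energy_every == 0L) {
      tmp <- new_polarization_field(grid, {
        A <- array(0, dim = c(grid$shape, 3L))
        A <- set_field_component(A, 1, P1)
        A <- set_field_component(A, 2, P2)
        set_field_component(A, 3, P3)
      }, field$temperature, field$seed, field$step_count + step)
      en <- total_free_energy(tmp, config)
      message(sprintf(
        "step %d: total %.6e (bulk %.3e grad %.3e elast %.3e elec %.3e)",
        field$step_count + step, en$total, en$bulk, en$gradient,
        en$elastic, en$electrostatic))
    }
  }
  A <- array(0, dim = c(grid$shape, 3L))
  A <- set_field_component(A, 1, P1)
  A <- set_field_component(A, 2, P2)
  A <- set_field_component(A, 3, P3)
  new_polarization_field(grid, A, field$temperature, field$seed,
                         field$step_count + as.integer(steps))
}

#' Simulated hysteresis loop
#'
#' Triangular sweep of the applied field along one component:
#' `0 -> +max -> -max -> +max`, evolving `equilibration_steps` TDGL steps at
#' each field value and recording the spatial mean of the swept component.
#' The leading `0 -> +max` leg is the virgin branch; the closed loop is the
#' `+max -> -max -> +max` cycle, whose first and last field values coincide.
#'
#' @param field Starting `polarization_field` (e.g. a relaxed domain
#'   structure).
#' @param config A [tdgl_config()]; its `applied_field` entry for the swept
#'   component is overwritten during the sweep.
#' @param component Swept component (1 = x, per the simulated loops).
#' @param max_field Sweep amplitude, V/m (> 0).
#' @param n_steps Field steps per quarter sweep (0 to max); >= 8 over the
#'   full sweep is required, i.e. `n_steps >= 2`.
#' @param equilibration_steps TDGL steps at each field value.
#' @return A `hysteresis_loop` data frame: `field` (V/m), `polarization`
#'   (C/m^2), `branch` (`"virgin"`, `"descending"`, `"ascending"`), with
#'   attributes `temperature`, `component`, `equilibration_steps`; the final
#'   state is attached as attribute `state`.
#' @export
run_hysteresis <- function(field, config, component = 1L, max_field,
                           n_steps = 8L, equilibration_steps = 200L) {
  stopifnot(max_field > 0, n_steps >= 2L, 4 * n_steps >= 8L)
  up1 <- seq(0, max_field, length.out = n_steps + 1L)
  down <- seq(max_field, -max_field, length.out = 2L * n_steps + 1L)
  up2 <- seq(-max_field, max_field, length.out = 2L * n_steps + 1L)
  values <- c(up1, down[-1L], up2[-1L])
  # the first +max sample opens the closed cycle: it belongs to the
  # descending branch, so the non-virgin rows start and end at +max
  branch <- c(rep("virgin", length(up1) - 1L),
              rep("descending", length(down)),
              rep("ascending", length(up2) - 1L))
  pbar <- numeric(length(values))
  state <- field
  for (i in seq_along(values)) {
    config$applied_field <- replace(c(0, 0, 0), component, values[i])
    state <- evolve(state, config, equilibration_steps)
    pbar[i] <- mean_polarization(state)[component]
  }
  out <- data.frame(field = values, polarization = pbar, branch = branch)
  attr(out, "temperature") <- config$temperature
  attr(out, "component") <- component
  attr(out, "equilibration_steps") <- equilibration_steps
  attr(out, "state") <- state
  class(out) <- c("hysteresis_loop", class(out))
  out
}
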