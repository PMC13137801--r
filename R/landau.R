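#' Bulk Landau-Devonshire free-energy density
#'
#' Sextic polynomial expansion of the zero-strain bulk free energy in the
#' three polarization components,
#' \deqn{f = \alpha_1 \sum P_i^2 + \alpha_{11} \sum P_i^4 +
#'   \alpha_{12} \sum_{i<j} P_i^2 P_j^2 + \alpha_{111} \sum P_i^6 +
#'   \alpha_{112} \sum_i P_i^4 (P_j^2 + P_k^2) +
#'   \alpha_{123} P_1^2 P_2^2 P_3^2,}
#' which has full cubic (m-3m parent) symmetry: it is invariant under all 48
#' signed permutations of the components.
#'
#' @param P Polarization in C/m^2: a length-3 vector or an n-by-3 matrix
#'   (rows are evaluated independently).
#' @param coeffs A `landau_coefficients` object (see [coefficients_at()]).
#' @return Energy density in J/m^3 (scalar or length-n vector).
#' @export
bulk_energy <- function(P, coeffs) {
  stopifnot(inherits(coeffs, "landau_coefficients"))
  if (is.null(dim(P))) {
    stopifnot(length(P) == 3L)
    P <- matrix(P, ncol = 3L)
  }
  stopifnot(ncol(P) == 3L)
  p2 <- P^2
  p4 <- p2^2
  p6 <- p2^3
  s2 <- rowSums(p2)
  pair <- p2[, 1] * p2[, 2] + p2[, 2] * p2[, 3] + p2[, 1] * p2[, 3]
  a112 <- p4[, 1] * (p2[, 2] + p2[, 3]) +
          p4[, 2] * (p2[, 1] + p2[, 3]) +
          p4[, 3] * (p2[, 1] + p2[, 2])
  f <- coeffs$alpha1 * s2 +
       coeffs$alpha11 * rowSums(p4) +
       coeffs$alpha12 * pair +
       coeffs$alpha111 * rowSums(p6) +
       coeffs$alpha112 * a112 +
       coeffs$alpha123 * p2[, 1] * p2[, 2] * p2[, 3]
  if (length(f) == 1L) as.numeric(f) else f
}

# Along a phase's symmetry line each of the n nonzero components equals p and
# the bulk energy collapses to A p^2 + B p^4 + C p^6.
phase_line_coeffs <- function(phase, coeffs) {
  switch(phase,
    T = c(A = coeffs$alpha1,
          B = coeffs$alpha11,
          C = coeffs$alpha111),
    O = c(A = 2 * coeffs$alpha1,
          B = 2 * coeffs$alpha11 + coeffs$alpha12,
          C = 2 * coeffs$alpha111 + 2 * coeffs$alpha112),
    R = c(A = 3 * coeffs$alpha1,
          B = 3 * coeffs$alpha11 + 3 * coeffs$alpha12,
          C = 3 * coeffs$alpha111 + 6 * coeffs$alpha112 + coeffs$alpha123),
    stop("phase must be one of 'T', 'O', 'R'; got '", phase, "'",
         call. = FALSE)
  )
}

n_components <- c(T = 1, O = 2, R = 3)

paraelectric_minimum <- function(coeffs) {
  structure(
    list(phase = "paraelectric", component_magnitude = 0, total_Ps = 0,
         energy_density = 0, temperature = coeffs$temperature,
         material_id = coeffs$material_id),
    class = "phase_minimum"
  )
}

#' Constrained minimum of the bulk energy on a phase's symmetry line
#'
#' Minimizes the bulk free energy along the tetragonal (one nonzero
#' component), orthorhombic (two equal nonzero components) or rhombohedral
#' (three equal nonzero components) symmetry line. On the line the energy is
#' `A p^2 + B p^4 + C p^6`, so stationarity is a quadratic in `p^2` solved in
#' closed form; of the real positive roots the one with lower energy is kept
#' (for a degenerate double root this is the larger-|P| root, which is the
#' minimum whenever the quartic coefficient is negative). If no real
#' ferroelectric root exists, or the best ferroelectric energy is >= 0, the
#' paraelectric record (Ps = 0, energy 0) is returned.
#'
#' @param phase `"T"`, `"O"` or `"R"`.
#' @param coeffs A `landau_coefficients` object.
#' @return A `phase_minimum` record: `phase`, `component_magnitude` (C/m^2,
#'   per nonzero axis), `total_Ps` (vector magnitude, `component * sqrt(n)`),
#'   `energy_density` (J/m^3), `temperature`.
#' @export
minimize_phase <- function(phase, coeffs) {
  stopifnot(inherits(coeffs, "landau_coefficients"))
  abc <- phase_line_coeffs(phase, coeffs)
  A <- abc[["A"]]; B <- abc[["B"]]; C <- abc[["C"]]
  f_line <- function(x) A * x + B * x^2 + C * x^3  # x = p^2
  # stationarity: A + 2 B x + 3 C x^2 = 0
  roots <- if (abs(C) < .Machine$double.xmin) {
    if (abs(B) < .Machine$double.xmin) numeric(0) else -A / (2 * B)
  } else {
    disc <- B^2 - 3 * A * C
    if (disc < 0) numeric(0) else {
      (-B + c(1, -1) * sqrt(disc)) / (3 * C)
    }
  }
  roots <- roots[roots > 0 & is.finite(roots)]
  if (length(roots) == 0L) {
    return(paraelectric_minimum(coeffs))
  }
  energies <- f_line(roots)
  # lower energy wins; exact tie resolved toward larger |P|
  ord <- order(energies, -roots)
  best_x <- roots[ord[1L]]
  best_e <- energies[ord[1L]]
  if (best_e >= 0) {
    return(paraelectric_minimum(coeffs))
  }
  p <- sqrt(best_x)
  n <- n_components[[phase]]
  structure(
    list(phase = phase, component_magnitude = p, total_Ps = p * sqrt(n),
         energy_density = best_e, temperature = coeffs$temperature,
         material_id = coeffs$material_id),
    class = "phase_minimum"
  )
}

#' Representative polarization vector of a phase minimum
#'
#' Canonical representatives: T along +z `(0, 0, p)`, O along `(p, p, 0)`,
#' R along `(p, p, p)`; paraelectric is the origin.
#'
#' @param minimum A `phase_minimum` record.
#' @return Length-3 polarization vector (C/m^2).
#' @export
phase_vector <- function(minimum) {
  stopifnot(inherits(minimum, "phase_minimum"))
  p <- minimum$component_magnitude
  switch(minimum$phase,
         paraelectric = c(0, 0, 0),
         T = c(0, 0, p),
         O = c(p, p, 0),
         R = c(p, p, p))
}

#' Stable phase and spontaneous polarization across temperature
#'
#' For each temperature the minimum-energy phase among paraelectric, T, O and
#' R is selected under constant-stress, constant-field conditions; its total
#' spontaneous polarization forms the Ps(T) curve from which the pyroelectric
#' coefficient dPs/dT is taken.
#'
#' @param material Material id or `landau_material`.
#' @param temperatures Non-empty, strictly increasing vector (K).
#' @return A `ps_t_curve` data frame with columns `temperature`, `ps`
#'   (C/m^2), `phase`, and attributes `material_id`, `conditions`.
#' @export
stable_phase_diagram <- function(material, temperatures) {
  stopifnot(is.numeric(temperatures), length(temperatures) >= 1L,
            all(diff(temperatures) > 0))
  mat <- landau_material(material)
  rows <- lapply(temperatures, function(temp) {
    co <- coefficients_at(mat, temp)
    mins <- lapply(c("T", "O", "R"), minimize_phase, coeffs = co)
    energies <- vapply(mins, `[[`, numeric(1), "energy_density")
    if (all(energies >= 0)) {
      data.frame(temperature = temp, ps = 0, phase = "paraelectric")
    } else {
      best <- mins[[which.min(energies)]]
      data.frame(temperature = temp, ps = best$total_Ps, phase = best$phase)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "material_id") <- mat$material_id
  attr(out, "conditions") <- "constant stress, constant field"
  class(out) <- c("ps_t_curve", class(out))
  out
}

#' Pyroelectric coefficient from a Ps(T) curve
#'
#' Finite-difference derivative dPs/dT (central differences at interior
#' points, one-sided at the ends) converted to uC m^-2 K^-1. The sign
#' convention follows the defining derivative: near a ferroelectric-to-
#' paraelectric transition Ps falls with T, so rho is negative; use
#' [rho_magnitude()] when comparing magnitudes.
#'
#' @param curve A `ps_t_curve` (or data frame with `temperature` and `ps`
#'   columns, in K and C/m^2) with at least 3 uniformly spaced points.
#' @return Data frame with `temperature` (K) and `rho` (uC m^-2 K^-1).
#' @export
pyroelectric_coefficient <- function(curve) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 3L,
            all(c("temperature", "ps") %in% names(curve)))
  tt <- curve$temperature
  h <- diff(tt)
  if (max(h) - min(h) > 1e-8 * mean(h)) {
    stop("temperatures must be uniformly spaced for the finite-difference ",
         "derivative", call. = FALSE)
  }
  h <- mean(h)
  ps <- curve$ps
  n <- length(ps)
  drho <- numeric(n)
  drho[1] <- (ps[2] - ps[1]) / h
  drho[n] <- (ps[n] - ps[n - 1]) / h
  if (n > 2) {
    drho[2:(n - 1)] <- (ps[3:n] - ps[1:(n - 2)]) / (2 * h)
  }
  data.frame(temperature = tt, rho = drho * 1e6)
}

#' Magnitude of the pyroelectric coefficient
#' @param rho Output of [pyroelectric_coefficient()] or a numeric vector.
#' @return Same shape with `rho` replaced by `|rho|`.
#' @export
rho_magnitude <- function(rho) {
  if (is.data.frame(rho)) {
    rho$rho <- abs(rho$rho)
    rho
  } else {
    abs(rho)
  }
}

#' Percent enhancement of one pyroelectric coefficient over a reference
#'
#' `100 * (|rho_test| - |rho_ref|) / |rho_ref|`; magnitudes are compared, so
#' the defining-derivative sign convention does not affect the result.
#'
#' @param rho_test,rho_ref Coefficients in uC m^-2 K^-1; `rho_ref` nonzero.
#' @return Percent enhancement.
#' @examples
#' enhancement_percent(3505, 450)  # ~679%
#' @export
enhancement_percent <- function(rho_test, rho_ref) {
  stopifnot(is.numeric(rho_test), is.numeric(rho_ref))
  if (any(rho_ref == 0)) {
    stop("reference coefficient must be nonzero", call. = FALSE)
  }
  100 * (abs(rho_test) - abs(rho_ref)) / abs(rho_ref)
}

#' Energy profile along a polarization-rotation path between two phases
#'
#' Samples the bulk energy along a path in polarization space between the
#' canonical minima of two ferroelectric phases. The default path is the
#' straight segment; `mode = "arc"` rotates the direction along the great
#' circle while interpolating |P| linearly (constant-|P| arc when the two
#' minima share a magnitude).
#'
#' @param phase_a,phase_b Phases in `{"T","O","R"}` (must both be
#'   ferroelectric at this temperature).
#' @param coeffs A `landau_coefficients` object.
#' @param n_points Number of samples (>= 101 recommended; default 101).
#' @param mode `"linear"` (default) or `"arc"`.
#' @return An `energy_barrier_profile` list: `path_parameter` in \[0, 1\],
#'   `energy_density` (J/m^3), `endpoints` (the two `phase_minimum` records),
#'   `barrier_a`, `barrier_b` (max over path minus each endpoint energy) and
#'   `gap` (absolute inter-minimum energy difference), plus the same `gap`
#'   in J/cm^3 (`gap_J_per_cm3`).
#' @export
barrier_profile <- function(phase_a, phase_b, coeffs, n_points = 101,
                            mode = c("linear", "arc")) {
  mode <- match.arg(mode)
  stopifnot(n_points >= 2L)
  min_a <- minimize_phase(phase_a, coeffs)
  min_b <- minimize_phase(phase_b, coeffs)
  if (min_a$phase == "paraelectric" || min_b$phase == "paraelectric") {
    stop("no rotation path: phase ", if (min_a$phase == "paraelectric")
         phase_a else phase_b, " has no ferroelectric minimum at ",
         coeffs$temperature, " K", call. = FALSE)
  }
  va <- phase_vector(min_a)
  vb <- phase_vector(min_b)
  s <- seq(0, 1, length.out = n_points)
  pts <- if (mode == "linear" || sum((va - vb)^2) < 1e-30) {
    outer(1 - s, va) + outer(s, vb)
  } else {
    ua <- va / sqrt(sum(va^2)); ub <- vb / sqrt(sum(vb^2))
    ang <- acos(min(1, max(-1, sum(ua * ub))))
    mags <- (1 - s) * min_a$total_Ps + s * min_b$total_Ps
    if (ang < 1e-12) {
      outer(mags, ua)
    } else {
      dirs <- (outer(sin((1 - s) * ang), ua) + outer(sin(s * ang), ub)) /
        sin(ang)
      dirs * mags
    }
  }
  e <- bulk_energy(pts, coeffs)
  e[1] <- min_a$energy_density
  e[n_points] <- min_b$energy_density
  structure(
    list(path_parameter = s, energy_density = e,
         endpoints = list(min_a, min_b),
         barrier_a = max(e) - min_a$energy_density,
         barrier_b = max(e) - min_b$energy_density,
         gap = abs(min_a$energy_density - min_b$energy_density),
         gap_J_per_cm3 = j_m3_to_j_cm3(
           abs(min_a$energy_density - min_b$energy_density)),
         mode = mode, temperature = coeffs$temperature),
    class = "energy_barrier_profile"
  )
}

#' Convert an energy density between J/m^3 and J/cm^3
#'
#' Explicit converters; no silent rescaling happens anywhere else in the
#' package (all internal energies are J/m^3).
#' @param x Energy density.
#' @return Converted energy density.
#' @export
j_m3_to_j_cm3 <- function(x) x * 1e-6

#' @rdname j_m3_to_j_cm3
#' @export
j_cm3_to_j_m3 <- function(x) x * 1e6
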