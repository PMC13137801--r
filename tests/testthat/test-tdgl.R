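test_that("field initialization modes honour their contracts", {
  g <- simulation_grid(c(16, 16))
  z <- initialize_field(g, "random", amplitude = 0, seed = 1)
  expect_true(all(z$P == 0))
  a <- initialize_field(g, "random", amplitude = 0.02, seed = 7)
  b <- initialize_field(g, "random", amplitude = 0.02, seed = 7)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  u <- initialize_field(g, "uniform", value = c(0, 0, 0.13))
  expect_true(all(u$P[, , 3] == 0.13) && all(u$P[, , 1:2] == 0))
  v <- initialize_field(g, "variant-mix", amplitude = 0.2, seed = 3)
  norms <- sqrt(rowSums(matrix(v$P, ncol = 3)^2))
  expect_equal(norms, rep(0.2, 256), tolerance = 1e-12)
  expect_error(simulation_grid(c(6, 16)), "even and >= 8")
  expect_error(simulation_grid(c(15, 16)), "even and >= 8")
})

test_that("field states round-trip through the text format", {
  f <- make_random_field(c(8, 8), amplitude = 0.05, seed = 2,
                         temperature = 273)
  path <- tempfile(fileext = ".csv")
  write_field_csv(f, path)
  g <- read_field_csv(path)
  expect_equal(g$P, f$P, tolerance = 1e-12)
  expect_identical(g$temperature, f$temperature)
  expect_identical(g$step_count, f$step_count)
})

test_that("depolarization field solves the bound-charge problem", {
  g <- simulation_grid(c(32, 32), spacing = 1e-9)
  eps0 <- 8.8541878128e-12
  x <- 0:31
  amp <- 0.1
  # longitudinal head-to-head sinusoid: E1 = -P1/(eps0 eps_b), 1-D closed form
  P <- array(0, dim = c(32, 32, 3))
  P[, , 1] <- matrix(rep(amp * sin(2 * pi * x / 32), times = 32), 32, 32)
  f <- pyrofield:::new_polarization_field(g, P, 298, 1L)
  Ed <- depolarization_field(f, eps_b = 45)
  expect_equal(Ed[, 1, 1], -amp * sin(2 * pi * x / 32) / (eps0 * 45),
               tolerance = 1e-6)
  # transverse single mode is divergence-free: no depolarization
  Pt <- array(0, dim = c(32, 32, 3))
  Pt[, , 2] <- P[, , 1]
  ft <- pyrofield:::new_polarization_field(g, Pt, 298, 1L)
  expect_lt(max(abs(depolarization_field(ft, 45))), 1e-20)
  # uniform field: zero under the short-circuit k = 0 convention
  fu <- initialize_field(g, "uniform", value = c(0.1, 0.05, 0))
  expect_lt(max(abs(depolarization_field(fu, 45))), 1e-20)
  # open-circuit mode depolarizes the mean
  Eo <- depolarization_field(fu, 45, kzero_mode = "open")
  expect_equal(Eo[1, 1, 1], -0.1 / (eps0 * 45), tolerance = 1e-12)
})

test_that("energy terms match closed forms on single-mode and uniform fields", {
  g <- simulation_grid(c(32, 32), spacing = 1e-9)
  cfg <- tdgl_config("btz", 273)
  # single Fourier mode P2(x): gradient term is (1/2) G44 k^2 <P2^2>
  amp <- 0.1
  k1 <- 2 * pi / (32 * 1e-9)
  P <- array(0, dim = c(32, 32, 3))
  P[, , 2] <- matrix(rep(amp * sin(2 * pi * (0:31) / 32), times = 32),
                     32, 32)
  f <- pyrofield:::new_polarization_field(g, P, 273, 1L)
  en <- total_free_energy(f, cfg)
  expect_equal(en$gradient, 0.5 * cfg$G44 * k1^2 * amp^2 / 2,
               tolerance = 1e-12)
  # uniform field: no gradient energy; elastic energy of the uniform
  # eigenstrain vanishes under zero mean stress
  fu <- initialize_field(g, "uniform", value = c(0, 0, 0.1),
                         temperature = 273)
  cfg_e <- tdgl_config("btz", 273, elastic_on = TRUE)
  en_u <- total_free_energy(fu, cfg_e)
  expect_identical(en_u$gradient, 0)
  expect_equal(en_u$elastic, 0, tolerance = 1e-12)
  expect_equal(en_u$total, bulk_energy(c(0, 0, 0.1),
                                       coefficients_at("btz", 273)))
  # zero field has zero total energy
  f0 <- initialize_field(g, "uniform", value = c(0, 0, 0))
  expect_identical(total_free_energy(f0, cfg)$total, 0)
  # defect-field shape mismatch is an error
  cfg_d <- tdgl_config("btz", 273,
                       defect_field = make_defect_field(c(16, 16)))
  expect_error(total_free_energy(f0, cfg_d), "does not match grid")
})

test_that("cubic stiffness inversion matches the numeric matrix inverse", {
  s11 <- 9.1e-12; s12 <- -3.2e-10; s44 <- 8.2e-10
  st <- cubic_stiffness_from_compliance(s11, s12, s44)
  S <- matrix(s12, 3, 3); diag(S) <- s11
  Cn <- solve(S)
  expect_equal(st$c11, Cn[1, 1], tolerance = 1e-12)
  expect_equal(st$c12, Cn[1, 2], tolerance = 1e-12)
  expect_equal(st$c44, 1 / s44)
  expect_error(cubic_stiffness_from_compliance(1e-12, -0.5e-12, 1e-12),
               "ill-conditioned")
})

test_that("uniform-field TDGL trajectories match the 0-D ODE oracle", {
  cases <- list(list(mat = "btz", temps = c(273, 283, 293),
                     dt = 5e-6, steps = 20000L),
                list(mat = "bto", temps = c(298, 318, 338),
                     dt = 1e-6, steps = 20000L))
  g <- simulation_grid(c(8, 8))
  p0 <- c(0.02, 0, 0.05)
  for (cs in cases) {
    for (tk in cs$temps) {
      cfg <- tdgl_config(cs$mat, tk, dt = cs$dt)
      f <- initialize_field(g, "uniform", value = p0, temperature = tk)
      f1 <- evolve(f, cfg, cs$steps, check_every = 10000L)
      want <- ode_relax(cs$mat, tk, p0, cs$dt * cs$steps)
      got <- mean_polarization(f1)
      expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6,
                label = sprintf("0-D oracle mismatch (%s, %g K)",
                                cs$mat, tk))
    }
  }
})

test_that("P = 0 is an exact fixed point without applied or defect fields", {
  g <- simulation_grid(c(16, 16))
  f <- initialize_field(g, "uniform", value = c(0, 0, 0), temperature = 273)
  f1 <- evolve(f, tdgl_config("btz", 273), 50)
  expect_true(all(f1$P == 0))
  expect_identical(f1$step_count, 50L)
})

test_that("evolution is deterministic and divergence is caught", {
  cfg <- tdgl_config("btz", 273, dt = 0.05,
                     defect_field = make_defect_field(c(16, 16), seed = 4))
  f <- make_random_field(c(16, 16), amplitude = 0.02, seed = 4,
                         temperature = 273)
  a <- evolve(f, cfg, 200)
  b <- evolve(f, cfg, 200)
  expect_identical(serialize(a$P, NULL), serialize(b$P, NULL))
  # grossly unstable step must abort with advice, not return garbage
  cfg_bad <- tdgl_config("btz", 273, dt = 50)
  expect_error(evolve(f, cfg_bad, 200, check_every = 10L),
               "reduce dt")
})

test_that("free energy is a Lyapunov function under static fields", {
  bound <- tdgl_stability_dt(tdgl_config("btz", 273))
  dt <- bound / 2
  for (seed in 1:10) {
    cfg <- tdgl_config("btz", 273, dt = dt,
                       applied_field = c(2e5, 0, 0),
                       defect_field = make_defect_field(c(16, 16),
                                                       seed = seed))
    st <- make_random_field(c(16, 16), amplitude = 0.02, seed = seed,
                            temperature = 273)
    e_prev <- total_free_energy(st, cfg)$total
    for (i in 1:8) {
      st <- evolve(st, cfg, 25)
      e <- total_free_energy(st, cfg)$total
      expect_lte(e, e_prev + 1e-8 * abs(e_prev))
      e_prev <- e
    }
  }
})

test_that("relaxed 273 K states are multiphase ferroelectric nanodomains", {
  for (seed in 1:5) {
    cfg <- tdgl_config("btz", 273, dt = 0.05,
                       defect_field = make_defect_field(c(128, 128),
                                                       seed = seed))
    st <- evolve(make_random_field(c(128, 128), amplitude = 0.02,
                                   seed = seed, temperature = 273),
                 cfg, 5000)
    vm <- classify_field(st)
    fr <- phase_fractions(vm)
    expect_lt(fr$fractions[["para"]], 0.5)
    expect_gte(length(unique(vm$labels[vm$labels != "para"])), 2L)
  }
})

test_that("halving the cell size barely changes a relaxed wall's energy", {
  wall_energy <- function(nx, dx) {
    g <- simulation_grid(c(nx, 8), spacing = dx)
    P <- array(0, dim = c(nx, 8, 3))
    # charge-neutral 180-degree wall: P3 reverses along x
    P[, , 3] <- matrix(rep(ifelse(seq_len(nx) <= nx / 2, 0.2, -0.2), 8),
                       nx, 8)
    f <- pyrofield:::new_polarization_field(g, P, 273, 1L)
    cfg <- tdgl_config("btz", 273, dt = 0.05)
    total_free_energy(evolve(f, cfg, 3000), cfg)$total
  }
  e_coarse <- wall_energy(64, 1e-9)
  e_fine <- wall_energy(128, 0.5e-9)
  expect_lt(abs(e_fine - e_coarse) / abs(e_coarse), 0.02)
})

test_that("hysteresis sweep is triangular, closed and physically sensible", {
  cfg <- tdgl_config("btz", 273, dt = 0.05)
  f <- evolve(make_random_field(c(32, 32), amplitude = 0.02, seed = 11,
                                temperature = 273), cfg, 800)
  loop <- run_hysteresis(f, cfg, component = 1, max_field = 4e6,
                         n_steps = 6, equilibration_steps = 250)
  lp <- loop[loop$branch != "virgin", ]
  expect_identical(lp$field[1], lp$field[nrow(lp)])  # closed in field
  psat <- max(abs(lp$polarization))
  # loop closes in polarization too
  expect_lt(abs(lp$polarization[1] - lp$polarization[nrow(lp)]) / psat,
            0.02)
  # antisymmetry (E, P) -> (-E, -P) between the two branches
  de <- lp[lp$branch == "descending", ]
  as_ <- lp[lp$branch == "ascending", ]
  m <- match(round(-as_$field, 6), round(de$field, 6))
  expect_lt(max(abs(as_$polarization + de$polarization[m]), na.rm = TRUE) /
            psat, 0.02)
  # saturation branch approaches the Landau single-domain Ps
  ps_t <- minimize_phase("T", coefficients_at("btz", 273))$total_Ps
  expect_lt(abs(psat - ps_t) / ps_t, 0.05)
  # remanent polarization and coercivity exist: P(0) on the descending
  # branch stays high, and the branch crosses zero at a negative field
  expect_gt(de$polarization[de$field == 0], 0.5 * psat)
})

test_that("a sub-coercive minor loop is nearly reversible", {
  g <- simulation_grid(c(16, 16))
  fu <- initialize_field(g, "uniform", value = c(0.2003, 0, 0),
                         temperature = 273)
  loop <- run_hysteresis(fu, tdgl_config("btz", 273, dt = 0.05),
                         component = 1, max_field = 2e5, n_steps = 4,
                         equilibration_steps = 400)
  lp <- loop[loop$branch != "virgin", ]
  area <- abs(sum(diff(lp$field) *
                  (head(lp$polarization, -1) + tail(lp$polarization, -1)) /
                  2))
  # compare with the area scale of a full switching loop at this amplitude
  full_scale <- 4 * 2e5 * max(abs(lp$polarization))
  expect_lt(area / full_scale, 0.02)
})
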