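test_that("coefficient evaluation follows the linear-in-T parameterization", {
  co293 <- coefficients_at("btz", 293)
  expect_identical(co293$alpha1, 0)

  co333 <- coefficients_at("btz", 333)
  expect_identical(co333$alpha11, 0)
  expect_equal(co333$alpha111, 2.61e9)

  co303 <- coefficients_at("btz", 303)
  expect_equal(co303$alpha1, 3.11e6)

  # temperature-independent coefficients never change
  expect_identical(co293$alpha12, co333$alpha12)
  expect_identical(co293$alpha112, co333$alpha112)
  expect_identical(co293$alpha123, co333$alpha123)
  # the temperature-dependent ones differ between two temperatures
  expect_false(co293$alpha1 == co333$alpha1)
  expect_false(co293$alpha11 == co333$alpha11)
  expect_false(co293$alpha111 == co333$alpha111)
})

test_that("unknown materials and bad temperatures are configuration errors", {
  expect_error(coefficients_at("unobtainium", 300), "available sets")
  expect_error(coefficients_at("btz", -10), "positive")
  expect_setequal(list_materials(), c("btz", "bto"))
})

test_that("bulk energy has full cubic symmetry and vanishes at the origin", {
  co <- coefficients_at("btz", 285)
  expect_identical(bulk_energy(c(0, 0, 0), co), 0)
  set.seed(42)
  P <- matrix(stats::runif(300, -0.3, 0.3), ncol = 3)
  f0 <- bulk_energy(P, co)
  for (g in signed_permutations()) {
    Pg <- sweep(P[, g$perm, drop = FALSE], 2, g$sign, `*`)
    expect_equal(bulk_energy(Pg, co), f0, tolerance = 1e-12)
  }
})

test_that("phase minima are stationary points of the bulk energy", {
  co <- coefficients_at("btz", 273)
  for (ph in c("T", "O", "R")) {
    m <- minimize_phase(ph, co)
    v <- phase_vector(m)
    h <- 1e-7
    dir <- v / sqrt(sum(v^2))
    deriv <- (bulk_energy(v + h * dir, co) -
              bulk_energy(v - h * dir, co)) / (2 * h)
    scale <- abs(bulk_energy(v, co)) / m$total_Ps
    expect_lt(abs(deriv) / scale, 1e-6)
    expect_equal(m$total_Ps,
                 m$component_magnitude * sqrt(c(T = 1, O = 2, R = 3)[[ph]]))
  }
})

test_that("analytic minimization matches a dense 1-D grid search", {
  set.seed(7)
  temps <- stats::runif(20, 260, 400)
  for (tk in temps) {
    co <- coefficients_at("btz", tk)
    for (ph in c("T", "O", "R")) {
      m <- minimize_phase(ph, co)
      gs <- grid_search_min(ph, co)
      e_scale <- max(abs(c(m$energy_density, gs$energy, 1e-9)))
      expect_lt(abs(m$energy_density - gs$energy) / e_scale, 1e-3)
      expect_lt(abs(m$component_magnitude - gs$p), 1e-3)
    }
  }
})

test_that("high temperature is paraelectric and 273 K favours R over T", {
  co500 <- coefficients_at("btz", 500)
  for (ph in c("T", "O", "R")) {
    m <- minimize_phase(ph, co500)
    expect_identical(m$phase, "paraelectric")
    expect_identical(m$total_Ps, 0)
    expect_identical(m$energy_density, 0)
  }
  co273 <- coefficients_at("btz", 273)
  expect_lte(minimize_phase("R", co273)$energy_density,
             minimize_phase("T", co273)$energy_density)
})

test_that("the Ps-T curve is consistent with pointwise minimization", {
  temps <- seq(250, 400, by = 5)
  curve <- stable_phase_diagram("btz", temps)
  expect_identical(curve$temperature, temps)
  expect_true(all(curve$ps >= 0))
  # endpoints reproduce minimize_phase pointwise
  for (i in c(1L, nrow(curve))) {
    co <- coefficients_at("btz", curve$temperature[i])
    mins <- lapply(c("T", "O", "R"), minimize_phase, coeffs = co)
    energies <- vapply(mins, `[[`, numeric(1), "energy_density")
    if (all(energies >= 0)) {
      expect_identical(curve$ps[i], 0)
    } else {
      expect_equal(curve$ps[i], mins[[which.min(energies)]]$total_Ps)
    }
  }
  # paraelectric above the last ferroelectric temperature
  last_fe <- max(which(curve$ps > 0))
  expect_true(all(curve$ps[seq_along(curve$ps) > last_fe] == 0))
  # Ps non-increasing at and above the steepest drop
  drop <- which.min(diff(curve$ps))
  expect_true(all(diff(curve$ps)[drop:(nrow(curve) - 1)] <= 1e-12))
})

test_that("a material with positive quadratic and quartic terms is all-paraelectric", {
  cfg <- list(material_id = "stub",
              description = "all-positive stub",
              coefficients = list(
                alpha1 = list(slope = 0, T_ref = 0, offset = 1e6),
                alpha11 = list(slope = 0, T_ref = 0, offset = 1e8),
                alpha12 = list(slope = 0, T_ref = 0, offset = 1e8),
                alpha111 = list(slope = 0, T_ref = 0, offset = 1e9),
                alpha112 = list(slope = 0, T_ref = 0, offset = 1e9),
                alpha123 = list(slope = 0, T_ref = 0, offset = 1e9)))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  curve <- stable_phase_diagram(path, seq(260, 400, 20))
  expect_true(all(curve$phase == "paraelectric"))
  expect_true(all(curve$ps == 0))
})

test_that("finite-difference pyroelectric coefficient recovers analytic slopes", {
  tt <- seq(280, 320, 2)
  # constant
  rho0 <- pyroelectric_coefficient(data.frame(temperature = tt, ps = 0.2))
  expect_true(all(rho0$rho == 0))
  # linear: exact everywhere including one-sided ends
  lin <- pyroelectric_coefficient(
    data.frame(temperature = tt, ps = 0.5 - 1e-3 * tt))
  expect_equal(lin$rho, rep(-1e-3 * 1e6, length(tt)), tolerance = 1e-10)
  # quadratic: central differences are exact at interior points
  quad <- pyroelectric_coefficient(
    data.frame(temperature = tt, ps = 1e-5 * (tt - 300)^2))
  interior <- 2:(length(tt) - 1)
  expect_equal(quad$rho[interior], 2e-5 * (tt[interior] - 300) * 1e6,
               tolerance = 1e-10)
  expect_error(
    pyroelectric_coefficient(
      data.frame(temperature = c(1, 2, 4), ps = c(1, 1, 1))),
    "uniformly spaced")
})

test_that("the |rho| peak sits at the steepest Ps drop", {
  curve <- stable_phase_diagram("btz", seq(250, 400, 1))
  rho <- pyroelectric_coefficient(curve)
  steep <- which.min(diff(curve$ps))
  peak <- which.max(abs(rho$rho))
  expect_lte(abs(rho$temperature[peak] -
                 mean(curve$temperature[steep + 0:1])), 1)
  expect_lt(rho$rho[peak], 0)  # Ps falls with T at the transition
  expect_gt(rho_magnitude(rho)$rho[peak], 0)
})

test_that("enhancement arithmetic", {
  expect_equal(enhancement_percent(900, 300), 200)
  expect_equal(enhancement_percent(450, 450), 0)
  expect_equal(enhancement_percent(-450, 450), 0)  # magnitudes compared
  expect_error(enhancement_percent(100, 0), "nonzero")
})

test_that("barrier profiles end exactly at the phase minima", {
  co <- coefficients_at("btz", 273)
  for (pair in list(c("T", "O"), c("O", "R"), c("T", "R"))) {
    for (mode in c("linear", "arc")) {
      pr <- barrier_profile(pair[1], pair[2], co, mode = mode)
      ma <- minimize_phase(pair[1], co)
      mb <- minimize_phase(pair[2], co)
      expect_equal(pr$energy_density[1], ma$energy_density,
                   tolerance = 1e-9)
      expect_equal(pr$energy_density[length(pr$energy_density)],
                   mb$energy_density, tolerance = 1e-9)
      expect_equal(pr$gap, abs(ma$energy_density - mb$energy_density))
      expect_gte(pr$barrier_a, 0)
      expect_gte(pr$barrier_b, 0)
    }
  }
  # identical phases give a flat profile with zero barrier
  flat <- barrier_profile("R", "R", co)
  expect_lt(diff(range(flat$energy_density)),
            1e-9 * abs(flat$endpoints[[1]]$energy_density))
  expect_lt(flat$barrier_a, 1e-9 * abs(flat$endpoints[[1]]$energy_density))
  # no path to/from a paraelectric phase
  expect_error(barrier_profile("T", "O", coefficients_at("btz", 400)),
               "no rotation path")
})

test_that("inter-phase energy gaps shrink on heating from 298 K to 313 K", {
  gaps <- function(tk) {
    co <- coefficients_at("btz", tk)
    e <- unname(vapply(c("T", "O", "R"),
                       function(ph) minimize_phase(ph, co)$energy_density,
                       numeric(1)))
    c(TO = abs(e[1] - e[2]), OR = abs(e[2] - e[3]), TR = abs(e[1] - e[3]))
  }
  g298 <- gaps(298)
  g313 <- gaps(313)
  expect_true(all(g313 <= g298))
  expect_true(any(g313 < g298))
  # unit converters round-trip
  expect_equal(j_cm3_to_j_m3(j_m3_to_j_cm3(g298[["TR"]])), g298[["TR"]])
})
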