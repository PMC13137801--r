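#' Seeded synthetic-fixture generators
#'
#' Every stochastic input the pipeline needs is generated from a single
#' integer seed. Seeds expand through a fixed splitting scheme — generator
#' `k` uses `set.seed((seed * 1009 + k * 7919) mod (2^31 - 1))` — so adding
#' a new fixture kind never perturbs the streams of existing ones, and the
#' same (kind, parameters, seed) always reproduces byte-identical output.
#'
#' @name synthetic_fixtures
#' @keywords internal
NULL

fixture_stream_ids <- c(random_field = 1L, defect_field = 2L,
                        composite_variants = 3L, spectrum = 4L,
                        protocol = 5L)

fixture_seed <- function(seed, kind) {
  offset <- fixture_stream_ids[[kind]]
  as.integer((as.numeric(seed) * 1009 + offset * 7919) %% 2147483647)
}

#' Random initial polarization field
#'
#' I.i.d. zero-mean uniform components in `[-amplitude, amplitude]` — the
#' random multiphase starting state for the phase-field relaxations.
#'
#' @param shape Grid shape (length 2 or 3).
#' @param amplitude Component amplitude, C/m^2 (>= 0).
#' @param seed Integer seed.
#' @param temperature Temperature tag, K.
#' @param spacing Cell size, m.
#' @return A `polarization_field`.
#' @export
make_random_field <- function(shape, amplitude = 0.01, seed = 1L,
                              temperature = 298, spacing = 1e-9) {
  grid <- simulation_grid(shape, spacing)
  initialize_field(grid, "random", amplitude = amplitude,
                   seed = fixture_seed(seed, "random_field"),
                   temperature = temperature)
}

#' Static random defect field
#'
#' A fraction `concentration` of cells, chosen uniformly without
#' replacement, carries a static local electric field with independent
#' zero-mean Gaussian components of standard deviation `sigma_E`; all other
#' cells are zero. This is the `E_RF` random-field term modelling point
#' defects.
#'
#' @param shape Grid shape.
#' @param concentration Fraction of defect cells in \[0, 1\] (default 0.05).
#' @param sigma_E Component standard deviation, V/m (default 5e5).
#' @param seed Integer seed.
#' @return Array (shape x 3) in V/m, suitable for `tdgl_config()`'s
#'   `defect_field`.
#' @export
make_defect_field <- function(shape, concentration = 0.05, sigma_E = 5e5,
                              seed = 1L) {
  stopifnot(concentration >= 0, concentration <= 1, sigma_E >= 0)
  shape <- as.integer(shape)
  n <- prod(shape)
  set.seed(fixture_seed(seed, "defect_field"))
  n_occ <- round(concentration * n)
  occ <- sample.int(n, n_occ)
  E <- matrix(0, n, 3L)
  if (n_occ > 0) {
    E[occ, ] <- stats::rnorm(3L * n_occ, 0, sigma_E)
  }
  array(E, dim = c(shape, 3L))
}

#' Composite variant field with known ground truth
#'
#' Assigns each cell a phase according to the requested fractions (largest-
#' remainder apportionment, so requested fractions with integer cell counts
#' are recovered exactly), a variant direction drawn uniformly within that
#' phase, and magnitude `Ps_magnitude` (paraelectric cells are zero).
#'
#' @param shape Grid shape.
#' @param fractions Named numeric over `para`, `T`, `O`, `R`; must sum to 1
#'   (tolerance 1e-9).
#' @param Ps_magnitude Polarization magnitude, C/m^2.
#' @param seed Integer seed.
#' @param temperature Temperature tag, K.
#' @return List `field` (a `polarization_field`) and `truth` (a
#'   `variant_map` of the generating labels).
#' @export
make_composite_variant_field <- function(shape,
                                         fractions = c(para = 0.25,
                                                       T = 0.25, O = 0.25,
                                                       R = 0.25),
                                         Ps_magnitude = 0.2, seed = 1L,
                                         temperature = 298) {
  stopifnot(all(c("para", "T", "O", "R") %in% names(fractions)))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1 (got ", sum(fractions), ")",
         call. = FALSE)
  }
  grid <- simulation_grid(shape)
  n <- n_cells(grid)
  fr <- fractions[c("para", "T", "O", "R")]
  counts <- floor(fr * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(fr * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  set.seed(fixture_seed(seed, "composite_variants"))
  phase_of_cell <- sample(rep(c("para", "T", "O", "R"), counts))
  vars <- enumerate_variants()
  labels <- character(n)
  P <- matrix(0, n, 3L)
  for (ph in c("T", "O", "R")) {
    cells <- which(phase_of_cell == ph)
    if (length(cells) == 0L) next
    pool <- which(vars$phase == ph)
    pick <- pool[sample.int(length(pool), length(cells), replace = TRUE)]
    labels[cells] <- vars$label[pick]
    P[cells, ] <- as.matrix(vars[pick, c("x", "y", "z")]) * Ps_magnitude
  }
  labels[phase_of_cell == "para"] <- "para"
  field <- new_polarization_field(
    grid, array(P, dim = c(grid$shape, 3L)), temperature,
    as.integer(seed))
  truth <- structure(
    list(grid = grid, labels = array(labels, dim = grid$shape),
         threshold = Ps_magnitude / 2, angle_tolerance = 15),
    class = "variant_map")
  list(field = field, truth = truth)
}

#' Synthetic direct/indirect-gap absorbance spectrum
#'
#' Above the gap the absorbance follows the ideal band-edge law — for a
#' direct gap `alpha = sqrt(hv - Eg)/hv`, so the Tauc signal
#' `(alpha hv)^2 = hv - Eg` is exactly linear — and is zero below it
#' (optionally with an exponential Urbach tail). Multiplicative Gaussian
#' noise of relative standard deviation `noise_sd` emulates measured
#' diffuse-reflectance edges.
#'
#' @param Eg Bandgap, eV (must lie inside the energy grid).
#' @param exponent `"direct"` or `"indirect"`.
#' @param noise_sd Relative noise standard deviation (default 0).
#' @param seed Integer seed.
#' @param energies Photon-energy grid, eV (default 2.5-4.0 eV, 301 points).
#' @param urbach_width Optional sub-gap exponential tail width, eV
#'   (default 0 = off).
#' @return An [absorbance_spectrum()].
#' @export
make_spectrum <- function(Eg, exponent = c("direct", "indirect"),
                          noise_sd = 0, seed = 1L,
                          energies = seq(2.5, 4.0, length.out = 301),
                          urbach_width = 0) {
  exponent <- match.arg(exponent)
  stopifnot(Eg > min(energies), Eg < max(energies), noise_sd >= 0)
  above <- energies > Eg
  alpha <- numeric(length(energies))
  pow <- if (exponent == "direct") 0.5 else 2
  alpha[above] <- (energies[above] - Eg)^pow / energies[above]
  if (urbach_width > 0) {
    edge <- (1e-6)^pow / Eg  # continuity scale at the edge
    alpha[!above] <- alpha_edge_tail(energies[!above], Eg, urbach_width,
                                     pow)
  }
  if (noise_sd > 0) {
    set.seed(fixture_seed(seed, "spectrum"))
    alpha <- alpha * pmax(0, 1 + stats::rnorm(length(alpha), 0, noise_sd))
  }
  absorbance_spectrum(energies, pmax(alpha, 0))
}

alpha_edge_tail <- function(e, Eg, width, pow) {
  # exponential Urbach tail matched to the just-above-gap magnitude
  a0 <- (0.05)^pow / Eg
  a0 * exp((e - Eg) / width)
}
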