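#' Periodic simulation grid
#'
#' A periodic 2D or 3D grid for the phase-field solver. Every axis must have
#' an even number of cells (>= 8) so the Fourier spectral operators are
#' symmetric; 2D fields still carry 3-component polarization vectors with
#' d/dz = 0.
#'
#' @param shape Integer vector of length 2 or 3, cells per axis.
#' @param spacing Physical cell size in metres (default 1e-9, i.e. 1 nm,
#'   which resolves the ~3 nm domain-wall width set by
#'   `sqrt(G110 / |alpha1|)` for the shipped coefficient sets).
#' @return A `simulation_grid` object.
#' @export
simulation_grid <- function(shape, spacing = 1e-9) {
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% c(2L, 3L), is.numeric(spacing),
            length(spacing) == 1L)
  if (any(shape < 8L) || any(shape %% 2L != 0L)) {
    stop("all grid dimensions must be even and >= 8; got ",
         paste(shape, collapse = "x"), call. = FALSE)
  }
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  structure(list(dimensions = length(shape), shape = shape,
                 spacing = spacing, periodic = TRUE),
            class = "simulation_grid")
}

n_cells <- function(grid) prod(grid$shape)

# internal constructor for a polarization field state
new_polarization_field <- function(grid, P, temperature, seed,
                                   step_count = 0L) {
  stopifnot(inherits(grid, "simulation_grid"),
            identical(dim(P), c(grid$shape, 3L)))
  structure(list(grid = grid, P = P, temperature = temperature,
                 seed = seed, step_count = step_count),
            class = "polarization_field")
}

#' Initialize a polarization field
#'
#' @param grid A [simulation_grid()].
#' @param mode `"random"` (i.i.d. zero-mean uniform components in
#'   `[-amplitude, amplitude]`), `"uniform"` (every cell set to `value`), or
#'   `"variant-mix"` (each cell assigned a uniformly drawn ferroelectric
#'   variant direction scaled to `amplitude`).
#' @param amplitude Component amplitude in C/m^2 (random / variant-mix).
#' @param seed Integer seed; identical seeds give bit-identical fields.
#' @param temperature Temperature tag in K (default 298).
#' @param value Length-3 polarization for `mode = "uniform"`.
#' @return A `polarization_field`.
#' @export
initialize_field <- function(grid, mode = c("random", "uniform",
                                            "variant-mix"),
                             amplitude = 0.01, seed = 1L,
                             temperature = 298, value = c(0, 0, 0)) {
  mode <- match.arg(mode)
  stopifnot(amplitude >= 0)
  n <- n_cells(grid)
  P <- switch(mode,
    random = {
      set.seed(seed)
      array(stats::runif(3 * n, -amplitude, amplitude), dim = c(grid$shape, 3L))
    },
    uniform = {
      stopifnot(length(value) == 3L)
      array(rep(value, each = n), dim = c(grid$shape, 3L))
    },
    `variant-mix` = {
      set.seed(seed)
      dirs <- enumerate_variants()
      idx <- sample.int(nrow(dirs), n, replace = TRUE)
      array(c(dirs$x[idx], dirs$y[idx], dirs$z[idx]) * amplitude,
            dim = c(grid$shape, 3L))
    })
  new_polarization_field(grid, P, temperature, as.integer(seed))
}

# Extract component i of a field array as a shape-dim array
field_component <- function(P, i) {
  nd <- length(dim(P))
  if (nd == 3L) P[, , i] else P[, , , i]
}

set_field_component <- function(P, i, value) {
  nd <- length(dim(P))
  if (nd == 3L) P[, , i] <- value else P[, , , i] <- value
  P
}

#' Spatial mean of each polarization component
#' @param field A `polarization_field`.
#' @return Length-3 vector (C/m^2).
#' @export
mean_polarization <- function(field) {
  apply(matrix(field$P, ncol = 3L), 2L, mean)
}

#' Save / load a polarization field as plain text
#'
#' Long-format CSV (`x,y[,z],p1,p2,p3`) plus a JSON sidecar
#' (`<path>.meta.json`) holding grid spacing, temperature, seed and step
#' count, so states round-trip exactly through text files.
#'
#' @param field A `polarization_field`.
#' @param path CSV path.
#' @return `write_field_csv` returns `path` invisibly; `read_field_csv`
#'   returns the `polarization_field`.
#' @export
write_field_csv <- function(field, path) {
  grid <- field$grid
  idx <- as.matrix(expand.grid(lapply(grid$shape, seq_len)))
  colnames(idx) <- c("x", "y", "z")[seq_len(grid$dimensions)]
  df <- data.frame(idx, p1 = as.vector(field_component(field$P, 1)),
                   p2 = as.vector(field_component(field$P, 2)),
                   p3 = as.vector(field_component(field$P, 3)))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(shape = grid$shape, spacing = grid$spacing,
         temperature = field$temperature, seed = field$seed,
         step_count = field$step_count),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(path)
  grid <- simulation_grid(meta$shape, as.numeric(meta$spacing))
  P <- array(c(df$p1, df$p2, df$p3), dim = c(grid$shape, 3L))
  new_polarization_field(grid, P, as.numeric(meta$temperature),
                         as.integer(meta$seed),
                         as.integer(meta$step_count))
}

#' @export
print.polarization_field <- function(x, ...) {
  cat("polarization field ", paste(x$grid$shape, collapse = "x"),
      " (", x$grid$dimensions, "D), T = ", x$temperature, " K, seed ",
      x$seed, ", ", x$step_count, " steps\n", sep = "")
  mp <- mean_polarization(x)
  cat(sprintf("  mean P = (%.4g, %.4g, %.4g) C/m^2\n", mp[1], mp[2], mp[3]))
  invisible(x)
}
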