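#' Canonical ferroelectric variant directions of the cubic parent
#'
#' The 26 symmetry-equivalent polarization directions: 6 tetragonal <100>,
#' 12 orthorhombic <110> and 8 rhombohedral <111> unit vectors. Canonical
#' order (used for reproducible tie-breaks): T, then O, then R, each block
#' sorted lexicographically by (x, y, z) components.
#'
#' @return Data frame with columns `label` (T1..T6, O1..O12, R1..R8),
#'   `phase` (T/O/R) and unit-vector components `x`, `y`, `z`.
#' @export
enumerate_variants <- function() {
  sgn <- c(-1, 1)
  t_dirs <- unique(do.call(rbind, lapply(1:3, function(i) {
    out <- matrix(0, 2, 3); out[, i] <- sgn; out
  })))
  o_dirs <- do.call(rbind, lapply(list(c(1, 2), c(1, 3), c(2, 3)),
    function(ij) {
      g <- expand.grid(a = sgn, b = sgn)
      out <- matrix(0, 4, 3)
      out[, ij[1]] <- g$a; out[, ij[2]] <- g$b
      out / sqrt(2)
    }))
  g <- expand.grid(x = sgn, y = sgn, z = sgn)
  r_dirs <- as.matrix(g) / sqrt(3)
  lex_order <- function(m) order(m[, 1], m[, 2], m[, 3])
  t_dirs <- t_dirs[lex_order(t_dirs), , drop = FALSE]
  o_dirs <- o_dirs[lex_order(o_dirs), , drop = FALSE]
  r_dirs <- r_dirs[lex_order(r_dirs), , drop = FALSE]
  dirs <- rbind(t_dirs, o_dirs, r_dirs)
  data.frame(
    label = c(paste0("T", 1:6), paste0("O", 1:12), paste0("R", 1:8)),
    phase = rep(c("T", "O", "R"), c(6L, 12L, 8L)),
    x = dirs[, 1], y = dirs[, 2], z = dirs[, 3],
    stringsAsFactors = FALSE)
}

#' Classify polarization vectors into phase variants
#'
#' A cell is paraelectric (`"para"`) when `|P| < threshold`; otherwise it is
#' assigned the variant whose unit direction maximizes the cosine with P
#' (nearest-direction rule; the assignment is invariant under positive
#' scaling of P). Exact ties resolve to the earliest variant in the
#' canonical order of [enumerate_variants()].
#'
#' @param P Length-3 vector or n-by-3 matrix of polarizations (C/m^2).
#' @param threshold |P| cutoff in C/m^2 (>= 0).
#' @param angle_tolerance Advisory angle (degrees): cells whose polarization
#'   deviates from the assigned direction by more than this are flagged in
#'   the `uncertain` attribute (assignment itself always succeeds).
#' @return Character vector of labels (`"para"`, `"T1"`...`"R8"`), with a
#'   logical `uncertain` attribute.
#' @export
classify_cell <- function(P, threshold = 0.01, angle_tolerance = 15) {
  stopifnot(threshold >= 0)
  if (is.null(dim(P))) P <- matrix(P, ncol = 3L)
  vars <- enumerate_variants()
  dirs <- t(as.matrix(vars[, c("x", "y", "z")]))  # 3 x 26
  norms <- sqrt(rowSums(P^2))
  cosines <- (P %*% dirs) / pmax(norms, .Machine$double.xmin)
  best <- max.col(cosines, ties.method = "first")
  labels <- vars$label[best]
  labels[norms < threshold] <- "para"
  best_cos <- cosines[cbind(seq_along(best), best)]
  uncertain <- labels != "para" &
    best_cos < cos(angle_tolerance * pi / 180)
  attr(labels, "uncertain") <- uncertain
  labels
}

#' Variant map of a solver state
#'
#' Classifies every cell of a polarization field. The default threshold is
#' 5% of the largest single-domain spontaneous polarization of the
#' material's globally stable phase at the field's temperature (separates
#' polar region interiors from walls); for temperatures where the model is
#' paraelectric a fixed 0.01 C/m^2 floor is used.
#'
#' @param field A `polarization_field`.
#' @param material Material id used for the default threshold (default
#'   `"btz"`).
#' @param threshold Override the |P| cutoff (C/m^2).
#' @param angle_tolerance Degrees, see [classify_cell()].
#' @return A `variant_map`: list with `grid`, `labels` (array of cell
#'   labels), `threshold`, `angle_tolerance`.
#' @export
classify_field <- function(field, material = "btz", threshold = NULL,
                           angle_tolerance = 15) {
  stopifnot(inherits(field, "polarization_field"))
  if (is.null(threshold)) {
    co <- coefficients_at(material, field$temperature)
    ps <- vapply(c("T", "O", "R"),
                 function(ph) minimize_phase(ph, co)$total_Ps, numeric(1))
    threshold <- if (max(ps) > 0) 0.05 * max(ps) else 0.01
  }
  labels <- classify_cell(matrix(field$P, ncol = 3L), threshold,
                          angle_tolerance)
  structure(
    list(grid = field$grid,
         labels = array(as.character(labels), dim = field$grid$shape),
         threshold = threshold, angle_tolerance = angle_tolerance),
    class = "variant_map")
}

#' Phase fractions and variant counts of a variant map
#'
#' @param map A `variant_map` (or a character vector/array of labels).
#' @return A `phase_fraction_report`: `fractions` (named numeric over para,
#'   T, O, R; sums to 1) and `variant_counts` (named integer over the 27
#'   labels, summing to the cell count).
#' @export
phase_fractions <- function(map) {
  labels <- if (inherits(map, "variant_map")) map$labels else map
  labels <- as.character(labels)
  all_labels <- c("para", enumerate_variants()$label)
  counts <- table(factor(labels, levels = all_labels))
  phase_of <- c(para = "para", stats::setNames(enumerate_variants()$phase,
                                               enumerate_variants()$label))
  phase_counts <- tapply(as.integer(counts), phase_of[names(counts)], sum)
  phases <- c("para", "T", "O", "R")
  phase_counts <- as.numeric(phase_counts[phases])
  phase_counts[is.na(phase_counts)] <- 0
  names(phase_counts) <- phases
  structure(
    list(fractions = phase_counts / length(labels),
         variant_counts = counts,
         n_cells = length(labels)),
    class = "phase_fraction_report")
}

#' @export
print.phase_fraction_report <- function(x, ...) {
  cat("phase fractions over", x$n_cells, "cells:\n")
  for (ph in names(x$fractions)) {
    cat(sprintf("  %-5s %6.2f%%\n", ph, 100 * x$fractions[[ph]]))
  }
  invisible(x)
}
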