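#' Electrode potential on the NHE scale from XPS quantities
#'
#' `E_NHE/V = phi + E_f - 4.44`, with `phi` the work function (eV), `E_f`
#' the valence-band XPS edge relative to the Fermi level (eV), and 4.44 eV
#' the absolute potential of the normal hydrogen electrode. One-electron
#' levels, so eV and V magnitudes are identified.
#'
#' @param phi Work function, eV (> 0).
#' @param ef VB-XPS edge, eV.
#' @return Potential in V vs NHE.
#' @export
nhe_from_xps <- function(phi, ef) {
  stopifnot(is.numeric(phi), is.numeric(ef))
  if (any(phi <= 0)) stop("work function must be positive", call. = FALSE)
  phi + ef - 4.44
}

#' Conduction-band minimum from the valence-band maximum and bandgap
#'
#' `CBM = VBM - Eg` on the NHE scale (more negative CBM = stronger
#' reductant).
#'
#' @param vbm_nhe VBM in V vs NHE.
#' @param bandgap Optical bandgap in eV (> 0).
#' @return CBM in V vs NHE.
#' @examples
#' cbm_from_vbm(1.99, 3.15)  # -1.16 V
#' @export
cbm_from_vbm <- function(vbm_nhe, bandgap) {
  stopifnot(is.numeric(vbm_nhe), is.numeric(bandgap))
  if (any(bandgap <= 0)) stop("bandgap must be positive", call. = FALSE)
  vbm_nhe - bandgap
}

#' Band alignment record
#'
#' @param vbm_nhe VBM in V vs NHE (give either this or `work_function` +
#'   `vb_edge`).
#' @param bandgap Bandgap in eV (> 0).
#' @param work_function,vb_edge Optional XPS route via [nhe_from_xps()].
#' @return A `band_alignment`: `vbm_nhe`, `cbm_nhe`, `bandgap`,
#'   `work_function`, `vb_edge`.
#' @export
band_alignment <- function(vbm_nhe = NULL, bandgap,
                           work_function = NULL, vb_edge = NULL) {
  if (is.null(vbm_nhe)) {
    if (is.null(work_function) || is.null(vb_edge)) {
      stop("give either vbm_nhe or both work_function and vb_edge",
           call. = FALSE)
    }
    vbm_nhe <- nhe_from_xps(work_function, vb_edge)
  }
  stopifnot(bandgap > 0)
  structure(
    list(vbm_nhe = vbm_nhe, cbm_nhe = cbm_from_vbm(vbm_nhe, bandgap),
         bandgap = bandgap, work_function = work_function,
         vb_edge = vb_edge),
    class = "band_alignment")
}

#' Redox ladder for ROS half-reactions
#'
#' Default half-reactions and potentials (V vs NHE): oxygen reduction to
#' superoxide (-0.33 V, reduction), one-electron reduction of H2O2 to the
#' hydroxyl radical (+0.73 V, reduction), and surface hydroxide oxidation
#' to the hydroxyl radical (+1.5 V, oxidation). Extensible via `extra`.
#'
#' @param extra Optional data frame with columns `reaction`, `potential`,
#'   `type` (`"reduction"`/`"oxidation"`) appended to the defaults.
#' @return Data frame `reaction`, `potential` (V vs NHE), `type`.
#' @export
redox_ladder <- function(extra = NULL) {
  ladder <- data.frame(
    reaction = c("O2_to_superoxide", "H2O2_to_OH", "OH_to_OHradical"),
    potential = c(-0.33, 0.73, 1.5),
    type = c("reduction", "reduction", "oxidation"),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(all(c("reaction", "potential", "type") %in% names(extra)),
              all(extra$type %in% c("reduction", "oxidation")))
    ladder <- rbind(ladder, extra[, c("reaction", "potential", "type")])
  }
  ladder
}

#' ROS half-reaction feasibility from a band alignment
#'
#' A reduction is thermodynamically permitted when the CBM lies below
#' (more negative than) the half-reaction potential; an oxidation when the
#' VBM lies above (more positive than) it. Margins are positive where
#' permitted and change sign exactly at equality.
#'
#' @param alignment A [band_alignment()].
#' @param ladder A [redox_ladder()] data frame.
#' @return Data frame `reaction`, `potential`, `type`, `margin` (V),
#'   `feasible`.
#' @export
ros_feasibility <- function(alignment, ladder = redox_ladder()) {
  stopifnot(inherits(alignment, "band_alignment"))
  margin <- ifelse(ladder$type == "reduction",
                   ladder$potential - alignment$cbm_nhe,
                   alignment$vbm_nhe - ladder$potential)
  data.frame(ladder, margin = margin, feasible = margin > 0)
}

#' Absorbance spectrum container
#'
#' @param photon_energies Strictly increasing photon energies, eV.
#' @param absorbance Non-negative absorbance (arbitrary units).
#' @return An `absorbance_spectrum` data frame (`energy`, `absorbance`).
#' @export
absorbance_spectrum <- function(photon_energies, absorbance) {
  stopifnot(length(photon_energies) == length(absorbance),
            all(diff(photon_energies) > 0), all(absorbance >= 0))
  structure(data.frame(energy = photon_energies, absorbance = absorbance),
            class = c("absorbance_spectrum", "data.frame"))
}

#' Tauc bandgap extraction
#'
#' Builds the Tauc signal `(alpha * hv)^n` (n = 2 for a direct gap, 1/2 for
#' an indirect gap), finds the steepest linear region of the absorption
#' edge, fits a line and returns its x-intercept as the optical bandgap.
#' Window auto-selection: among all contiguous windows (width ~ the larger
#' of 8 points and a tenth of the spectrum) with linear R^2 >= 0.995, the
#' one with maximal slope is used; if none reaches 0.995, the top-slope
#' quartile of the rising edge is used instead, and if even that fits with
#' R^2 < 0.9 the extraction aborts with diagnostics. The result is
#' invariant under positive scaling of the absorbance.
#'
#' @param spectrum An [absorbance_spectrum()] (>= 20 points spanning the
#'   edge).
#' @param exponent `"direct"` (Tauc exponent n = 2, the default
#'   convention for this material family) or `"indirect"` (n = 1/2).
#' @param fit_window Optional explicit index range `c(i_lo, i_hi)` for the
#'   linear fit (for reproducibility).
#' @return Bandgap in eV, with attributes `window` (indices used), `r2` and
#'   `slope`.
#' @export
tauc_bandgap <- function(spectrum, exponent = c("direct", "indirect"),
                         fit_window = NULL) {
  exponent <- match.arg(exponent)
  stopifnot(is.data.frame(spectrum), nrow(spectrum) >= 20L)
  e <- spectrum$energy
  n <- if (exponent == "direct") 2 else 0.5
  y <- (spectrum$absorbance * e)^n
  npts <- length(e)
  fit_stats <- function(idx) {
    fit <- stats::lm.fit(cbind(1, e[idx]), y[idx])
    slope <- fit$coefficients[2]
    r2 <- 1 - sum(fit$residuals^2) /
      max(sum((y[idx] - mean(y[idx]))^2), .Machine$double.xmin)
    list(slope = slope, intercept = fit$coefficients[1], r2 = r2)
  }
  if (is.null(fit_window)) {
    w <- max(8L, ceiling(npts / 10))
    starts <- seq_len(npts - w + 1L)
    cands <- lapply(starts, function(s) {
      idx <- s:(s + w - 1L)
      c(fit_stats(idx), list(idx = idx))
    })
    ok <- vapply(cands, function(cc) cc$r2 >= 0.995 && cc$slope > 0,
                 logical(1))
    if (any(ok)) {
      best <- cands[ok][[which.max(vapply(cands[ok], `[[`, numeric(1),
                                          "slope"))]]
      idx <- best$idx
    } else {
      # fallback: top-slope quartile of the rising edge
      dy <- diff(y) / diff(e)
      thresh <- stats::quantile(dy[dy > 0], 0.75)
      idx <- which(c(dy, 0) >= thresh)
      idx <- sort(unique(c(idx, idx + 1L)))
      idx <- idx[idx <= npts]
      if (length(idx) < 3L) {
        stop("Tauc extraction failed: no rising linear region found",
             call. = FALSE)
      }
    }
  } else {
    idx <- fit_window[1]:fit_window[2]
  }
  st <- fit_stats(idx)
  if (st$r2 < 0.9 || st$slope <= 0) {
    stop("Tauc extraction failed: best linear window has R^2 = ",
         format(st$r2, digits = 3), " (slope ", format(st$slope,
         digits = 3), "); supply fit_window explicitly", call. = FALSE)
  }
  eg <- -st$intercept / st$slope
  structure(as.numeric(eg), window = range(idx), r2 = st$r2,
            slope = as.numeric(st$slope))
}
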