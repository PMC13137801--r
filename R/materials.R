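#' Material coefficient parameterizations
#'
#' Landau-Devonshire coefficient sets are shipped as JSON config files under
#' `inst/extdata/materials/`. Each of the six sextic coefficients is stored as
#' a `{slope, T_ref, offset}` triple and evaluated as
#' `slope * (T - T_ref) + offset` (temperature in kelvin, coefficients in SI:
#' C^-2 m^2 N, C^-4 m^6 N, C^-6 m^10 N).
#'
#' @param material Material id (e.g. `"btz"`, `"bto"`) or the path to a JSON
#'   config file with the same layout.
#' @return A `landau_material` object: the parameterization (not yet evaluated
#'   at a temperature).
#' @seealso [coefficients_at()]
#' @export
landau_material <- function(material) {
  if (inherits(material, "landau_material")) {
    return(material)
  }
  stopifnot(is.character(material), length(material) == 1L)
  path <- if (file.exists(material)) {
    material
  } else {
    system.file("extdata", "materials", paste0(tolower(material), ".json"),
                package = "pyrofield")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown material '", material, "'; available sets: ",
         paste(list_materials(), collapse = ", "), call. = FALSE)
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("alpha1", "alpha11", "alpha12", "alpha111", "alpha112", "alpha123")
  if (!all(needed %in% names(cfg$coefficients))) {
    stop("material config '", path, "' is missing coefficients: ",
         paste(setdiff(needed, names(cfg$coefficients)), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(material_id = cfg$material_id,
         description = cfg$description,
         coefficients = cfg$coefficients[needed]),
    class = "landau_material"
  )
}

#' List the material ids shipped with the package
#' @return Character vector of material ids.
#' @export
list_materials <- function() {
  files <- list.files(system.file("extdata", "materials", package = "pyrofield"),
                      pattern = "\\.json$")
  sub("\\.json$", "", files)
}

#' Evaluate Landau coefficients at a temperature
#'
#' Evaluates a material's per-coefficient linear-in-T parameterization at a
#' single temperature, yielding the six sextic free-energy coefficients in SI
#' units.
#'
#' @param material Material id, config path, or `landau_material` object.
#' @param temperature Temperature in kelvin (> 0).
#' @return A `landau_coefficients` object with fields `alpha1`, `alpha11`,
#'   `alpha12`, `alpha111`, `alpha112`, `alpha123`, `temperature`,
#'   `material_id`.
#' @examples
#' co <- coefficients_at("btz", 298)
#' co$alpha1  # 3.11e5 * (298 - 293)
#' @export
coefficients_at <- function(material, temperature) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature))
  if (temperature <= 0) {
    stop("temperature must be positive (kelvin); got ", temperature,
         call. = FALSE)
  }
  mat <- landau_material(material)
  ev <- lapply(mat$coefficients, function(tr) {
    tr$slope * (temperature - tr$T_ref) + tr$offset
  })
  structure(
    c(ev, list(temperature = temperature, material_id = mat$material_id)),
    class = "landau_coefficients"
  )
}

#' @export
print.landau_coefficients <- function(x, ...) {
  cat("Landau coefficients for '", x$material_id, "' at ", x$temperature,
      " K\n", sep = "")
  for (nm in c("alpha1", "alpha11", "alpha12", "alpha111", "alpha112",
               "alpha123")) {
    cat(sprintf("  %-8s %+.4e\n", nm, x[[nm]]))
  }
  invisible(x)
}
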