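#' Physical model of an encapsulated HDR line source
#'
#' Dimensions of a cylindrical HDR brachytherapy source. The dosimetrically
#' relevant quantity is the active length `L`; the remaining dimensions
#' document the capsule. All lengths are in cm. The default instance is the
#' IRAsource-HDR Ir-192 prototype (active length 3.5 mm, total length
#' 4.3 mm, core diameter 0.6 mm, external diameter 0.9 mm).
#'
#' @param active_length active (radioactive core) length, cm.
#' @param total_length overall encapsulated length, cm; must be >= active
#'   length.
#' @param active_core_diameter,external_diameter core / capsule outer
#'   diameter, cm.
#' @param capsule_thickness,distal_capsule_thickness radial / distal capsule
#'   wall thickness, cm.
#' @param name label carried through reports.
#' @return an object of class `source_model`.
#' @examples
#' src <- source_model()
#' src$active_length
#' @export
source_model <- function(active_length = 0.35,
                         total_length = 0.43,
                         active_core_diameter = 0.06,
                         external_diameter = 0.09,
                         capsule_thickness = 0.015,
                         distal_capsule_thickness = 0.025,
                         name = "IRAsource") {
  dims <- c(active_length = active_length, total_length = total_length,
            active_core_diameter = active_core_diameter,
            external_diameter = external_diameter,
            capsule_thickness = capsule_thickness,
            distal_capsule_thickness = distal_capsule_thickness)
  for (nm in names(dims)) check_scalar(dims[[nm]], nm, positive = TRUE)
  if (total_length < active_length)
    stop_domain("total_length must be >= active_length")
  structure(c(as.list(dims), list(name = name)), class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf("<source_model> %s: L = %.2f cm, total %.2f cm, ext. diam %.2f cm\n",
              x$name, x$active_length, x$total_length, x$external_diameter))
  invisible(x)
}

#' Published dimensions of common HDR Ir-192 source models
#'
#' Reference table of physical dimensions (in mm, as conventionally printed)
#' for HDR Ir-192 sources in clinical use plus the IRAsource prototype,
#' shipped as a package fixture. Use [as_source_model()] to turn a row into
#' a [source_model()] (converted to cm).
#'
#' @return data.frame with one row per source model.
#' @export
hdr_source_table <- function() {
  path <- system.file("extdata", "source_dimensions_mm.csv",
                      package = "tg43film", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}

#' @rdname hdr_source_table
#' @param row one-row data.frame in the layout of [hdr_source_table()].
#' @export
as_source_model <- function(row) {
  stopifnot(nrow(row) == 1L)
  source_model(active_length = row$active_length_mm / 10,
               total_length = row$total_length_mm / 10,
               active_core_diameter = row$active_core_diameter_mm / 10,
               external_diameter = row$external_diameter_mm / 10,
               capsule_thickness = row$capsule_thickness_mm / 10,
               distal_capsule_thickness = row$distal_capsule_thickness_mm / 10,
               name = row$source)
}

#' Validate a polar coordinate pair
#'
#' Coordinates are polar about the source center: `r` in cm, `theta` in
#' degrees with 0 deg at the source's proximal (cable) end and 90 deg on the
#' transverse axis. The TG-43U1 convention (0 deg at the distal tip) is
#' obtained by `theta -> 180 - theta`; see `theta_origin` in
#' [tg43_dataset()].
#'
#' @param r radial distance from the source center, cm; must be > 0.
#' @param theta polar angle, degrees in `[0, 180]`.
#' @return a list of class `polar_point`.
#' @export
polar_point <- function(r, theta) {
  check_scalar(r, "r", positive = TRUE)
  check_scalar(theta, "theta")
  if (theta < 0 || theta > 180)
    stop_domain("`theta` must lie in [0, 180] degrees")
  structure(list(r = r, theta = theta), class = "polar_point")
}
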