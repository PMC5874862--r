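# Extraction of TG-43 parameters from a polar dose-rate map and the
# inter-method comparison statistics.

# mean of unmasked cells inside a (r, theta) window; optionally also the
# mirrored window about the transverse axis (theta -> 180 - theta)
window_mean <- function(map, r0, theta0, r_half, theta_half,
                        mirror = TRUE) {
  sel_r <- abs(map$r_mid - r0) <= r_half + 1e-9
  th <- map$theta_mid
  sel_t <- abs(th - theta0) <= theta_half + 1e-9
  if (mirror) sel_t <- sel_t | abs(th - (180 - theta0)) <= theta_half + 1e-9
  v <- map$values[sel_r, sel_t]
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  mean(v)
}

# window mean of value / G_L(cell): dividing each cell by the geometry
# function before averaging removes the first-order inverse-square bias of
# asymmetric windows (e.g. at the film edge, where only the inner half of
# the window has pixels). G is evaluated at the cell's pixel-mean (r, theta)
# when the map carries them (see to_dose_rate_map), which also removes the
# pixel-grid/polar-cell aliasing of up to half a pixel in radius.
window_geom_mean <- function(map, r0, theta0, r_half, theta_half, L,
                             mirror = TRUE) {
  sel_r <- which(abs(map$r_mid - r0) <= r_half + 1e-9)
  th <- map$theta_mid
  sel_t <- which(
    abs(th - theta0) <= theta_half + 1e-9 |
      (mirror & abs(th - (180 - theta0)) <= theta_half + 1e-9))
  if (!length(sel_r) || !length(sel_t)) return(NA_real_)
  v <- map$values[sel_r, sel_t, drop = FALSE]
  if (!is.null(map$r_bar)) {
    rr <- map$r_bar[sel_r, sel_t, drop = FALSE]
    tt <- map$theta_bar[sel_r, sel_t, drop = FALSE]
  } else {
    rr <- matrix(map$r_mid[sel_r], length(sel_r), length(sel_t))
    tt <- matrix(th[sel_t], length(sel_r), length(sel_t), byrow = TRUE)
  }
  keep <- !is.na(v) & !is.na(rr)
  if (!any(keep)) return(NA_real_)
  G <- geometry_function_linear(rr[keep], tt[keep], L)
  if (!is.null(map$inv_r2_bar)) {
    # second-order within-cell curvature: the pixel mean of the dose varies
    # as E[1/r^2], not 1/r_bar^2; the line-source departure from pure
    # inverse square is negligible at this scale
    G <- G * map$inv_r2_bar[sel_r, sel_t, drop = FALSE][keep] * rr[keep]^2
  }
  mean(v[keep] / G)
}

#' Extract the dose rate constant from a dose-rate map
#'
#' Lambda is estimated from the per-unit-Sk dose-rate cells in a small
#' window around the reference point (defaults: r in [0.95, 1.05] cm, theta
#' in [85, 95] deg, both sides of the source axis averaged). The window
#' matches the scoring-grid resolution and keeps g/F variation below ~0.1%
#' inside it. The default `"geometry_corrected"` method divides each cell
#' by `G_L` at the cell's pixel-mean coordinates and rescales by
#' `G_L(1, 90)`, cancelling the inverse-square curvature across the window
#' (a plain `"window_mean"` carries a ~+0.2% bias and is kept for
#' reference).
#'
#' @param map a [to_dose_rate_map()] result (values in cGy/h/U).
#' @param source a [source_model()] (supplies the active length for the
#'   geometry correction).
#' @param r_half,theta_half window half-widths (cm, degrees).
#' @param mirror average the window with its mirror about 90 deg.
#' @param method `"geometry_corrected"` (default) or `"window_mean"`.
#' @return Lambda, cGy h^-1 U^-1.
#' @export
extract_dose_rate_constant <- function(map, source = source_model(),
                                       r_half = 0.05, theta_half = 5,
                                       mirror = TRUE,
                                       method = c("geometry_corrected",
                                                  "window_mean")) {
  method <- match.arg(method)
  lam <- if (method == "window_mean") {
    window_mean(map, 1, 90, r_half, theta_half, mirror)
  } else {
    L <- source$active_length
    window_geom_mean(map, 1, 90, r_half, theta_half, L, mirror) *
      geometry_function_linear(1, 90, L)
  }
  if (is.na(lam))
    stop_extract("no unmasked cells in the reference window around (1 cm, 90 deg)")
  lam
}

#' Extract the radial dose function
#'
#' `g(r) = [D(r, 90) / D(1, 90)] * [G_L(1, 90) / G_L(r, 90)]` with the
#' line-source geometry function (active length from `source`), normalized
#' so g(1 cm) = 1 exactly. Transverse-axis dose rates are window means
#' about (r, 90 deg). Radii whose window is empty yield NA with a
#' missing-value flag.
#'
#' @param map a [to_dose_rate_map()] result.
#' @param source a [source_model()].
#' @param radii requested radii, cm.
#' @param r_half,theta_half window half-widths.
#' @param mirror average both sides of the axis.
#' @return data.frame `r_cm`, `g`, `n_missing` attribute-free; NA rows mark
#'   missing windows.
#' @export
extract_radial_dose_function <- function(map, source = source_model(),
                                         radii = c(1, 1.5, 2, 2.5, 3, 4),
                                         r_half = 0.05, theta_half = 2.5,
                                         mirror = TRUE) {
  L <- source$active_length
  d0 <- window_geom_mean(map, 1, 90, r_half, theta_half, L, mirror)
  if (is.na(d0)) stop_extract("reference window (1 cm, 90 deg) is empty")
  g <- vapply(radii, function(r) {
    d <- window_geom_mean(map, r, 90, r_half, theta_half, L, mirror)
    d / d0
  }, numeric(1))
  data.frame(r_cm = radii, g = g)
}

#' Extract the 2D anisotropy function
#'
#' `F(r, theta) = [D(r, theta) / D(r, 90)] * [G_L(r, 90) / G_L(r, theta)]`,
#' so F(r, 90 deg) = 1 by construction. By default F is reported for theta
#' in [10, 170] deg: close to the source axis the signal is degraded by
#' oblique filtration through the capsule, which the film cannot resolve.
#'
#' @param map a [to_dose_rate_map()] result.
#' @param source a [source_model()].
#' @param radii requested radii, cm.
#' @param angles requested polar angles, degrees.
#' @param r_half,theta_half window half-widths.
#' @param mirror average theta with 180 - theta (film half-planes).
#' @return list `r_cm`, `theta_deg`, `F` (matrix theta x r, NA where the
#'   window is empty).
#' @export
extract_anisotropy <- function(map, source = source_model(),
                               radii = c(1, 2, 3),
                               angles = seq(10, 170, by = 10),
                               r_half = 0.05, theta_half = 2,
                               mirror = TRUE) {
  L <- source$active_length
  Fm <- matrix(NA_real_, length(angles), length(radii))
  for (j in seq_along(radii)) {
    r <- radii[j]
    d90 <- window_geom_mean(map, r, 90, r_half, theta_half, L, mirror)
    if (is.na(d90)) next
    for (i in seq_along(angles)) {
      d <- window_geom_mean(map, r, angles[i], r_half, theta_half, L, mirror)
      if (is.na(d)) next
      Fm[i, j] <- d / d90
    }
  }
  list(r_cm = radii, theta_deg = angles, F = Fm)
}

#' Full TG-43 parameter extraction
#'
#' Convenience wrapper running [extract_dose_rate_constant()],
#' [extract_radial_dose_function()] and [extract_anisotropy()] on one map.
#'
#' @inheritParams extract_radial_dose_function
#' @param angles anisotropy angles, degrees.
#' @return list of class `extraction_result`: `lambda`, `g`, `anisotropy`.
#' @export
extract_tg43 <- function(map, source = source_model(),
                         radii = c(1, 1.5, 2, 2.5, 3, 4),
                         angles = seq(10, 170, by = 10), mirror = TRUE) {
  structure(list(
    lambda = extract_dose_rate_constant(map, source, mirror = mirror),
    g = extract_radial_dose_function(map, source, radii, mirror = mirror),
    anisotropy = extract_anisotropy(map, source,
                                    radii = radii[radii %in% c(1, 2, 3, 4)],
                                    angles = angles, mirror = mirror)
  ), class = "extraction_result")
}

#' Relative difference in percent
#'
#' `100 * |a - b| / reference`, rounded half-away-from-zero to the report
#' precision (1 decimal by default, as difference statistics are
#' conventionally printed).
#'
#' @param a,b values to compare.
#' @param reference denominator (nonzero).
#' @param decimals report decimals; `NULL` for unrounded.
#' @return percent difference.
#' @examples
#' relative_difference(1.084, 1.112, 1.112)  # 2.5
#' @export
relative_difference <- function(a, b, reference, decimals = 1) {
  if (any(reference == 0)) stop_domain("reference must be nonzero")
  d <- 100 * abs(a - b) / reference
  if (is.null(decimals)) d else round_half_out(d, decimals)
}

#' Compare two radial dose function tables
#'
#' Per-radius percent differences `100 * |g_a - g_b| / g_b` over the shared
#' radii, plus the maximum and its radius. Radii present in only one table
#' (or NA in either) are skipped and reported.
#'
#' @param g_a,g_b data.frames with columns `r_cm` and `g`.
#' @param decimals report decimals for the per-radius differences;
#'   `NULL` for unrounded.
#' @return list: `table` (r_cm, g_a, g_b, diff_pct), `max_diff_pct`,
#'   `at_r_cm`, `skipped_radii`.
#' @export
compare_g_tables <- function(g_a, g_b, decimals = 1) {
  stopifnot(all(c("r_cm", "g") %in% names(g_a)),
            all(c("r_cm", "g") %in% names(g_b)))
  key_a <- round(g_a$r_cm, 6); key_b <- round(g_b$r_cm, 6)
  shared <- intersect(key_a, key_b)
  ga <- g_a$g[match(shared, key_a)]
  gb <- g_b$g[match(shared, key_b)]
  usable <- !is.na(ga) & !is.na(gb)
  skipped <- sort(unique(c(setdiff(key_a, shared), setdiff(key_b, shared),
                           shared[!usable])))
  shared <- shared[usable]; ga <- ga[usable]; gb <- gb[usable]
  if (length(shared) == 0L)
    stop_compare("no shared radii with values in both tables")
  d <- 100 * abs(ga - gb) / gb
  dd <- if (is.null(decimals)) d else round_half_out(d, decimals)
  i <- which.max(d)
  list(table = data.frame(r_cm = shared, g_a = ga, g_b = gb, diff_pct = dd),
       max_diff_pct = dd[i], at_r_cm = shared[i], skipped_radii = skipped)
}
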