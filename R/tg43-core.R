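# TG-43 line-source formalism: geometry function, dose-rate equation,
# interpolation over tabulated g(r) and F(r,theta).

#' Angle subtended by the active line at a calculation point
#'
#' `beta` is the angle, in radians, that the active length `L` of a line
#' source subtends at the polar point `(r, theta)`. It is computed from the
#' angles of the two endpoint vectors, which is numerically exact for all
#' admissible geometries. On the source axis (`theta` = 0 or 180 deg) the
#' subtended angle degenerates to 0 (the line is seen end-on).
#'
#' @param r radial distance(s) from the source center, cm.
#' @param theta polar angle(s), degrees in `[0, 180]` (0 deg at the proximal
#'   cable end).
#' @param L active length, cm (>= 0).
#' @return subtended angle(s), radians in `[0, pi]`.
#' @examples
#' beta_subtended(1, 90, 0.35)     # 2*atan(0.175)
#' @export
beta_subtended <- function(r, theta, L) {
  check_scalar(L, "L", nonneg = TRUE)
  if (any(!is.finite(r)) || any(r <= 0)) stop_domain("`r` must be > 0")
  if (any(theta < 0) || any(theta > 180))
    stop_domain("`theta` must lie in [0, 180] degrees")
  th <- deg2rad(theta)
  x <- r * sin(th)
  z <- r * cos(th)
  on_axis <- theta == 0 | theta == 180
  if (any(on_axis & r <= L / 2))
    stop_domain("point lies inside the source's axial extent (r <= L/2 on the axis)")
  b <- abs(atan2(x, z - L / 2) - atan2(x, z + L / 2))
  b[on_axis] <- 0
  b
}

#' Line-source geometry function G_L(r, theta)
#'
#' The TG-43U1 line-source geometry function:
#' `G_L = beta / (L * r * sin(theta))` off the axis and
#' `G_L = (r^2 - L^2/4)^-1` on the axis, in cm^-2. It reduces to the
#' point-source `1/r^2` as `L -> 0` and is continuous in `theta`.
#'
#' @inheritParams beta_subtended
#' @return geometry function value(s), cm^-2.
#' @seealso [geometry_function_point()]
#' @export
geometry_function_linear <- function(r, theta, L) {
  check_scalar(L, "L", positive = TRUE)
  if (any(r <= L / 2))
    stop_domain(sprintf("`r` must exceed L/2 = %.3f cm", L / 2))
  b <- beta_subtended(r, theta, L)
  th <- deg2rad(theta)
  g <- b / (L * r * sin(th))
  on_axis <- theta == 0 | theta == 180
  g[on_axis] <- 1 / (r[on_axis]^2 - L^2 / 4)
  g
}

#' Point-source geometry function 1/r^2
#'
#' @param r radial distance(s), cm (> 0).
#' @return `1/r^2`, cm^-2.
#' @export
geometry_function_point <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0)) stop_domain("`r` must be > 0")
  1 / r^2
}

#' Assemble a TG-43 source dataset
#'
#' Bundles the dose rate constant Lambda, the tabulated radial dose function
#' g(r) and the gridded 2D anisotropy function F(r, theta) together with the
#' source model. The reference point is fixed at (r0 = 1 cm, theta0 = 90 deg).
#' Invariants are validated on construction: radii strictly increasing,
#' g interpolated at 1 cm equal to 1 (within 1e-12), F = 1 on the transverse
#' axis for every tabulated radius, and all values positive.
#'
#' @param dose_rate_constant Lambda, cGy h^-1 U^-1.
#' @param radial_table data.frame with columns `r_cm`, `g`.
#' @param anisotropy list with `r_cm` (radii), `theta_deg` (angles incl. 90),
#'   and `F` (matrix, rows = theta, cols = r).
#' @param source a [source_model()].
#' @param theta_origin `"proximal"` (0 deg at the cable end, default) or
#'   `"distal"` (TG-43U1 tip convention); recorded so readers can flip.
#' @return object of class `tg43_dataset`.
#' @export
tg43_dataset <- function(dose_rate_constant, radial_table, anisotropy,
                         source = source_model(),
                         theta_origin = c("proximal", "distal")) {
  theta_origin <- match.arg(theta_origin)
  check_scalar(dose_rate_constant, "dose_rate_constant", positive = TRUE)
  stopifnot(is.data.frame(radial_table),
            all(c("r_cm", "g") %in% names(radial_table)))
  r <- radial_table$r_cm
  if (any(diff(r) <= 0)) stop_domain("radial_table radii must be strictly increasing")
  if (any(r <= 0) || any(radial_table$g <= 0))
    stop_domain("radial_table must have positive r and g")
  stopifnot(is.list(anisotropy),
            all(c("r_cm", "theta_deg", "F") %in% names(anisotropy)))
  Fm <- anisotropy$F
  stopifnot(is.matrix(Fm),
            nrow(Fm) == length(anisotropy$theta_deg),
            ncol(Fm) == length(anisotropy$r_cm))
  if (any(diff(anisotropy$r_cm) <= 0) || any(diff(anisotropy$theta_deg) <= 0))
    stop_domain("anisotropy grid axes must be strictly increasing")
  if (any(Fm <= 0)) stop_domain("anisotropy values must be positive")
  if (!any(anisotropy$theta_deg == 90))
    stop_domain("anisotropy grid must include theta = 90 deg")
  if (any(abs(Fm[anisotropy$theta_deg == 90, ] - 1) > 1e-9))
    stop_domain("F(r, 90 deg) must equal 1 for every tabulated r")
  ds <- structure(list(
    dose_rate_constant = dose_rate_constant,
    radial_table = radial_table,
    anisotropy = anisotropy,
    reference = polar_point(1, 90),
    source = source,
    theta_origin = theta_origin
  ), class = "tg43_dataset")
  g1 <- interp_g(ds, 1)
  if (abs(g1 - 1) > 1e-12)
    stop_domain(sprintf("g interpolated at r = 1 cm must be 1 (got %.3e off)", g1 - 1))
  ds
}

#' @export
print.tg43_dataset <- function(x, ...) {
  cat(sprintf(
    "<tg43_dataset> Lambda = %.4g cGy/h/U; g on r in [%g, %g] cm (%d nodes); F grid %d theta x %d r; theta0 at %s end\n",
    x$dose_rate_constant, min(x$radial_table$r_cm), max(x$radial_table$r_cm),
    nrow(x$radial_table), length(x$anisotropy$theta_deg),
    length(x$anisotropy$r_cm), x$theta_origin))
  invisible(x)
}

range_msg <- function(what, q, lo, hi) {
  sprintf("%s query %.4g outside tabulated range [%g, %g]", what, q, lo, hi)
}

#' Interpolate the radial dose function
#'
#' Linear interpolation of the tabulated g(r); exact at table nodes, no
#' extrapolation (out-of-range queries raise a range error naming the table
#' bounds). Interpolation is plain linear: tabulated g spans ~1.000-1.021 so
#' curvature is negligible.
#'
#' @param dataset a [tg43_dataset()].
#' @param r query radius / radii, cm.
#' @return interpolated g value(s), dimensionless.
#' @export
interp_g <- function(dataset, r) {
  tab <- dataset$radial_table
  lo <- tab$r_cm[1]; hi <- tab$r_cm[nrow(tab)]
  bad <- r < lo - 1e-12 | r > hi + 1e-12
  if (any(bad)) stop_range(range_msg("g(r)", r[which(bad)[1]], lo, hi))
  stats::approx(tab$r_cm, tab$g, xout = pmin(pmax(r, lo), hi), rule = 1)$y
}

#' Interpolate the 2D anisotropy function
#'
#' Bilinear interpolation of the gridded F(r, theta); exact at grid nodes,
#' no extrapolation.
#'
#' @inheritParams interp_g
#' @param theta query polar angle(s), degrees.
#' @return interpolated F value(s), dimensionless.
#' @export
interp_F <- function(dataset, r, theta) {
  an <- dataset$anisotropy
  rg <- an$r_cm; tg <- an$theta_deg
  if (length(theta) == 1L && length(r) > 1L) theta <- rep(theta, length(r))
  if (length(r) == 1L && length(theta) > 1L) r <- rep(r, length(theta))
  bad <- r < rg[1] - 1e-12 | r > rg[length(rg)] + 1e-12
  if (any(bad)) stop_range(range_msg("F(r,theta) radius", r[which(bad)[1]],
                                     rg[1], rg[length(rg)]))
  bad <- theta < tg[1] - 1e-9 | theta > tg[length(tg)] + 1e-9
  if (any(bad)) stop_range(range_msg("F(r,theta) angle", theta[which(bad)[1]],
                                     tg[1], tg[length(tg)]))
  r <- pmin(pmax(r, rg[1]), rg[length(rg)])
  theta <- pmin(pmax(theta, tg[1]), tg[length(tg)])
  ir <- pmin(pmax(findInterval(r, rg), 1L), length(rg) - 1L)
  it <- pmin(pmax(findInterval(theta, tg), 1L), length(tg) - 1L)
  fr <- (r - rg[ir]) / (rg[ir + 1L] - rg[ir])
  ft <- (theta - tg[it]) / (tg[it + 1L] - tg[it])
  Fm <- an$F
  (1 - ft) * (1 - fr) * Fm[cbind(it, ir)] +
    (1 - ft) * fr       * Fm[cbind(it, ir + 1L)] +
    ft       * (1 - fr) * Fm[cbind(it + 1L, ir)] +
    ft       * fr       * Fm[cbind(it + 1L, ir + 1L)]
}

#' TG-43 dose rate at a point
#'
#' The TG-43 dose-rate equation
#' `D(r,theta) = Sk * Lambda * G_L(r,theta)/G_L(r0,theta0) * g(r) * F(r,theta)`
#' with the line-source geometry function. At the reference point
#' (1 cm, 90 deg) this returns `Sk * Lambda` exactly.
#'
#' @param Sk air-kerma strength, U (1 U = 1 cGy cm^2 h^-1); >= 0.
#' @param dataset a [tg43_dataset()].
#' @param r,theta polar coordinates (cm, degrees), vectorized.
#' @return dose rate(s), cGy h^-1.
#' @export
dose_rate <- function(Sk, dataset, r, theta) {
  check_scalar(Sk, "Sk", nonneg = TRUE)
  L <- dataset$source$active_length
  G0 <- geometry_function_linear(dataset$reference$r, dataset$reference$theta, L)
  G <- geometry_function_linear(r, theta, L)
  Sk * dataset$dose_rate_constant * (G / G0) *
    interp_g(dataset, r) * interp_F(dataset, r, theta)
}

#' Read / write a TG-43 dataset as CSV
#'
#' Serialization used by the pipeline: a radial table CSV with header
#' `r_cm,g` and an anisotropy grid CSV whose first column is `theta_deg` and
#' remaining columns are named by radius in cm. Invariants are re-validated
#' on load.
#'
#' @param dataset a [tg43_dataset()].
#' @param radial_path,anisotropy_path file paths.
#' @param dose_rate_constant,source,theta_origin passed to [tg43_dataset()]
#'   on read (the CSVs carry only the tables).
#' @return `write_tg43_dataset()` returns the paths invisibly;
#'   `read_tg43_dataset()` a [tg43_dataset()].
#' @export
write_tg43_dataset <- function(dataset, radial_path, anisotropy_path) {
  utils::write.csv(dataset$radial_table, radial_path, row.names = FALSE)
  an <- dataset$anisotropy
  grid <- data.frame(theta_deg = an$theta_deg, an$F, check.names = FALSE)
  names(grid) <- c("theta_deg", format(an$r_cm, trim = TRUE))
  utils::write.csv(grid, anisotropy_path, row.names = FALSE)
  invisible(c(radial_path, anisotropy_path))
}

#' @rdname write_tg43_dataset
#' @export
read_tg43_dataset <- function(radial_path, anisotropy_path,
                              dose_rate_constant, source = source_model(),
                              theta_origin = "proximal") {
  rad <- utils::read.csv(radial_path)
  grid <- utils::read.csv(anisotropy_path, check.names = FALSE)
  theta <- grid[[1L]]
  r <- as.numeric(names(grid)[-1L])
  if (any(is.na(r))) stop_config("anisotropy CSV columns must be named by radius in cm")
  tg43_dataset(dose_rate_constant, rad,
               list(r_cm = r, theta_deg = theta,
                    F = as.matrix(grid[-1L])),
               source = source, theta_origin = theta_origin)
}
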