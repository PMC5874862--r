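# Scan-to-dose chain: ROI statistics, optical density, calibration
# fitting/inversion, dose maps and polar dose-rate maps.

#' Disc region of interest
#'
#' @param center_cm ROI center `c(x, y)` in cm from the image corner.
#' @param area_cm2 disc area, cm^2 (default pi, i.e. radius 1 cm — the
#'   conventional calibration-film ROI).
#' @return object of class `roi`.
#' @export
roi_disc <- function(center_cm, area_cm2 = pi) {
  check_scalar(area_cm2, "area_cm2", positive = TRUE)
  structure(list(center_cm = center_cm, area_cm2 = area_cm2,
                 radius_cm = sqrt(area_cm2 / pi)), class = "roi")
}

#' Mean pixel value over a disc ROI
#'
#' Arithmetic mean of the pixel values whose centers fall inside the disc.
#' For RGB scans the red channel is used (standard single-channel
#' radiochromic practice). The ROI must lie fully inside the image.
#'
#' @param image a [scan_image()].
#' @param roi an [roi_disc()].
#' @return mean pixel value (scalar).
#' @export
mean_pixel_roi <- function(image, roi) {
  px <- scan_channel(image)
  pitch <- pixel_pitch_cm(image$dpi)
  w <- ncol(px) * pitch; h <- nrow(px) * pitch
  cx <- roi$center_cm[1]; cy <- roi$center_cm[2]; rad <- roi$radius_cm
  if (cx - rad < 0 || cy - rad < 0 || cx + rad > w || cy + rad > h)
    stop_geometry(sprintf(
      "ROI (center %.2f,%.2f cm, radius %.2f cm) extends beyond the %.2f x %.2f cm image",
      cx, cy, rad, w, h))
  x <- (seq_len(ncol(px)) - 0.5) * pitch
  y <- (seq_len(nrow(px)) - 0.5) * pitch
  inside <- outer((y - cy)^2, (x - cx)^2, "+") <= rad^2
  mean(px[inside])
}

#' Optical density from scanner signals
#'
#' `OD = log10(S0 / S)` with `S0` the unirradiated and `S` the irradiated
#' signal. Net OD is the irradiated-film OD minus the background-film OD,
#' which with a shared `S0` reduces to `log10(S_bg / S)`.
#'
#' @param S0 unirradiated signal (> 0), scalar or vector.
#' @param S irradiated signal (> 0).
#' @return optical density value(s).
#' @export
optical_density <- function(S0, S) {
  if (any(S0 <= 0) || any(S <= 0))
    stop_domain("signals must be positive")
  log10(S0 / S)
}

#' Polynomial calibration curve dose = P(netOD)
#'
#' Least-squares polynomial of the stated order fitted to (netOD, dose)
#' calibration points, in the conversion direction actually used (dose as a
#' function of net OD, unweighted). The fit is rejected unless it is
#' monotone increasing over the valid net-OD interval `[0, max(netOD)]`.
#' Residuals are stored as percent of dose.
#'
#' @param netod net optical densities (distinct).
#' @param dose doses, Gy (positive).
#' @param order polynomial order (3 for EBT-like, 4 for HD810-like).
#' @param film_kind label carried in reports.
#' @return object of class `calibration_curve` with elements
#'   `coefficients` (ascending powers), `valid_netod`, `residual_pct`,
#'   `points`.
#' @export
fit_calibration <- function(netod, dose, order = 3, film_kind = "EBT") {
  if (length(netod) != length(dose)) stop_fit("netod and dose lengths differ")
  if (length(netod) < order + 2)
    stop_fit(sprintf("need at least %d points for an order-%d fit, got %d",
                     order + 2, order, length(netod)))
  if (anyDuplicated(signif(netod, 12))) stop_fit("netod values must be distinct")
  if (any(dose <= 0)) stop_fit("doses must be positive")
  X <- outer(netod, 0:order, "^")
  beta <- qr.coef(qr(X), dose)
  valid <- c(0, max(netod))
  # monotonicity on the valid interval, checked on a dense grid
  xx <- seq(valid[1], valid[2], length.out = 512)
  dP <- outer(xx, 0:(order - 1), "^") %*% (beta[-1] * seq_len(order))
  if (any(dP <= 0))
    stop_fit(sprintf(
      "fitted order-%d polynomial is non-monotone on [%.3f, %.3f] (min dP/dx = %.3g at netOD %.3f)",
      order, valid[1], valid[2], min(dP), xx[which.min(dP)]))
  fitted <- as.vector(X %*% beta)
  structure(list(film_kind = film_kind, order = order,
                 coefficients = as.vector(beta), valid_netod = valid,
                 residual_pct = 100 * (fitted - dose) / dose,
                 points = data.frame(netod = netod, dose_Gy = dose)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s order %d, %d points, netOD in [%.3f, %.3f], max |resid| %.2f%%\n",
    x$film_kind, x$order, nrow(x$points), x$valid_netod[1], x$valid_netod[2],
    max(abs(x$residual_pct))))
  invisible(x)
}

#' Evaluate a calibration curve
#'
#' @param curve a [fit_calibration()] result.
#' @param netod net OD value(s); values outside the valid interval give NA
#'   (masking, never extrapolation).
#' @return dose(s), Gy.
#' @export
predict_dose <- function(curve, netod) {
  out <- outer(netod, 0:curve$order, "^") %*% curve$coefficients
  out <- as.vector(out)
  out[netod < curve$valid_netod[1] | netod > curve$valid_netod[2]] <- NA_real_
  out
}

#' Convert a scanned film to a dose map
#'
#' Pixelwise net OD against the background film (`S0` = mean background
#' signal by default) converted to dose through the calibration polynomial.
#' Pixels with net OD outside the curve's valid interval (or nonpositive
#' signal) are masked and counted; more than `max_masked_frac` masked
#' pixels is a quality error.
#'
#' @param image irradiated-film [scan_image()].
#' @param background_image unirradiated [scan_image()] of the same batch.
#' @param curve a [fit_calibration()] result.
#' @param S0_policy `"background_mean"` (only supported policy): S0 is the
#'   mean pixel of the background film.
#' @param max_masked_frac mask-fraction threshold for the quality error.
#' @return list of class `film_dose_map`: `dose_Gy` matrix (NA where
#'   masked), `mask`, `masked_frac`, `S0`, `dpi`.
#' @export
convert_dose <- function(image, background_image, curve,
                         S0_policy = "background_mean",
                         max_masked_frac = 0.5) {
  if (!identical(S0_policy, "background_mean"))
    stop_config("only S0_policy = 'background_mean' is implemented")
  S0 <- mean(scan_channel(background_image))
  S <- scan_channel(image)
  bad_signal <- S <= 0
  S[bad_signal] <- NA_real_
  netod <- log10(S0 / S)
  netod[!bad_signal & netod < 0] <- 0  # background fluctuation below S0
  dose <- matrix(predict_dose(curve, as.vector(netod)), nrow(netod), ncol(netod))
  mask <- bad_signal | is.na(dose)
  masked_frac <- mean(mask)
  if (masked_frac > max_masked_frac)
    stop_quality(sprintf("%.0f%% of pixels masked (limit %.0f%%)",
                         100 * masked_frac, 100 * max_masked_frac))
  structure(list(dose_Gy = dose, mask = mask, masked_frac = masked_frac,
                 S0 = S0, dpi = image$dpi,
                 pitch_cm = pixel_pitch_cm(image$dpi)),
            class = "film_dose_map")
}

#' Locate the source on a dose map
#'
#' Intensity-weighted centroid of the top-percentile dose region and the
#' principal axis of that region's second moments. Used when no mechanical
#' pose is available; a config-provided pose is passed through unchanged.
#'
#' @param dose_map a `film_dose_map` or `dose_map` (or plain matrix, Gy).
#' @param pose optional known pose `list(xy_cm, axis_deg)`; returned as-is.
#' @param top_quantile pixels above this dose quantile define the core
#'   region.
#' @return list with `xy_cm` (source center) and `axis_deg` in `[0, 180)`.
#' @export
locate_source <- function(dose_map, pose = NULL, top_quantile = 0.995) {
  if (!is.null(pose)) return(pose)
  dose <- if (is.matrix(dose_map)) dose_map else dose_map$dose_Gy
  pitch <- if (is.matrix(dose_map)) pixel_pitch_cm(300) else dose_map$pitch_cm
  v <- dose; v[is.na(v)] <- 0
  if (max(v) <= 0) stop_localize("dose map is empty (all zero or masked)")
  thr <- stats::quantile(v[v > 0], top_quantile, names = FALSE)
  sel <- which(v >= thr, arr.ind = TRUE)
  wts <- v[sel]
  x <- (sel[, 2] - 0.5) * pitch
  y <- (sel[, 1] - 0.5) * pitch
  cx <- sum(wts * x) / sum(wts); cy <- sum(wts * y) / sum(wts)
  cxx <- sum(wts * (x - cx)^2); cyy <- sum(wts * (y - cy)^2)
  cxy <- sum(wts * (x - cx) * (y - cy))
  ang <- 0.5 * atan2(2 * cxy, cxx - cyy) * 180 / pi
  list(xy_cm = c(cx, cy), axis_deg = ang %% 180)
}

#' Resample a dose map onto a polar dose-rate grid
#'
#' Bins film pixels into annular sectors (defaults: 0.05 cm radial, 1 deg
#' angular — the conventional MC scoring grid) about the source pose, takes
#' the cell mean and divides by exposure time and air-kerma strength,
#' giving dose rate per unit Sk in cGy h^-1 U^-1. Cells with no (or mostly
#' masked) pixels are masked.
#'
#' @param dose_map a `film_dose_map` (Gy) or forward-model `dose_map`.
#' @param plan the [exposure_plan()] (supplies Sk and time).
#' @param pose source pose `list(xy_cm, axis_deg)`; default from the map
#'   (forward maps carry it) or [locate_source()].
#' @param dr,dtheta grid spacing (cm, degrees).
#' @param r_range radial coverage, cm.
#' @return object of class `dose_rate_map` with `values` (nr x ntheta
#'   matrix, cGy/h/U), `r_mid`, `theta_mid`, `n_pixels`, `provenance`.
#' @export
to_dose_rate_map <- function(dose_map, plan, pose = NULL,
                             dr = 0.05, dtheta = 1,
                             r_range = c(0.2, NA)) {
  if (plan$Sk <= 0) stop_config("Sk must be > 0")
  if (plan$time_h <= 0) stop_config("exposure time must be > 0")
  dose <- dose_map$dose_Gy
  pitch <- dose_map$pitch_cm
  if (is.null(pose)) {
    pose <- if (!is.null(dose_map$source_xy_cm))
      list(xy_cm = dose_map$source_xy_cm, axis_deg = dose_map$axis_deg)
    else locate_source(dose_map)
  }
  grid <- list(x = (seq_len(ncol(dose)) - 0.5) * pitch,
               y = (seq_len(nrow(dose)) - 0.5) * pitch,
               nx = ncol(dose), ny = nrow(dose), pitch = pitch)
  pc <- film_polar_coords(grid, pose$xy_cm, pose$axis_deg)
  if (is.na(r_range[2])) r_range[2] <- max(pc$r)
  r_edges <- seq(r_range[1], r_range[2] + dr, by = dr)
  t_edges <- seq(0, 180, by = dtheta)
  ir <- findInterval(as.vector(pc$r), r_edges, rightmost.closed = TRUE)
  it <- findInterval(as.vector(pc$theta), t_edges, rightmost.closed = TRUE)
  nr <- length(r_edges) - 1L; nt <- length(t_edges) - 1L
  ok <- ir >= 1L & ir <= nr & it >= 1L & it <= nt
  d <- as.vector(dose)
  if (!is.null(dose_map$mask)) ok <- ok & !as.vector(dose_map$mask)
  ok <- ok & !is.na(d)
  cell <- (it[ok] - 1L) * nr + ir[ok]
  sums <- tabulate_sum(cell, d[ok], nr * nt)
  counts <- tabulate(cell, nbins = nr * nt)
  # per-cell pixel-mean coordinates: the pixel grid does not tile the thin
  # polar cells evenly, so a cell's true mean radius can sit up to half a
  # pixel off its nominal center; extraction corrects geometry with these
  r_sums <- tabulate_sum(cell, as.vector(pc$r)[ok], nr * nt)
  t_sums <- tabulate_sum(cell, as.vector(pc$theta)[ok], nr * nt)
  ir2_sums <- tabulate_sum(cell, 1 / as.vector(pc$r)[ok]^2, nr * nt)
  vals <- matrix(NA_real_, nr, nt)
  r_bar <- matrix(NA_real_, nr, nt); t_bar <- matrix(NA_real_, nr, nt)
  ir2_bar <- matrix(NA_real_, nr, nt)
  nz <- counts > 0
  vals[nz] <- sums[nz] / counts[nz]
  r_bar[nz] <- r_sums[nz] / counts[nz]
  t_bar[nz] <- t_sums[nz] / counts[nz]
  ir2_bar[nz] <- ir2_sums[nz] / counts[nz]
  vals <- vals * 100 / (plan$time_h * plan$Sk)  # Gy -> cGy, per h per U
  structure(list(values = vals, r_mid = r_edges[-1] - dr / 2,
                 theta_mid = t_edges[-1] - dtheta / 2,
                 r_bar = r_bar, theta_bar = t_bar, inv_r2_bar = ir2_bar,
                 n_pixels = matrix(counts, nr, nt),
                 dr = dr, dtheta = dtheta,
                 provenance = list(Sk = plan$Sk, time_h = plan$time_h,
                                   film_kind = plan$film$film_kind,
                                   pose = pose)),
            class = "dose_rate_map")
}

tabulate_sum <- function(bin, x, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(x, bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
print.dose_rate_map <- function(x, ...) {
  cat(sprintf(
    "<dose_rate_map> r in [%.2f, %.2f] cm (dr %.2g), theta 0-180 (dtheta %g), %.0f%% cells filled\n",
    min(x$r_mid), max(x$r_mid), x$dr, x$dtheta, 100 * mean(!is.na(x$values))))
  invisible(x)
}

#' Write / read a dose-rate map as long-format CSV
#'
#' Columns `r_cm`, `theta_deg`, `value` (cGy/h/U); masked cells are omitted.
#' A JSON sidecar (same path + `.json`) records provenance.
#'
#' @param map a `dose_rate_map`.
#' @param path CSV path.
#' @return the path, invisibly (writer); a data.frame (reader).
#' @export
write_dose_rate_map <- function(map, path) {
  df <- expand.grid(r_cm = map$r_mid, theta_deg = map$theta_mid)
  df$value <- as.vector(map$values)
  df <- df[!is.na(df$value), ]
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  writeLines(jsonlite::toJSON(map$provenance, auto_unbox = TRUE, digits = NA),
             sidecar)
  invisible(path)
}

#' @rdname write_dose_rate_map
#' @export
read_dose_rate_map <- function(path) utils::read.csv(path)
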