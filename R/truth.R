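# Ground-truth dataset builders for the virtual experiment.

#' Reference radial dose function tables
#'
#' The tabulated g(r) columns shipped with the package (Monte Carlo and
#' HD-810 film columns for the IRAsource, plus literature columns for
#' Flexisource, mHDR-v2r and GammaMed 12i), as a data.frame in long-friendly
#' wide layout. Radii 1-4 cm; absent entries are NA.
#'
#' @return data.frame with column `r_cm` and one column per method/source.
#' @export
radial_dose_reference <- function() {
  utils::read.csv(system.file("extdata", "radial_dose_reference.csv",
                              package = "tg43film", mustWork = TRUE))
}

#' Reference dose rate constants
#'
#' Published dose rate constants (cGy h^-1 U^-1) for HDR Ir-192 sources and
#' the IRAsource MC/film determinations, shipped as a fixture.
#'
#' @return data.frame with columns source, method, lambda_cGy_per_hU,
#'   uncertainty_k1.
#' @export
dose_rate_constant_reference <- function() {
  utils::read.csv(system.file("extdata", "dose_rate_constants.csv",
                              package = "tg43film", mustWork = TRUE))
}

#' Parametric 2D anisotropy profile
#'
#' Smooth anisotropy model used as ground truth: unity on the transverse
#' axis with a configurable dip toward the source poles,
#' `F(theta) = 1 - dip * |cos(theta)|^exponent`. Typical HDR Ir-192 sources
#' show pole dips of 2-10%.
#'
#' @param theta polar angle(s), degrees.
#' @param dip fractional dip at the poles (default 0.06).
#' @param exponent shape exponent (default 2.5; larger = dip confined closer
#'   to the axis).
#' @return anisotropy value(s).
#' @export
anisotropy_profile <- function(theta, dip = 0.06, exponent = 2.5) {
  1 - dip * abs(cos(deg2rad(theta)))^exponent
}

#' Ground-truth TG-43 dataset for the virtual experiment
#'
#' Builds the default "injected truth" dataset: Lambda from the IRAsource
#' Monte Carlo determination (1.112 cGy h^-1 U^-1), g(r) from a reference
#' column of [radial_dose_reference()] extended flat below 1 cm with a
#' configurable g(0.5 cm) (default 1.000, also used down to `r_min`), and a
#' parametric anisotropy grid from [anisotropy_profile()]. The MC column has
#' no entry at 3.5 cm; linear interpolation bridges 3-4 cm.
#'
#' @param g_column column of [radial_dose_reference()] to use
#'   (default `"mcnp"`).
#' @param lambda dose rate constant, cGy h^-1 U^-1.
#' @param g_at_half_cm g value assigned at and below 0.5 cm.
#' @param dip,exponent anisotropy shape, see [anisotropy_profile()].
#' @param r_min inner tabulated radius, cm (film pixels inside it are
#'   masked by the forward model).
#' @param r_max outer tabulated radius, cm; the last tabulated g segment is
#'   linearly extended there so film corners beyond the reference table's
#'   4 cm edge (but inside `r_max`) can be rendered. The extension is
#'   synthetic and never enters comparisons.
#' @param theta_step anisotropy grid angular spacing, degrees.
#' @param source a [source_model()].
#' @return a [tg43_dataset()].
#' @export
reference_tg43_dataset <- function(g_column = "mcnp", lambda = 1.112,
                                   g_at_half_cm = 1.000,
                                   dip = 0.06, exponent = 2.5,
                                   r_min = 0.2, r_max = 6.5, theta_step = 2,
                                   source = source_model()) {
  ref <- radial_dose_reference()
  if (!g_column %in% names(ref))
    stop_config(sprintf("unknown g column '%s'", g_column))
  keep <- !is.na(ref[[g_column]])
  r <- c(r_min, 0.5, ref$r_cm[keep])
  g <- c(g_at_half_cm, g_at_half_cm, ref[[g_column]][keep])
  if (r_max > max(r)) {
    n <- length(r)
    slope <- (g[n] - g[n - 1]) / (r[n] - r[n - 1])
    g_ext <- g[n] + slope * (r_max - r[n])
    if (g_ext <= 0) g_ext <- g[n]
    r <- c(r, r_max); g <- c(g, g_ext)
  }
  radial <- data.frame(r_cm = r, g = g)
  theta <- seq(0, 180, by = theta_step)
  if (!any(theta == 90)) stop_config("theta_step must divide 90")
  r_an <- c(r_min, 0.5, 1, 1.5, 2, 3, 4, if (r_max > 4) r_max)
  Fm <- matrix(rep(anisotropy_profile(theta, dip, exponent), length(r_an)),
               nrow = length(theta))
  Fm[theta == 90, ] <- 1
  tg43_dataset(lambda, radial,
               list(r_cm = r_an, theta_deg = theta, F = Fm),
               source = source)
}
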