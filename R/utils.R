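# Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180

#' Round half away from zero
#'
#' Presentation rounding used throughout the reporting layer: ties go away
#' from zero (so 3.775 -> 3.78 at 2 decimals), unlike base [round()]'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_out <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values that are exact ties after
  # floating-point representation still round away from zero
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

abort2 <- function(msg, class) {
  stop(structure(
    class = c(class, "tg43film_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_domain   <- function(msg) abort2(msg, "tg43_domain_error")
stop_range    <- function(msg) abort2(msg, "tg43_range_error")
stop_geometry <- function(msg) abort2(msg, "tg43_geometry_error")
stop_fit      <- function(msg) abort2(msg, "tg43_fit_error")
stop_quality  <- function(msg) abort2(msg, "tg43_quality_error")
stop_config   <- function(msg) abort2(msg, "tg43_config_error")
stop_extract  <- function(msg) abort2(msg, "tg43_extraction_error")
stop_compare  <- function(msg) abort2(msg, "tg43_comparison_error")
stop_localize <- function(msg) abort2(msg, "tg43_localization_error")

# Deterministic per-stage sub-seed derived from the master seed. Keeps every
# stream below 2^31 and distinct across stage labels.
sub_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 8191) %% 2147483647)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("`%s` must be a finite numeric scalar", name))
  if (positive && x <= 0) stop_domain(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) stop_domain(sprintf("`%s` must be >= 0", name))
  invisible(x)
}
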