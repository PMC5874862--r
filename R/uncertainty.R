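# Type A/B uncertainty bookkeeping: quadrature sums, chained budgets and
# the Monte Carlo budget arithmetic.

#' Quadrature sum
#'
#' Square root of the sum of squares of relative uncertainty components
#' (percent, 1 sigma). An empty input gives 0. Permutation-invariant and
#' homogeneous of degree 1.
#'
#' @param values nonnegative percentages.
#' @return combined value, %.
#' @examples
#' quadrature(c(2, 2.5, 2))   # 3.77 (2 dp)
#' @export
quadrature <- function(values) {
  if (length(values) == 0L) return(0)
  if (any(values < 0)) stop_domain("uncertainty components must be >= 0")
  sqrt(sum(values^2))
}

#' Uncertainty component and budget containers
#'
#' A budget is a labeled list of Type A (statistical) and Type B
#' (systematic) relative uncertainty components in percent (1 sigma).
#'
#' @param label component description.
#' @param kind `"A"` or `"B"`.
#' @param value_pct 1-sigma relative uncertainty, %.
#' @return `uncertainty_component()`: one-row data.frame; `budget()`: object
#'   of class `budget` wrapping a components data.frame.
#' @export
uncertainty_component <- function(label, kind = c("A", "B"), value_pct) {
  kind <- match.arg(kind)
  check_scalar(value_pct, "value_pct", nonneg = TRUE)
  data.frame(label = label, kind = kind, value_pct = value_pct)
}

#' @rdname uncertainty_component
#' @param components data.frame with columns label, kind, value_pct (or a
#'   list of [uncertainty_component()] rows).
#' @export
budget <- function(components) {
  if (is.list(components) && !is.data.frame(components))
    components <- do.call(rbind, components)
  stopifnot(all(c("label", "kind", "value_pct") %in% names(components)))
  if (!all(components$kind %in% c("A", "B")))
    stop_domain("component kind must be 'A' or 'B'")
  if (any(components$value_pct < 0))
    stop_domain("component values must be >= 0")
  structure(list(components = components), class = "budget")
}

#' @export
print.budget <- function(x, ...) {
  cat(sprintf("<budget> %d components (A: %d, B: %d)\n",
              nrow(x$components), sum(x$components$kind == "A"),
              sum(x$components$kind == "B")))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Combine a budget in quadrature
#'
#' Per-kind quadrature sums and the overall (A+B) quadrature. Computation is
#' at full precision; rounding (half away from zero) happens only at
#' presentation when `decimals` is given. `overall^2 = qA^2 + qB^2` holds to
#' machine precision before rounding.
#'
#' @param b a [budget()].
#' @param decimals optional presentation decimals.
#' @return list `qA`, `qB`, `overall` (%).
#' @examples
#' b <- budget(data.frame(label = c("u1", "u2", "u3", "u4"),
#'                        kind = c("A", "B", "B", "B"),
#'                        value_pct = c(1.5, 2, 2.5, 2)))
#' combine_budget(b, decimals = 1)$overall  # 4.1
#' @export
combine_budget <- function(b, decimals = NULL) {
  comp <- b$components
  if (nrow(comp) == 0L) stop_domain("budget has no components")
  qA <- quadrature(comp$value_pct[comp$kind == "A"])
  qB <- quadrature(comp$value_pct[comp$kind == "B"])
  overall <- quadrature(c(qA, qB))
  out <- list(qA = qA, qB = qB, overall = overall)
  if (!is.null(decimals)) out <- lapply(out, round_half_out, digits = decimals)
  out
}

#' Chain the calibration budget into the experimental budget
#'
#' The film budget is evaluated in two stages: the calibration (dose
#' conversion) budget is combined first and its overall value enters the
#' experimental budget as one additional Type B component ("dose conversion"),
#' exactly as printed budget tables chain their rows. Conventionally the
#' chained value is the rounded printed calibration overall (e.g. 4.1 / 3.9),
#' which this function takes as given.
#'
#' @param calibration_overall overall calibration uncertainty, % (>= 0).
#' @param experiment_budget a [budget()] of the experimental components
#'   (without the conversion row).
#' @return a [budget()] with the conversion component appended.
#' @export
chain_film_budget <- function(calibration_overall, experiment_budget) {
  check_scalar(calibration_overall, "calibration_overall", nonneg = TRUE)
  comp <- experiment_budget$components
  if (calibration_overall > 0)
    comp <- rbind(comp, data.frame(label = "Overall conversion uncertainty",
                                   kind = "B",
                                   value_pct = calibration_overall))
  budget(comp)
}

#' Monte Carlo uncertainty budget arithmetic
#'
#' MC budgets distinguish general points from near-longitudinal-axis points
#' (poorer tally statistics). Type A components are the dose-tally
#' statistics (general / axis) each combined with the air-kerma-strength
#' tally statistic; overall values add the combined Type B aggregate in
#' quadrature.
#'
#' @param typeA_general dose-tally Type A for general points, %.
#' @param typeA_axis dose-tally Type A near the longitudinal axis, %.
#' @param typeA_sk air-kerma-strength tally Type A, %.
#' @param typeB_combined combined Type B aggregate, %.
#' @param decimals optional presentation decimals.
#' @return list `qA_general`, `qA_axis`, `overall_general`, `overall_axis`.
#' @examples
#' mc_budget(0.1, 0.5, 0.4, 0.71, decimals = 2)
#' @export
mc_budget <- function(typeA_general, typeA_axis, typeA_sk, typeB_combined,
                      decimals = NULL) {
  for (v in c(typeA_general, typeA_axis, typeA_sk, typeB_combined))
    check_scalar(v, "mc budget component", nonneg = TRUE)
  out <- list(
    qA_general = quadrature(c(typeA_general, typeA_sk)),
    qA_axis = quadrature(c(typeA_axis, typeA_sk)),
    overall_general = quadrature(c(typeA_general, typeA_sk, typeB_combined)),
    overall_axis = quadrature(c(typeA_axis, typeA_sk, typeB_combined))
  )
  if (!is.null(decimals)) out <- lapply(out, round_half_out, digits = decimals)
  out
}

#' Packaged calibration / experimental budget fixtures
#'
#' The component rows of the calibration (dose-conversion) and experimental
#' uncertainty budgets for the two film kinds, shipped as CSV fixtures. The
#' experimental budget excludes the chained conversion row — add it with
#' [chain_film_budget()].
#'
#' @param film_kind `"EBT"` or `"HD810"`.
#' @return a [budget()].
#' @export
calibration_budget <- function(film_kind = c("EBT", "HD810")) {
  film_kind <- match.arg(film_kind)
  read_budget(system.file("extdata",
                          sprintf("budget_calibration_%s.csv", tolower(film_kind)),
                          package = "tg43film", mustWork = TRUE))
}

#' @rdname calibration_budget
#' @export
experimental_budget <- function(film_kind = c("EBT", "HD810")) {
  film_kind <- match.arg(film_kind)
  read_budget(system.file("extdata",
                          sprintf("budget_experiment_%s.csv", tolower(film_kind)),
                          package = "tg43film", mustWork = TRUE))
}

#' Read / write budget CSVs
#'
#' CSV layout: columns `label`, `kind` (A/B), `value_pct`.
#'
#' @param path CSV file path.
#' @param b a [budget()] (writer).
#' @return a [budget()] (reader); the path invisibly (writer).
#' @export
read_budget <- function(path) budget(utils::read.csv(path))

#' @rdname read_budget
#' @export
write_budget <- function(b, path) {
  utils::write.csv(b$components, path, row.names = FALSE)
  invisible(path)
}

#' Render a budget as a printed report table
#'
#' Mirrors the conventional budget-table layout: one row per component with
#' Type A / Type B columns, then quadrature-sum and overall rows, rounded
#' half away from zero at the requested precision.
#'
#' @param b a [budget()].
#' @param decimals presentation decimals (default 2).
#' @return data.frame.
#' @export
budget_table <- function(b, decimals = 2) {
  comp <- b$components
  res <- combine_budget(b)
  rows <- data.frame(
    label = c(comp$label, "Quadrature sum", "Overall"),
    type_A_pct = c(ifelse(comp$kind == "A", comp$value_pct, NA),
                   round_half_out(res$qA, decimals), NA),
    type_B_pct = c(ifelse(comp$kind == "B", comp$value_pct, NA),
                   round_half_out(res$qB, decimals), NA))
  rows$combined_pct <- c(rep(NA, nrow(comp) + 1),
                         round_half_out(res$overall, 1))
  rows
}
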