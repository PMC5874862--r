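# End-to-end pipeline: simulate -> calibrate -> reconstruct -> extract ->
# budget -> compare, plus report tables.

#' Pipeline configuration
#'
#' Flat configuration for [run_pipeline()]. Defaults reproduce the
#' reference experiment: a ~50 mCi source (188.5 U), 2.1 h EBT-like and
#' 182.4 h HD810-like exposures, 300 dpi 16-bit scans, 0.05 cm x 1 deg
#' polar resampling. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults (see [default_config()]).
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- default_config()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_config(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_config <- function() {
  list(
    seed = 1L,
    film_kinds = c("EBT", "HD810"),
    activity_Bq = 1.85e9,            # ~50 mCi
    ebt_time_h = 2.1,
    hd810_time_h = 182.4,
    ebt_film_size_cm = c(3, 3),
    hd810_film_size_cm = c(9, 9),    # far field; the physical 5x5 piece
                                     # cannot reach r = 4 cm on-axis
    noise = TRUE,
    lra = FALSE,
    dpi = 300,
    g_column = "mcnp",
    lambda = 1.112,
    anisotropy_dip = 0.06,
    dip_exponent = 2.5,
    dr = 0.05,
    dtheta = 1,
    ebt_g_radii = c(1, 1.5),
    hd810_g_radii = c(1, 1.5, 2, 2.5, 3, 3.5, 4),
    f_radii = c(1, 2, 3),
    f_angles = seq(10, 170, by = 10),
    g_decimals = 4,
    diff_decimals = 1
  )
}

validate_config <- function(cfg) {
  check_scalar(cfg$activity_Bq, "activity_Bq", nonneg = TRUE)
  check_scalar(cfg$dpi, "dpi", positive = TRUE)
  check_scalar(cfg$dr, "dr", positive = TRUE)
  check_scalar(cfg$dtheta, "dtheta", positive = TRUE)
  if (!all(cfg$film_kinds %in% c("EBT", "HD810")))
    stop_config("film_kinds must be a subset of EBT, HD810")
  invisible(cfg)
}

#' Read a flat key-value config file
#'
#' YAML-style `key: value` lines; `#` comments and blank lines ignored.
#' Values are parsed as numeric vectors (comma-separated) when possible,
#' `true`/`false` as logical, otherwise kept as strings. Keys must exist in
#' [default_config()].
#'
#' @param path config file path.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop_config(sprintf("cannot parse config line: '%s'", ln))
    key <- m[2]; val <- trimws(m[3])
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    over[[key]] <-
      if (!any(is.na(num))) num
      else if (length(parts) == 1L && tolower(parts) %in% c("true", "false"))
        tolower(parts) == "true"
      else parts
  }
  do.call(pipeline_config, over)
}

log_line <- function(log, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 sprintf(fmt, ...))
  if (!is.null(log)) cat(msg, "\n", file = log, append = TRUE, sep = "")
  invisible(msg)
}

run_stage <- function(stage, log, expr) {
  log_line(log, "stage %s: start", stage)
  tryCatch(expr, error = function(e) {
    abort2(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)),
           "tg43_pipeline_error")
  })
}

simulate_film <- function(truth, cfg, kind, seed) {
  film <- film_spec(kind, size_cm = if (kind == "EBT") cfg$ebt_film_size_cm
                    else cfg$hd810_film_size_cm)
  if (!cfg$noise) film$uniformity_sigma_pct <- 0
  plan <- exposure_plan(activity_Bq = cfg$activity_Bq,
                        time_h = if (kind == "EBT") cfg$ebt_time_h
                        else cfg$hd810_time_h,
                        film = film, dpi = cfg$dpi)
  scanner <- scanner_spec(
    consistency_sigma_pct = if (!cfg$noise) 0
    else if (kind == "EBT") 1.5 else 1,
    lra_profile = if (isTRUE(cfg$lra)) lra_quadratic() else NULL)
  set.seed(sub_seed(seed, paste0("experiment_", kind)))
  dm <- dose_map_forward(truth, plan, beyond_range = "mask")
  netod <- film_response_forward(dm, film, uniformity = cfg$noise)
  scan <- render_scan(netod, scanner, S0 = film$unexposed_signal,
                      dpi = cfg$dpi)
  set.seed(sub_seed(seed, paste0("calibration_", kind)))
  cal <- generate_calibration_set(
    film, scanner = scanner, dpi = cfg$dpi,
    flatness_sigma_pct = if (!cfg$noise) 0 else NULL)
  list(film = film, plan = plan, scanner = scanner, dose_map = dm,
       scan = scan, calibration = cal)
}

#' Measure calibration strips and fit the conversion polynomial
#'
#' Takes the mean signal in a centered disc ROI on every strip, forms net
#' optical densities against the background strip and fits the calibration
#' polynomial (order 3 for EBT-like, 4 for HD810-like). The ROI radius
#' defaults to 0.4 cm so the disc fits the 1 x 1.5 cm calibration pieces.
#'
#' @param cal result of [generate_calibration_set()].
#' @param film a [film_spec()].
#' @param roi_radius_cm calibration-strip ROI radius, cm.
#' @return a [fit_calibration()] curve.
#' @export
calibrate_film_set <- function(cal, film, roi_radius_cm = 0.4) {
  strips <- cal$strips
  n <- length(strips)
  size <- dim(scan_channel(strips[[1]]))
  pitch <- pixel_pitch_cm(strips[[1]]$dpi)
  center <- c(size[2], size[1]) * pitch / 2
  roi <- roi_disc(center, area_cm2 = pi * roi_radius_cm^2)
  S <- vapply(strips, mean_pixel_roi, numeric(1), roi = roi)
  S0 <- S[n]  # trailing background strip
  netod <- optical_density(S0, S[-n])
  dose <- cal$manifest$nominal_dose_Gy[-n]
  fit_calibration(netod, dose, order = if (film$film_kind == "EBT") 3 else 4,
                  film_kind = film$film_kind)
}

#' Run the full virtual-experiment pipeline
#'
#' Chains simulate -> calibrate -> convert -> polar resample -> extract ->
#' budget -> compare for every configured film kind. Deterministic for a
#' given seed (per-stage sub-seeds are derived from it); any stage error
#' aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param seed master seed (overrides `config$seed` when given).
#' @param outdir optional directory: report tables, a log and provenance
#'   sidecars are written there via [render_tables()].
#' @return list of class `pipeline_result`: `truth`, per-kind results
#'   (`curve`, `map`, `extraction`), `budgets`, `comparison`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = NULL,
                         outdir = NULL) {
  validate_config(config)
  if (is.null(seed)) seed <- config$seed
  log <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    log <- file.path(outdir, "pipeline.log")
    if (file.exists(log)) file.remove(log)
  }
  truth <- run_stage("truth", log, reference_tg43_dataset(
    g_column = config$g_column, lambda = config$lambda,
    dip = config$anisotropy_dip, exponent = config$dip_exponent))
  per_kind <- list()
  for (kind in config$film_kinds) {
    sim <- run_stage(paste0("simulate_", kind), log,
                     simulate_film(truth, config, kind, seed))
    curve <- run_stage(paste0("calibrate_", kind), log,
                       calibrate_film_set(sim$calibration, sim$film))
    rec <- run_stage(paste0("reconstruct_", kind), log, {
      bg <- sim$calibration$strips[[length(sim$calibration$strips)]]
      fdm <- convert_dose(sim$scan, bg, curve)
      fdm$pitch_cm <- pixel_pitch_cm(sim$scan$dpi)
      pose <- list(xy_cm = sim$dose_map$source_xy_cm,
                   axis_deg = sim$dose_map$axis_deg)
      to_dose_rate_map(fdm, sim$plan, pose = pose,
                       dr = config$dr, dtheta = config$dtheta)
    })
    g_radii <- if (kind == "EBT") config$ebt_g_radii else config$hd810_g_radii
    extr <- run_stage(paste0("extract_", kind), log, list(
      lambda = extract_dose_rate_constant(rec, truth$source),
      g = extract_radial_dose_function(rec, truth$source, radii = g_radii),
      anisotropy = extract_anisotropy(
        rec, truth$source,
        radii = config$f_radii[config$f_radii <=
                                 max(g_radii[!is.na(g_radii)])],
        angles = config$f_angles)
    ))
    per_kind[[kind]] <- list(sim = sim, curve = curve, map = rec,
                             extraction = extr)
    log_line(log, "%s: lambda = %.4f, max |cal resid| = %.2f%%",
             kind, extr$lambda, max(abs(curve$residual_pct)))
  }
  budgets <- run_stage("budget", log, {
    out <- list()
    for (kind in intersect(c("EBT", "HD810"), config$film_kinds)) {
      calb <- calibration_budget(kind)
      cal_overall <- round_half_out(combine_budget(calb)$overall, 1)
      expb <- chain_film_budget(cal_overall, experimental_budget(kind))
      out[[kind]] <- list(calibration = calb, experimental = expb,
                          calibration_overall = cal_overall,
                          experimental_overall =
                            round_half_out(combine_budget(expb)$overall, 1))
    }
    out$mc <- mc_budget(0.1, 0.5, 0.4, 0.71, decimals = 2)
    out
  })
  comparison <- run_stage("compare", log, {
    ref_lambda <- truth$dose_rate_constant
    lam <- lapply(per_kind, function(x) x$extraction$lambda)
    diffs <- lapply(lam, function(l)
      relative_difference(l, ref_lambda, ref_lambda,
                          decimals = config$diff_decimals))
    g_cmp <- NULL
    if ("HD810" %in% names(per_kind)) {
      truth_g <- data.frame(r_cm = truth$radial_table$r_cm,
                            g = truth$radial_table$g)
      g_cmp <- compare_g_tables(per_kind$HD810$extraction$g, truth_g,
                                decimals = config$diff_decimals)
    }
    list(lambda = lam, lambda_diff_pct = diffs, g = g_cmp)
  })
  res <- structure(list(truth = truth, films = per_kind, budgets = budgets,
                        comparison = comparison, config = config,
                        seed = seed),
                   class = "pipeline_result")
  if (!is.null(outdir)) render_tables(res, outdir)
  res
}

#' Write the report tables
#'
#' Emits CSVs mirroring the conventional report layout: a dose-rate-constant
#' table (extracted values plus the packaged literature column), a radial
#' dose function table (per method, including the reference-source fixture
#' columns), anisotropy grids, the budget tables and the comparison
#' statistics. Stable column order; deterministic bytes for a fixed seed.
#'
#' @param res a [run_pipeline()] result.
#' @param outdir output directory.
#' @return paths written, invisibly.
#' @export
render_tables <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  # dose rate constants
  lam_ref <- dose_rate_constant_reference()
  lam_ext <- data.frame(
    source = "virtual IRAsource",
    method = paste0(names(res$films), " film (virtual)"),
    lambda_cGy_per_hU = round_half_out(
      vapply(res$films, function(x) x$extraction$lambda, numeric(1)), 4),
    uncertainty_k1 = NA_real_)
  wr(rbind(lam_ref, lam_ext), "lambda_table.csv")
  # radial dose function
  ref <- radial_dose_reference()
  gtab <- ref
  for (kind in names(res$films)) {
    g <- res$films[[kind]]$extraction$g
    col <- round_half_out(g$g[match(ref$r_cm, g$r_cm)], res$config$g_decimals)
    gtab[[paste0(tolower(kind), "_virtual")]] <- col
  }
  wr(gtab, "radial_dose_table.csv")
  # anisotropy
  for (kind in names(res$films)) {
    an <- res$films[[kind]]$extraction$anisotropy
    if (all(is.na(an$F))) {
      warning(sprintf("anisotropy grid for %s is empty; table omitted", kind))
      next
    }
    df <- data.frame(theta_deg = an$theta_deg,
                     round_half_out(an$F, res$config$g_decimals),
                     check.names = FALSE)
    names(df) <- c("theta_deg", paste0("r_", an$r_cm))
    wr(df, sprintf("anisotropy_%s.csv", tolower(kind)))
  }
  # budgets
  for (kind in intersect(c("EBT", "HD810"), names(res$budgets))) {
    wr(budget_table(res$budgets[[kind]]$calibration),
       sprintf("budget_calibration_%s.csv", tolower(kind)))
    wr(budget_table(res$budgets[[kind]]$experimental),
       sprintf("budget_experimental_%s.csv", tolower(kind)))
  }
  wr(as.data.frame(res$budgets$mc), "budget_mc.csv")
  # comparison
  cmp <- res$comparison
  cmp_df <- data.frame(
    quantity = paste0("lambda_diff_", names(cmp$lambda_diff_pct), "_vs_truth_pct"),
    value = unlist(cmp$lambda_diff_pct))
  if (!is.null(cmp$g))
    cmp_df <- rbind(cmp_df, data.frame(
      quantity = c("g_max_diff_pct", "g_max_diff_at_r_cm"),
      value = c(cmp$g$max_diff_pct, cmp$g$at_r_cm)))
  wr(cmp_df, "comparison.csv")
  # provenance sidecar
  prov <- list(seed = res$seed, config = unclass(res$config))
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA, null = "null"),
             file.path(outdir, "provenance.json"))
  paths <- c(paths, file.path(outdir, "provenance.json"))
  invisible(paths)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (kind in names(x$films))
    cat(sprintf("  %s: lambda = %.4f (truth %.4f)\n", kind,
                x$films[[kind]]$extraction$lambda,
                x$truth$dose_rate_constant))
  invisible(x)
}
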