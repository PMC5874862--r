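# Independent oracles and small fixtures shared across the suite.

# beta by explicit endpoint trigonometry: angles of the vectors from the
# point to the two line endpoints (independent of the package's atan2 form
# only in derivation; kept separate so regressions in either show up)
oracle_beta <- function(r, theta_deg, L) {
  th <- theta_deg * pi / 180
  x <- r * sin(th); z <- r * cos(th)
  abs(atan2(x, z - L / 2) - atan2(x, z + L / 2))
}

# brute-force numerical line integral (1/L) * int dl / |p - l|^2
oracle_G_integral <- function(r, theta_deg, L) {
  th <- theta_deg * pi / 180
  x <- r * sin(th); z <- r * cos(th)
  stats::integrate(function(l) 1 / (x^2 + (z - l)^2), -L / 2, L / 2,
                   rel.tol = 1e-10)$value / L
}

# small truth dataset with flat g and F (for isolation tests)
flat_truth <- function(lambda = 1.112, r_max = 5) {
  tg43_dataset(lambda,
               data.frame(r_cm = c(0.2, 1, r_max), g = c(1, 1, 1)),
               list(r_cm = c(0.2, r_max), theta_deg = c(0, 90, 180),
                    F = matrix(1, 3, 2)))
}

# quick noiseless EBT-like simulation at reduced size/resolution
quick_noiseless_sim <- function(size_cm = c(2.4, 2.4), dpi = 150,
                                time_h = 2.1, truth = NULL) {
  if (is.null(truth)) truth <- reference_tg43_dataset()
  film <- film_spec("EBT", size_cm = size_cm)
  film$uniformity_sigma_pct <- 0
  plan <- exposure_plan(Sk = 188.5, time_h = time_h, film = film, dpi = dpi)
  scanner <- scanner_spec(consistency_sigma_pct = 0)
  dm <- dose_map_forward(truth, plan)
  netod <- film_response_forward(dm, film, uniformity = FALSE)
  scan <- render_scan(netod, scanner, S0 = film$unexposed_signal, dpi = dpi)
  cal <- generate_calibration_set(film, scanner = scanner,
                                  flatness_sigma_pct = 0, dpi = dpi)
  list(truth = truth, film = film, plan = plan, dm = dm, scan = scan,
       cal = cal)
}
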