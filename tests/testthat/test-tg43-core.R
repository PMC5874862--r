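# Line-source geometry function, dose-rate equation and interpolation.

test_that("beta_subtended matches the endpoint-trigonometry oracle", {
  # frozen oracle values
  expect_equal(beta_subtended(1, 90, 0.35), 0.346491333, tolerance = 1e-8)
  expect_equal(beta_subtended(0.5, 90, 0.35), 2 * atan(0.35), tolerance = 1e-12)
  expect_equal(beta_subtended(1, 90, 0), 0)
  # property: agreement with the oracle over a grid, and mirror symmetry
  set.seed(42)
  r <- runif(50, 0.3, 8)
  th <- runif(50, 1, 179)
  expect_equal(beta_subtended(r, th, 0.35), oracle_beta(r, th, 0.35),
               tolerance = 1e-12)
  expect_equal(beta_subtended(r, th, 0.35),
               beta_subtended(r, 180 - th, 0.35), tolerance = 1e-13)
  expect_true(all(beta_subtended(r, th, 0.35) >= 0))
  expect_true(all(beta_subtended(r, th, 0.35) <= pi))
})

test_that("beta_subtended degenerate and error cases", {
  expect_equal(beta_subtended(1, 0, 0.35), 0)
  expect_equal(beta_subtended(1, 180, 0.35), 0)
  expect_error(beta_subtended(0.1, 0, 0.35), class = "tg43_domain_error")
  expect_error(beta_subtended(-1, 90, 0.35), class = "tg43_domain_error")
  expect_error(beta_subtended(1, 190, 0.35), class = "tg43_domain_error")
})

test_that("geometry_function_linear: frozen values and closed-form poles", {
  expect_equal(geometry_function_linear(1, 90, 0.35), 0.989975237,
               tolerance = 1e-8)
  expect_equal(geometry_function_linear(1, 0, 0.35), 1 / (1 - 0.35^2 / 4),
               tolerance = 1e-12)
  expect_equal(geometry_function_linear(1, 0, 0.35), 1.031592521,
               tolerance = 1e-8)
  # continuity at the pole
  expect_equal(geometry_function_linear(1, 1e-4, 0.35),
               geometry_function_linear(1, 0, 0.35), tolerance = 1e-6)
  expect_error(geometry_function_linear(0.1, 90, 0.35),
               class = "tg43_domain_error")
})

test_that("geometry_function_linear agrees with the line-integral oracle", {
  for (r in c(0.5, 1, 2.7, 6)) for (th in c(3, 30, 90, 145, 177)) {
    expect_equal(geometry_function_linear(r, th, 0.35),
                 oracle_G_integral(r, th, 0.35),
                 tolerance = 1e-6)
  }
})

test_that("geometry function point-source limit is monotone in L", {
  Ls <- c(0.35, 0.2, 0.1, 0.05, 0.01)
  for (r in c(1, 2)) {
    dev <- abs(sapply(Ls, function(L) geometry_function_linear(r, 90, L)) -
                 1 / r^2)
    expect_true(all(diff(dev) < 0))
    expect_lt(dev[length(dev)], 1e-5 / r^2)
  }
  expect_equal(geometry_function_point(c(1, 2, 0.5)), c(1, 0.25, 4))
  expect_error(geometry_function_point(0), class = "tg43_domain_error")
})

make_table3_dataset <- function() {
  ref <- radial_dose_reference()
  keep <- !is.na(ref$mcnp)
  tg43_dataset(1.112,
               data.frame(r_cm = ref$r_cm[keep], g = ref$mcnp[keep]),
               list(r_cm = c(1, 4), theta_deg = c(0, 90, 180),
                    F = matrix(1, 3, 2)))
}

test_that("interp_g is exact at nodes and linear between them", {
  ds <- make_table3_dataset()
  expect_equal(interp_g(ds, 2), 1.0044)
  expect_equal(interp_g(ds, 1), 1)
  expect_equal(interp_g(ds, 1.75), 1.00355)  # hand interpolation
  err <- expect_error(interp_g(ds, 5), class = "tg43_range_error")
  expect_match(conditionMessage(err), "\\[1, 4\\]")
  expect_error(interp_g(ds, 0.5), class = "tg43_range_error")
})

test_that("interp_F is bilinear and exact at grid nodes", {
  theta <- c(0, 45, 90, 135, 180)
  r <- c(0.5, 2, 4)
  Fm <- 1 - 0.08 * abs(cos(theta * pi / 180))^2 %o% rep(1, 3) *
    matrix(rep(c(1.2, 1, 0.9), each = 5), 5, 3)
  Fm[3, ] <- 1
  ds <- tg43_dataset(1, data.frame(r_cm = c(0.5, 1, 4), g = c(1, 1, 1)),
                     list(r_cm = r, theta_deg = theta, F = Fm))
  for (i in seq_along(theta)) for (j in seq_along(r))
    expect_equal(interp_F(ds, r[j], theta[i]), Fm[i, j])
  # hand bilinear midpoint
  expect_equal(interp_F(ds, 1.25, 67.5),
               mean(Fm[2:3, 1:2]), tolerance = 1e-12)
  expect_error(interp_F(ds, 5, 90), class = "tg43_range_error")
})

test_that("tg43_dataset enforces its invariants", {
  good_rad <- data.frame(r_cm = c(0.5, 1, 2), g = c(1.01, 1, 1.005))
  an <- list(r_cm = c(0.5, 2), theta_deg = c(0, 90, 180), F = matrix(1, 3, 2))
  expect_s3_class(tg43_dataset(1.1, good_rad, an), "tg43_dataset")
  # g(1) must interpolate to 1
  bad_g <- data.frame(r_cm = c(0.5, 2), g = c(1.01, 1.005))
  expect_error(tg43_dataset(1.1, bad_g, an), class = "tg43_domain_error")
  # radii strictly increasing
  expect_error(tg43_dataset(1.1, data.frame(r_cm = c(1, 1), g = c(1, 1)), an),
               class = "tg43_domain_error")
  # F must be 1 on the transverse axis
  an_bad <- an; an_bad$F[2, 1] <- 1.02
  expect_error(tg43_dataset(1.1, good_rad, an_bad),
               class = "tg43_domain_error")
  # positive Lambda
  expect_error(tg43_dataset(-1, good_rad, an), class = "tg43_domain_error")
})

test_that("dose_rate reference-point identity holds exactly", {
  # for any admissible dataset, D(r0, theta0) = Sk * Lambda
  set.seed(7)
  for (i in 1:5) {
    lam <- runif(1, 0.9, 1.3)
    g2 <- runif(1, 0.95, 1.05)
    ds <- tg43_dataset(lam,
                       data.frame(r_cm = c(0.5, 1, 2), g = c(1, 1, g2)),
                       list(r_cm = c(0.5, 2), theta_deg = c(0, 90, 180),
                            F = matrix(c(0.9, 1, 0.95), 3, 2)))
    Sk <- runif(1, 1, 200)
    expect_equal(dose_rate(Sk, ds, 1, 90), Sk * lam, tolerance = 1e-15)
  }
  ds <- flat_truth(lambda = 1.112)
  expect_equal(dose_rate(1, ds, 1, 90), 1.112)
  expect_equal(dose_rate(0, ds, 2, 40), 0)
  # oracle-derived product at r = 2 (flat g and F)
  expect_equal(dose_rate(188.5, ds, 2, 90), 52.7992, tolerance = 1e-5)
  expect_error(dose_rate(1, ds, 10, 90), class = "tg43_range_error")
})

test_that("TG-43 dataset CSV round trip preserves tables and invariants", {
  ds <- reference_tg43_dataset()
  rad <- withr::local_tempfile(fileext = ".csv")
  an <- withr::local_tempfile(fileext = ".csv")
  write_tg43_dataset(ds, rad, an)
  ds2 <- read_tg43_dataset(rad, an, dose_rate_constant = ds$dose_rate_constant)
  expect_equal(ds2$radial_table, ds$radial_table)
  expect_equal(ds2$anisotropy$r_cm, ds$anisotropy$r_cm)
  expect_equal(unname(ds2$anisotropy$F), unname(ds$anisotropy$F))
  expect_equal(interp_F(ds2, 1.3, 37), interp_F(ds, 1.3, 37))
})

test_that("source_model validates dimensions; table fixture row matches default", {
  src <- source_model()
  expect_equal(src$active_length, 0.35)
  expect_equal(src$total_length, 0.43)
  tab <- hdr_source_table()
  ira <- as_source_model(tab[tab$source == "IRAsource", ])
  expect_equal(ira[c("active_length", "total_length", "active_core_diameter",
                     "external_diameter")],
               src[c("active_length", "total_length", "active_core_diameter",
                     "external_diameter")])
  expect_error(source_model(active_length = 0.5, total_length = 0.43),
               class = "tg43_domain_error")
  expect_error(source_model(active_length = -1), class = "tg43_domain_error")
  expect_error(polar_point(1, 181), class = "tg43_domain_error")
  expect_error(polar_point(0, 90), class = "tg43_domain_error")
})
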