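# Virtual experiment: forward dose model, film response, scanner, and
# calibration sets.

test_that("sk_from_activity converts correctly", {
  expect_equal(sk_from_activity(1), 10.19e-8)
  expect_equal(sk_from_activity(0), 0)
  expect_equal(sk_from_activity(1.85e9), 188.5, tolerance = 1e-3)
  expect_error(sk_from_activity(-1), class = "tg43_domain_error")
})

test_that("dose_map_forward reproduces the TG-43 dose pixelwise", {
  truth <- reference_tg43_dataset()
  film <- film_spec("EBT", size_cm = c(2.4, 2.4))
  plan <- exposure_plan(Sk = 188.5, time_h = 2.1, film = film, dpi = 150)
  dm <- dose_map_forward(truth, plan)
  # reference-point product: 188.5 * 1.112 * 2.1 cGy = 4.40186 Gy
  expect_equal(dose_rate(188.5, truth, 1, 90) * 2.1 / 100, 4.40186,
               tolerance = 1e-5)
  # a pixel's value equals dose_rate at that pixel's exact polar coordinates
  pitch <- 2.54 / 150
  i <- 20; j <- 55
  dx <- (j - 0.5) * pitch - dm$source_xy_cm[1]
  dy <- (i - 0.5) * pitch - dm$source_xy_cm[2]
  r <- sqrt(dx^2 + dy^2)
  th <- acos(dx / r) * 180 / pi
  expect_equal(dm$dose_Gy[i, j],
               dose_rate(188.5, truth, r, th) * 2.1 / 100,
               tolerance = 1e-12)
  # mirror symmetry across the source axis
  expect_equal(dm$dose_Gy, dm$dose_Gy[nrow(dm$dose_Gy):1, ],
               tolerance = 1e-12)
  # t = 0 gives an all-zero map
  plan0 <- exposure_plan(Sk = 188.5, time_h = 0, film = film, dpi = 150)
  expect_true(all(dose_map_forward(truth, plan0)$dose_Gy == 0))
})

test_that("dose_map_forward masks near-source pixels and checks range", {
  truth <- reference_tg43_dataset()
  film <- film_spec("EBT", size_cm = c(2, 2))
  plan <- exposure_plan(Sk = 10, time_h = 1, film = film, dpi = 150)
  dm <- dose_map_forward(truth, plan, r_min = 0.3)
  pitch <- 2.54 / 150
  expect_gt(sum(dm$mask), 0)
  expect_equal(mean(dm$mask), pi * 0.3^2 / 4, tolerance = 0.05)
  # oversized film: range error by default; corners maskable on request,
  # but a film mostly outside the tables is always an error
  big <- exposure_plan(Sk = 10, time_h = 1,
                       film = film_spec("HD810", size_cm = c(11, 11)),
                       dpi = 75)
  expect_error(dose_map_forward(truth, big), class = "tg43_range_error")
  dm2 <- dose_map_forward(truth, big, beyond_range = "mask")
  expect_true(any(dm2$mask))
  huge <- exposure_plan(Sk = 10, time_h = 1,
                        film = film_spec("HD810", size_cm = c(20, 20)),
                        dpi = 75)
  expect_error(dose_map_forward(truth, huge, beyond_range = "mask"),
               class = "tg43_range_error")
})

test_that("film response is invertible and its noise field is seeded", {
  film <- film_spec("EBT")
  D <- c(0, 0.5, 2, 5, 8)
  expect_equal(netod_from_dose(film, 0), 0)
  expect_equal(dose_from_netod(film, netod_from_dose(film, D[-1])), D[-1],
               tolerance = 1e-9)
  expect_true(all(diff(netod_from_dose(film, seq(0, 9, 0.1))) > 0))
  # zero dose, no noise -> netOD identically 0
  dm <- matrix(0, 20, 20)
  expect_true(all(film_response_forward(dm, film, uniformity = FALSE) == 0))
  # seeded determinism of the uniformity field
  dm <- matrix(2, 50, 60)
  set.seed(11); a <- film_response_forward(dm, film)
  set.seed(11); b <- film_response_forward(dm, film)
  expect_identical(a, b)
  # field magnitude ~ uniformity_sigma (low-frequency, so wide tolerance)
  set.seed(12)
  big <- film_response_forward(matrix(2, 300, 300), film)
  rel <- big / netod_from_dose(film, 2) - 1
  expect_gt(stats::sd(rel), 0.005)
  expect_lt(stats::sd(rel), 0.045)
})

test_that("render_scan inverts the OD definition, clips and quantizes", {
  sc0 <- scanner_spec(consistency_sigma_pct = 0)
  img <- render_scan(matrix(0, 10, 10), sc0, S0 = 40000)
  expect_true(all(img$pixels == 40000))
  img1 <- render_scan(matrix(1, 4, 4), sc0, S0 = 40000)
  expect_true(all(img1$pixels == 4000))
  # seeded scan noise: ROI mean within 3 sigma/sqrt(n) of nominal
  sc <- scanner_spec(consistency_sigma_pct = 1.5)
  set.seed(21)
  strip <- render_scan(matrix(0.3, 118, 118), sc, S0 = 40000)
  nominal <- 40000 * 10^-0.3
  m <- mean(strip$pixels)
  expect_lt(abs(m - nominal), 3 * nominal * 0.015 / sqrt(118^2))
  # determinism: same seed, bit-identical TIFF bytes
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  set.seed(5); write_tiff(render_scan(matrix(0.3, 30, 30), sc), f1)
  set.seed(5); write_tiff(render_scan(matrix(0.3, 30, 30), sc), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("lateral response artifact profile behaves as specified", {
  lra <- lra_quadratic(max_dose_error_pct = 9, half_width_cm = 5)
  expect_equal(lra(0), 1)
  expect_lt(lra(5), 1)           # signal drops -> apparent dose rises
  expect_equal(lra(-5), lra(5))
  sc <- scanner_spec(consistency_sigma_pct = 0, lra_profile = lra)
  img <- render_scan(matrix(0.3, 11, 201), sc, S0 = 40000, dpi = 300)
  mid <- img$pixels[6, 101]
  expect_true(all(img$pixels[6, c(1, 201)] < mid))
})

test_that("generate_calibration_set produces the standard sets", {
  film_e <- film_spec("EBT"); film_h <- film_spec("HD810")
  expect_length(default_calibration_doses("EBT"), 12)
  expect_length(default_calibration_doses("HD810"), 17)
  expect_equal(range(default_calibration_doses("EBT")), c(0.5, 9))
  expect_equal(range(default_calibration_doses("HD810")), c(10, 500))
  sc0 <- scanner_spec(consistency_sigma_pct = 0)
  set.seed(2)
  cal <- generate_calibration_set(film_e, scanner = sc0, dpi = 75)
  expect_length(cal$strips, 13)  # 12 + background
  expect_equal(cal$manifest$nominal_dose_Gy[13], 0)
  set.seed(2)
  cal_h <- generate_calibration_set(film_h, scanner = sc0, dpi = 75)
  expect_length(cal_h$strips, 18)  # 17 + background
  expect_error(generate_calibration_set(film_e, doses = numeric(0)),
               class = "tg43_domain_error")
  expect_error(generate_calibration_set(film_e, doses = c(1, 50)),
               class = "tg43_domain_error")
  # manifest + TIFFs written when outdir given
  out <- withr::local_tempdir()
  set.seed(2)
  generate_calibration_set(film_e, doses = c(1, 2), scanner = sc0,
                           outdir = out, dpi = 75)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_length(list.files(out, pattern = "\\.tif$"), 3)
})

test_that("noiseless forward chain is invertible to the quantization limit", {
  sim <- quick_noiseless_sim()
  curve <- calibrate_film_set(sim$cal, sim$film)
  bg <- sim$cal$strips[[length(sim$cal$strips)]]
  fdm <- convert_dose(sim$scan, bg, curve)
  sel <- !fdm$mask & !sim$dm$mask & sim$dm$dose_Gy >= 0.5 &
    sim$dm$dose_Gy <= 8
  rel <- abs(fdm$dose_Gy[sel] / sim$dm$dose_Gy[sel] - 1)
  expect_lt(stats::quantile(rel, 0.99), 1e-3)
})

test_that("exposure plans respect their domains", {
  expect_error(exposure_plan(Sk = -1, time_h = 1), class = "tg43_domain_error")
  expect_error(exposure_plan(Sk = 1, time_h = -1), class = "tg43_domain_error")
  p <- exposure_plan(activity_Bq = 1.85e9, time_h = 2.1)
  expect_equal(p$Sk, 188.515, tolerance = 1e-6)
  expect_error(exposure_plan(time_h = 1), class = "tg43_config_error")
  expect_error(phantom_spec(film_plane_offset_cm = 0.2),
               class = "tg43_domain_error")
})
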