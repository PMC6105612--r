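test_that("distance exponent calibration matches the closed form and passes through both anchors", {
  m <- calibrated_model()
  # independent closed form for two anchors
  expect_equal(m$gamma, log(25.2 / 4.7) / log(35 / 20), tolerance = 1e-10)
  expect_equal(m$P_ref, 25.2)
  expect_equal(m$D_ref, 20)
  cfg35 <- microscope_config(working_distance_cm = 35)
  expect_equal(incident_power_density(cfg35, m), 4.7, tolerance = 1e-10)
  cfg20 <- microscope_config(working_distance_cm = 20)
  expect_equal(incident_power_density(cfg20, m), 25.2)

  # constructed cubic law recovers gamma = 3 exactly
  m3 <- calibrate_distance_exponent(rbind(c(20, 25.2), c(40, 25.2 / 8)))
  expect_equal(m3$gamma, 3, tolerance = 1e-12)

  # >2 anchors: gamma equals a brute-force log-log regression slope
  d <- c(20, 25, 30, 35)
  p <- 25.2 * (20 / d)^2.7 * exp(c(0.02, -0.01, 0.03, -0.02))
  mm <- calibrate_distance_exponent(cbind(d, p))
  x <- -log(d); y <- log(p)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(mm$gamma, slope, tolerance = 1e-10)
})

test_that("calibration rejects degenerate or invalid anchors", {
  expect_error(calibrate_distance_exponent(rbind(c(20, 25.2))), "at least 2")
  expect_error(calibrate_distance_exponent(rbind(c(20, 10), c(30, 10))),
               "strictly decrease")
  expect_error(calibrate_distance_exponent(rbind(c(20, -1), c(30, 5))),
               "positive")
  expect_error(calibrate_distance_exponent(rbind(c(20, 5), c(20, 4))),
               "distinct")
})

test_that("incident power density is linear in setting, homogeneous in gain, decreasing in distance", {
  m <- calibrated_model()
  p <- function(s, d, g = 1)
    incident_power_density(microscope_config(s, d, gain = g), m)
  expect_equal(p(0.5, 20), 0.5 * p(1, 20))
  expect_equal(p(0, 27), 0)
  expect_equal(p(1, 25, g = 2), 2 * p(1, 25))
  dists <- seq(20, 40, by = 2.5)
  expect_true(all(diff(vapply(dists, function(d) p(1, d), 0)) < 0))
  # 25-cm prediction sits inside the measured 8.9-18.4 mW/cm^2 range
  expect_equal(p(1, 25), 25.2 * (20 / 25)^m$gamma)
  expect_gt(p(1, 25), 8.9)
  expect_lt(p(1, 25), 18.4)
  for (g in c(0.71, 1, 1.4))
    expect_true(p(1, 25, g) > 8.9 && p(1, 25, g) < 18.4)
})

test_that("beam field is bell-shaped, peak-normalized and vertically skewed", {
  m <- calibrated_model()
  cfg <- microscope_config(tilt_skew = 1.15)
  f <- beam_field(cfg, m, c(101, 101), pitch_mm = 0.5)
  peak <- incident_power_density(cfg, m)
  expect_equal(max(f), peak)
  expect_equal(which(f == max(f)), (51 - 1) * 101 + 51)  # centre pixel (51,51)
  # strictly decreasing away from the peak along both axes
  expect_true(all(diff(f[51, 51:101]) < 0))
  expect_true(all(diff(f[51:101, 51]) < 0))
  expect_true(all(diff(rev(f[1:51, 51])) < 0))
  # skew: 5 mm above the peak (10 px up) brighter than 5 mm below
  expect_gt(f[41, 51], f[61, 51])
  # analytic two-sided Gaussian value at +5 mm / -5 mm
  scale <- cfg$working_distance_cm / m$D_ref
  expect_equal(f[41, 51], peak * exp(-0.5 * (5 / (m$sigma_y_mm * 1.15 * scale))^2))
  expect_equal(f[61, 51], peak * exp(-0.5 * (5 / (m$sigma_y_mm * scale))^2))
  # horizontal symmetry always; vertical symmetry iff tilt_skew = 1
  expect_equal(f[, 51 + 1:50], f[, 51 - 1:50])
  f1 <- beam_field(microscope_config(tilt_skew = 1), m, c(101, 101), 0.5)
  expect_equal(f1[51 + 1:50, ], f1[51 - 1:50, ])
  expect_error(beam_field(cfg, m, c(10, 10), pitch_mm = 0), "positive")
})

test_that("dose/time conversion reproduces the printed arithmetic and round-trips", {
  expect_equal(dose_to_time(14.4, 25.2) / 60, 9.5, tolerance = 0.005)
  expect_equal(dose_to_time(12.4, 8) / 60, 25.8, tolerance = 0.005)
  expect_equal(dose_to_time(0, 13), 0)
  for (dose in c(0.01, 1, 14.4, 50)) {
    for (p in c(4.7, 8, 25.2)) {
      expect_equal(time_to_dose(dose_to_time(dose, p), p), dose)
    }
  }
  expect_error(dose_to_time(1, 0), "positive")
  expect_error(dose_to_time(-1, 5), "non-negative")
})

test_that("illumination model serialization round-trips", {
  m <- calibrated_model(sigma_x_mm = 18, sigma_y_mm = 22)
  path <- withr::local_tempfile(fileext = ".json")
  write_illumination_model(m, path)
  m2 <- read_illumination_model(path)
  expect_equal(unclass(m), unclass(m2), tolerance = 1e-12)
})

test_that("power-meter CSV reader enforces the header contract", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("distance_cm,setting_pct,power_mw_cm2", "20,100,25.2", "35,100,4.7"), path)
  x <- read_power_meter(path)
  expect_equal(x$power_mw_cm2, c(25.2, 4.7))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("d,s,p", "20,100,25.2"), bad)
  expect_error(read_power_meter(bad), "header")
})
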