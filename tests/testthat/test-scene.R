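test_that("standard emission is linear in thickness with concentration-ordered slope and bounded drift", {
  p <- 25.2
  lo <- standard_spec(0.04, 0.5)
  hi <- standard_spec(0.04, 8.1)
  expect_equal(standard_emission(standard_spec(0, 0.5), p, 0, p), 0)
  # linear in thickness at fixed concentration
  e1 <- standard_emission(standard_spec(0.02, 2.7), p, 0, p)
  e2 <- standard_emission(standard_spec(0.04, 2.7), p, 0, p)
  e4 <- standard_emission(standard_spec(0.08, 2.7), p, 0, p)
  expect_equal(e2, 2 * e1)
  expect_equal(e4, 4 * e1)
  # higher concentration emits strictly more at equal thickness
  expect_gt(standard_emission(hi, p, 0, p), standard_emission(lo, p, 0, p))
  # drift reaches its +3.5% maximum at 30 min and stays bounded
  s <- standard_spec(0.02, 0.5, drift_30min = 0.035)
  expect_equal(standard_emission(s, p, 30, p) / standard_emission(s, p, 0, p),
               1.035)
  for (t in c(0, 5, 10, 20, 30)) {
    ratio <- standard_emission(s, p, t, p) / standard_emission(s, p, 0, p)
    expect_lte(abs(ratio - 1), 0.035 + 1e-12)
  }
  expect_error(standard_spec(0.02, 0.5, drift_30min = 0.05), "0.035")
  expect_error(standard_emission(s, -1, 0, p), "non-negative")
})

test_that("tissue emission follows irradiance-scaled logarithmic bleaching", {
  tumor <- tissue_spec("tumor", I0 = 36.8, c_log = -8.94)
  p <- 25.2
  expect_equal(tissue_emission(tumor, p, 0, p), 36.8)
  expect_equal(tissue_emission(tumor, p, 10, p), 36.8 - 8.94 * log(11))
  expect_equal(round(tissue_emission(tumor, p, 10, p), 1), 15.4)
  # no light, no bleaching
  expect_equal(tissue_emission(tumor, 0, 30, p), 36.8)
  # halved irradiance halves the decay coefficient
  full <- 36.8 - tissue_emission(tumor, p, 10, p)
  half <- 36.8 - tissue_emission(tumor, p / 2, 10, p)
  expect_equal(half, full / 2)
  # monotone non-increasing and floored at zero
  tt <- c(0, 1, 2, 5, 10, 20, 30, 200)
  vals <- vapply(tt, function(t) tissue_emission(tumor, p, t, p), 0)
  expect_true(all(diff(vals) <= 0))
  expect_gte(min(vals), 0)
  expect_error(tissue_spec("dark_background", 1.5, -1), "c_log = 0")
  expect_error(tissue_spec("brain", 8, 0.5), "<= 0")
})

test_that("default glioma constants reproduce the printed trajectories", {
  lay <- default_glioma_layout()
  specs <- setNames(lapply(lay$regions, `[[`, "spec"),
                    vapply(lay$regions, `[[`, "", "id"))
  tumor <- specs$tumor; brain <- specs$brain
  p <- 25.2
  tbr <- function(t) tissue_emission(tumor, p, t, p) / tissue_emission(brain, p, t, p)
  expect_equal(tbr(0), 4.6)
  expect_equal(round(tbr(10), 1), 2.8)
  expect_equal(tissue_emission(brain, p, 0, p), 8.0)
  expect_equal(round(tissue_emission(brain, p, 30, p), 1), 4.4)
  expect_equal(round(tissue_emission(brain, p, 30, p) / lay$floor$I0, 2), 2.86)
  expect_equal(round(tissue_emission(brain, p, 0, p) / lay$floor$I0, 1), 5.2)
})

test_that("the default schedule yields 15 frames and the six analysis ROIs", {
  d <- study_design(seed = 1)
  expect_length(d$times_min, 15)
  expect_identical(d$times_min, c(0:10, 15, 20, 25, 30))
  labels <- vapply(design_rois(d), `[[`, "", "label")
  expect_true(all(c("standard-1", "standard-4", "standard-6", "standard-9",
                    "tumor", "brain") %in% labels))
  expect_error(study_design(times_min = c(1, 2, 3), seed = 1), "start at 0")
  expect_error(study_design(times_min = c(0, 2, 2), seed = 1), "strictly increasing")
  expect_error(study_design(n_specimens = 0, seed = 1), "n_specimens")
})

test_that("overlapping scene regions raise a layout error", {
  lay <- default_glioma_layout()
  lay$regions[[5]]$center_mm <- c(4.5, 0)  # tumor shoved onto brain
  expect_error(study_design(layout = lay, seed = 1), "overlap")
  lay2 <- default_glioma_layout()
  lay2$regions[[1]]$center_mm <- c(-24, 24)
  expect_error(study_design(layout = lay2, seed = 1), "outside the field")
})

test_that("generation is deterministic and ground truth matches the closed forms", {
  d <- small_design(n_specimens = 1, seed = 11)
  s1 <- generate_series(d)
  s2 <- generate_series(d)
  expect_identical(s1$stacks, s2$stacks)
  expect_identical(s1$ground_truth, s2$ground_truth)

  # oracle: evaluate the emission closed forms at the ROI-centre irradiance
  peak <- incident_power_density(d$cfg, d$model)
  P <- beam_field(d$cfg, d$model, d$shape, d$pitch_mm)
  g <- s1$specimen_gains$gain[1]; j <- s1$specimen_gains$tumor_jitter[1]
  gt <- s1$ground_truth
  for (id in c("standard-9", "tumor", "brain", "dark_background")) {
    reg <- Filter(function(r) r$id == id, d$layout$regions)[[1]]
    ctr <- ceiling(d$shape / 2)
    px <- c(ctr[1] - reg$center_mm[2] / d$pitch_mm,
            ctr[2] + reg$center_mm[1] / d$pitch_mm)
    local_p <- P[round(px[1]), round(px[2])]
    got <- gt$radiance[gt$roi == id & gt$time_min == 10]
    want <- switch(reg$type,
      standard = standard_emission(reg$spec, local_p, 10, peak),
      tissue = (if (reg$spec$role == "tumor") g * j else g) *
        tissue_emission(reg$spec, local_p, 10, peak),
      floor = d$layout$floor$I0)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("rendered standards stay within 4% while tumor decreases monotonically", {
  d <- small_design(n_specimens = 2, seed = 3)
  ts <- run_study(d)$timeseries
  for (s in 1:2) {
    sub <- ts[ts$specimen == s, ]
    for (std in c("standard-4", "standard-6", "standard-9")) {
      v <- sub$mean[sub$roi == std]
      expect_lt(max(abs(v / v[1] - 1)), 0.04)
    }
    tumor <- sub$mean[sub$label == "tumor"]
    expect_true(all(diff(tumor) < 0))
  }
})

test_that("central regions bleach faster than peripheral ones under the bell-shaped field", {
  spec <- tissue_spec("tumor", I0 = 36.8, c_log = -8.94)
  lay <- list(regions = list(
    scene_region("central", spec, c(0, 0), 5),
    scene_region("peripheral", spec, c(16, -16), 5)),
    floor = tissue_spec("dark_background", I0 = 1.54, c_log = 0))
  d <- small_design(n_specimens = 1, seed = 5, layout = lay,
                    specimen_sigma = 0, tumor_jitter_sigma = 0)
  ts <- run_study(d)$timeseries
  fits <- fit_log_decay_table(ts, time_offset = 1)
  expect_gt(abs(fits$c[fits$roi == "central"]),
            abs(fits$c[fits$roi == "peripheral"]))
})

test_that("written studies round-trip through TIFF stacks", {
  d <- small_design(n_specimens = 1, seed = 8)
  series <- generate_series(d)
  dir <- withr::local_tempdir()
  write_study(series, dir)
  expect_true(file.exists(file.path(dir, "specimen01_external.tiff")))
  stack <- read_stack(file.path(dir, "specimen01_external.tiff"))
  expect_identical(stack, series$stacks[[1]]$external)
  rois <- read_roi_config(file.path(dir, "rois.json"))
  expect_equal(length(rois), length(series$rois))
  expect_equal(rois[[1]]$center, series$rois[[1]]$center)
})
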