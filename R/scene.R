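# Synthetic scene generator: photostable dye-in-polymer standards plus
# photobleaching tumor/brain tissue under the modelled blue beam, rendered
# through one or more camera models with per-specimen variability.

#' Dye-in-polymer standard specification
#'
#' A photostable reference sheet whose red emission is linear in thickness
#' with a concentration-dependent slope, scaled by local excitation power,
#' with a small bounded temporal drift.
#'
#' @param thickness_in Sheet thickness in inches (> 0; fabricated sheets are
#'   0.02, 0.04 or 0.08 in).
#' @param concentration_ppt Europium pigment concentration, parts-per-thousand
#'   by weight (> 0).
#' @param slope_per_ppt Emitted radiance per inch of thickness per ppt of
#'   concentration, at full excitation (a.u.).
#' @param drift_30min Signed fractional intensity change over 30 min
#'   (|drift| <= 0.035, the largest change observed in any standard).
#' @return An object of class `standard_spec`.
#' @export
standard_spec <- function(thickness_in, concentration_ppt,
                          slope_per_ppt = 100, drift_30min = 0.035) {
  if (thickness_in < 0) stop("thickness must be non-negative")
  if (concentration_ppt <= 0) stop("concentration must be positive")
  if (slope_per_ppt < 0) stop("slope_per_ppt must be non-negative")
  if (abs(drift_30min) > 0.035)
    stop("|drift over 30 min| must be <= 0.035 (photostable standard)")
  structure(list(thickness_in = thickness_in,
                 concentration_ppt = concentration_ppt,
                 slope_per_ppt = slope_per_ppt, drift_30min = drift_30min),
            class = "standard_spec")
}

#' Tissue specification
#'
#' Fluorescing tissue with logarithmic, irradiance-dependent photobleaching:
#' radiance `max(0, I0 + c_log * (P/P_ref) * ln(t + 1))`. The bleaching rate
#' scales with local excitation power, so central regions bleach faster than
#' the periphery.
#'
#' @param role `"tumor"`, `"brain"` or `"dark_background"`.
#' @param I0 Initial red radiance (a.u., >= 0).
#' @param c_log Decay coefficient (a.u. per ln(min); <= 0 for fluorescing
#'   tissue, 0 for the dark background).
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(role = c("tumor", "brain", "dark_background"),
                        I0, c_log) {
  role <- match.arg(role)
  if (I0 < 0) stop("I0 must be non-negative")
  if (role == "dark_background" && c_log != 0)
    stop("dark_background must have c_log = 0")
  if (role != "dark_background" && c_log > 0)
    stop("fluorescing tissue must have c_log <= 0")
  structure(list(role = role, I0 = I0, c_log = c_log), class = "tissue_spec")
}

#' Standard emission model
#'
#' Radiance of a dye-in-polymer standard:
#' `slope * concentration * thickness * (P / P_ref) * (1 + drift(t))`, with a
#' linear drift ramp reaching `drift_30min` at t = 30 min. Linear in
#' thickness at fixed concentration; slope increases with concentration.
#'
#' @param spec A [standard_spec()].
#' @param local_power Local excitation power density (mW/cm^2, >= 0);
#'   vectorized.
#' @param t_min Time in minutes (>= 0).
#' @param p_ref Reference (peak) power density the emission is scaled to.
#' @return Radiance in arbitrary units.
#' @export
standard_emission <- function(spec, local_power, t_min, p_ref) {
  stopifnot(inherits(spec, "standard_spec"))
  if (t_min < 0) stop("time must be non-negative")
  if (any(local_power < 0)) stop("local power must be non-negative")
  if (p_ref <= 0) stop("reference power must be positive")
  drift <- spec$drift_30min * min(t_min, 30) / 30
  spec$slope_per_ppt * spec$concentration_ppt * spec$thickness_in *
    (local_power / p_ref) * (1 + drift)
}

#' Tissue emission model
#'
#' Radiance `max(0, I0 + c_log * (P / P_ref) * ln(t + 1))`: logarithmic
#' photobleaching whose rate scales with local irradiance. Constant at `I0`
#' when there is no light (no bleaching without excitation).
#'
#' @param spec A [tissue_spec()].
#' @inheritParams standard_emission
#' @return Radiance in arbitrary units.
#' @export
tissue_emission <- function(spec, local_power, t_min, p_ref) {
  stopifnot(inherits(spec, "tissue_spec"))
  if (t_min < 0) stop("time must be non-negative")
  if (any(local_power < 0)) stop("local power must be non-negative")
  if (p_ref <= 0) stop("reference power must be positive")
  pmax(0, spec$I0 + spec$c_log * (local_power / p_ref) * log(t_min + 1))
}

#' Scene region
#'
#' A disc-shaped region of the scene carrying a standard or tissue spec, or
#' an ROI location on the dark floor (`type = "floor"`, no material of its
#' own).
#'
#' @param id,label ROI identifier and label (`standard-k`, `tumor`, `brain`,
#'   `dark_background`).
#' @param spec A [standard_spec()] or [tissue_spec()]; `NULL` for floor ROIs.
#' @param center_mm `(x, y)` centre in mm relative to the field centre
#'   (x right, y up).
#' @param radius_mm Disc radius in mm.
#' @return A `scene_region` list.
#' @export
scene_region <- function(id, spec, center_mm, radius_mm, label = id) {
  type <- if (is.null(spec)) "floor"
  else if (inherits(spec, "standard_spec")) "standard"
  else if (inherits(spec, "tissue_spec")) "tissue"
  else stop("spec must be a standard_spec, tissue_spec, or NULL")
  structure(list(id = as.character(id), label = as.character(label),
                 type = type, spec = spec, center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm),
            class = "scene_region")
}

#' Default glioma scene layout
#'
#' The layout of the murine glioma photobleaching experiment: standards 1, 4,
#' 6 and 9 (spanning the fabricated thickness/concentration grid) at the four
#' field corners, tumor and adjacent normal-brain discs near the field
#' centre, a dark floor elsewhere, and a dark-background ROI on the floor.
#'
#' Tissue constants are calibrated to the printed group trajectories:
#' tumor `36.8 - 8.94 ln(t+1)` and brain `8.0 - 1.048 ln(t+1)` give a
#' tumor-to-background ratio of 4.6 at t = 0 and 2.8 at t = 10 min, and brain
#' decay 8.0 to 4.4 a.u. over 30 min; the constant 1.54 a.u. dark floor gives
#' a brain-to-background ratio of 5.2 at t = 0 and 2.85 at 30 min.
#'
#' @param slope_per_ppt Standard brightness scale passed to [standard_spec()].
#' @return List with `regions` (list of [scene_region()]) and `floor`
#'   (a [tissue_spec()] for the dark floor).
#' @export
default_glioma_layout <- function(slope_per_ppt = 100) {
  std <- function(k, th, conc) standard_spec(th, conc, slope_per_ppt)
  regions <- list(
    scene_region("standard-1", std(1, 0.02, 0.5), c(-18, 18), 6),
    scene_region("standard-4", std(4, 0.02, 2.7), c(18, 18), 6),
    scene_region("standard-6", std(6, 0.08, 2.7), c(-18, -18), 6),
    scene_region("standard-9", std(9, 0.08, 8.1), c(18, -18), 6),
    scene_region("tumor", tissue_spec("tumor", I0 = 36.8, c_log = -8.94),
                 c(-5.7, 0), 5.6),
    scene_region("brain", tissue_spec("brain", I0 = 8.0, c_log = -1.048),
                 c(5.7, 0), 5.6),
    scene_region("dark_background", NULL, c(0, -18), 6)
  )
  list(regions = regions,
       floor = tissue_spec("dark_background", I0 = 1.54, c_log = 0))
}

#' Study design
#'
#' Full specification of a synthetic photobleaching study: acquisition
#' schedule, image geometry, microscope and illumination state, cameras,
#' scene layout and specimen variability.
#'
#' Per-specimen variability: one lognormal gain (sd `specimen_sigma` on the
#' log scale) common to tumor and brain radiance, plus an independent
#' lognormal jitter (`tumor_jitter_sigma`) applied to the tumor only, which
#' spreads the tumor-to-background ratio across specimens.
#'
#' @param n_specimens Number of specimens (>= 1).
#' @param times_min Acquisition times in minutes, strictly increasing from 0.
#'   The default is every 1 min for the first 10 min, then every 5 min to
#'   30 min (15 frames).
#' @param shape Image shape `c(nrow, ncol)` in pixels.
#' @param pitch_mm Physical pixel pitch (mm/pixel).
#' @param cfg A [microscope_config()].
#' @param model An [illumination_model()]; the default is calibrated to the
#'   measured 25.2 mW/cm^2 at 20 cm and 4.7 mW/cm^2 at 35 cm.
#' @param cameras Named list of [camera_model()]s to render with.
#' @param layout Scene layout, as from [default_glioma_layout()].
#' @param specimen_sigma Lognormal sigma of the common tumor+brain gain.
#' @param tumor_jitter_sigma Lognormal sigma of the tumor-only jitter.
#' @param blue_scale Blue-reflectance radiance at the beam peak (a.u.).
#' @param roi_radius_px Analysis ROI radius in pixels (default 51).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_specimens = 6,
                         times_min = c(0:10, seq(15, 30, by = 5)),
                         shape = c(512, 512), pitch_mm = 0.1,
                         cfg = microscope_config(),
                         model = NULL,
                         cameras = list(external = external_camera(),
                                        internal = internal_camera()),
                         layout = default_glioma_layout(),
                         specimen_sigma = 0.3, tumor_jitter_sigma = 0.15,
                         blue_scale = 100, roi_radius_px = 51, seed = 1L) {
  if (n_specimens < 1) stop("n_specimens must be >= 1")
  if (times_min[1] != 0 || any(diff(times_min) <= 0))
    stop("times must be strictly increasing and start at 0")
  if (is.null(model))
    model <- calibrate_distance_exponent(rbind(c(20, 25.2), c(35, 4.7)))
  if (is.null(names(cameras)) || any(names(cameras) == ""))
    stop("cameras must be a named list")
  if (is.null(seed)) stop("a seed is mandatory")
  d <- structure(list(n_specimens = as.integer(n_specimens),
                      times_min = times_min, shape = as.integer(shape),
                      pitch_mm = pitch_mm, cfg = cfg, model = model,
                      cameras = cameras, layout = layout,
                      specimen_sigma = specimen_sigma,
                      tumor_jitter_sigma = tumor_jitter_sigma,
                      blue_scale = blue_scale,
                      roi_radius_px = as.integer(roi_radius_px),
                      seed = as.integer(seed)),
                 class = "study_design")
  .validate_layout(d)
  d
}

# mm scene coordinates -> pixel (row, col); centre pixel = ceiling(shape/2)
.mm_to_px <- function(center_mm, shape, pitch_mm) {
  ctr <- ceiling(shape / 2)
  c(ctr[1] - center_mm[2] / pitch_mm, ctr[2] + center_mm[1] / pitch_mm)
}

.validate_layout <- function(design) {
  regs <- design$layout$regions
  n <- length(regs)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      d <- sqrt(sum((regs[[i]]$center_mm - regs[[j]]$center_mm)^2))
      if (d < regs[[i]]$radius_mm + regs[[j]]$radius_mm)
        stop("layout error: regions '", regs[[i]]$id, "' and '",
             regs[[j]]$id, "' overlap")
    }
  }
  half <- design$shape * design$pitch_mm / 2
  for (r in regs) {
    if (abs(r$center_mm[1]) + r$radius_mm > half[2] ||
        abs(r$center_mm[2]) + r$radius_mm > half[1])
      stop("layout error: region '", r$id, "' extends outside the field")
  }
  invisible(TRUE)
}

#' Analysis ROIs for a study design
#'
#' One circular ROI per scene region, centred on the region, with the
#' design's ROI radius.
#'
#' @param design A [study_design()].
#' @return List of [roi()] objects.
#' @export
design_rois <- function(design) {
  lapply(design$layout$regions, function(r)
    roi(r$id, .mm_to_px(r$center_mm, design$shape, design$pitch_mm),
        design$roi_radius_px, r$label))
}

# Precompute per-specimen static geometry: normalized beam field, region
# pixel indices, local normalized power per region, floor radiance.
.scene_geometry <- function(design) {
  peak <- incident_power_density(design$cfg, design$model)
  P <- beam_field(design$cfg, design$model, design$shape, design$pitch_mm)
  Pn <- P / peak
  ctr <- ceiling(design$shape / 2)
  rows <- seq_len(design$shape[1]); cols <- seq_len(design$shape[2])
  regions <- lapply(design$layout$regions, function(r) {
    if (r$type == "floor") return(list(region = r, idx = integer(0)))
    px <- .mm_to_px(r$center_mm, design$shape, design$pitch_mm)
    rad_px <- r$radius_mm / design$pitch_mm
    dr <- (rows - px[1])^2
    dc <- (cols - px[2])^2
    idx <- which(outer(dr, dc, `+`) <= rad_px^2)
    list(region = r, idx = idx, Pn = Pn[idx],
         Pn_center = Pn[round(px[1]), round(px[2])])
  })
  names(regions) <- vapply(design$layout$regions, `[[`, "", "id")
  list(peak = peak, Pn = Pn, regions = regions,
       blue = design$blue_scale * Pn)
}

# Red radiance field at time t for one specimen (gains g: tumor+brain,
# j: tumor only), from precomputed geometry.
.red_radiance <- function(geom, design, t, g, j) {
  red <- matrix(design$layout$floor$I0, design$shape[1], design$shape[2])
  for (rg in geom$regions) {
    r <- rg$region
    if (r$type == "floor") next
    local_p <- rg$Pn * geom$peak
    if (r$type == "standard") {
      red[rg$idx] <- standard_emission(r$spec, local_p, t, geom$peak)
    } else {
      mult <- if (r$spec$role == "tumor") g * j
      else if (r$spec$role == "brain") g else 1
      red[rg$idx] <- mult * tissue_emission(r$spec, local_p, t, geom$peak)
    }
  }
  red
}

# Noiseless ROI-centre radiance (ground truth) for one region/time.
.truth_radiance <- function(rg, geom, design, t, g, j) {
  r <- rg$region
  if (r$type == "floor") return(design$layout$floor$I0)
  local_p <- rg$Pn_center * geom$peak
  if (r$type == "standard") return(standard_emission(r$spec, local_p, t, geom$peak))
  mult <- if (r$spec$role == "tumor") g * j else if (r$spec$role == "brain") g else 1
  mult * tissue_emission(r$spec, local_p, t, geom$peak)
}

#' Generate a synthetic image time series
#'
#' Renders the full study: for each specimen, standards at the four corners,
#' tumor and brain discs near the field centre and a dark floor elsewhere,
#' with per-specimen lognormal gains, rendered by each camera model.
#' Deterministic given the design seed.
#'
#' @param design A [study_design()].
#' @return A list with `stacks` (per specimen, per camera: integer array
#'   `c(nrow, ncol, 3, n_times)`), `rois` ([design_rois()]), `ground_truth`
#'   (data.frame `specimen, roi, label, time_min, radiance` of noiseless
#'   ROI-centre radiances), and `design`.
#' @export
generate_series <- function(design) {
  res <- .simulate(design, keep_frames = TRUE)
  res
}

#' Simulate and quantify a study in one pass
#'
#' Renders every frame and immediately extracts circular-ROI red-channel
#' statistics, without retaining the images (memory-light). Identical RNG
#' stream to [generate_series()], so the quantified values agree exactly.
#'
#' @param design A [study_design()].
#' @return A list with `timeseries` (data.frame `specimen, camera, roi,
#'   label, time_min, mean, sd`), `ground_truth` and `rois` as in
#'   [generate_series()].
#' @export
run_study <- function(design) {
  res <- .simulate(design, keep_frames = FALSE)
  res
}

.simulate <- function(design, keep_frames = FALSE) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(design$seed)

  geom <- .scene_geometry(design)
  rois <- design_rois(design)
  masks <- lapply(rois, function(r)
    circular_roi_mask(r$center, r$radius, design$shape))
  times <- design$times_min
  nt <- length(times)

  g_spec <- stats::rlnorm(design$n_specimens, 0, design$specimen_sigma)
  j_spec <- stats::rlnorm(design$n_specimens, 0, design$tumor_jitter_sigma)

  stacks <- if (keep_frames) vector("list", design$n_specimens)
  ts_rows <- list()
  truth_rows <- list()

  for (s in seq_len(design$n_specimens)) {
    g <- g_spec[s]; j <- j_spec[s]
    red_fields <- lapply(times, function(t)
      .red_radiance(geom, design, t, g, j))
    if (keep_frames) stacks[[s]] <- list()
    for (cam_name in names(design$cameras)) {
      cam <- design$cameras[[cam_name]]
      if (keep_frames)
        stack <- array(0L, dim = c(design$shape, 3L, nt))
      stats_list <- vector("list", nt)
      for (ti in seq_len(nt)) {
        frame <- render_frame(red_fields[[ti]], geom$blue, cam, seed = NULL)
        if (keep_frames) stack[, , , ti] <- frame
        red_ch <- frame[, , 1L]
        stats_list[[ti]] <- t(vapply(masks, function(m) {
          px <- red_ch[m]
          c(mean(px), stats::sd(px))
        }, numeric(2)))
      }
      if (keep_frames) stacks[[s]][[cam_name]] <- stack
      for (ri in seq_along(rois)) {
        ts_rows[[length(ts_rows) + 1L]] <- data.frame(
          specimen = s, camera = cam_name, roi = rois[[ri]]$id,
          label = rois[[ri]]$label, time_min = times,
          mean = vapply(stats_list, function(m) m[ri, 1], 0),
          sd = vapply(stats_list, function(m) m[ri, 2], 0))
      }
    }
    for (rg in geom$regions) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        specimen = s, roi = rg$region$id, label = rg$region$label,
        time_min = times,
        radiance = vapply(times, function(t)
          .truth_radiance(rg, geom, design, t, g, j), 0))
    }
  }
  ts <- do.call(rbind, ts_rows)
  class(ts) <- c("roi_timeseries", "data.frame")
  out <- list(timeseries = ts,
              ground_truth = do.call(rbind, truth_rows),
              rois = rois, design = design,
              specimen_gains = data.frame(specimen = seq_len(design$n_specimens),
                                          gain = g_spec, tumor_jitter = j_spec))
  if (keep_frames) out$stacks <- stacks
  out
}

#' Write a generated study to disk
#'
#' Writes one multi-page 8-bit RGB TIFF per specimen per camera, the ROI
#' layout and ground-truth radiance table as JSON/CSV, and the design
#' parameters as JSON.
#'
#' @param series Output of [generate_series()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(series, dir) {
  if (is.null(series$stacks))
    stop("series has no frames: use generate_series(), not run_study()")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_along(series$stacks)) {
    for (cam_name in names(series$stacks[[s]])) {
      stack <- series$stacks[[s]][[cam_name]]
      pages <- lapply(seq_len(dim(stack)[4]), function(ti)
        stack[, , , ti] / 255)
      tiff::writeTIFF(pages, file.path(dir,
        sprintf("specimen%02d_%s.tiff", s, cam_name)),
        bits.per.sample = 8L)
    }
  }
  write_roi_config(series$rois, file.path(dir, "rois.json"))
  utils::write.csv(series$ground_truth,
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  d <- series$design
  jsonlite::write_json(list(
    schema_version = 1L, n_specimens = d$n_specimens,
    times_min = d$times_min, shape = d$shape, pitch_mm = d$pitch_mm,
    working_distance_cm = d$cfg$working_distance_cm,
    light_setting = d$cfg$light_setting, tilt_skew = d$cfg$tilt_skew,
    specimen_sigma = d$specimen_sigma,
    tumor_jitter_sigma = d$tumor_jitter_sigma,
    blue_scale = d$blue_scale, roi_radius_px = d$roi_radius_px,
    seed = d$seed),
    file.path(dir, "design.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an image stack written by [write_study()]
#'
#' @param path Path to a multi-page RGB TIFF.
#' @return Integer array `c(nrow, ncol, 3, n_pages)` with values 0..255.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, dim = c(dim(pages[[1]])[1:2], 3L, length(pages)))
  for (i in seq_along(pages))
    arr[, , , i] <- as.integer(round(pages[[i]] * 255))
  arr
}
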