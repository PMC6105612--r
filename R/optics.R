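# Illumination optics: power-law distance response and the bell-shaped,
# vertically skewed blue excitation field of an operating microscope.

#' Microscope configuration
#'
#' Describes the operating state of the fluorescence microscope: lamp power
#' setting, working (focus) distance, a per-microscope brightness scale, and
#' the vertical asymmetry of the beam caused by microscope angulation.
#'
#' @param light_setting Fraction of maximum lamp output, in `[0, 1]`.
#' @param working_distance_cm Working (focus) distance in cm; must be positive.
#' @param gain Dimensionless per-microscope scale factor (different units of
#'   the same model differ substantially in output at identical settings).
#' @param tilt_skew Dimensionless vertical asymmetry factor (>= 1); the beam
#'   half-width above the field centre is `tilt_skew` times the half-width
#'   below it.
#' @return An object of class `microscope_config`.
#' @export
microscope_config <- function(light_setting = 1.0, working_distance_cm = 20,
                              gain = 1.0, tilt_skew = 1.15) {
  stopifnot(is.numeric(light_setting), length(light_setting) == 1L)
  if (light_setting < 0 || light_setting > 1)
    stop("light_setting must lie in [0, 1]")
  if (!is.numeric(working_distance_cm) || working_distance_cm <= 0)
    stop("working_distance_cm must be positive")
  if (!is.numeric(gain) || gain <= 0) stop("gain must be positive")
  if (!is.numeric(tilt_skew) || tilt_skew < 1) stop("tilt_skew must be >= 1")
  structure(list(light_setting = light_setting,
                 working_distance_cm = working_distance_cm,
                 gain = gain, tilt_skew = tilt_skew),
            class = "microscope_config")
}

#' Illumination model
#'
#' Parametric model of the incident blue-light power density: a peak power
#' density `P_ref` at reference distance `D_ref` that falls off as
#' `(D_ref / D)^gamma`, with a two-sided Gaussian beam profile whose
#' half-widths grow linearly with distance (cone geometry).
#'
#' @param P_ref Peak power density at the reference distance (mW/cm^2).
#' @param D_ref Reference distance (cm).
#' @param gamma Distance exponent (dimensionless, > 0 so power density is
#'   strictly decreasing in distance).
#' @param sigma_x_mm,sigma_y_mm Beam half-widths at `D_ref` (mm).
#' @param spot_scale_mm_per_cm Beam spot radius per cm of working distance
#'   (mm/cm); the illuminated field is cone-shaped, so the spot radius grows
#'   linearly with distance.
#' @return An object of class `illumination_model`.
#' @export
illumination_model <- function(P_ref, D_ref, gamma,
                               sigma_x_mm = 20, sigma_y_mm = 20,
                               spot_scale_mm_per_cm = 1) {
  if (!is.numeric(P_ref) || P_ref <= 0) stop("P_ref must be positive")
  if (!is.numeric(D_ref) || D_ref <= 0) stop("D_ref must be positive")
  if (!is.numeric(gamma) || gamma <= 0)
    stop("gamma must be positive: power density must strictly decrease with distance")
  if (sigma_x_mm <= 0 || sigma_y_mm <= 0) stop("beam half-widths must be positive")
  if (spot_scale_mm_per_cm <= 0) stop("spot_scale_mm_per_cm must be positive")
  structure(list(P_ref = P_ref, D_ref = D_ref, gamma = gamma,
                 sigma_x_mm = sigma_x_mm, sigma_y_mm = sigma_y_mm,
                 spot_scale_mm_per_cm = spot_scale_mm_per_cm),
            class = "illumination_model")
}

#' Calibrate the distance exponent from power-meter anchors
#'
#' Fits the power law `P(D) = P_ref * (D_ref / D)^gamma` to measured
#' (distance, power density) pairs by least squares on the log-log scale.
#' The reference point is pinned to the nearest (smallest-distance) anchor,
#' so with exactly two anchors the model passes through both exactly.
#'
#' @param anchors A two-column matrix or data.frame (`distance_cm`,
#'   `power_mw_cm2`), or a list of length-2 numeric vectors.
#' @param ... Passed on to [illumination_model()] (beam-shape parameters).
#' @return An [illumination_model()].
#' @examples
#' calibrate_distance_exponent(rbind(c(20, 25.2), c(35, 4.7)))
#' @export
calibrate_distance_exponent <- function(anchors, ...) {
  if (is.list(anchors) && !is.data.frame(anchors))
    anchors <- do.call(rbind, lapply(anchors, function(a) as.numeric(a[1:2])))
  anchors <- as.matrix(as.data.frame(anchors)[, 1:2])
  storage.mode(anchors) <- "double"
  if (nrow(anchors) < 2L)
    stop("calibration requires at least 2 (distance, power) anchors")
  d <- anchors[, 1]; p <- anchors[, 2]
  if (any(!is.finite(d)) || any(!is.finite(p)) || any(d <= 0) || any(p <= 0))
    stop("anchor distances and powers must be positive and finite")
  if (anyDuplicated(d)) stop("anchor distances must be distinct")
  fit <- stats::lm(log(p) ~ log(d))
  gamma <- -unname(stats::coef(fit)[2])
  if (!is.finite(gamma) || gamma <= 0)
    stop("calibrated exponent is not positive; power density must strictly decrease with distance")
  i <- which.min(d)
  illumination_model(P_ref = p[i], D_ref = d[i], gamma = gamma, ...)
}

#' Incident power density at the field centre
#'
#' Peak blue-light power density for a given microscope state:
#' `gain * light_setting * P_ref * (D_ref / D)^gamma`. Linear in the light
#' setting (through the origin) and strictly decreasing in distance.
#'
#' @param cfg A [microscope_config()].
#' @param model An [illumination_model()].
#' @return Power density in mW/cm^2.
#' @export
incident_power_density <- function(cfg, model) {
  stopifnot(inherits(cfg, "microscope_config"), inherits(model, "illumination_model"))
  cfg$gain * cfg$light_setting * model$P_ref *
    (model$D_ref / cfg$working_distance_cm)^model$gamma
}

#' Radius of the illuminated spot
#'
#' The beam is cone-shaped, so the spot radius grows linearly with working
#' distance.
#'
#' @inheritParams incident_power_density
#' @return Spot radius in mm.
#' @export
fov_radius_mm <- function(cfg, model) {
  stopifnot(inherits(cfg, "microscope_config"), inherits(model, "illumination_model"))
  model$spot_scale_mm_per_cm * cfg$working_distance_cm
}

#' Blue-light power density field over a pixel grid
#'
#' Evaluates the two-sided asymmetric Gaussian beam profile over an image
#' grid. The peak sits at the centre pixel and equals
#' [incident_power_density()]. The horizontal profile is symmetric with
#' half-width `sigma_x * (D / D_ref)`; the vertical profile uses `sigma_y`
#' below the centre and `sigma_y * tilt_skew` above it, giving the
#' bell-shaped, vertically skewed field produced by the tilted microscope.
#'
#' @inheritParams incident_power_density
#' @param shape Integer vector `c(nrow, ncol)` of the pixel grid.
#' @param pitch_mm Physical pixel pitch in mm (> 0).
#' @return A `nrow x ncol` matrix of power densities (mW/cm^2). The centre
#'   pixel is `(ceiling(nrow/2), ceiling(ncol/2))`; rows above it (smaller
#'   row index) are "up".
#' @export
beam_field <- function(cfg, model, shape, pitch_mm) {
  stopifnot(inherits(cfg, "microscope_config"), inherits(model, "illumination_model"))
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) stop("shape must be c(nrow, ncol)")
  if (!is.numeric(pitch_mm) || pitch_mm <= 0) stop("pixel pitch must be positive")
  peak <- incident_power_density(cfg, model)
  scale <- cfg$working_distance_cm / model$D_ref
  sx <- model$sigma_x_mm * scale
  sy <- model$sigma_y_mm * scale
  ctr <- ceiling(shape / 2)
  # dy > 0 above the centre row (towards the top of the image)
  dy <- (ctr[1] - seq_len(shape[1])) * pitch_mm
  dx <- (seq_len(shape[2]) - ctr[2]) * pitch_mm
  sy_side <- ifelse(dy > 0, sy * cfg$tilt_skew, sy)
  vert <- exp(-0.5 * (dy / sy_side)^2)
  horiz <- exp(-0.5 * (dx / sx)^2)
  peak * outer(vert, horiz)
}

#' Convert radiant exposure (dose) to exposure time, and back
#'
#' Radiant exposure links photobleaching extent across instruments of
#' different brightness: `dose = power * time`. With dose in J/cm^2 and
#' power density in mW/cm^2, `time = dose * 1000 / power` seconds.
#'
#' @param dose_J_cm2 Radiant exposure in J/cm^2 (>= 0).
#' @param power_mW_cm2 Power density in mW/cm^2 (> 0).
#' @return `dose_to_time`: exposure time in seconds. `time_to_dose`: dose in
#'   J/cm^2.
#' @examples
#' dose_to_time(14.4, 25.2) / 60  # ~9.5 min
#' @export
dose_to_time <- function(dose_J_cm2, power_mW_cm2) {
  if (any(dose_J_cm2 < 0)) stop("dose must be non-negative")
  if (any(power_mW_cm2 <= 0)) stop("power density must be positive")
  dose_J_cm2 * 1000 / power_mW_cm2
}

#' @rdname dose_to_time
#' @param time_s Exposure time in seconds (>= 0).
#' @export
time_to_dose <- function(time_s, power_mW_cm2) {
  if (any(time_s < 0)) stop("time must be non-negative")
  if (any(power_mW_cm2 <= 0)) stop("power density must be positive")
  time_s * power_mW_cm2 / 1000
}

#' Read power-meter readings
#'
#' Reads a CSV of sparse power-meter measurements with required header
#' `distance_cm, setting_pct, power_mw_cm2`.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with those three numeric columns.
#' @export
read_power_meter <- function(path) {
  x <- utils::read.csv(path, check.names = TRUE)
  need <- c("distance_cm", "setting_pct", "power_mw_cm2")
  if (!all(need %in% names(x)))
    stop("power-meter CSV must have header: ", paste(need, collapse = ", "))
  x[need]
}

#' Serialize / deserialize an illumination model
#'
#' Writes the model as flat JSON with fields named exactly as in
#' [illumination_model()].
#'
#' @param model An [illumination_model()].
#' @param path Output (or input) file path.
#' @return `read_illumination_model` returns an [illumination_model()].
#' @export
write_illumination_model <- function(model, path) {
  stopifnot(inherits(model, "illumination_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_illumination_model
#' @export
read_illumination_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(illumination_model, x)
}

#' @export
print.illumination_model <- function(x, ...) {
  cat(sprintf("Illumination model: P_ref = %.3g mW/cm^2 at D_ref = %g cm, gamma = %.4g\n",
              x$P_ref, x$D_ref, x$gamma))
  cat(sprintf("  beam half-widths %g x %g mm at D_ref; spot %g mm per cm distance\n",
              x$sigma_x_mm, x$sigma_y_mm, x$spot_scale_mm_per_cm))
  invisible(x)
}
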