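# End-to-end study summaries: per-specimen ratios and replicate-study
# grand means for the default glioma scenario.

#' Per-specimen ratio summary of a quantified study
#'
#' For each specimen (and camera) computes the tumor-to-brain ratio at
#' requested time points and the normal-brain-to-dark-background ratio.
#'
#' @param ts A quantified time-series data.frame with `specimen`, `camera`,
#'   `label`, `time_min`, `mean` columns (from [run_study()]).
#' @param tbr_times Time points (min) at which to report the
#'   tumor-to-background ratio.
#' @param brain_bg_time Time point for the brain-to-dark-background ratio.
#' @return Data.frame with one row per specimen x camera: `tbr_<t>` columns
#'   and `brain_dark_<t>`.
#' @export
study_ratios <- function(ts, tbr_times = c(0, 10), brain_bg_time = 30) {
  ts <- as.data.frame(ts)
  if (!"camera" %in% names(ts)) ts$camera <- "camera"
  if (!"specimen" %in% names(ts)) ts$specimen <- 1L
  groups <- split(ts, ts[c("specimen", "camera")], drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(sub) {
    r <- tumor_background_ratio(sub)
    row <- data.frame(specimen = sub$specimen[1], camera = sub$camera[1])
    for (t in tbr_times)
      row[[sprintf("tbr_%g", t)]] <- r$ratio[match(t, r$time_min)]
    br <- sub$mean[sub$label == "brain" & sub$time_min == brain_bg_time]
    dk <- sub$mean[sub$label == "dark_background" & sub$time_min == brain_bg_time]
    row[[sprintf("brain_dark_%g", brain_bg_time)]] <-
      if (length(br) && length(dk) && dk > 0) br / dk else NA_real_
    row
  }))
  rownames(out) <- NULL
  out
}

#' Replicate the default glioma photobleaching experiment
#'
#' Simulates `n_studies` independent studies of the default 6-specimen
#' glioma scenario through the external-camera pipeline, quantifies every
#' frame, and collects the per-specimen tumor-to-background ratios at 0 and
#' 10 min and the brain-to-dark-background ratio at 30 min.
#'
#' @param n_studies Number of replicate studies.
#' @param base_seed Integer; study i uses seed `base_seed + i - 1`.
#' @param ... Overrides passed to [study_design()] (the camera set defaults
#'   to the external camera only).
#' @return Data.frame with one row per specimen per study (`study`,
#'   `specimen`, `tbr_0`, `tbr_10`, `brain_dark_30`).
#' @export
replicate_glioma_studies <- function(n_studies = 20, base_seed = 1, ...) {
  args <- list(...)
  if (is.null(args$cameras))
    args$cameras <- list(external = external_camera())
  do.call(rbind, lapply(seq_len(n_studies), function(i) {
    args$seed <- base_seed + i - 1L
    res <- do.call(study_design, args)
    ts <- run_study(res)$timeseries
    cbind(study = i, study_ratios(ts))
  }))
}
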