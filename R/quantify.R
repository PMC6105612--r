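# Circular-ROI statistics and tumor-to-background ratios.

#' Circular region of interest
#'
#' @param id ROI identifier (character).
#' @param center Length-2 numeric `(row, col)` pixel centre, 1-based,
#'   origin top-left.
#' @param radius Radius in pixels (>= 0); the default 51 matches a
#'   51-pixel-radius analysis circle.
#' @param label One of `"standard-<k>"`, `"tumor"`, `"brain"`,
#'   `"dark_background"` (free-form labels are allowed).
#' @return An object of class `roi`.
#' @export
roi <- function(id, center, radius = 51, label = id) {
  stopifnot(length(center) == 2L, is.numeric(center))
  if (radius < 0) stop("radius must be non-negative")
  structure(list(id = as.character(id), center = as.numeric(center),
                 radius = radius, label = as.character(label)),
            class = "roi")
}

#' Boolean mask of a circular ROI
#'
#' A pixel is included iff its centre lies within Euclidean distance
#' `radius` of the ROI centre (centre-in-circle rule). The circle must lie
#' fully inside the image.
#'
#' @param center Length-2 `(row, col)` centre, 1-based.
#' @param radius Radius in pixels.
#' @param image_shape Integer `c(nrow, ncol)`.
#' @return A logical `nrow x ncol` matrix.
#' @export
circular_roi_mask <- function(center, radius, image_shape) {
  image_shape <- as.integer(image_shape)
  stopifnot(length(center) == 2L, length(image_shape) == 2L)
  if (radius < 0) stop("radius must be non-negative")
  if (center[1] - radius < 1 || center[1] + radius > image_shape[1] ||
      center[2] - radius < 1 || center[2] + radius > image_shape[2])
    stop("ROI circle extends outside the image")
  dr <- (seq_len(image_shape[1]) - center[1])^2
  dc <- (seq_len(image_shape[2]) - center[2])^2
  outer(dr, dc, `+`) <= radius^2
}

#' Mean and standard deviation of ROI pixel intensities
#'
#' @param image A 2D numeric matrix (one channel).
#' @param x An [roi()], or a logical mask of the same shape as `image`.
#' @return Named numeric vector `c(mean, sd)`; `sd` is the sample standard
#'   deviation (0 for a single-pixel ROI).
#' @export
roi_stats <- function(image, x) {
  stopifnot(is.matrix(image))
  mask <- if (inherits(x, "roi"))
    circular_roi_mask(x$center, x$radius, dim(image))
  else x
  stopifnot(is.logical(mask), identical(dim(mask), dim(image)))
  px <- image[mask]
  if (length(px) == 0L) stop("ROI mask selects no pixels")
  s <- if (length(px) > 1L) stats::sd(px) else 0
  c(mean = mean(px), sd = s)
}

#' Extract red-channel ROI time series from an image stack
#'
#' @param stack An integer/numeric array `c(nrow, ncol, 3, n_times)`
#'   (channel order RGB), or a list of `c(nrow, ncol, 3)` frames.
#' @param rois A list of [roi()] objects.
#' @param times_min Acquisition times in minutes, one per frame.
#' @return A data.frame of class `roi_timeseries` with columns
#'   `roi, label, time_min, mean, sd`.
#' @export
extract_timeseries <- function(stack, rois, times_min) {
  if (is.list(stack)) stack <- simplify2array(stack)
  stopifnot(length(dim(stack)) == 4L, dim(stack)[3] == 3L)
  nt <- dim(stack)[4]
  if (length(times_min) != nt)
    stop("times_min must have one entry per frame")
  shape <- dim(stack)[1:2]
  masks <- lapply(rois, function(r) circular_roi_mask(r$center, r$radius, shape))
  out <- do.call(rbind, lapply(seq_along(rois), function(i) {
    vals <- vapply(seq_len(nt), function(t)
      roi_stats(stack[, , 1L, t], masks[[i]]), c(mean = 0, sd = 0))
    data.frame(roi = rois[[i]]$id, label = rois[[i]]$label,
               time_min = times_min, mean = vals["mean", ], sd = vals["sd", ],
               row.names = NULL)
  }))
  class(out) <- c("roi_timeseries", "data.frame")
  out
}

#' Tumor-to-background ratio time series
#'
#' Per-time-point ratio of the tumor ROI mean to the background ROI mean
#' (adjacent normal brain by default). Invariant to any per-frame
#' multiplicative gain. A zero background mean yields `NA` for that time
#' point (flagged with a warning), not an error.
#'
#' @param ts A `roi_timeseries` data.frame from [extract_timeseries()].
#' @param tumor,background ROI labels of numerator and denominator.
#' @return A data.frame `time_min, ratio`.
#' @export
tumor_background_ratio <- function(ts, tumor = "tumor", background = "brain") {
  tu <- ts[ts$label == tumor, ]
  bg <- ts[ts$label == background, ]
  if (nrow(tu) == 0L || nrow(bg) == 0L)
    stop("tumor and background ROIs must both be present")
  tu <- tu[order(tu$time_min), ]
  bg <- bg[order(bg$time_min), ]
  if (!isTRUE(all.equal(tu$time_min, bg$time_min)))
    stop("tumor and background series cover different time points")
  ratio <- ifelse(bg$mean == 0, NA_real_, tu$mean / bg$mean)
  if (anyNA(ratio))
    warning("zero background mean: ratio undefined at ",
            sum(is.na(ratio)), " time point(s)")
  data.frame(time_min = tu$time_min, ratio = ratio)
}

#' Read / write ROI configurations
#'
#' ROI configs are JSON lists of `{id, row, col, radius, label}` with
#' 1-based `(row, col)` pixel coordinates, origin top-left.
#'
#' @param rois List of [roi()] objects.
#' @param path File path.
#' @return `read_roi_config` returns a list of [roi()] objects.
#' @export
write_roi_config <- function(rois, path) {
  x <- lapply(rois, function(r)
    list(id = r$id, row = r$center[1], col = r$center[2],
         radius = r$radius, label = r$label))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_config
#' @export
read_roi_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(x, function(r) roi(r$id, c(r$row, r$col), r$radius, r$label))
}

#' Write an ROI time-series table as CSV
#'
#' Columns `specimen, roi, label, time_min, mean, sd` (plus any extra
#' columns already present, e.g. `normalized_pct`).
#'
#' @param ts A data.frame (one or several specimens' series).
#' @param path Output path.
#' @export
write_timeseries_csv <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}
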