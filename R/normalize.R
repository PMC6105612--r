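# Ratiometric normalization of ROI time series against a photostable
# reference standard.

#' Ratiometric normalization to a reference standard
#'
#' Converts ROI means to percentage values relative to a designated
#' photostable reference standard, per time point:
#' `norm(roi, t) = nominal_pct * mean(roi, t) / mean(reference, t)`.
#' The reference ROI itself is assigned the nominal constant (10% by
#' default) at every time point. Because the division happens per time
#' point, any per-frame multiplicative gain — lamp fluctuation, exposure
#' variation, ambient light acting multiplicatively — cancels exactly.
#' Field-of-view non-uniformity is not corrected: ROIs at different field
#' positions still see different excitation.
#'
#' @param ts A `roi_timeseries` data.frame (columns `roi, label, time_min,
#'   mean`, optionally `specimen`/`camera`, from [extract_timeseries()] or
#'   [run_study()]). When `specimen`/`camera` columns are present each
#'   series is normalized within its own specimen and camera.
#' @param reference_id ROI id of the reference standard.
#' @param nominal_pct Nominal percent assigned to the reference (default 10).
#' @return The input with a `normalized_pct` column added, of class
#'   `normalized_series`, with attributes `reference` and `nominal_pct`.
#' @export
ratiometric_normalize <- function(ts, reference_id, nominal_pct = 10) {
  ts <- as.data.frame(ts)
  if (!all(c("roi", "time_min", "mean") %in% names(ts)))
    stop("ts must have columns roi, time_min, mean")
  if (!reference_id %in% ts$roi)
    stop("reference ROI '", reference_id, "' not present")
  keys <- intersect(c("specimen", "camera"), names(ts))
  grp <- if (length(keys)) interaction(ts[keys], drop = TRUE)
  else factor(rep(1L, nrow(ts)))
  out <- ts
  out$normalized_pct <- NA_real_
  for (g in levels(grp)) {
    i <- which(grp == g)
    sub <- ts[i, ]
    ref <- sub[sub$roi == reference_id, c("time_min", "mean")]
    if (nrow(ref) == 0L)
      stop("reference ROI '", reference_id, "' missing in group ", g)
    bad <- ref$time_min[ref$mean <= 0]
    if (length(bad))
      stop("reference mean is not positive at time point(s) ",
           paste(bad, collapse = ", "), " min")
    ref_mean <- ref$mean[match(sub$time_min, ref$time_min)]
    out$normalized_pct[i] <- nominal_pct * sub$mean / ref_mean
  }
  class(out) <- c("normalized_series", class(ts))
  attr(out, "reference") <- reference_id
  attr(out, "nominal_pct") <- nominal_pct
  out
}

#' Write a normalized series as CSV
#'
#' Same schema as the quantification CSV with the `normalized_pct` column,
#' preceded by comment header lines naming the reference ROI and nominal
#' percent.
#'
#' @param ns A `normalized_series` from [ratiometric_normalize()].
#' @param path Output path.
#' @export
write_normalized_csv <- function(ns, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# reference: %s", attr(ns, "reference")),
               sprintf("# nominal_pct: %g", attr(ns, "nominal_pct"))), con)
  utils::write.csv(as.data.frame(ns), con, row.names = FALSE)
  invisible(path)
}
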