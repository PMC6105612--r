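# Photobleaching kinetics: logarithmic decay fits, pseudo-R-squared,
# two-point half-life, percent change, and group comparison.

#' Fit a logarithmic photobleaching decay
#'
#' Least-squares fit of `y = c * ln(t + offset) + y0`. The goodness of fit
#' is the Cox-Snell pseudo-R-squared computed from the Gaussian likelihood
#' ratio, `1 - exp(2 * (ll0 - ll1) / n)`; with Gaussian maximum-likelihood
#' variances this equals the classical `1 - SSE/SST` identically, so both
#' are reported and must agree.
#'
#' @param times_min Times in minutes.
#' @param values Signal values (same length).
#' @param time_offset Minutes added to `t` inside the log (default 1 so the
#'   t = 0 frame is usable). With `time_offset = 0`, samples at t <= 0 are
#'   dropped with a warning.
#' @return An object of class `log_decay_fit`: list with `c`, `y0`, `r2`
#'   (Cox-Snell), `r2_classical`, `time_offset`, `n`.
#' @examples
#' t <- c(1:10, 15, 20, 25, 30)
#' f <- fit_log_decay(t, -0.048 * log(t) + 0.2877, time_offset = 0)
#' @export
fit_log_decay <- function(times_min, values, time_offset = 1.0) {
  if (length(times_min) != length(values))
    stop("times and values must have equal length")
  keep <- is.finite(times_min) & is.finite(values) &
    (times_min + time_offset > 0)
  if (sum(keep) < length(values) && time_offset == 0)
    warning("dropping ", sum(!keep), " sample(s) with t <= 0 (offset 0)")
  t <- times_min[keep]; y <- values[keep]
  n <- length(y)
  if (n < 3L) stop("log-decay fit needs at least 3 valid samples")
  if (stats::var(y) == 0) {
    fit <- structure(list(c = 0, y0 = y[1], r2 = 0, r2_classical = 0,
                          time_offset = time_offset, n = n),
                     class = "log_decay_fit")
    return(fit)
  }
  x <- log(t + time_offset)
  m <- stats::lm(y ~ x)
  co <- unname(stats::coef(m))
  sse <- sum(stats::resid(m)^2)
  sst <- sum((y - mean(y))^2)
  # Gaussian log-likelihoods at the MLE variance, for the Cox-Snell ratio
  ll <- function(ss) -n / 2 * (log(2 * pi * ss / n) + 1)
  r2_cs <- 1 - exp(2 * (ll(sst) - ll(sse)) / n)
  structure(list(c = co[2], y0 = co[1], r2 = r2_cs,
                 r2_classical = 1 - sse / sst,
                 time_offset = time_offset, n = n),
            class = "log_decay_fit")
}

#' @export
print.log_decay_fit <- function(x, ...) {
  cat(sprintf("y = %.4g * ln(t + %g) + %.4g   (pseudo-R^2 = %.3f, n = %d)\n",
              x$c, x$time_offset, x$y0, x$r2, x$n))
  invisible(x)
}

#' Fit log-decay models for every ROI series in a table
#'
#' @param ts A data.frame with columns `roi, time_min` and a value column.
#' @param value Name of the value column (default `"mean"`).
#' @param time_offset Passed to [fit_log_decay()].
#' @return Data.frame `roi, c, y0, r2, n, time_offset`.
#' @export
fit_log_decay_table <- function(ts, value = "mean", time_offset = 1.0) {
  ts <- as.data.frame(ts)
  do.call(rbind, lapply(split(ts, ts$roi), function(sub) {
    f <- fit_log_decay(sub$time_min, sub[[value]], time_offset)
    data.frame(roi = sub$roi[1], c = f$c, y0 = f$y0, r2 = f$r2,
               n = f$n, time_offset = time_offset, row.names = NULL)
  }))
}

#' Two-point exponential half-life
#'
#' The logarithmic decay model has no finite half-life from t = 0, so the
#' half-life is computed by the exponential-through-two-points convention:
#' `t_half = (t2 - t1) * ln(2) / ln(y1 / y2)`. Scale-invariant in y and
#' translation-invariant in t.
#'
#' @param t1,t2 Times (t2 > t1), any unit; the result is in the same unit.
#' @param y1,y2 Signal values with `y1 > y2 > 0`.
#' @return Half-life in the unit of `t`.
#' @examples
#' half_life_two_point(0, 8.0, 30, 4.4)  # ~34.8 min
#' @export
half_life_two_point <- function(t1, y1, t2, y2) {
  if (t2 <= t1) stop("t2 must exceed t1")
  if (!(y1 > y2 && y2 > 0)) stop("no decay: need y1 > y2 > 0")
  (t2 - t1) * log(2) / log(y1 / y2)
}

#' Signed percent change between two time points of a series
#'
#' `100 * (v(t_b) - v(t_a)) / v(t_a)`.
#'
#' @param series A data.frame with `time_min` and a value column, or a
#'   numeric vector named by time.
#' @param t_a,t_b Time points; both must be present.
#' @param value Value column name when `series` is a data.frame.
#' @return Signed percent.
#' @export
percent_change <- function(series, t_a, t_b, value = "mean") {
  if (is.data.frame(series)) {
    v <- series[[value]]
    tt <- series$time_min
  } else {
    v <- unname(series)
    tt <- as.numeric(names(series))
  }
  ia <- match(t_a, tt); ib <- match(t_b, tt)
  if (is.na(ia) || is.na(ib))
    stop("time point not present in the series")
  if (v[ia] == 0) stop("value at t_a is zero; percent change undefined")
  100 * (v[ib] - v[ia]) / v[ia]
}

#' Two-sided t-test comparison of two groups
#'
#' Thin wrapper over [stats::t.test()]; Student's equal-variance test by
#' default, paired if requested.
#'
#' @param a,b Numeric samples (each n >= 2; equal lengths when paired).
#' @param paired Paired test flag.
#' @param var_equal Assume equal variances (classic Student test).
#' @return List with `statistic`, `p_value`, `df`.
#' @export
compare_groups <- function(a, b, paired = FALSE, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  ht <- stats::t.test(a, b, paired = paired, var.equal = var_equal)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}
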