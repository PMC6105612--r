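# Multi-rater ordinal agreement statistics for the 0-4 visual fluorescence
# grading scale.

#' Rating table
#'
#' Items x raters matrix of integer ordinal scores on a k-category scale
#' (scores 0..k-1, no missing cells). The category space is fixed at the
#' full grading scale (k = 5, "no fluorescence" to "very high fluorescence")
#' even when some categories are unused, which matters for the
#' free-marginal kappa.
#'
#' @param x Integer matrix or data.frame, rows = items, columns = raters.
#' @param k Number of categories (default 5).
#' @return An integer matrix of class `rating_table` with attribute `k`.
#' @export
rating_table <- function(x, k = 5L) {
  m <- as.matrix(x)
  storage.mode(m) <- "integer"
  if (anyNA(m)) stop("rating table must have no missing cells")
  if (k < 2L) stop("need at least 2 categories")
  if (any(m < 0L) || any(m >= k))
    stop("all scores must lie in {0, ..., k-1}")
  structure(m, class = c("rating_table", "matrix"), k = as.integer(k))
}

#' Per-item modal agreement
#'
#' Percent of raters giving the item's most frequent score. With tied
#' modes the (identical) maximal count is used.
#'
#' @param row Integer vector of one item's scores (>= 2 raters).
#' @return Percent in (0, 100].
#' @examples
#' item_modal_agreement(c(3, 4, 3, 4))  # 50
#' @export
item_modal_agreement <- function(row) {
  row <- as.integer(row)
  if (length(row) < 2L) stop("need at least 2 raters")
  100 * max(tabulate(row + 1L)) / length(row)
}

#' Overall pairwise interobserver agreement
#'
#' Fraction of agreeing rater pairs over all items:
#' `sum over items of agreeing pairs / (items * choose(raters, 2))`.
#'
#' @param table A [rating_table()] (or plain items x raters matrix).
#' @return Proportion of agreement `P_o` in `[0, 1]`.
#' @export
overall_pairwise_agreement <- function(table) {
  m <- as.matrix(table)
  r <- ncol(m)
  if (r < 2L) stop("need at least 2 raters")
  if (nrow(m) < 1L) stop("need at least 1 item")
  agree <- apply(m, 1L, function(row) {
    counts <- tabulate(as.integer(row) + 1L)
    sum(counts * (counts - 1L) / 2)
  })
  sum(agree) / (nrow(m) * choose(r, 2))
}

#' Fixed-marginal (Fleiss-type) kappa
#'
#' Chance-corrected multi-rater agreement `(P_o - P_e) / (1 - P_e)` with
#' `P_o` the overall pairwise agreement and `P_e = sum_j p_j^2` over the
#' observed overall category proportions `p_j`. When every rating falls in
#' one category, `P_e = 1` and kappa is undefined: `NA` is returned with a
#' warning.
#'
#' @param table A [rating_table()].
#' @return Kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
fleiss_kappa <- function(table) {
  m <- as.matrix(table)
  k <- attr(table, "k")
  if (is.null(k)) k <- max(m) + 1L
  po <- overall_pairwise_agreement(table)
  p_j <- tabulate(as.integer(m) + 1L, nbins = k) / length(m)
  pe <- sum(p_j^2)
  if (pe >= 1) {
    warning("all ratings fall in a single category: kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Free-marginal kappa
#'
#' Chance-corrected agreement assuming uniform chance use of the k
#' categories: `(P_o - 1/k) / (1 - 1/k)`.
#'
#' @param table A [rating_table()], or a numeric `P_o` directly.
#' @param k Number of categories (taken from the table when given one).
#' @return Free-marginal kappa.
#' @export
free_marginal_kappa <- function(table, k = NULL) {
  if (inherits(table, "rating_table") || is.matrix(table)) {
    if (is.null(k)) k <- attr(table, "k")
    po <- overall_pairwise_agreement(table)
  } else {
    po <- table
  }
  if (is.null(k) || k < 2L) stop("need at least 2 categories")
  (po - 1 / k) / (1 - 1 / k)
}

#' Intrarater agreement between two grading attempts
#'
#' Per-rater percent of items scored identically in both attempts, with a
#' mean and sample-sd summary across raters.
#'
#' @param attempt1,attempt2 Items x raters matrices of identical shape.
#' @return List with `per_rater` (named percents), `mean`, `sd`.
#' @export
intrarater_agreement <- function(attempt1, attempt2) {
  a <- as.matrix(attempt1); b <- as.matrix(attempt2)
  if (!identical(dim(a), dim(b)))
    stop("the two attempts must have identical shape")
  per <- 100 * colMeans(a == b)
  list(per_rater = per, mean = mean(per), sd = stats::sd(per))
}

#' Agreement summary for a rating table
#'
#' @param table A [rating_table()].
#' @return List with `per_item_modal_pct`, `overall_pairwise_pct`,
#'   `fleiss_kappa`, `free_marginal_kappa` (percent values rounded to 1
#'   decimal; raw fractions retained under `raw`).
#' @export
agreement_summary <- function(table) {
  po <- overall_pairwise_agreement(table)
  kf <- fleiss_kappa(table)
  kfree <- free_marginal_kappa(table)
  list(per_item_modal_pct = apply(as.matrix(table), 1L, item_modal_agreement),
       overall_pairwise_pct = round(100 * po, 1),
       fleiss_kappa_pct = round(100 * kf, 1),
       free_marginal_kappa_pct = round(100 * kfree, 1),
       raw = list(P_o = po, fleiss_kappa = kf, free_marginal_kappa = kfree))
}

#' Read a ratings CSV
#'
#' Rows = items, columns = raters, integer cells; an optional first column
#' named `item` is used for row names.
#'
#' @param path CSV path.
#' @param k Number of categories.
#' @return A [rating_table()].
#' @export
read_ratings_csv <- function(path, k = 5L) {
  x <- utils::read.csv(path, check.names = FALSE)
  if (tolower(names(x)[1]) %in% c("item", "standard")) {
    rn <- x[[1]]
    x <- x[-1]
    rownames(x) <- rn
  }
  rating_table(x, k = k)
}

#' Packaged fluorescence-grading scores
#'
#' The 9 dye-in-polymer standards scored 0-4 by four observers (two
#' neurosurgeons, two medical students) on the visual fluorescence
#' intensity scale; the second grading attempt, used for interobserver
#' agreement.
#'
#' @return A 9 x 4 [rating_table()] (k = 5), rows named by standard.
#' @export
ppix_grading_scores <- function() {
  path <- system.file("extdata", "standards_ratings.csv",
                      package = "ppixquant", mustWork = TRUE)
  read_ratings_csv(path, k = 5L)
}

#' Synthetic first grading attempt
#'
#' The per-observer agreement percentages between the two grading attempts
#' are published, but the first attempt's scores are not. This helper
#' reconstructs a synthetic first attempt consistent with those
#' percentages: for each rater, the stated number of disagreeing items is
#' obtained by shifting the score of the first items by one category
#' (downwards at the top of the scale).
#'
#' @param scores The second attempt (default [ppix_grading_scores()]).
#' @param disagreements Integer disagreeing-item count per rater; the
#'   default reproduces the published 67/56/67/89 percent agreements over
#'   9 items.
#' @return An items x raters integer matrix.
#' @export
synthetic_first_attempt <- function(scores = ppix_grading_scores(),
                                    disagreements = c(3L, 4L, 3L, 1L)) {
  m <- as.matrix(scores)
  if (length(disagreements) != ncol(m))
    stop("one disagreement count per rater required")
  k <- attr(scores, "k")
  if (is.null(k)) k <- 5L
  for (j in seq_len(ncol(m))) {
    d <- disagreements[j]
    if (d > nrow(m)) stop("more disagreements than items")
    i <- seq_len(d)
    m[i, j] <- ifelse(m[i, j] >= k - 1L, m[i, j] - 1L, m[i, j] + 1L)
  }
  m
}

#' The visual fluorescence grading scale
#'
#' @return Data.frame `score, definition` for the 0-4 scale.
#' @export
fluorescence_grading_scale <- function() {
  path <- system.file("extdata", "grading_scale.csv",
                      package = "ppixquant", mustWork = TRUE)
  utils::read.csv(path)
}
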