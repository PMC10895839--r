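# Evaluation metrics and diagnostics: regression metrics on the yield-point
# scale, the positive/negative pair-divergence CDF diagnostic for the
# alignment space, and histogram distribution-shift metrics between yield
# samples.

#' Regression metrics for yield prediction
#'
#' Mean absolute error, root mean squared error (both in yield points) and
#' the coefficient of determination.
#'
#' @param y true yields; `y_hat` predictions (equal nonzero length).
#' @return list with `mae`, `rmse`, `r2`.
#' @export
regression_metrics <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) > 0L)
  if (stats::var(y) == 0)
    stop("error: r2 undefined for constant targets")
  res <- y - y_hat
  list(mae = mean(abs(res)),
       rmse = sqrt(mean(res^2)),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

#' Positive/negative pair-divergence distributions in the alignment space
#'
#' Draws seeded batches from a dataset, computes per-sample Jeffreys
#' divergences between the two views of the same reaction (positive pairs)
#' and between views of different reactions within the batch (negative
#' pairs), and returns both empirical CDFs.
#'
#' @param d an `mvrxn_dataset` with conformers.
#' @param model an `mvrxn_model` (with projector).
#' @param batch_size batch size (default 32; must be >= 2 for negatives).
#' @param seed integer seed.
#' @param max_batches cap on the number of batches scanned (NULL = all).
#' @return object of class `mvrxn_divergence_cdf`: list with `positive`,
#'   `negative` (sorted divergence values) and summary medians.
#' @export
pair_divergence_distribution <- function(d, model, batch_size = 32L,
                                         seed = 1L, max_batches = NULL) {
  if (batch_size < 2L) stop("error: batch size < 2 yields no negative pairs")
  ids <- names(d$records)
  withr::with_seed(as.integer(seed), {
    ids <- sample(ids)
  })
  batches <- split(ids, ceiling(seq_along(ids) / batch_size))
  batches <- Filter(function(b) length(b) >= 2L, batches)
  if (!is.null(max_batches)) batches <- utils::head(batches, max_batches)
  pos <- neg <- numeric(0)
  for (bt in batches) {
    emb <- alignment_embeddings(d, model, bt)
    lp <- row_log_softmax(emb$X_s)
    lq <- row_log_softmax(emb$X_c)
    p <- exp(lp); q <- exp(lq)
    n <- nrow(lp)
    for (i in seq_len(n)) {
      for (k in seq_len(n)) {
        jd <- sum((p[i, ] - q[k, ]) * (lp[i, ] - lq[k, ]))
        if (i == k) pos <- c(pos, jd) else neg <- c(neg, jd)
      }
    }
  }
  structure(list(positive = sort(pos), negative = sort(neg),
                 median_positive = stats::median(pos),
                 median_negative = stats::median(neg)),
            class = "mvrxn_divergence_cdf")
}

#' @export
print.mvrxn_divergence_cdf <- function(x, ...) {
  cat("<mvrxn_divergence_cdf>", length(x$positive), "positive /",
      length(x$negative), "negative pairs | medians",
      signif(x$median_positive, 4), "vs", signif(x$median_negative, 4), "\n")
  invisible(x)
}

#' Empirical CDF coordinates of a divergence sample
#'
#' @param values sorted (or unsorted) divergence values.
#' @return data.frame with `value` (sorted) and `cum_fraction`
#'   (nondecreasing, ending at 1).
#' @export
divergence_cdf_points <- function(values) {
  v <- sort(values)
  data.frame(value = v, cum_fraction = seq_along(v) / length(v))
}

#' Histogram distribution-shift metrics between two yield samples
#'
#' Both samples are binned with shared equal-width bins on [0, 100] and
#' normalized to bin masses p, q.  Reported: normalized histogram
#' intersection `sum min(p, q)` (1 iff identical), symmetric chi-squared
#' distance `sum (p-q)^2 / (p+q)` (empty bins contribute 0), and Jeffreys
#' divergence `sum (p-q) (ln p - ln q)` with additive smoothing
#' `eps = 1e-10` on empty bins.
#'
#' @param a,b numeric yield samples in [0, 100].
#' @param bins number of equal-width bins (default 20).
#' @return list with `intersection`, `chi_squared`, `jeffreys`, `bins`.
#' @export
histogram_shift_metrics <- function(a, b, bins = 20L) {
  if (bins < 2L) stop("config error: bins must be >= 2")
  stopifnot(length(a) > 0L, length(b) > 0L)
  edges <- seq(0, 100, length.out = bins + 1L)
  p <- tabulate(findInterval(a, edges, rightmost.closed = TRUE), bins)
  q <- tabulate(findInterval(b, edges, rightmost.closed = TRUE), bins)
  p <- p / sum(p); q <- q / sum(q)
  chi_terms <- ifelse(p + q > 0, (p - q)^2 / (p + q), 0)
  eps <- 1e-10
  ps <- p + eps; qs <- q + eps
  list(intersection = sum(pmin(p, q)),
       chi_squared = sum(chi_terms),
       jeffreys = sum((ps - qs) * (log(ps) - log(qs))),
       bins = as.integer(bins))
}

#' Histogram-shift metrics from explicit bin masses
#'
#' Same metrics as [histogram_shift_metrics()] on already-normalized bin
#' mass vectors (useful for worked examples and cross-checks).
#' @param p,q normalized bin-mass vectors of equal length.
#' @return list with `intersection`, `chi_squared`, `jeffreys`.
#' @export
histogram_shift_from_masses <- function(p, q) {
  stopifnot(length(p) == length(q))
  chi_terms <- ifelse(p + q > 0, (p - q)^2 / (p + q), 0)
  eps <- 1e-10
  ps <- p + eps; qs <- q + eps
  list(intersection = sum(pmin(p, q)),
       chi_squared = sum(chi_terms),
       jeffreys = sum((ps - qs) * (log(ps) - log(qs))))
}
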