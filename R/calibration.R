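# Probability bias corrections and calibration assessment: the
# undersampling correction, the Elkan-Noto estimators of the labeling
# probability c, the PU correction p/c, Brier score, reliability (calibration)
# curves with exact binomial intervals, and implied positive-class totals.

#' Correct the upward probability bias of class-balanced undersampling
#'
#' Applies `p' = beta * p / (beta * p - p + 1)`, where `beta` is the
#' probability of selecting a negative instance under undersampling. The
#' transform fixes 0 and 1, is strictly increasing, and for `beta < 1`
#' shrinks interior probabilities downward.
#'
#' @param p Probability vector in `[0, 1]`.
#' @param beta Positive negative-selection probability (e.g. `130/15076`
#'   when all 130 positives are paired with 130 of 15,076 negatives).
#' @return Corrected probability vector.
#' @examples
#' correct_undersampling(0.5, 0.5)        # 1/3
#' correct_undersampling(0.5, 130/15076)  # ~0.0085
#' @export
correct_undersampling <- function(p, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop_domain("'beta' must be a positive real")
  if (!is_prob(p)) stop_domain("'p' must contain probabilities in [0, 1]")
  pmin(pmax(beta * p / (beta * p - p + 1), 0), 1)
}

#' Elkan-Noto estimators of the labeling probability c
#'
#' Estimates `c = p(s = 1 | y = 1)` from classifier outputs
#' `g(x) = p(s = 1 | x)` on a validation set `V` with labeled subset `P`:
#' `e1` is the mean of `g` over `P`; `e2` is `sum(g over P) / sum(g over V)`;
#' `e3` is the maximum of `g` over `V`.
#'
#' @param probs Probabilities `g(x)` on the validation set.
#' @param labels Binary labels `s` on the validation set (1 = labeled).
#' @param method `"e1"`, `"e2"` or `"e3"`.
#' @return The estimate, a single value in (0, 1] (assuming some `g > 0`).
#' @export
estimate_c <- function(probs, labels, method = c("e1", "e2", "e3")) {
  method <- match.arg(method)
  if (length(probs) == 0L) stop_data("validation set is empty")
  if (length(probs) != length(labels)) stop_data("'probs' and 'labels' lengths differ")
  if (!is_prob(probs)) stop_domain("'probs' must be probabilities in [0, 1]")
  lab <- as.integer(labels) == 1L
  if (method != "e3" && !any(lab))
    stop_data(sprintf("method %s requires labeled positives in the validation set", method))
  switch(method,
         e1 = mean(probs[lab]),
         e2 = sum(probs[lab]) / sum(probs),
         e3 = max(probs))
}

#' PU correction of probabilities
#'
#' Divides PU-classifier probabilities `p(s = 1 | x)` by an estimate of
#' `c = p(s = 1 | y = 1)` to obtain `p(y = 1 | x)`, truncating at 1.
#'
#' @param probs Probability vector.
#' @param c Labeling probability estimate in (0, 1].
#' @return Corrected vector; the number of values truncated at 1 is attached
#'   as attribute `"n_truncated"`.
#' @export
correct_pu <- function(probs, c) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop_domain("'c' must be a positive real")
  if (!is_prob(probs)) stop_domain("'probs' must be probabilities in [0, 1]")
  out <- probs / c
  n_trunc <- sum(out > 1)
  out[out > 1] <- 1
  structure(out, n_truncated = n_trunc)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; 0 for perfect predictions, 0.25 for a constant 0.5.
#'
#' @param probs Probability vector.
#' @param y Binary outcomes of the same length.
#' @return Non-negative scalar.
#' @export
brier_score <- function(probs, y) {
  if (length(probs) == 0L) stop_data("empty input")
  if (length(probs) != length(y)) stop_data("'probs' and 'y' lengths differ")
  mean((as.numeric(y) - probs)^2)
}

#' Reliability (calibration) curve
#'
#' Discretizes the prediction space into `n_bins` equal-width bins on
#' `[0, 1]` (11 by default, so the first bin is roughly 0-0.09) and reports,
#' per bin, the mean predicted value, the observed positive fraction with its
#' exact (Clopper-Pearson) 95% binomial confidence interval, and the count.
#'
#' @param probs Probability vector.
#' @param y Binary outcomes.
#' @param n_bins Number of bins (>= 2).
#' @return List of class `calibration_report`: `bins` (data frame with
#'   `bin`, `lower`, `upper`, `mean_pred`, `obs_frac`, `ci_lo`, `ci_hi`,
#'   `count`), `brier`, and `n`.
#' @export
calibration_curve <- function(probs, y, n_bins = 11) {
  if (!is.numeric(n_bins) || n_bins < 2) stop_domain("'n_bins' must be >= 2")
  if (!is_prob(probs)) stop_domain("'probs' must be probabilities in [0, 1]")
  y <- as.integer(y)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  idx <- findInterval(probs, breaks, rightmost.closed = TRUE)
  bins <- data.frame(bin = seq_len(n_bins), lower = breaks[-length(breaks)],
                     upper = breaks[-1], mean_pred = NA_real_,
                     obs_frac = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                     count = 0L)
  for (b in seq_len(n_bins)) {
    sel <- idx == b
    bins$count[b] <- sum(sel)
    if (!any(sel)) next
    bins$mean_pred[b] <- mean(probs[sel])
    k <- sum(y[sel]); n <- sum(sel)
    bins$obs_frac[b] <- k / n
    ci <- stats::binom.test(k, n)$conf.int
    bins$ci_lo[b] <- ci[1]; bins$ci_hi[b] <- ci[2]
  }
  structure(list(bins = bins, brier = brier_score(probs, y), n = length(probs)),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("calibration_report: %d cases, Brier score %.4g\n", x$n, x$brier))
  print(x$bins, digits = 3)
  invisible(x)
}

#' Implied total number of positives
#'
#' Given `n_labeled` labeled positives and a labeling probability `c`, the
#' implied total positive-class size is `n_labeled / c`, reported raw and
#' rounded to two significant figures (e.g. 130 labeled genes with
#' `c = 0.032` imply 4.1e3 deafness genes).
#'
#' @param n_labeled Number of labeled positives (>= 1).
#' @param c Labeling probability in (0, 1].
#' @return List with `raw` and `rounded`.
#' @export
implied_total_positives <- function(n_labeled, c) {
  if (!is.numeric(n_labeled) || n_labeled < 1) stop_data("'n_labeled' must be >= 1")
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0 || c > 1)
    stop_domain("'c' must be in (0, 1]")
  raw <- n_labeled / c
  list(raw = raw, rounded = signif(raw, 2))
}
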