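# The positive-unlabeled bagging classifier: stratified 75/25 splits,
# per-learner downsampling of the unlabeled ("negative") class to the
# labeled-positive count, aggregation of decision-tree probabilities over
# learners and splits, plus rank-based AUC and DeLong's test.

#' Stratified train/test split of a PU label set
#'
#' Samples `train_frac` of each label stratum without replacement, so the
#' positive (labeled) fraction in the training set matches the overall
#' fraction up to rounding.
#'
#' @param labels Data frame with columns `gene_id` and `s` (1 = labeled
#'   positive, 0 = unlabeled), e.g. from [gen_pu_labels()].
#' @param train_frac Training fraction in (0, 1); default 0.75.
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_frac = 0.75, seed = 1L) {
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1)
    stop_domain("'train_frac' must be in (0, 1)")
  s <- check_labels(labels)
  with_rng(seed, {
    train <- character(0)
    for (lev in c(0L, 1L)) {
      ids <- labels$gene_id[s == lev]
      if (length(ids) < 2L)
        stop_data(sprintf("stratum s=%d has fewer than 2 genes", lev))
      train <- c(train, sample(ids, round(length(ids) * train_frac)))
    }
    list(train = sort(train), test = sort(setdiff(labels$gene_id, train)))
  })
}

check_labels <- function(labels) {
  if (!is.data.frame(labels) || !all(c("gene_id", "s") %in% names(labels)))
    stop_data("'labels' must be a data frame with columns gene_id and s")
  s <- as.integer(labels$s)
  if (!all(s %in% c(0L, 1L))) stop_data("labels$s must be 0 or 1")
  if (sum(s == 1L) < 2L || sum(s == 0L) < 2L)
    stop_data("need at least 2 labeled and 2 unlabeled genes")
  s
}

feature_matrix <- function(features) {
  if (!is.data.frame(features) || !"gene_id" %in% names(features))
    stop_data("'features' must be a data frame with a gene_id column")
  num <- vapply(features, is.numeric, logical(1)) & names(features) != "gene_id"
  X <- as.matrix(features[, num, drop = FALSE])
  rownames(X) <- features$gene_id
  if (ncol(X) == 0L) stop_data("'features' has no numeric feature columns")
  X
}

#' Base-learner control for the bagged trees
#'
#' CART regularization settings for each tree in the bag. The defaults are
#' the standard CART ones (minimum 20 cases to attempt a split, minimum
#' leaf size 7, complexity penalty 0.01): leaf class proportions then stay
#' strictly inside (0, 1) whenever a leaf mixes classes, which keeps the
#' ensemble's probabilities smooth enough for the maximum-based c estimator
#' e3 to be usable. Fully grown trees (`minsplit = 2`, `minbucket = 1`,
#' `cp = 0`) are available but make the ensemble overconfident: on cleanly
#' separable data every deep positive gets a unanimous vote, g(x) pins to 1
#' and e3 saturates.
#'
#' @param minsplit,minbucket,cp,maxdepth Passed to [rpart::rpart.control()].
#' @return An rpart control list.
#' @export
tree_control <- function(minsplit = 20, minbucket = 7, cp = 0.01, maxdepth = 30) {
  rpart::rpart.control(minsplit = minsplit, minbucket = minbucket, cp = cp,
                       maxdepth = maxdepth, xval = 0, maxcompete = 0,
                       maxsurrogate = 0, usesurrogate = 0)
}

#' Bagged decision trees with negative downsampling
#'
#' For each of `n_learners` base learners, all labeled positives in the
#' training set are combined with an equal number of unlabeled training genes
#' drawn uniformly at random; a CART tree (Gini) is fit on this balanced set
#' with unlabeled treated as negative, and its positive-class leaf
#' probability is predicted on the test set. The output is the mean over
#' learners.
#'
#' @param features Gene feature table ([gene_features()] or any data frame
#'   with `gene_id` plus numeric feature columns).
#' @param labels PU labels (`gene_id`, `s`).
#' @param split Split from [stratified_split()].
#' @param n_learners Number of trees (default 1000).
#' @param seed Integer seed.
#' @param control Base-learner regularization from [tree_control()].
#' @return Data frame with columns `gene_id` and `prob` for the test genes;
#'   attribute `"stage"` is `"raw"`.
#' @export
bagged_fit_predict <- function(features, labels, split, n_learners = 1000,
                               seed = 1L, control = tree_control()) {
  if (!is.numeric(n_learners) || n_learners < 1) stop_domain("'n_learners' must be >= 1")
  s <- check_labels(labels)
  X <- feature_matrix(features)
  names(s) <- labels$gene_id
  tr <- split$train; te <- split$test
  pos <- tr[s[tr] == 1L]; unl <- tr[s[tr] == 0L]
  if (length(unl) < length(pos))
    stop_data("fewer unlabeled than labeled-positive genes in the training set")
  test_df <- as.data.frame(X[te, , drop = FALSE])
  acc <- numeric(length(te))
  with_rng(seed, {
    for (b in seq_len(n_learners)) {
      neg <- sample(unl, length(pos))
      dat <- as.data.frame(X[c(pos, neg), , drop = FALSE])
      dat$.y <- factor(rep(c(1L, 0L), c(length(pos), length(neg))), levels = c(0L, 1L))
      fit <- rpart::rpart(.y ~ ., data = dat, method = "class", control = control)
      acc <- acc + predict(fit, test_df, type = "prob")[, "1"]
    }
  })
  structure(data.frame(gene_id = te, prob = acc / n_learners), stage = "raw")
}

#' Run the full PU bagging classifier over repeated splits
#'
#' Repeats: stratified 75/25 split, bagged fit and test-set prediction,
#' undersampling correction with `beta`, per-split estimation of the
#' labeling probability `c` on the test set by all three estimators (e1, e2,
#' e3), and PU correction by the chosen method. Per-gene probabilities are
#' averaged over the splits in which the gene appeared in the test set.
#'
#' @param features Gene feature table.
#' @param labels PU labels (`gene_id`, `s`).
#' @param n_splits Number of repeated splits (default 2000; the ranking
#'   typically plateaus by about 150).
#' @param n_learners Trees per split.
#' @param beta Negative-selection probability for the undersampling
#'   correction; defaults to (number labeled)/(number unlabeled).
#' @param c_method Estimator used for the PU correction: `"e1"`, `"e2"` or
#'   `"e3"` (default).
#' @param train_frac Training fraction per split.
#' @param seed Integer seed.
#' @param control Base-learner regularization from [tree_control()].
#' @return List with elements `probs` (data frame: `gene_id`, `raw`,
#'   `undersampling_corrected`, `pu_corrected`, `n_test`; genes never seen
#'   in a test set carry `NA`), `c_estimates` (data frame: `method`, `mean`,
#'   `sd`), `splits` (per-split c values and seeds) and `settings`.
#' @export
run_pu <- function(features, labels, n_splits = 2000, n_learners = 1000,
                   beta = NULL, c_method = c("e3", "e1", "e2"),
                   train_frac = 0.75, seed = 1L, control = tree_control()) {
  if (!is.numeric(n_splits) || n_splits < 1) stop_domain("'n_splits' must be >= 1")
  c_method <- match.arg(c_method)
  s <- check_labels(labels)
  if (is.null(beta)) beta <- sum(s == 1L) / sum(s == 0L)
  if (!is.numeric(beta) || beta <= 0) stop_domain("'beta' must be positive")

  ids <- labels$gene_id
  sums <- matrix(0, length(ids), 3,
                 dimnames = list(ids, c("raw", "undersampling_corrected", "pu_corrected")))
  n_test <- integer(length(ids)); names(n_test) <- ids
  seeds <- derive_seeds(seed, 2L * n_splits)
  recs <- vector("list", n_splits)
  s_named <- s; names(s_named) <- ids

  for (i in seq_len(n_splits)) {
    sp <- stratified_split(labels, train_frac, seed = seeds[2L * i - 1L])
    raw <- bagged_fit_predict(features, labels, sp, n_learners,
                              seed = seeds[2L * i], control = control)
    corr <- correct_undersampling(raw$prob, beta)
    y_test <- s_named[raw$gene_id]
    cs <- c(e1 = estimate_c(corr, y_test, "e1"),
            e2 = estimate_c(corr, y_test, "e2"),
            e3 = estimate_c(corr, y_test, "e3"))
    pu <- as.numeric(correct_pu(corr, cs[[c_method]]))
    sums[raw$gene_id, "raw"] <- sums[raw$gene_id, "raw"] + raw$prob
    sums[raw$gene_id, "undersampling_corrected"] <-
      sums[raw$gene_id, "undersampling_corrected"] + corr
    sums[raw$gene_id, "pu_corrected"] <- sums[raw$gene_id, "pu_corrected"] + pu
    n_test[raw$gene_id] <- n_test[raw$gene_id] + 1L
    recs[[i]] <- data.frame(split = i, c_e1 = cs[["e1"]], c_e2 = cs[["e2"]],
                            c_e3 = cs[["e3"]])
  }

  probs <- data.frame(gene_id = ids,
                      raw = sums[, "raw"] / n_test,
                      undersampling_corrected = sums[, "undersampling_corrected"] / n_test,
                      pu_corrected = sums[, "pu_corrected"] / n_test,
                      n_test = n_test, row.names = NULL)
  probs[n_test == 0L, c("raw", "undersampling_corrected", "pu_corrected")] <- NA_real_
  if (any(n_test == 0L))
    warning(sprintf("%d gene(s) never appeared in a test set; probabilities are NA",
                    sum(n_test == 0L)))
  splits <- do.call(rbind, recs)
  c_est <- data.frame(method = c("e1", "e2", "e3"),
                      mean = c(mean(splits$c_e1), mean(splits$c_e2), mean(splits$c_e3)),
                      sd = c(stats::sd(splits$c_e1), stats::sd(splits$c_e2),
                             stats::sd(splits$c_e3)))
  list(probs = probs, c_estimates = c_est, splits = splits,
       settings = list(n_splits = n_splits, n_learners = n_learners, beta = beta,
                       c_method = c_method, train_frac = train_frac, seed = seed))
}

#' Rank-based ROC AUC
#'
#' Probability that a random positive outranks a random negative; ties get
#' average rank (midrank AUC).
#'
#' @param probs Numeric scores.
#' @param labels Binary labels (0/1 or logical) of the same length.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(probs, labels) {
  labels <- as.integer(labels)
  ok <- is.finite(probs) & !is.na(labels)
  probs <- probs[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_domain("both classes must be present")
  r <- rank(probs)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# midrank placements per DeLong/Sun-Xu
delong_placements <- function(x, labels) {
  pos <- x[labels == 1L]; neg <- x[labels == 0L]
  m <- length(pos); n <- length(neg)
  rc <- rank(c(pos, neg))
  v10 <- (rc[seq_len(m)] - rank(pos)) / n
  v01 <- 1 - (rc[m + seq_len(n)] - rank(neg)) / m
  list(theta = sum(rc[seq_len(m)]) / (m * n) - (m + 1) / (2 * n),
       v10 = v10, v01 = v01)
}

#' DeLong's test for two correlated ROC curves
#'
#' Two-sided test of equality of the AUCs of two markers measured on the
#' same cases, using the fast midrank (placement) form of DeLong's
#' covariance estimate.
#'
#' @param probs_a,probs_b Two score vectors over the same cases.
#' @param labels Binary labels shared by both markers.
#' @return List with `auc_a`, `auc_b`, `z` and two-sided `p.value`.
#' @export
delong_test <- function(probs_a, probs_b, labels) {
  labels <- as.integer(labels)
  if (length(probs_a) != length(probs_b) || length(probs_a) != length(labels))
    stop_data("'probs_a', 'probs_b' and 'labels' must have equal length")
  if (!all(labels %in% 0:1) || length(unique(labels)) < 2L)
    stop_domain("both classes must be present")
  pa <- delong_placements(probs_a, labels)
  pb <- delong_placements(probs_b, labels)
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (v <= .Machine$double.eps) {
    warning("zero variance of the AUC difference; returning p = 1")
    return(list(auc_a = pa$theta, auc_b = pb$theta, z = 0, p.value = 1))
  }
  z <- (pa$theta - pb$theta) / sqrt(v)
  list(auc_a = pa$theta, auc_b = pb$theta, z = z,
       p.value = 2 * stats::pnorm(-abs(z)))
}
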