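# The rerun classifier: unlabeled genes are probabilistically reassigned to
# the positive or negative class from calibrated initial probabilities before
# every iteration, the bagging classifier is retrained on the reassigned
# classes, and a single undersampling correction with an expectation-based
# beta is applied at the end. No PU correction is applied, since reassigned
# classes are soft truth rather than PU labels.

#' Probabilistic class reassignment
#'
#' Labeled genes are always positive; each unlabeled gene is independently
#' assigned positive with its initial probability `p_g` and negative
#' otherwise.
#'
#' @param p_init Per-gene initial probabilities in `[0, 1]`.
#' @param labeled_mask Logical vector: `TRUE` for known (labeled) positives.
#' @param seed Integer seed.
#' @return Integer vector of classes (1 = positive, 0 = negative).
#' @export
reassign_classes <- function(p_init, labeled_mask, seed = 1L) {
  if (!is_prob(p_init)) stop_domain("'p_init' must be probabilities in [0, 1]")
  if (length(p_init) != length(labeled_mask))
    stop_data("'p_init' and 'labeled_mask' lengths differ")
  with_rng(seed, {
    cls <- stats::rbinom(length(p_init), 1L, p_init)
    cls[as.logical(labeled_mask)] <- 1L
    cls
  })
}

#' Run the rerun (reassignment) classifier
#'
#' Per iteration: reassign classes ([reassign_classes()]), stratify a 75/25
#' split on the reassigned classes, fit the downsampled bagging classifier
#' (negatives downsampled to that iteration's positive count) and predict on
#' the test set. Probabilities are averaged over iterations and finally
#' corrected once for undersampling with
#' `beta = E(N+) / (N - E(N+))`, where `E(N+)` is the expected positive
#' count under `p_init` (labeled genes contribute 1). Iterations whose
#' reassignment leaves fewer than 2 genes in either class are skipped with a
#' warning; the run fails if more than half are skipped.
#'
#' @param features Gene feature table.
#' @param p_init Initial (calibrated, PU-corrected) probabilities, one per
#'   feature row.
#' @param labeled_mask Logical vector marking known positives.
#' @param n_splits,n_learners,train_frac,seed As in [run_pu()].
#' @param beta Optional override of the final correction's beta.
#' @param control Base-learner regularization from [tree_control()].
#' @return List with `probs` (data frame: `gene_id`, `raw_mean`, `prob`
#'   (final, undersampling-corrected), `n_test`), `beta`, `expected_n_pos`,
#'   `n_skipped` and `settings`.
#' @export
run_rerun <- function(features, p_init, labeled_mask, n_splits = 2000,
                      n_learners = 1000, beta = NULL, train_frac = 0.75,
                      seed = 1L, control = tree_control()) {
  X_ids <- feature_matrix(features)  # validates features
  ids <- features$gene_id
  if (length(p_init) != length(ids) || length(labeled_mask) != length(ids))
    stop_data("'p_init' and 'labeled_mask' must have one entry per feature row")
  if (!is_prob(p_init)) stop_domain("'p_init' must be probabilities in [0, 1]")
  labeled_mask <- as.logical(labeled_mask)

  e_npos <- sum(labeled_mask) + sum(p_init[!labeled_mask])
  if (is.null(beta)) beta <- e_npos / (length(ids) - e_npos)
  if (!is.numeric(beta) || beta <= 0) stop_domain("'beta' must be positive")

  sums <- numeric(length(ids)); names(sums) <- ids
  n_test <- integer(length(ids)); names(n_test) <- ids
  seeds <- derive_seeds(seed, 3L * n_splits)
  n_skipped <- 0L

  for (i in seq_len(n_splits)) {
    cls <- reassign_classes(p_init, labeled_mask, seed = seeds[3L * i - 2L])
    if (sum(cls == 1L) < 2L || sum(cls == 0L) < 2L) {
      warning(sprintf("iteration %d skipped: a reassigned class has < 2 genes", i))
      n_skipped <- n_skipped + 1L
      next
    }
    lab_i <- data.frame(gene_id = ids, s = cls)
    sp <- stratified_split(lab_i, train_frac, seed = seeds[3L * i - 1L])
    pred <- bagged_fit_predict(features, lab_i, sp, n_learners,
                               seed = seeds[3L * i], control = control)
    sums[pred$gene_id] <- sums[pred$gene_id] + pred$prob
    n_test[pred$gene_id] <- n_test[pred$gene_id] + 1L
  }
  if (n_skipped > n_splits / 2)
    stop_data(sprintf("more than half of the iterations were skipped (%d of %d)",
                      n_skipped, n_splits))

  raw_mean <- ifelse(n_test > 0L, sums / pmax(n_test, 1L), NA_real_)
  final <- rep(NA_real_, length(ids))
  final[n_test > 0L] <- correct_undersampling(raw_mean[n_test > 0L], beta)
  probs <- data.frame(gene_id = ids, raw_mean = raw_mean, prob = final,
                      n_test = as.integer(n_test), row.names = NULL)
  list(probs = probs, beta = beta, expected_n_pos = e_npos,
       n_skipped = n_skipped,
       settings = list(n_splits = n_splits, n_learners = n_learners,
                       train_frac = train_frac, seed = seed))
}
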