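# Text-mining association scores and discrimination-threshold selection:
# the DiGSeE-style article/sentence score, the rank-based combined score,
# the Youden (ROC) threshold, and the Wilcoxon rank-sum threshold scan.

#' DiGSeE-style association score
#'
#' `n_articles + n_sentences / (max_sentences + 1)`: the article count
#' dominates and the sentence count breaks ties, since the sentence term is
#' always below 1.
#'
#' @param n_articles,n_sentences Non-negative integer vectors.
#' @param max_sentences Maximum sentence count over the gene universe; must
#'   be at least every `n_sentences`.
#' @return Numeric score vector.
#' @export
digsee_score <- function(n_articles, n_sentences, max_sentences) {
  if (any(n_articles < 0) || any(n_sentences < 0) || max_sentences < 0)
    stop_domain("counts must be non-negative")
  if (any(n_sentences > max_sentences))
    stop_domain("'max_sentences' must be >= every n_sentences")
  n_articles + n_sentences / (max_sentences + 1)
}

#' Combined (mean-rank) association score
#'
#' Ranks each source's scores ascending (ties get the average rank), takes
#' the per-gene mean rank across sources, and shifts so the minimum combined
#' score over the universe is exactly 0. Being rank-based, it is invariant
#' under monotone per-source rescaling.
#'
#' @param scores Data frame with `gene_id` plus one numeric column per
#'   source, or a numeric matrix (genes x sources).
#' @return Numeric vector of combined scores (named by gene id if
#'   available).
#' @export
combined_score <- function(scores) {
  if (is.data.frame(scores)) {
    ids <- if ("gene_id" %in% names(scores)) scores$gene_id else rownames(scores)
    m <- as.matrix(scores[, setdiff(names(scores), "gene_id"), drop = FALSE])
  } else {
    ids <- rownames(scores)
    m <- as.matrix(scores)
  }
  if (!is.numeric(m) || ncol(m) < 1L) stop_data("need at least one numeric source column")
  ranks <- apply(m, 2, rank)
  comb <- rowMeans(ranks)
  comb <- comb - min(comb)
  names(comb) <- ids
  comb
}

#' Youden-optimal discrimination threshold
#'
#' Scans the observed probability values as candidate thresholds (a gene
#' passes if its probability is at or above the threshold) and returns the
#' one maximizing sensitivity + specificity; ties are broken toward the
#' smallest threshold.
#'
#' @param probs Predicted probabilities.
#' @param associated Binary labels (1 = associated).
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden`,
#'   `n_passing`.
#' @export
choose_threshold_roc <- function(probs, associated) {
  y <- as.integer(associated)
  ok <- is.finite(probs) & !is.na(y)
  probs <- probs[ok]; y <- y[ok]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop_domain("both classes must be present")
  cand <- sort(unique(probs))
  best <- NULL
  for (t in cand) {
    pass <- probs >= t
    sens <- sum(pass & y == 1L) / n1
    spec <- sum(!pass & y == 0L) / n0
    if (is.null(best) || sens + spec > best$youden + 1e-12) {
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   youden = sens + spec, n_passing = sum(pass))
    }
  }
  best
}

local_maxima <- function(v) {
  n <- length(v)
  if (n == 1L) return(1L)
  which(vapply(seq_len(n), function(i) {
    left <- if (i > 1L) v[i] > v[i - 1L] else TRUE
    right <- if (i < n) v[i] >= v[i + 1L] else TRUE
    left && right
  }, logical(1)))
}

#' Wilcoxon rank-sum threshold scan
#'
#' For each threshold in `grid`, compares the association scores of genes
#' with probability strictly above the threshold against all other genes
#' with a one-tailed rank-sum test (alternative: higher scores above the
#' threshold) and records `-log2(p)`, per source and for the combined
#' score. Known labeled positives should be excluded via `exclude`. The
#' chosen threshold is the one most significant for the combined score;
#' local maxima of the combined curve are reported as alternatives.
#'
#' @param probs Named numeric vector (or data frame column) of predicted
#'   probabilities, one per gene.
#' @param scores Data frame with `gene_id` plus per-source score columns
#'   (e.g. `digsee`, `disgenet`, `diseases`); a `combined` column is added
#'   via [combined_score()] if absent.
#' @param gene_id Gene ids aligned with `probs` (defaults to
#'   `names(probs)`).
#' @param grid Increasing threshold grid; defaults to the sorted unique
#'   probabilities (endpoints leaving an empty side get `p = 1` and a flag).
#' @param exclude Gene ids to drop before scanning (known positives).
#' @return List of class `threshold_scan`: `table` (threshold, one
#'   `neg_log2_p_*` column per source and combined, `n_above`, `empty_side`
#'   flag), `chosen` (threshold, `neg_log2_p`, `n_passing`),
#'   `local_maxima` (alternative thresholds).
#' @export
wilcoxon_threshold_scan <- function(probs, scores, gene_id = names(probs),
                                    grid = NULL, exclude = NULL) {
  if (is.null(gene_id)) stop_data("'gene_id' required when 'probs' is unnamed")
  if (!is.data.frame(scores) || !"gene_id" %in% names(scores))
    stop_data("'scores' must be a data frame with a gene_id column")
  keep <- !(gene_id %in% exclude) & is.finite(probs)
  probs <- probs[keep]; gene_id <- gene_id[keep]
  sc <- scores[match(gene_id, scores$gene_id), , drop = FALSE]
  if (anyNA(sc$gene_id)) stop_data("'scores' must cover every gene in 'probs'")
  src_cols <- setdiff(names(sc), "gene_id")
  if (!"combined" %in% src_cols) {
    sc$combined <- as.numeric(combined_score(sc))
    src_cols <- c(src_cols, "combined")
  }
  if (is.null(grid)) grid <- sort(unique(probs))
  if (is.unsorted(grid, strictly = TRUE)) stop_domain("'grid' must be strictly increasing")

  tab <- data.frame(threshold = grid)
  tab$n_above <- vapply(grid, function(t) sum(probs > t), integer(1))
  tab$empty_side <- tab$n_above == 0L | tab$n_above == length(probs)
  for (cn in src_cols) {
    p <- vapply(seq_along(grid), function(i) {
      if (tab$empty_side[i]) return(1)
      above <- probs > grid[i]
      rank_sum_one_sided(sc[[cn]][above], sc[[cn]][!above], "greater")
    }, numeric(1))
    tab[[paste0("neg_log2_p_", cn)]] <- -log2(p)
  }
  comb_curve <- tab$neg_log2_p_combined
  best_i <- which.max(comb_curve)
  lm_i <- local_maxima(comb_curve)
  lm_i <- lm_i[!tab$empty_side[lm_i]]
  structure(list(
    table = tab,
    chosen = list(threshold = grid[best_i], neg_log2_p = comb_curve[best_i],
                  n_passing = tab$n_above[best_i]),
    local_maxima = data.frame(threshold = grid[lm_i],
                              neg_log2_p = comb_curve[lm_i],
                              n_passing = tab$n_above[lm_i])),
    class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("threshold_scan: %d thresholds; chosen %.4g (-log2 p = %.2f, %d genes pass)\n",
              nrow(x$table), x$chosen$threshold, x$chosen$neg_log2_p,
              x$chosen$n_passing))
  invisible(x)
}
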