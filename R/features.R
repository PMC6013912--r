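# Expression-derived classifier features: log2-CPM, the expressed-gene
# filter, and the four per-gene features (average expression and three log2
# fold changes: age, tissue, age-tissue interaction).

#' Log2 counts-per-million with a prior count
#'
#' `log2((count + prior) / (library_size + 2 * prior) * 1e6)`, computed per
#' sample. The prior keeps all values finite; the `2 * prior` term in the
#' denominator mirrors the usual prior-augmented library size.
#'
#' @param x A [count_matrix] or a numeric count matrix.
#' @param prior Positive prior count added to every gene (default 0.5).
#' @return Gene x sample matrix of log2-CPM values.
#' @export
log_cpm <- function(x, prior = 0.5) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  if (!is.numeric(prior) || length(prior) != 1L || prior <= 0)
    stop_domain("'prior' must be a positive real")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop_data(sprintf("sample(s) with zero total count: %s",
                      paste(colnames(counts)[lib == 0], collapse = ", ")))
  log2(sweep(counts + prior, 2, lib + 2 * prior, "/") * 1e6)
}

#' Filter to expressed genes
#'
#' Keeps genes with CPM at or above `min_cpm` in at least `min_samples`
#' samples, the standard expressed-gene rule (defaults: at least one read per
#' million in three or more samples).
#'
#' @param x A [count_matrix].
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples Minimum number of samples meeting the threshold
#'   (default 3); `0` keeps every gene.
#' @return A filtered [count_matrix].
#' @export
filter_expressed <- function(x, min_cpm = 1, min_samples = 3) {
  x <- as_count_matrix(x)
  if (min_cpm < 0 || min_samples < 0) stop_domain("thresholds must be non-negative")
  lib <- colSums(x$counts)
  if (any(lib == 0)) stop_data("sample(s) with zero total count")
  cpm <- sweep(x$counts, 2, lib, "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  if (!any(keep)) warning("no genes pass the expression filter")
  count_matrix(x$counts[keep, , drop = FALSE], x$sample_meta)
}

group_mean_logcpm <- function(x, prior) {
  lc <- log_cpm(x, prior)
  meta <- x$sample_meta
  combos <- expand.grid(tissue = c("cochlea", "vestibule"),
                        age = c("E16.5", "P0"), stringsAsFactors = FALSE)
  gm <- matrix(NA_real_, nrow(lc), nrow(combos),
               dimnames = list(rownames(lc),
                               paste(combos$age, combos$tissue, sep = ".")))
  for (g in seq_len(nrow(combos))) {
    sel <- meta$tissue == combos$tissue[g] & meta$age == combos$age[g]
    if (!any(sel))
      stop_data(sprintf("missing sample group: %s %s", combos$age[g], combos$tissue[g]))
    gm[, g] <- rowMeans(lc[, sel, drop = FALSE])
  }
  list(logcpm = lc, group_means = gm)
}

#' Per-gene classifier features
#'
#' Computes, for every gene, (1) the average log2-CPM over all samples,
#' (2) the log2 fold change between ages (P0 over E16.5), (3) between
#' tissues (cochlea over vestibule), and (4) the interaction fold change,
#' i.e. the log2 of the (cochlea/vestibule ratio at P0) over the same ratio
#' at E16.5. Fold changes are differences of group-mean log2-CPMs, each
#' (tissue, age) group weighted equally.
#'
#' @param x A [count_matrix] containing all four (tissue, age) groups.
#' @param prior Prior count passed to [log_cpm()].
#' @return Data frame with columns `gene_id`, `avg_log_cpm`, `logfc_age`,
#'   `logfc_tissue`, `logfc_interaction`. Fold-change direction conventions
#'   are recorded in attribute `"directions"`.
#' @export
gene_features <- function(x, prior = 0.5) {
  x <- as_count_matrix(x)
  gm <- group_mean_logcpm(x, prior)
  g <- gm$group_means
  e_c <- g[, "E16.5.cochlea"]; e_v <- g[, "E16.5.vestibule"]
  p_c <- g[, "P0.cochlea"];    p_v <- g[, "P0.vestibule"]
  out <- data.frame(
    gene_id = rownames(g),
    avg_log_cpm = rowMeans(gm$logcpm),
    logfc_age = (p_c + p_v) / 2 - (e_c + e_v) / 2,
    logfc_tissue = (e_c + p_c) / 2 - (e_v + p_v) / 2,
    logfc_interaction = (p_c - p_v) - (e_c - e_v))
  rownames(out) <- NULL
  attr(out, "directions") <- c(age = "P0/E16.5", tissue = "cochlea/vestibule",
                               interaction = "(C/V at P0)/(C/V at E16.5)")
  out
}
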