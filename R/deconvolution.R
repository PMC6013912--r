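# Deconvolution of heterogeneous sensory-epithelium samples: variance-ranked
# marker signatures over four reference populations (hair cells and
# supporting cells of cochlea and utricle), constrained least-squares
# estimation of mixing proportions on the log scale, a cross-tissue
# contamination objective, and signature-size selection minimizing it.

ref_col_tissue <- function(cols) sub("_.*$", "", cols)

same_tissue <- function(sample_tissue, col_tissue) {
  vest <- c("vestibule", "utricle")
  (sample_tissue == "cochlea" & col_tissue == "cochlea") |
    (sample_tissue %in% vest & col_tissue %in% vest)
}

#' Rank candidate signature genes by reference variance
#'
#' Removes genes whose CPM falls below `min_cpm` in any reference condition,
#' then orders the remainder by decreasing variance of log2(CPM + 1) across
#' the reference profiles; ties are broken by gene id for determinism.
#'
#' @param reference Genes x conditions CPM matrix (>= 2 conditions), e.g.
#'   [gen_reference_profiles()].
#' @param min_cpm Expression filter applied within the reference (default 1).
#' @return Character vector of gene ids, most variable first, with the
#'   variances attached as attribute `"variance"`.
#' @export
rank_signature_genes <- function(reference, min_cpm = 1) {
  if (ncol(reference) < 2L) stop_data("need at least 2 reference conditions")
  keep <- rowSums(reference < min_cpm) == 0L
  if (!any(keep)) stop_data("no genes pass the reference CPM filter")
  m <- log2(reference[keep, , drop = FALSE] + 1)
  v <- apply(m, 1, stats::var)
  ord <- order(-v, rownames(m))
  structure(rownames(m)[ord], variance = unname(v[ord]))
}

#' Build a log-scale signature matrix
#'
#' @param reference Genes x cell-types CPM matrix.
#' @param genes Gene ids to include (usually the first `k` of
#'   [rank_signature_genes()]).
#' @return log2(CPM + 1) matrix restricted to `genes`.
#' @export
build_signature <- function(reference, genes) {
  if (length(genes) < 2L) stop_data("a signature needs at least 2 genes")
  missing <- setdiff(genes, rownames(reference))
  if (length(missing)) stop_data(sprintf("genes absent from reference: %s",
                                         paste(utils::head(missing, 3), collapse = ", ")))
  log2(reference[genes, , drop = FALSE] + 1)
}

# Least squares on the probability simplex: min ||S w - m|| s.t. w >= 0,
# sum(w) = 1. With at most a handful of cell types the support can be
# enumerated exhaustively; each support is solved through the
# equality-constrained KKT system (pseudo-inverse when rank-deficient), and
# the feasible support with the smallest residual is globally optimal.
nnls_simplex <- function(S, m) {
  p <- ncol(S)
  G <- crossprod(S)            # p x p
  h <- crossprod(S, m)         # p
  best <- NULL; best_obj <- Inf
  for (mask in seq_len(2^p - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) > 0L)
    q <- length(idx)
    K <- rbind(cbind(2 * G[idx, idx, drop = FALSE], rep(1, q)), c(rep(1, q), 0))
    rhs <- c(2 * h[idx], 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) pracma::pinv(K) %*% rhs)
    w_sub <- sol[seq_len(q)]
    if (any(w_sub < -1e-9)) next
    w <- numeric(p); w[idx] <- pmax(w_sub, 0)
    w <- w / sum(w)
    obj <- sum(w * (G %*% w)) - 2 * sum(w * h)
    if (obj < best_obj - 1e-12) { best <- w; best_obj <- obj }
  }
  if (is.null(best)) {
    warning("degenerate solve; returning uniform proportions")
    best <- rep(1 / p, p)
  }
  best
}

#' Estimate cell-type mixing proportions
#'
#' Solves, per sample, the constrained least-squares problem
#' `min || S w - m ||^2` subject to `w >= 0`, `sum(w) = 1` on log-scale
#' expression. Under the `within_tissue` scenario only the sample's own
#' tissue's cell types are allowed; `cross_contamination` uses all four.
#'
#' @param mixture_log_expr Genes x samples matrix of log2-scale expression
#'   (e.g. [gen_mixtures()] output, or `log2(CPM + 1)` of real samples).
#' @param signature Log-scale signature from [build_signature()].
#' @param scenario `"cross_contamination"` (default) or `"within_tissue"`.
#' @param sample_tissue Per-sample tissue (`"cochlea"` / `"vestibule"` /
#'   `"utricle"`); required for `within_tissue` and for
#'   [contamination_objective()].
#' @return Object of class `mixture_estimate`: `proportions` (samples x
#'   cell-types, rows on the simplex; disallowed types are 0), `scenario`,
#'   `sample_tissue`, `objective` (per-sample residual norm).
#' @export
estimate_proportions <- function(mixture_log_expr, signature,
                                 scenario = c("cross_contamination", "within_tissue"),
                                 sample_tissue = NULL) {
  scenario <- match.arg(scenario)
  genes <- rownames(signature)
  if (!all(genes %in% rownames(mixture_log_expr)))
    stop_data("mixture does not contain all signature genes")
  M <- mixture_log_expr[genes, , drop = FALSE]
  n_samp <- ncol(M)
  if (scenario == "within_tissue" && (is.null(sample_tissue) ||
                                      length(sample_tissue) != n_samp))
    stop_usage("'sample_tissue' (one per sample) is required for within_tissue")
  if (qr(signature)$rank < ncol(signature))
    warning("rank-deficient signature; proportions may not be unique")
  col_t <- ref_col_tissue(colnames(signature))
  W <- matrix(0, n_samp, ncol(signature),
              dimnames = list(colnames(M), colnames(signature)))
  obj <- numeric(n_samp)
  for (j in seq_len(n_samp)) {
    use <- if (scenario == "within_tissue")
      which(same_tissue(sample_tissue[j], col_t)) else seq_len(ncol(signature))
    if (length(use) == 0L) stop_data(sprintf("no signature columns match tissue '%s'",
                                             sample_tissue[j]))
    w <- nnls_simplex(signature[, use, drop = FALSE], M[, j])
    W[j, use] <- w
    obj[j] <- sqrt(sum((signature[, use, drop = FALSE] %*% w - M[, j])^2))
  }
  structure(list(proportions = W, scenario = scenario,
                 sample_tissue = sample_tissue, objective = obj),
            class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat(sprintf("mixture_estimate (%s): %d samples\n", x$scenario, nrow(x$proportions)))
  print(round(x$proportions, 3))
  invisible(x)
}

#' Cross-tissue contamination objective
#'
#' The estimated percentage of cochlear cells in vestibular samples plus
#' the estimated percentage of vestibular cells in cochlear samples
#' (averaged within each tissue group; 0-200 scale).
#'
#' @param estimate A `cross_contamination` [estimate_proportions()] result
#'   with `sample_tissue` set.
#' @return Percentage in `[0, 200]`.
#' @export
contamination_objective <- function(estimate) {
  if (!inherits(estimate, "mixture_estimate") ||
      estimate$scenario != "cross_contamination")
    stop_usage("'estimate' must come from the cross_contamination scenario")
  st <- estimate$sample_tissue
  if (is.null(st)) stop_usage("the estimate must carry 'sample_tissue'")
  col_t <- ref_col_tissue(colnames(estimate$proportions))
  contam <- vapply(seq_len(nrow(estimate$proportions)), function(j)
    100 * sum(estimate$proportions[j, !same_tissue(st[j], col_t)]), numeric(1))
  is_coch <- st == "cochlea"
  if (!any(is_coch) || all(is_coch))
    stop_data("need samples from both tissues to compute the objective")
  mean(contam[!is_coch]) + mean(contam[is_coch])
}

basin_widths <- function(v) {
  n <- length(v)
  mins <- which(vapply(seq_len(n), function(i) {
    (i == 1L || v[i] < v[i - 1L]) && (i == n || v[i] <= v[i + 1L])
  }, logical(1)))
  widths <- vapply(mins, function(i) {
    l <- i; while (l > 1L && v[l - 1L] >= v[l]) l <- l - 1L
    r <- i; while (r < n && v[r + 1L] >= v[r]) r <- r + 1L
    r - l + 1L
  }, integer(1))
  data.frame(index = mins, value = v[mins], width = widths)
}

#' Select the signature size k
#'
#' Evaluates the cross-tissue contamination objective for every signature
#' size from 2 to `k_max` genes along the variance ranking and returns the
#' minimizing `k`, after discarding local minima whose basin (the span of
#' monotone descent into the minimum) is narrower than `min_width` genes —
#' the automated analogue of ignoring a narrow spurious dip.
#'
#' @param reference Genes x cell-types CPM matrix.
#' @param mixtures Genes x samples log-scale expression matrix.
#' @param sample_tissue Per-sample tissue labels.
#' @param k_max Largest signature size scanned (default 1000; capped at the
#'   ranked-gene count).
#' @param min_width Minimum basin width in genes (default 10).
#' @param min_cpm Reference expression filter.
#' @return List with `k`, `objective` (at `k`), `curve` (data frame `k`,
#'   `objective`), `minima` (all local minima with basin widths) and the
#'   gene `ranking`.
#' @export
select_k <- function(reference, mixtures, sample_tissue, k_max = 1000,
                     min_width = 10, min_cpm = 1) {
  ranking <- rank_signature_genes(reference, min_cpm)
  k_max <- min(k_max, length(ranking))
  if (k_max < 2L) stop_data("fewer than 2 ranked genes available")
  ks <- 2:k_max
  obj <- vapply(ks, function(k) {
    sig <- build_signature(reference, ranking[seq_len(k)])
    est <- suppressWarnings(
      estimate_proportions(mixtures, sig, "cross_contamination", sample_tissue))
    contamination_objective(est)
  }, numeric(1))
  minima <- basin_widths(obj)
  minima$k <- ks[minima$index]
  eligible <- minima[minima$width >= min_width, , drop = FALSE]
  if (nrow(eligible) == 0L) {
    warning("no basin reaches min_width; using the global minimum")
    eligible <- minima
  }
  best <- eligible[order(eligible$value, eligible$k), ][1, ]
  list(k = best$k, objective = best$value,
       curve = data.frame(k = ks, objective = obj),
       minima = minima[, c("k", "value", "width")], ranking = ranking)
}
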