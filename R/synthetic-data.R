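# Synthetic-data generators: count matrices with planted deafness genes,
# PU labels at a known labeling rate, noisy per-source association scores,
# and reference-profile mixtures for the deconvolution stage. Every
# generator takes an explicit seed and is bitwise reproducible.

#' Configuration for the synthetic count generator
#'
#' Defaults emulate the bulk inner-ear study design this package targets:
#' an expressed-gene universe of roughly 15,206 genes measured in cochlea and
#' vestibule at E16.5 and P0, a planted set of true deafness genes (DGs) whose
#' tissue fold-changes are larger in absolute value and whose age and
#' age-tissue-interaction fold-changes are positive, and PU labeling in which
#' each true DG is labeled independently with probability `c_label` (defaults
#' chosen so that about 130 labeled DGs arise from ~250 true DGs).
#'
#' @param n_genes Number of genes in the expressed universe.
#' @param n_true_dg Number of planted true deafness genes.
#' @param c_label Labeling probability `c = p(s = 1 | y = 1)`.
#' @param reps_per_group Replicates per (tissue, age) group.
#' @param nb_dispersion Negative-binomial dispersion shared across genes
#'   (`variance = mu + dispersion * mu^2`); `0` gives Poisson counts.
#' @param effect_shifts Named numeric vector of mean log2 shifts applied to
#'   true DGs: `tissue_abs` (magnitude of the tissue effect, sign random per
#'   gene), `age` (P0 over E16.5) and `interaction` (applied to the
#'   P0-cochlea group so the interaction feature equals it in expectation).
#' @param lib_size Expected library size per sample.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 15206, n_true_dg = 250, c_label = 0.52,
                       reps_per_group = 3, nb_dispersion = 0.05,
                       effect_shifts = c(tissue_abs = 2, age = 1, interaction = 1),
                       lib_size = 5e6, seed = 1L) {
  chk_count <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || x != floor(x))
      stop_config(sprintf("'%s' must be a positive integer", name))
  }
  chk_count(n_genes, "n_genes"); chk_count(n_true_dg, "n_true_dg")
  chk_count(reps_per_group, "reps_per_group"); chk_count(lib_size, "lib_size")
  if (n_true_dg >= n_genes) stop_config("'n_true_dg' must be smaller than 'n_genes'")
  if (!is.numeric(c_label) || length(c_label) != 1L || !is.finite(c_label) ||
      c_label <= 0 || c_label > 1)
    stop_config("'c_label' must be a probability in (0, 1]")
  if (!is.numeric(nb_dispersion) || length(nb_dispersion) != 1L ||
      !is.finite(nb_dispersion) || nb_dispersion < 0)
    stop_config("'nb_dispersion' must be a non-negative real")
  need <- c("tissue_abs", "age", "interaction")
  if (!is.numeric(effect_shifts) || !all(need %in% names(effect_shifts)) ||
      !all(is.finite(effect_shifts[need])))
    stop_config("'effect_shifts' must be finite and name tissue_abs, age, interaction")
  structure(list(n_genes = as.integer(n_genes), n_true_dg = as.integer(n_true_dg),
                 c_label = c_label, reps_per_group = as.integer(reps_per_group),
                 nb_dispersion = nb_dispersion, effect_shifts = effect_shifts[need],
                 lib_size = lib_size, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic count matrix with planted deafness genes
#'
#' Gene baselines are log-normal on the log2-CPM scale; per-sample expected
#' counts are the library size times the gene's relative abundance under its
#' (tissue, age) group mean, and observed counts are negative-binomial with a
#' shared dispersion. True DGs receive the configured log2 shifts: a tissue
#' effect of magnitude `tissue_abs` with random sign (split symmetrically
#' between the tissues), a positive age effect (split between the ages), and
#' an interaction effect added to the P0-cochlea group only.
#'
#' @param cfg A [sim_config].
#' @return A list with elements `counts` (a [count_matrix]) and `truth`
#'   (gene universe, `true_dg_ids`, per-gene planted shifts, `true_c`).
#' @export
gen_counts <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop_config("'cfg' must be a sim_config object")
  with_rng(cfg$seed, {
    n <- cfg$n_genes
    gene_ids <- sprintf("gene%05d", seq_len(n))
    dg_ids <- sort(sample(gene_ids, cfg$n_true_dg))
    is_dg <- gene_ids %in% dg_ids

    # baseline abundance, log2-CPM-like scale
    mu0 <- stats::rnorm(n, mean = 4, sd = 2)
    sh <- cfg$effect_shifts
    tissue_eff <- ifelse(is_dg, sh[["tissue_abs"]] * sample(c(-1, 1), n, replace = TRUE), 0)
    age_eff <- ifelse(is_dg, sh[["age"]], 0)
    int_eff <- ifelse(is_dg, sh[["interaction"]], 0)

    grp <- expand.grid(tissue = c("cochlea", "vestibule"), age = c("E16.5", "P0"),
                       stringsAsFactors = FALSE)
    # symmetric half-shifts keep the average expression feature centred
    grp_offset <- function(tissue, age) {
      off <- mu0 +
        tissue_eff / 2 * ifelse(tissue == "cochlea", 1, -1) +
        age_eff / 2 * ifelse(age == "P0", 1, -1)
      if (tissue == "cochlea" && age == "P0") off <- off + int_eff
      off
    }

    meta <- do.call(rbind, lapply(seq_len(nrow(grp)), function(g) {
      data.frame(sample_id = sprintf("%s_%s_r%d", grp$age[g], grp$tissue[g],
                                     seq_len(cfg$reps_per_group)),
                 tissue = grp$tissue[g], age = grp$age[g],
                 replicate = seq_len(cfg$reps_per_group))
    }))

    counts <- matrix(0L, n, nrow(meta), dimnames = list(gene_ids, meta$sample_id))
    size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf
    for (j in seq_len(nrow(meta))) {
      w <- 2^grp_offset(meta$tissue[j], meta$age[j])
      mu <- cfg$lib_size * w / sum(w)
      counts[, j] <- if (is.finite(size)) stats::rnbinom(n, mu = mu, size = size)
                     else stats::rpois(n, mu)
    }

    truth <- list(gene_ids = gene_ids, true_dg_ids = dg_ids,
                  labeled_ids = character(0), true_c = NA_real_,
                  shifts = data.frame(gene_id = gene_ids, tissue = tissue_eff,
                                      age = age_eff, interaction = int_eff))
    list(counts = count_matrix(counts, meta), truth = truth)
  })
}

#' Draw PU labels over a synthetic truth
#'
#' Each true DG is labeled independently with probability `c`; non-DGs are
#' never labeled. This realizes the PU assumption that the known DGs are a
#' random subset of all DGs.
#'
#' @param truth Truth list from [gen_counts()] (needs `gene_ids`,
#'   `true_dg_ids`).
#' @param c Labeling probability in (0, 1].
#' @param seed Integer seed.
#' @return A data frame (`pu_labels`) with columns `gene_id` and `s`
#'   (1 = labeled positive, 0 = unlabeled), plus the updated truth in
#'   attribute `"truth"`.
#' @export
gen_pu_labels <- function(truth, c, seed = 1L) {
  check_scalar_prob(c, "c")
  with_rng(seed, {
    is_dg <- truth$gene_ids %in% truth$true_dg_ids
    s <- integer(length(truth$gene_ids))
    s[is_dg] <- stats::rbinom(sum(is_dg), 1L, c)
    labels <- data.frame(gene_id = truth$gene_ids, s = s)
    truth$labeled_ids <- labels$gene_id[labels$s == 1L]
    truth$true_c <- c
    structure(labels, truth = truth, class = c("pu_labels", "data.frame"))
  })
}

#' Generate noisy per-source association scores
#'
#' Emulates three text-mining sources. For each source a true DG is reported
#' with probability `sensitivity` and a non-DG with probability `false_rate`.
#' Reported genes get a positive score (article/sentence counts for the
#' DiGSeE-style source, a continuous score for the other two); unreported
#' genes score exactly 0.
#'
#' @param truth Truth list from [gen_counts()].
#' @param noise_cfg List with elements `sensitivity` and `false_rate`, each a
#'   probability (recycled across the three sources if scalar).
#' @param seed Integer seed.
#' @return Data frame with columns `gene_id`, `digsee`, `disgenet`,
#'   `diseases`.
#' @export
gen_association_scores <- function(truth, noise_cfg = list(sensitivity = 0.8,
                                                           false_rate = 0.05),
                                   seed = 1L) {
  sens <- rep_len(noise_cfg$sensitivity, 3L)
  fr <- rep_len(noise_cfg$false_rate, 3L)
  for (v in c(sens, fr)) check_scalar_prob(v, "sensitivity/false_rate", allow_zero = TRUE)
  with_rng(seed, {
    ids <- truth$gene_ids
    is_dg <- ids %in% truth$true_dg_ids
    p_assoc <- function(k) ifelse(is_dg, sens[k], fr[k])
    assoc <- vapply(1:3, function(k) stats::rbinom(length(ids), 1L, p_assoc(k)) == 1L,
                    logical(length(ids)))
    # DiGSeE-style source: article and sentence counts
    n_art <- ifelse(assoc[, 1], 1L + stats::rpois(length(ids), 2), 0L)
    n_sen <- ifelse(assoc[, 1], n_art + stats::rpois(length(ids), 3), 0L)
    digsee <- if (any(assoc[, 1])) digsee_score(n_art, n_sen, max(n_sen)) else n_art * 0
    disgenet <- ifelse(assoc[, 2], round(stats::runif(length(ids), 0.01, 1), 3), 0)
    diseases <- ifelse(assoc[, 3], round(stats::rgamma(length(ids), 2, 1), 3), 0)
    data.frame(gene_id = ids, digsee = digsee, disgenet = disgenet,
               diseases = diseases)
  })
}

#' Generate synthetic reference expression profiles for four cell populations
#'
#' Builds CPM-scale profiles for hair cells (HC) and supporting cells (SC) of
#' cochlea and utricle with planted marker structure: `n_tissue_markers`
#' genes separate the tissues and `n_celltype_markers` genes separate HC from
#' SC, each with a `marker_shift` log2 effect; all remaining genes share a
#' common log-normal baseline plus small profile-specific noise.
#'
#' @param n_genes Number of genes.
#' @param n_tissue_markers,n_celltype_markers Numbers of planted markers.
#' @param marker_shift Log2 effect size of a marker.
#' @param profile_noise_sd SD of non-marker log2 variation between profiles.
#' @param seed Integer seed.
#' @return A genes x 4 CPM matrix with columns `cochlea_HC`, `cochlea_SC`,
#'   `utricle_HC`, `utricle_SC`; planted marker ids in attributes
#'   `"tissue_markers"` and `"celltype_markers"`.
#' @export
gen_reference_profiles <- function(n_genes = 2000, n_tissue_markers = 50,
                                   n_celltype_markers = 50, marker_shift = 4,
                                   profile_noise_sd = 0.1, seed = 1L) {
  if (n_tissue_markers + n_celltype_markers > n_genes)
    stop_config("more markers requested than genes")
  with_rng(seed, {
    ids <- sprintf("gene%05d", seq_len(n_genes))
    base <- stats::rnorm(n_genes, 5, 1.5)
    types <- c("cochlea_HC", "cochlea_SC", "utricle_HC", "utricle_SC")
    logp <- matrix(base, n_genes, 4, dimnames = list(ids, types)) +
      stats::rnorm(n_genes * 4, 0, profile_noise_sd)
    tm <- seq_len(n_tissue_markers)
    cm <- n_tissue_markers + seq_len(n_celltype_markers)
    up_cochlea <- sample(c(TRUE, FALSE), n_tissue_markers, replace = TRUE)
    logp[tm, c("cochlea_HC", "cochlea_SC")] <-
      logp[tm, c("cochlea_HC", "cochlea_SC")] + ifelse(up_cochlea, marker_shift, -marker_shift)
    up_hc <- sample(c(TRUE, FALSE), n_celltype_markers, replace = TRUE)
    logp[cm, c("cochlea_HC", "utricle_HC")] <-
      logp[cm, c("cochlea_HC", "utricle_HC")] + ifelse(up_hc, marker_shift, -marker_shift)
    cpm <- 2^logp
    cpm <- sweep(cpm, 2, colSums(cpm), "/") * 1e6
    attr(cpm, "tissue_markers") <- ids[tm]
    attr(cpm, "celltype_markers") <- ids[cm]
    cpm
  })
}

#' Re-measure reference profiles with independent noise
#'
#' Emulates references and mixtures coming from separate experiments: each
#' entry of the CPM matrix is perturbed by independent log2-normal noise and
#' columns are rescaled back to CPM. Mixtures built from the perturbed copy
#' share only the planted marker structure with the original, so non-marker
#' reference variance is uninformative for deconvolving them — the regime in
#' which signature-size selection is meaningful.
#'
#' @param profiles Genes x cell-types CPM matrix.
#' @param sd SD of the log2 perturbation.
#' @param seed Integer seed.
#' @return A perturbed CPM matrix of the same shape.
#' @export
perturb_profiles <- function(profiles, sd = 0.3, seed = 1L) {
  if (!is.numeric(sd) || sd < 0) stop_domain("'sd' must be >= 0")
  with_rng(seed, {
    cpm <- 2^(log2(profiles + 1) + stats::rnorm(length(profiles), 0, sd)) - 1
    cpm[cpm < 0] <- 0
    sweep(cpm, 2, colSums(cpm), "/") * 1e6
  })
}

#' Generate synthetic mixtures of reference profiles
#'
#' Each sample is the given convex combination of the reference profiles in
#' log space (log2(CPM + 1)) plus i.i.d. Gaussian noise.
#'
#' @param profiles Genes x cell-types CPM matrix (e.g.
#'   [gen_reference_profiles()]).
#' @param proportions Samples x cell-types matrix of mixing weights; each row
#'   must be non-negative and sum to 1 (tolerance 1e-8). Column names must
#'   match `colnames(profiles)`.
#' @param noise_sd SD of the additive Gaussian noise on the log2 scale.
#' @param seed Integer seed.
#' @return Genes x samples matrix of log2-scale expression.
#' @export
gen_mixtures <- function(profiles, proportions, noise_sd = 0, seed = 1L) {
  proportions <- as.matrix(proportions)
  if (is.null(colnames(proportions)) ||
      !identical(colnames(proportions), colnames(profiles)))
    stop_domain("colnames(proportions) must equal colnames(profiles)")
  if (any(proportions < 0) || any(abs(rowSums(proportions) - 1) > 1e-8))
    stop_domain("each proportions row must be non-negative and sum to 1 (tol 1e-8)")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_domain("'noise_sd' must be >= 0")
  with_rng(seed, {
    logp <- log2(profiles + 1)
    m <- logp %*% t(proportions)
    if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
    if (is.null(rownames(proportions)))
      colnames(m) <- sprintf("mix%02d", seq_len(nrow(proportions)))
    else colnames(m) <- rownames(proportions)
    m
  })
}
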