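# Shared small fixtures, built in code.

# 2 x 2 design with equal library sizes of 1e6 and hand-set counts
toy_counts <- function(counts_by_group = list(`E16.5.cochlea` = c(10, 10),
                                              `E16.5.vestibule` = c(10, 10),
                                              `P0.cochlea` = c(40, 40),
                                              `P0.vestibule` = c(10, 10)),
                       n_filler = 1) {
  reps <- length(counts_by_group[[1]])
  meta <- expand.grid(replicate = seq_len(reps),
                      tissue = c("cochlea", "vestibule"),
                      age = c("E16.5", "P0"), stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_%s_r%d", meta$age, meta$tissue, meta$replicate)
  n_genes <- 1 + n_filler
  counts <- matrix(0, n_genes, nrow(meta),
                   dimnames = list(c("gA", sprintf("f%02d", seq_len(n_filler))),
                                   meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    key <- paste(meta$age[j], meta$tissue[j], sep = ".")
    counts["gA", j] <- counts_by_group[[key]][meta$replicate[j]]
  }
  # filler genes absorb the rest of the 1e6 library
  counts[-1, ] <- matrix(rep((1e6 - colSums(counts)) / n_filler, each = n_filler),
                         n_filler, nrow(meta))
  count_matrix(counts, meta[, c("sample_id", "tissue", "age", "replicate")])
}

# small separable PU scenario for classifier tests
small_pu_scenario <- function(n = 400, n_dg = 40, c = 0.5, shift = 3, seed = 11) {
  withr::with_seed(seed, {
    ids <- sprintf("g%03d", seq_len(n))
    is_dg <- seq_len(n) <= n_dg
    feats <- data.frame(
      gene_id = ids,
      avg_log_cpm = rnorm(n, 4, 1),
      logfc_age = rnorm(n, 0, 0.3) + ifelse(is_dg, shift / 2, 0),
      logfc_tissue = rnorm(n, 0, 0.3) + ifelse(is_dg, shift * sample(c(-1, 1), n, TRUE), 0),
      logfc_interaction = rnorm(n, 0, 0.3) + ifelse(is_dg, shift / 2, 0))
    s <- integer(n)
    s[is_dg] <- rbinom(n_dg, 1, c)
    list(features = feats, labels = data.frame(gene_id = ids, s = s),
         truth = as.integer(is_dg))
  })
}

# 1 x 4 proportions matrix putting all weight on column i
diag_props <- function(i, types) {
  m <- matrix(0, 1, length(types), dimnames = list("m1", types))
  m[1, i] <- 1
  m
}

# a random point on the 4-simplex
random_simplex <- function(k = 4) {
  w <- rexp(k)
  w / sum(w)
}

# end-to-end synthetic input files for the pipeline
make_pipeline_fixture <- function(dir, seed = 90) {
  cfg <- sim_config(n_genes = 300, n_true_dg = 50, c_label = 0.7,
                    reps_per_group = 2, seed = seed)
  sim <- gen_counts(cfg)
  labels <- gen_pu_labels(sim$truth, 0.7, seed = seed + 1)
  assoc <- gen_association_scores(sim$truth, seed = seed + 2)
  paths <- list(counts = file.path(dir, "counts.tsv"),
                meta = file.path(dir, "meta.tsv"),
                labels = file.path(dir, "labels.tsv"),
                assoc = file.path(dir, "assoc.tsv"))
  write_counts(sim$counts, paths$counts, paths$meta)
  write_gene_table(data.frame(gene_id = labels$gene_id[labels$s == 1]),
                   paths$labels)
  write_gene_table(assoc, paths$assoc)
  list(paths = paths, sim = sim, labels = labels)
}
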