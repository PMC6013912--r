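# The generators must plant exactly the structure the downstream stages are
# tested against: larger absolute tissue fold changes for true deafness
# genes, PU labels at a known rate, enriched association scores, and exact
# convex mixtures.

test_that("sim_config validates its fields and names the offender", {
  expect_s3_class(sim_config(n_genes = 100, n_true_dg = 10), "sim_config")
  expect_error(sim_config(n_genes = 10, n_true_dg = 10), "n_true_dg",
               class = "deafPU_config_error")
  expect_error(sim_config(n_genes = 100, n_true_dg = 10, c_label = 0),
               "c_label", class = "deafPU_config_error")
  expect_error(sim_config(n_genes = 100, n_true_dg = 10, nb_dispersion = -1),
               "nb_dispersion", class = "deafPU_config_error")
  expect_error(sim_config(n_genes = 100, n_true_dg = 10,
                          effect_shifts = c(tissue_abs = Inf, age = 0, interaction = 0)),
               "effect_shifts", class = "deafPU_config_error")
  expect_error(sim_config(n_genes = 0.5, n_true_dg = 1), "n_genes",
               class = "deafPU_config_error")
})

test_that("without planted effects and near-zero dispersion fold changes vanish", {
  cfg <- sim_config(n_genes = 300, n_true_dg = 10, nb_dispersion = 0,
                    effect_shifts = c(tissue_abs = 0, age = 0, interaction = 0),
                    lib_size = 5e6, seed = 5)
  sim <- gen_counts(cfg)
  f <- gene_features(filter_expressed(sim$counts))
  expect_lt(mean(abs(f$logfc_tissue)), 0.1)
  expect_lt(mean(abs(f$logfc_age)), 0.1)
  expect_lt(mean(abs(f$logfc_interaction)), 0.15)
})

test_that("planted tissue shifts give DGs larger absolute fold changes", {
  cfg <- sim_config(n_genes = 2000, n_true_dg = 100,
                    effect_shifts = c(tissue_abs = 2, age = 1, interaction = 1),
                    seed = 9)
  sim <- gen_counts(cfg)
  f <- gene_features(sim$counts)
  is_dg <- f$gene_id %in% sim$truth$true_dg_ids
  p <- rank_sum_one_sided(abs(f$logfc_tissue[is_dg]), abs(f$logfc_tissue[!is_dg]),
                          "greater")
  expect_lt(p, 0.01)
  # the +1 interaction adds +0.5 to the tissue feature under either sign, so
  # the expected mean |tissue logFC| is (|2 + 0.5| + |-2 + 0.5|)/2 = 2; the
  # interaction itself is attenuated slightly by the compositional
  # (library-renormalization) effect of planting one-sided shifts
  expect_lt(abs(mean(abs(f$logfc_tissue[is_dg])) - 2), 0.3)
  expect_lt(abs(mean(f$logfc_interaction[is_dg]) - 1), 0.25)
})

test_that("gen_counts is deterministic given the seed", {
  cfg <- sim_config(n_genes = 150, n_true_dg = 15, seed = 21)
  a <- gen_counts(cfg); b <- gen_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$true_dg_ids, b$truth$true_dg_ids)
})

test_that("PU labeling hits the configured rate and never labels non-DGs", {
  cfg <- sim_config(n_genes = 200, n_true_dg = 50, seed = 2)
  sim <- gen_counts(cfg)
  all_lab <- gen_pu_labels(sim$truth, 1, seed = 1)
  expect_setequal(all_lab$gene_id[all_lab$s == 1], sim$truth$true_dg_ids)
  expect_error(gen_pu_labels(sim$truth, 0), class = "deafPU_domain_error")
  expect_error(gen_pu_labels(sim$truth, 1.2), class = "deafPU_domain_error")

  counts <- vapply(1:200, function(i) {
    lab <- gen_pu_labels(sim$truth, 0.3, seed = i)
    non_dg <- setdiff(lab$gene_id, sim$truth$true_dg_ids)
    expect_identical(sum(lab$s[lab$gene_id %in% non_dg]), 0L)
    sum(lab$s)
  }, numeric(1))
  se <- sqrt(50 * 0.3 * 0.7 / 200)
  expect_lt(abs(mean(counts) - 15), 3 * se)
})

test_that("association scores separate true DGs from the background", {
  cfg <- sim_config(n_genes = 2000, n_true_dg = 100, seed = 3)
  sim <- gen_counts(cfg)
  perfect <- gen_association_scores(sim$truth, list(sensitivity = 1, false_rate = 0),
                                    seed = 1)
  nz <- perfect$gene_id[perfect$digsee > 0 & perfect$disgenet > 0 & perfect$diseases > 0]
  expect_setequal(nz, sim$truth$true_dg_ids)
  silent <- gen_association_scores(sim$truth, list(sensitivity = 0, false_rate = 0),
                                   seed = 1)
  expect_true(all(silent[, -1] == 0))
  expect_error(gen_association_scores(sim$truth, list(sensitivity = 2, false_rate = 0)),
               class = "deafPU_domain_error")

  noisy <- gen_association_scores(sim$truth, list(sensitivity = 0.8, false_rate = 0.05),
                                  seed = 4)
  any_hit <- as.integer(rowSums(noisy[, -1] > 0) > 0)
  truth <- as.integer(noisy$gene_id %in% sim$truth$true_dg_ids)
  expect_gt(roc_auc(any_hit, truth), 0.8)
})

test_that("mixtures are exact convex combinations in log space", {
  prof <- gen_reference_profiles(n_genes = 300, seed = 6)
  props <- matrix(c(1, 0, 0, 0), 1, dimnames = list("m1", colnames(prof)))
  m <- gen_mixtures(prof, props, noise_sd = 0, seed = 1)
  expect_equal(unname(m[, 1]), unname(log2(prof[, 1] + 1)), tolerance = 1e-12)

  bad <- matrix(c(0.5, 0.2, 0, 0), 1, dimnames = list(NULL, colnames(prof)))
  expect_error(gen_mixtures(prof, bad), class = "deafPU_domain_error")
})
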