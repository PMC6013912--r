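test_that("stratified splits preserve the label proportions exactly", {
  labels <- data.frame(gene_id = sprintf("g%04d", 1:1000),
                       s = rep(c(1L, 0L), c(100, 900)))
  sp <- stratified_split(labels, 0.75, seed = 3)
  s <- setNames(labels$s, labels$gene_id)
  expect_identical(sum(s[sp$train]), 75L)
  expect_identical(length(sp$train), 750L)
  expect_identical(sort(c(sp$train, sp$test)), sort(labels$gene_id))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, stratified_split(labels, 0.75, seed = 3))
  expect_false(identical(sp, stratified_split(labels, 0.75, seed = 4)))

  tiny <- data.frame(gene_id = c("a", "b", "c"), s = c(1L, 0L, 0L))
  expect_error(stratified_split(tiny), class = "deafPU_data_error")
  expect_error(stratified_split(labels, 1), class = "deafPU_domain_error")
})

test_that("bagged trees score separable positives near 1 and stay in [0,1]", {
  sc <- small_pu_scenario(n = 400, n_dg = 60, c = 1, shift = 4, seed = 12)
  sp <- stratified_split(sc$labels, seed = 1)
  pred <- bagged_fit_predict(sc$features, sc$labels, sp, n_learners = 200, seed = 2)
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  s <- setNames(sc$labels$s, sc$labels$gene_id)
  expect_gt(min(pred$prob[s[pred$gene_id] == 1]), 0.9)
  expect_identical(attr(pred, "stage"), "raw")
})

test_that("a single tree on constant features returns the balanced base rate", {
  feats <- data.frame(gene_id = sprintf("g%02d", 1:40), f1 = 1, f2 = 2)
  labels <- data.frame(gene_id = feats$gene_id, s = rep(c(1L, 0L), c(10, 30)))
  sp <- stratified_split(labels, seed = 5)
  pred <- bagged_fit_predict(feats, labels, sp, n_learners = 1, seed = 6)
  expect_true(all(pred$prob == 0.5))
})

test_that("bagging refuses training sets with too few unlabeled genes", {
  feats <- data.frame(gene_id = sprintf("g%02d", 1:12), f1 = rnorm(12))
  labels <- data.frame(gene_id = feats$gene_id, s = rep(c(1L, 0L), c(9, 3)))
  sp <- list(train = feats$gene_id[c(1:8, 10, 11)], test = feats$gene_id[c(9, 12)])
  expect_error(bagged_fit_predict(feats, labels, sp, 5, 1),
               class = "deafPU_data_error")
})

test_that("run_pu aggregates test appearances at about a quarter of the splits", {
  sc <- small_pu_scenario(n = 200, n_dg = 30, c = 0.8, seed = 13)
  res <- run_pu(sc$features, sc$labels, n_splits = 60, n_learners = 20, seed = 14)
  expect_true(all(res$probs$n_test > 0))
  # each gene is in the 25% test side of each split
  se <- sqrt(0.25 * 0.75 / 60)
  expect_lt(abs(mean(res$probs$n_test / 60) - 0.25), 4 * se)
  expect_identical(nrow(res$splits), 60L)
  expect_true(all(res$c_estimates$mean > 0 & res$c_estimates$mean <= 1))
})

test_that("run_pu ranks separable synthetic positives highly, nulls at chance", {
  sc <- small_pu_scenario(n = 300, n_dg = 40, c = 0.6, shift = 3, seed = 15)
  res <- run_pu(sc$features, sc$labels, n_splits = 30, n_learners = 50, seed = 16)
  unl <- sc$labels$s == 0
  expect_gt(roc_auc(res$probs$pu_corrected[unl], sc$truth[unl]), 0.85)

  # with permuted labels the averaged ROC against the hidden truth is chance
  null_aucs <- vapply(1:3, function(k) {
    perm <- sc$labels
    perm$s <- withr::with_seed(16 + k, sample(perm$s))
    null_res <- suppressWarnings(run_pu(sc$features, perm, n_splits = 25,
                                        n_learners = 30, seed = 20 + k))
    roc_auc(null_res$probs$pu_corrected, sc$truth)
  }, numeric(1))
  expect_lt(abs(mean(null_aucs) - 0.5), 0.1)
})

test_that("rank AUC matches the pair-counting oracle and handles edge cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2), c(1, 1, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.9), c(1, 1, 0)), 0)
  expect_error(roc_auc(c(0.5, 0.6), c(1, 1)), class = "deafPU_domain_error")
  withr::with_seed(20, {
    for (i in 1:10) {
      p <- round(runif(30), 1)  # induce ties
      y <- rbinom(30, 1, 0.4)
      if (length(unique(y)) < 2) next
      expect_equal(roc_auc(p, y), oracle_auc(p, y))
    }
  })
})

test_that("DeLong's test matches pROC and a paired bootstrap", {
  withr::with_seed(21, {
    y <- rbinom(500, 1, 0.3)
    good <- y + rnorm(500, 0, 0.7)
    noise <- rnorm(500)
    strong <- delong_test(good, noise, y)
    expect_lt(strong$p.value, 0.01)
    expect_warning(same <- delong_test(good, good, y), "zero variance")
    expect_equal(same$p.value, 1)

    if (requireNamespace("pROC", quietly = TRUE)) {
      for (i in 1:5) {
        yy <- rbinom(80, 1, 0.5)
        a <- yy * 0.5 + rnorm(80); b <- yy * 0.3 + rnorm(80)
        ours <- delong_test(a, b, yy)
        ref <- pROC::roc.test(pROC::roc(yy, a, quiet = TRUE),
                              pROC::roc(yy, b, quiet = TRUE), method = "delong")
        expect_equal(ours$p.value, as.numeric(ref$p.value), tolerance = 1e-8)
      }
    }
  })
  withr::with_seed(22, {
    for (i in 1:3) {
      y <- rbinom(60, 1, 0.5)
      a <- y * 0.8 + rnorm(60); b <- y * 0.2 + rnorm(60)
      ours <- delong_test(a, b, y)$p.value
      boot <- oracle_delong_bootstrap(a, b, y, n_boot = 600, seed = i)
      expect_lt(abs(ours - boot), 0.05)
    }
  })
})
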