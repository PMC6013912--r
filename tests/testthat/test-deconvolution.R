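test_that("signature ranking filters low expression and sorts by log variance", {
  ref <- matrix(c(0.5, 10, 10, 10,       # fails CPM >= 1 in one condition
                  8, 8, 8, 8,            # constant: zero variance
                  1, 100, 1, 100,        # high variance
                  4, 6, 4, 6),           # modest variance
                4, 4, byrow = TRUE,
                dimnames = list(c("low", "flat", "hot", "mild"),
                                c("cochlea_HC", "cochlea_SC",
                                  "utricle_HC", "utricle_SC")))
  ranked <- rank_signature_genes(ref)
  expect_false("low" %in% ranked)
  expect_identical(as.vector(ranked), c("hot", "mild", "flat"))
  v <- apply(log2(ref[as.vector(ranked), ] + 1), 1, var)
  expect_identical(as.vector(ranked), names(sort(-v)))
  expect_error(rank_signature_genes(ref, min_cpm = 1e9), class = "deafPU_data_error")
})

test_that("ranking order matches direct variance computation on a random toy", {
  withr::with_seed(70, {
    ref <- matrix(2^rnorm(40, 5, 2), 10, 4,
                  dimnames = list(sprintf("g%02d", 1:10),
                                  c("cochlea_HC", "cochlea_SC",
                                    "utricle_HC", "utricle_SC")))
    ref[ref < 1] <- 1.5
    ranked <- rank_signature_genes(ref)
    v <- apply(log2(ref + 1), 1, var)
    expect_identical(as.vector(ranked), rownames(ref)[order(-v, rownames(ref))])
  })
})

test_that("noiseless mixtures are recovered exactly", {
  prof <- gen_reference_profiles(n_genes = 500, seed = 71)
  sig <- build_signature(prof, rank_signature_genes(prof)[1:60])

  # a pure column returns the unit vector
  pure <- gen_mixtures(prof, diag_props(1, colnames(prof)), 0, seed = 1)
  est_pure <- estimate_proportions(pure, sig)
  expect_equal(unname(est_pure$proportions[1, 1]), 1, tolerance = 1e-8)

  # a 0.6/0.4 two-type mixture round-trips below 1e-6
  w <- c(0.6, 0.4, 0, 0)
  props <- matrix(w, 1, dimnames = list("m", colnames(prof)))
  mix <- gen_mixtures(prof, props, 0, seed = 2)
  est <- estimate_proportions(mix, sig)
  expect_lt(max(abs(est$proportions[1, ] - w)), 1e-6)
  expect_equal(unname(rowSums(est$proportions)), 1, tolerance = 1e-8)

  # the reference profiles themselves deconvolve to the identity
  self <- estimate_proportions(log2(prof + 1), sig)
  expect_equal(unname(self$proportions), diag(4), tolerance = 1e-6)
})

test_that("noisy mixtures are recovered within 0.05 median absolute error", {
  prof <- gen_reference_profiles(n_genes = 500, seed = 72)
  sig <- build_signature(prof, rank_signature_genes(prof)[1:60])
  errs <- vapply(1:10, function(i) {
    withr::with_seed(200 + i, {
      w <- random_simplex()
      props <- matrix(w, 1, dimnames = list("m", colnames(prof)))
      mix <- gen_mixtures(prof, props, noise_sd = 0.1, seed = 300 + i)
      est <- estimate_proportions(mix, sig)
      median(abs(est$proportions[1, ] - w))
    })
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("the within-tissue scenario restricts to the sample's own cell types", {
  prof <- gen_reference_profiles(n_genes = 400, seed = 73)
  sig <- build_signature(prof, rank_signature_genes(prof)[1:50])
  w <- c(0.7, 0.3, 0, 0)
  mix <- gen_mixtures(prof, matrix(w, 1, dimnames = list("m", colnames(prof))),
                      0, seed = 3)
  est <- estimate_proportions(mix, sig, "within_tissue", sample_tissue = "cochlea")
  expect_equal(unname(est$proportions[1, 3:4]), c(0, 0))
  expect_equal(unname(est$proportions[1, 1:2]), c(0.7, 0.3), tolerance = 1e-6)
  expect_error(estimate_proportions(mix, sig, "within_tissue"),
               class = "deafPU_usage_error")
})

test_that("the contamination objective hits its limits", {
  prof <- gen_reference_profiles(n_genes = 400, seed = 74)
  sig <- build_signature(prof, rank_signature_genes(prof)[1:50])
  own <- rbind(c(0.6, 0.4, 0, 0), c(0, 0, 0.5, 0.5))
  dimnames(own) <- list(c("co", "ve"), colnames(prof))
  est_own <- estimate_proportions(gen_mixtures(prof, own, 0, seed = 4), sig,
                                  sample_tissue = c("cochlea", "vestibule"))
  expect_lt(contamination_objective(est_own), 1)

  swapped <- own[2:1, ]; rownames(swapped) <- c("co", "ve")
  est_swap <- estimate_proportions(gen_mixtures(prof, swapped, 0, seed = 5), sig,
                                   sample_tissue = c("cochlea", "vestibule"))
  expect_gt(contamination_objective(est_swap), 199)

  est_within <- estimate_proportions(gen_mixtures(prof, own, 0, seed = 6), sig,
                                     "within_tissue",
                                     sample_tissue = c("cochlea", "vestibule"))
  expect_error(contamination_objective(est_within), class = "deafPU_usage_error")

  planted <- rbind(c(0.55, 0.35, 0.06, 0.04), c(0.04, 0.06, 0.5, 0.4))
  dimnames(planted) <- list(c("co", "ve"), colnames(prof))
  est_pl <- estimate_proportions(gen_mixtures(prof, planted, 0.02, seed = 7), sig,
                                 sample_tissue = c("cochlea", "vestibule"))
  expect_lt(abs(contamination_objective(est_pl) - 20), 5)
})

test_that("narrow basins are discarded when selecting k", {
  bw <- deafPU:::basin_widths
  # monotone decreasing curve: one basin spanning everything
  mono <- bw(seq(10, 1, length.out = 20))
  expect_identical(nrow(mono), 1L)
  expect_identical(mono$index, 20L)
  expect_identical(mono$width, 20L)
  # a narrow dip next to a broad valley
  v <- c(5, 1, 5, 5, 4.5, 4, 3.5, 3.2, 3.1, 3.3, 3.6, 4, 4.5, 5, 5.5)
  res <- bw(v)
  expect_identical(res$index, c(2L, 9L))
  expect_lt(res$width[1], res$width[2])
})

test_that("hair-cell proportions agree between scenarios without contamination", {
  prof <- gen_reference_profiles(n_genes = 500, seed = 75)
  sig <- build_signature(prof, rank_signature_genes(prof)[1:80])
  props <- rbind(c(0.35, 0.65, 0, 0), c(0.45, 0.55, 0, 0),
                 c(0, 0, 0.25, 0.75), c(0, 0, 0.4, 0.6))
  dimnames(props) <- list(sprintf("s%d", 1:4), colnames(prof))
  tissue <- c("cochlea", "cochlea", "vestibule", "vestibule")
  mix <- gen_mixtures(prof, props, noise_sd = 0.05, seed = 8)
  cross <- estimate_proportions(mix, sig, "cross_contamination", tissue)
  within <- estimate_proportions(mix, sig, "within_tissue", tissue)
  hc_cols <- grepl("_HC$", colnames(prof))
  hc_cross <- rowSums(cross$proportions[, hc_cols])
  hc_within <- rowSums(within$proportions[, hc_cols])
  expect_lt(max(abs(hc_cross - hc_within)), 0.05)
})
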