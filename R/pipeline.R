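# End-to-end orchestration and tabular I/O. All tables are TSV with a
# gene_id first column; the manifest records package version, seed, the full
# configuration and md5 sums of every output, so a config + seed fully
# determines all stochastic stages.

#' Read / write a gene-keyed TSV table
#'
#' Tab-separated text with a header row whose first column is `gene_id`.
#' Duplicate gene ids and ragged rows are rejected with the offending id or
#' line number.
#'
#' @param path File path.
#' @return `read_gene_table()` returns a data frame; `write_gene_table()`
#'   returns its input invisibly.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  nf <- utils::count.fields(path, sep = "\t", quote = "\"")
  if (length(nf) < 2L) stop_data(sprintf("%s: empty table", path))
  bad <- which(nf != nf[1])
  if (length(bad))
    stop_data(sprintf("%s: ragged row at line %d", path, bad[1]))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop_data(sprintf("%s: empty table", path))
  names(df)[1] <- "gene_id"
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop_data(sprintf("%s: duplicate gene id '%s'", path, dup[1]))
  df
}

#' @rdname read_gene_table
#' @param df Data frame whose first column is `gene_id`.
#' @export
write_gene_table <- function(df, path) {
  if (!is.data.frame(df) || nrow(df) == 0L) stop_data("refusing to write an empty table")
  if (names(df)[1] != "gene_id") stop_data("first column must be gene_id")
  if (anyDuplicated(df$gene_id)) stop_data("duplicate gene ids")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Pipeline configuration
#'
#' Collects the file paths and stage parameters for [run_pipeline()].
#' Numbers of splits and learners default to fast-mode values suitable for
#' the bundled synthetic scale; raise them for production runs.
#'
#' @param counts,meta,labels,assoc Input TSV paths: the count matrix and
#'   sample metadata (see [read_counts()]), the labeled-gene list (TSV with
#'   a `gene_id` column), and the association-score table (`gene_id`,
#'   `digsee`, `disgenet`, `diseases`, or `digsee_articles` +
#'   `digsee_sentences` in place of `digsee`).
#' @param out_dir Output directory (created if missing).
#' @param n_splits,n_learners PU classifier size parameters.
#' @param rerun_n_splits,rerun_n_learners Rerun classifier size parameters
#'   (default to the PU values).
#' @param prior Prior count for [log_cpm()].
#' @param min_cpm,min_samples Expressed-gene filter thresholds.
#' @param c_method Estimator used for the PU correction inside [run_pu()].
#' @param n_bins Calibration-curve bins.
#' @param grid Optional fixed threshold grid for the Wilcoxon scan.
#' @param seed Integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts, meta, labels, assoc, out_dir,
                            n_splits = 150, n_learners = 200,
                            rerun_n_splits = n_splits,
                            rerun_n_learners = n_learners,
                            prior = 0.5, min_cpm = 1, min_samples = 3,
                            c_method = "e3", n_bins = 11, grid = NULL,
                            seed = 1L) {
  structure(list(counts = counts, meta = meta, labels = labels, assoc = assoc,
                 out_dir = out_dir, n_splits = n_splits, n_learners = n_learners,
                 rerun_n_splits = rerun_n_splits,
                 rerun_n_learners = rerun_n_learners, prior = prior,
                 min_cpm = min_cpm, min_samples = min_samples,
                 c_method = c_method, n_bins = n_bins, grid = grid,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, deafPU_error = function(e) {
    e$message <- sprintf("[stage %s] %s", stage, conditionMessage(e))
    stop(e)
  })
}

#' Run the full prioritization pipeline
#'
#' Sequences: expressed-gene filtering and feature computation; the PU
#' bagging classifier with undersampling and PU corrections; calibration
#' comparison of the three c estimators by Brier score under the
#' assumption that deafness-associated genes (any positive association
#' score) are true positives; the rerun classifier seeded with the
#' best-calibrated probabilities; and threshold selection (Youden and the
#' Wilcoxon scan, both ignoring known labeled genes). All intermediates are
#' written to `out_dir` together with a manifest.
#'
#' @param config A [pipeline_config].
#' @return (Invisibly) a result bundle: `features`, `pu`, `calibration`,
#'   `p_init_method`, `rerun`, `thresholds`, `roc`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop_config("'config' must be a pipeline_config")
  for (f in c(config$counts, config$meta, config$labels, config$assoc))
    if (!file.exists(f)) stop_config(sprintf("input file not found: %s", f))

  cm <- run_stage("read", read_counts(config$counts, config$meta))
  lab_tab <- run_stage("read", read_gene_table(config$labels))
  assoc <- run_stage("read", read_gene_table(config$assoc))
  if (all(c("digsee_articles", "digsee_sentences") %in% names(assoc))) {
    assoc$digsee <- digsee_score(assoc$digsee_articles, assoc$digsee_sentences,
                                 max(assoc$digsee_sentences))
    assoc <- assoc[, setdiff(names(assoc), c("digsee_articles", "digsee_sentences"))]
  }

  cm <- run_stage("filter", filter_expressed(cm, config$min_cpm, config$min_samples))
  feats <- run_stage("features", gene_features(cm, config$prior))
  labels <- data.frame(gene_id = feats$gene_id,
                       s = as.integer(feats$gene_id %in% lab_tab$gene_id))

  pu <- run_stage("pu_bagging",
                  run_pu(feats, labels, n_splits = config$n_splits,
                         n_learners = config$n_learners,
                         c_method = config$c_method, seed = config$seed))

  # association truth: any positive score in any source, or a known label
  a <- assoc[match(feats$gene_id, assoc$gene_id), , drop = FALSE]
  src <- setdiff(names(a), "gene_id")
  score_mat <- as.matrix(a[, src, drop = FALSE])
  score_mat[is.na(score_mat)] <- 0
  associated <- as.integer(rowSums(score_mat > 0) > 0 | labels$s == 1L)

  calib <- run_stage("calibration", {
    base <- pu$probs$undersampling_corrected
    ok <- !is.na(base)
    briers <- c(no_fix = brier_score(base[ok], associated[ok]))
    for (m in c("e1", "e2", "e3")) {
      cm_hat <- pu$c_estimates$mean[pu$c_estimates$method == m]
      pc <- as.numeric(correct_pu(base[ok], min(cm_hat, 1)))
      briers[m] <- brier_score(pc, associated[ok])
    }
    best <- names(briers[-1])[which.min(briers[-1])]
    cc <- calibration_curve(base[ok], associated[ok], config$n_bins)
    list(briers = briers, best_method = best, curve = cc)
  })

  c_best <- pu$c_estimates$mean[pu$c_estimates$method == calib$best_method]
  p_init <- as.numeric(correct_pu(
    ifelse(is.na(pu$probs$undersampling_corrected), 0,
           pu$probs$undersampling_corrected), min(c_best, 1)))

  rr <- run_stage("rerun",
                  run_rerun(feats, p_init, labels$s == 1L,
                            n_splits = config$rerun_n_splits,
                            n_learners = config$rerun_n_learners,
                            seed = config$seed + 1L))

  unl <- labels$s == 0L & !is.na(rr$probs$prob)
  roc <- run_stage("evaluate", {
    list(pu_vs_associated = roc_auc(pu$probs$undersampling_corrected[unl],
                                    associated[unl]),
         rerun_vs_associated = roc_auc(rr$probs$prob[unl], associated[unl]),
         delong_p = delong_test(pu$probs$undersampling_corrected[unl],
                                rr$probs$prob[unl], associated[unl])$p.value)
  })

  thresholds <- run_stage("threshold", {
    pr <- stats::setNames(rr$probs$prob[unl], rr$probs$gene_id[unl])
    sc_df <- data.frame(gene_id = feats$gene_id, score_mat)[unl, , drop = FALSE]
    youden <- choose_threshold_roc(pr, associated[unl])
    scan <- wilcoxon_threshold_scan(pr, sc_df, grid = config$grid)
    list(roc_threshold = youden, wilcoxon = scan)
  })

  run_stage("write", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_gene_table(feats, out("features.tsv"))
    write_gene_table(pu$probs, out("pu_probabilities.tsv"))
    write_gene_table(rr$probs, out("rerun_probabilities.tsv"))
    utils::write.table(thresholds$wilcoxon$table, out("threshold_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report <- list(
      c_estimates = pu$c_estimates, briers = as.list(calib$briers),
      best_method = calib$best_method, roc = roc,
      roc_threshold = thresholds$roc_threshold,
      wilcoxon_threshold = thresholds$wilcoxon$chosen)
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    cfg <- unclass(config)
    manifest <- list(package = "deafPU",
                     version = as.character(utils::packageVersion("deafPU")),
                     seed = config$seed, config = cfg,
                     outputs = as.list(tools::md5sum(
                       vapply(c("features.tsv", "pu_probabilities.tsv",
                                "rerun_probabilities.tsv", "threshold_scan.tsv",
                                "report.json"), out, character(1)))))
    names(manifest$outputs) <- basename(names(manifest$outputs))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })

  invisible(list(features = feats, pu = pu, calibration = calib,
                 p_init_method = calib$best_method, rerun = rr,
                 thresholds = thresholds, roc = roc,
                 out_dir = config$out_dir))
}
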