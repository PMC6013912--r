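#' Gene-by-sample count matrix with sample metadata
#'
#' Bundles an integer count matrix (genes in rows, samples in columns) with a
#' sample-metadata table describing the 2 x 2 inner-ear design: tissue
#' (`cochlea` / `vestibule`) by developmental age (`E16.5` / `P0`).
#'
#' @param counts Numeric matrix of non-negative counts with unique rownames
#'   (gene ids) and colnames (sample ids).
#' @param sample_meta Data frame with columns `sample_id`, `tissue`, `age`,
#'   `replicate`; `sample_id` must match `colnames(counts)`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `sample_meta`.
#' @examples
#' cm <- count_matrix(
#'   matrix(1:8, 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4))),
#'   data.frame(sample_id = paste0("s", 1:4),
#'              tissue = rep(c("cochlea", "vestibule"), 2),
#'              age = rep(c("E16.5", "P0"), each = 2),
#'              replicate = 1L))
#' @export
count_matrix <- function(counts, sample_meta) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_data("'counts' must be a numeric matrix")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_data("'counts' must be finite and non-negative")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop_data("'counts' must have unique rownames (gene ids)")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop_data("'counts' must have unique colnames (sample ids)")
  need <- c("sample_id", "tissue", "age", "replicate")
  if (!is.data.frame(sample_meta) || !all(need %in% names(sample_meta)))
    stop_data("'sample_meta' must contain columns sample_id, tissue, age, replicate")
  if (!identical(sort(as.character(sample_meta$sample_id)), sort(colnames(counts))))
    stop_data("sample_meta$sample_id must match colnames(counts)")
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  bad_t <- setdiff(unique(sample_meta$tissue), c("cochlea", "vestibule"))
  if (length(bad_t)) stop_data(sprintf("unknown tissue level(s): %s", paste(bad_t, collapse = ", ")))
  bad_a <- setdiff(unique(sample_meta$age), c("E16.5", "P0"))
  if (length(bad_a)) stop_data(sprintf("unknown age level(s): %s", paste(bad_a, collapse = ", ")))
  structure(list(counts = counts, sample_meta = sample_meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  grp <- table(x$sample_meta$tissue, x$sample_meta$age)
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  print(grp)
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

as_count_matrix <- function(x) {
  if (inherits(x, "count_matrix")) return(x)
  stop_data("expected a 'count_matrix' object (see count_matrix())")
}

#' Read / write a count matrix as tab-separated text
#'
#' The counts file is a TSV with gene ids in the first column (`gene_id`) and
#' one column per sample; the metadata file is a TSV with columns
#' `sample_id`, `tissue`, `age`, `replicate`.
#'
#' @param counts_file,meta_file Paths to the two TSV files.
#' @return `read_counts()` returns a [count_matrix]; `write_counts()` returns
#'   the input invisibly.
#' @export
read_counts <- function(counts_file, meta_file) {
  for (f in c(counts_file, meta_file))
    if (!file.exists(f)) stop_config(sprintf("file not found: %s", f))
  tab <- read_gene_table(counts_file)
  meta <- utils::read.delim(meta_file, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  count_matrix(m, meta)
}

#' @rdname read_counts
#' @param x A [count_matrix].
#' @export
write_counts <- function(x, counts_file, meta_file) {
  x <- as_count_matrix(x)
  df <- data.frame(gene_id = rownames(x$counts), x$counts, check.names = FALSE)
  write_gene_table(df, counts_file)
  utils::write.table(x$sample_meta, meta_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
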