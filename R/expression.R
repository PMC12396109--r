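#' Expression matrix with a sample-to-condition design
#'
#' Container for a gene x sample table of UMI (or read) counts plus the
#' condition label of each sample. Counts must be non-negative integers;
#' gene ids must be unique; every sample must have exactly one condition.
#'
#' @param counts gene x sample numeric matrix with row and column names.
#' @param design data frame with columns `sample` and `condition`,
#'   covering every column of `counts` exactly once.
#' @return an object of class `expression_matrix` with fields `counts`,
#'   `gene_ids`, `sample_ids`, `design`.
#' @export
expression_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in counts")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(design)))
    stop("design needs columns 'sample' and 'condition'")
  if (anyDuplicated(design$sample)) stop("duplicate samples in design")
  missing <- setdiff(colnames(counts), design$sample)
  if (length(missing))
    stop("samples missing from design: ", paste(missing, collapse = ", "))
  design <- design[match(colnames(counts), design$sample), c("sample", "condition")]
  rownames(design) <- NULL
  structure(list(counts = counts, gene_ids = rownames(counts),
                 sample_ids = colnames(counts), design = design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples; conditions: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sort(unique(x$design$condition)), collapse = ", ")))
  invisible(x)
}

#' Read a count table and design table from TSV
#'
#' The count TSV has the gene id in its first column and one column per
#' sample; the design TSV has columns `sample` and `condition`.
#'
#' @param counts_path,design_path paths to the two tab-separated files.
#' @return an [expression_matrix].
#' @export
read_expression <- function(counts_path, design_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(counts) <- tab[[1L]]
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  expression_matrix(counts, design)
}

#' Counts per million
#'
#' `cpm[g, s] = counts[g, s] / library_size[s] * 1e6`, where the library
#' size is the raw column sum.
#'
#' @param counts gene x sample count matrix.
#' @return matrix of the same shape in counts-per-million.
#' @export
compute_cpm <- function(counts) {
  counts <- as.matrix(counts)
  libs <- colSums(counts)
  if (any(libs == 0)) {
    bad <- colnames(counts)[libs == 0]
    if (is.null(bad)) bad <- which(libs == 0)
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "))
  }
  sweep(counts, 2L, libs, "/") * 1e6
}

#' Expression-filter parameters
#'
#' Defaults mirror the widely used `filterByExpr`-style rule: a gene is
#' kept when it reaches roughly `min_count` raw counts (expressed as a
#' CPM cutoff against the median library size) in a sufficient proportion
#' of the condition's samples, and its total count over those samples is
#' at least `min_total_count`.
#'
#' @param min_count minimum per-sample count (via CPM cutoff), default 10.
#' @param min_total_count minimum total count over the condition, default 15.
#' @param min_prop proportion of the condition's samples that must pass
#'   the CPM cutoff, default 0.7.
#' @param method `"filter_by_expr"` (default), `"raw_count"` (count >=
#'   `min_count` in >= `ceil(min_prop * n)` samples), or `"cpm"` (CPM >=
#'   `min_count` treated directly as a CPM cutoff, same sample rule).
#' @return a list of class `filter_params`.
#' @export
filter_params <- function(min_count = 10, min_total_count = 15, min_prop = 0.7,
                          method = c("filter_by_expr", "raw_count", "cpm")) {
  method <- match.arg(method)
  stopifnot(min_count >= 0, min_total_count >= 0,
            min_prop > 0, min_prop <= 1)
  structure(list(min_count = min_count, min_total_count = min_total_count,
                 min_prop = min_prop, method = method),
            class = "filter_params")
}

#' Expressed genes of one condition
#'
#' Applies the expression-threshold filter to the samples of one
#' condition and returns the sorted list of expressed gene ids — the
#' gene evidence that drives carving.
#'
#' With the default method a gene is kept iff (i) its CPM reaches
#' `cutoff = min_count / median(library sizes) * 1e6` in at least
#' `ceil(min_prop * n_samples)` of the condition's samples, and (ii) its
#' total count over the condition's samples is at least
#' `min_total_count`.
#'
#' @param expr an [expression_matrix].
#' @param condition condition label to filter within.
#' @param params a [filter_params].
#' @return sorted character vector of expressed gene ids.
#' @export
filter_expressed <- function(expr, condition, params = filter_params()) {
  stopifnot(inherits(expr, "expression_matrix"))
  labs <- unique(expr$design$condition)
  if (!condition %in% labs)
    stop("unknown condition '", condition, "'; available: ",
         paste(sort(labs), collapse = ", "))
  samples <- expr$design$sample[expr$design$condition == condition]
  cnt <- expr$counts[, samples, drop = FALSE]
  n <- length(samples)
  n_kept <- ceiling(params$min_prop * n)
  keep <- switch(
    params$method,
    filter_by_expr = {
      libs <- colSums(cnt)
      cutoff <- params$min_count / stats::median(libs) * 1e6
      cpm <- compute_cpm(cnt)
      rowSums(cpm >= cutoff) >= n_kept & rowSums(cnt) >= params$min_total_count
    },
    raw_count = rowSums(cnt >= params$min_count) >= n_kept,
    cpm = rowSums(compute_cpm(cnt) >= params$min_count) >= n_kept)
  # a gene with no counts at all is never "expressed"
  keep <- keep & rowSums(cnt) > 0
  sort(unique(rownames(cnt)[keep]))
}
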