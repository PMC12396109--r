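#' Pairwise flux correlation matrix
#'
#' Pearson (or Spearman) correlation of the sampled flux columns of each
#' reaction against every other. Zero-variance (constant-flux) columns
#' get correlation 0 against everything, including themselves, so the
#' cumulative score of a constant reaction is exactly 0; the diagonal is
#' 1 for every non-constant column.
#'
#' @param samples a `flux_samples` object (or samples x reactions matrix)
#'   with at least 3 samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return symmetric reactions x reactions correlation matrix.
#' @export
correlation_matrix <- function(samples, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  vals <- if (inherits(samples, "flux_samples")) samples$values else as.matrix(samples)
  if (nrow(vals) < 3)
    stop("correlation matrix needs at least 3 samples, got ", nrow(vals))
  sds <- apply(vals, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(vals, method = method))
  cc[sds == 0, ] <- 0
  cc[, sds == 0] <- 0
  cc[is.na(cc)] <- 0
  cc
}

#' Reaction Cumulative Correlation (RCC) scores
#'
#' The RCC of reaction i is the sum over all reactions j (including
#' j = i) of |corr(i, j)|. It ranges from 0 (a constant-flux reaction,
#' under the zero-variance convention of [correlation_matrix()]) to the
#' total number of reactions (a reaction perfectly correlated with every
#' other). A high RCC marks a reaction whose flux variation propagates
#' through the whole network — a centrality-like essentiality measure.
#'
#' @param corr symmetric correlation matrix from [correlation_matrix()].
#' @return named numeric vector of RCC scores.
#' @export
rcc_scores <- function(corr) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || max(abs(corr - t(corr))) > 1e-8)
    stop("corr must be a symmetric square matrix")
  rowSums(abs(corr))
}

#' Per-reaction mean flux and standard deviation
#'
#' The sampled mean flux (mol kgDW^-1 h^-1) reflects a reaction's usage
#' — how much metabolic material passes through it — complementing RCC,
#' which reflects its importance for maintaining the phenotype.
#'
#' @param samples a `flux_samples` object (or samples x reactions matrix).
#' @return data frame with columns `reaction`, `mean_flux`, `flux_sd`.
#' @export
mean_fluxes <- function(samples) {
  vals <- if (inherits(samples, "flux_samples")) samples$values else as.matrix(samples)
  if (nrow(vals) < 1) stop("no samples")
  data.frame(reaction = colnames(vals),
             mean_flux = colMeans(vals),
             flux_sd = apply(vals, 2L, stats::sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Score every reaction of one carved model
#'
#' Combines [rcc_scores()] and [mean_fluxes()] into the per-condition
#' reaction score table.
#'
#' @param samples a `flux_samples` object.
#' @param method correlation type, see [correlation_matrix()].
#' @return data frame of class `reaction_scores` with columns `reaction`,
#'   `rcc`, `mean_flux`, `flux_sd`, `n_samples`.
#' @export
reaction_scores <- function(samples, method = "pearson") {
  rcc <- rcc_scores(correlation_matrix(samples, method))
  mf <- mean_fluxes(samples)
  out <- data.frame(reaction = mf$reaction, rcc = as.numeric(rcc[mf$reaction]),
                    mean_flux = mf$mean_flux, flux_sd = mf$flux_sd,
                    n_samples = nrow(samples$values),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("reaction_scores", "data.frame")
  out
}

#' RCC histogram data
#'
#' Bin edges and counts of the RCC distribution, ready for plotting or
#' for comparing two models' RCC profiles.
#'
#' @param scores a `reaction_scores` table.
#' @param n_bins number of equal-width bins over `[0, max(rcc)]`.
#' @return data frame with columns `bin_lower`, `bin_upper`, `count`.
#' @export
rcc_histogram <- function(scores, n_bins = 20L) {
  edges <- seq(0, max(scores$rcc, 1e-12), length.out = n_bins + 1L)
  cut_idx <- pmin(findInterval(scores$rcc, edges, rightmost.closed = TRUE),
                  n_bins)
  data.frame(bin_lower = edges[-length(edges)], bin_upper = edges[-1L],
             count = tabulate(cut_idx, nbins = n_bins))
}

#' Differential reaction table between two conditions
#'
#' For every reaction in the union of two carved models' reaction sets:
#' the difference of sampled mean fluxes (`A - B`; a reaction absent
#' from one model contributes flux 0 on that side), the difference of
#' RCC scores (absent side 0), and a two-sided Welch unequal-variance
#' p-value computed on strided (decorrelated) subsamples of the two flux
#' chains. Degenerate cases follow fixed conventions: two constant
#' columns give p = 1 when their means agree and p = 0 otherwise; one
#' constant column is compared by a one-sample t test against its value.
#'
#' @param a,b lists `list(scores = reaction_scores, samples = flux_samples)`
#'   for the two conditions (as produced per condition by the pipeline).
#' @param test_stride keep every `test_stride`-th sample for testing;
#'   `NULL` (default) picks the smallest stride leaving at most
#'   `max_test_n` values per side.
#' @param max_test_n cap on per-side test sample size (default 1000).
#' @return data frame of class `differential_reactions` with columns
#'   `reaction`, `delta_mean_flux`, `p_value`, `delta_rcc`, `in_model_a`,
#'   `in_model_b`; attribute `"test_stride"` records the stride used.
#' @export
differential_reactions <- function(a, b, test_stride = NULL, max_test_n = 1000L) {
  ra <- a$scores$reaction; rb <- b$scores$reaction
  if (!length(intersect(ra, rb)))
    stop("the two models share no reactions; are they carved from the same universal model?")
  union_rx <- sort(union(ra, rb))
  stride_for <- function(n) if (!is.null(test_stride)) test_stride else
    max(1L, ceiling(n / max_test_n))
  sa <- stride_for(nrow(a$samples$values))
  sb <- stride_for(nrow(b$samples$values))
  col_or_zero <- function(side, rxn, stride) {
    v <- side$samples$values
    if (rxn %in% colnames(v)) v[seq.int(1L, nrow(v), by = stride), rxn]
    else numeric(0)
  }
  welch_p <- function(x, y) {
    # absent reaction = identically-zero flux on that side
    if (!length(x)) x <- rep(0, length(y))
    if (!length(y)) y <- rep(0, length(x))
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx == 0 && vy == 0) return(if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0)
    if (vx == 0) return(stats::t.test(y, mu = mean(x))$p.value)
    if (vy == 0) return(stats::t.test(x, mu = mean(y))$p.value)
    stats::t.test(x, y, var.equal = FALSE)$p.value
  }
  ia <- match(union_rx, ra); ib <- match(union_rx, rb)
  out <- data.frame(
    reaction = union_rx,
    delta_mean_flux = ifelse(is.na(ia), 0, a$scores$mean_flux[ia]) -
      ifelse(is.na(ib), 0, b$scores$mean_flux[ib]),
    p_value = vapply(union_rx, function(rxn)
      welch_p(col_or_zero(a, rxn, sa), col_or_zero(b, rxn, sb)), numeric(1L)),
    delta_rcc = ifelse(is.na(ia), 0, a$scores$rcc[ia]) -
      ifelse(is.na(ib), 0, b$scores$rcc[ib]),
    in_model_a = !is.na(ia), in_model_b = !is.na(ib),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("differential_reactions", "data.frame")
  attr(out, "test_stride") <- c(a = sa, b = sb)
  out
}
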