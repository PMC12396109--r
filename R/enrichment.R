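#' Read a GMT gene-set collection
#'
#' GMT is tab-separated: set name, description, then member gene ids.
#'
#' @param path GMT file.
#' @return named list of character vectors, with a `"descriptions"`
#'   attribute. Set names must be unique; empty sets are rejected.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1L)) < 3L
  if (any(bad))
    stop("GMT line(s) without members: ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  nm <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set names in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, character(1L), 2L), nm)
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene-id vectors.
#' @param descriptions optional named descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis (hypergeometric test)
#'
#' For each gene set, the upper-tail hypergeometric probability of
#' observing at least the seen overlap between the selected genes and
#' the set, drawing `|selected|` genes from the universe. Sets are
#' intersected with the universe before testing; p-values are
#' Benjamini-Hochberg adjusted across all tested sets.
#'
#' @param selected character vector of selected gene ids (must be a
#'   subset of `universe`).
#' @param universe character vector of background gene ids (typically
#'   the carved model's gene set).
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @return data frame sorted by `p_value` with columns `set`, `overlap`,
#'   `set_size`, `universe_size`, `selected_size`, `p_value`,
#'   `bh_adjusted_p`, `overlap_genes`.
#' @export
ora <- function(selected, universe, collection) {
  selected <- unique(selected); universe <- unique(universe)
  extra <- setdiff(selected, universe)
  if (length(extra))
    stop("selected genes outside the universe: ",
         paste(utils::head(extra, 10L), collapse = ", "))
  N <- length(universe); n <- length(selected)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    K <- length(set)
    ov <- intersect(set, selected)
    k <- length(ov)
    p <- if (K == 0) 1 else stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, universe_size = N,
               selected_size = n, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set),
             c("set", "overlap", "set_size", "universe_size", "selected_size",
               "p_value", "bh_adjusted_p", "overlap_genes")]
  rownames(out) <- NULL
  out
}

# weighted Kolmogorov-Smirnov running-sum enrichment score (weight
# exponent 1); ranked = scores sorted decreasingly, hits = logical
gsea_es <- function(scores_sorted, hits) {
  nh <- sum(hits)
  n <- length(hits)
  w <- abs(scores_sorted[hits])
  denom_hit <- sum(w)
  inc <- numeric(n)
  if (denom_hit > 0) inc[hits] <- w / denom_hit
  else inc[hits] <- 1 / nh          # all-zero scores: unweighted steps
  inc[!hits] <- -1 / (n - nh)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Genes are ranked by a per-gene score (here: the differential
#' metabolic score), decreasing, ties broken by gene id. Each set's
#' enrichment score (ES) is the extremum of the weighted running sum
#' (weight exponent 1); significance comes from `n_perm` random
#' gene-label permutations: NES = ES divided by the mean |null ES| of
#' matching sign, and the permutation p-value counts same-sign null ES
#' at least as extreme, with a +1 pseudocount.
#'
#' @param ranked named numeric vector: gene -> score.
#' @param collection named list of gene sets.
#' @param n_perm number of permutations (>= 100, default 1000).
#' @param seed RNG seed for the permutations.
#' @return data frame sorted by `p_value` with columns `set`, `size`,
#'   `es`, `nes`, `p_value`; sets with fewer than 2 members in the
#'   ranked list are skipped with a warning.
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 1000L, seed = 1) {
  stopifnot(n_perm >= 100L)
  genes <- names(ranked)
  ord <- order(-ranked, genes)
  scores_sorted <- as.numeric(ranked[ord])
  genes_sorted <- genes[ord]
  set.seed(seed)
  rows <- list()
  for (nm in names(collection)) {
    members <- intersect(collection[[nm]], genes)
    if (length(members) < 2L) {
      warning("gene set '", nm, "' has < 2 members in the ranked list; skipped")
      next
    }
    hits <- genes_sorted %in% members
    es <- gsea_es(scores_sorted, hits)
    null_es <- vapply(seq_len(n_perm), function(i) {
      ph <- logical(length(hits))
      ph[sample.int(length(hits), sum(hits))] <- TRUE
      gsea_es(scores_sorted, ph)
    }, numeric(1L))
    same <- null_es[sign(null_es) == sign(es) | es == 0]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    rows[[nm]] <- data.frame(set = nm, size = sum(hits), es = es, nes = nes,
                             p_value = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(set = character(), size = integer(),
                                      es = numeric(), nes = numeric(),
                                      p_value = numeric()))
  out <- out[order(out$p_value, out$set), ]
  rownames(out) <- NULL
  out
}
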