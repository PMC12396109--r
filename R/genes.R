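#' Gene-to-reaction membership map
#'
#' Maps every gene of the model to the set of reactions whose GPR rule
#' mentions it (isozyme vs complex semantics do not matter for
#' membership: any gene appearing anywhere in the rule is involved).
#'
#' @param model a [metabolic_model].
#' @param universe optional gene ids to include even when absent from
#'   this (e.g. carved) model; they map to empty sets.
#' @return named list: gene id -> character vector of reaction ids.
#' @export
gene_reaction_map <- function(model, universe = NULL) {
  rx <- model$reactions
  mapping <- list()
  for (i in seq_len(nrow(rx))) {
    if (!nzchar(rx$gpr[i])) next
    expr <- tryCatch(parse_gpr(rx$gpr[i]), error = function(e)
      stop("unparseable GPR for reaction '", rx$id[i], "': ",
           conditionMessage(e), call. = FALSE))
    for (g in gpr_genes(expr)) mapping[[g]] <- c(mapping[[g]], rx$id[i])
  }
  for (g in setdiff(universe, names(mapping))) mapping[[g]] <- character()
  mapping[order(names(mapping))]
}

#' Project reaction scores onto genes
#'
#' Propagates reaction-level RCC and flux usage to genes through GPR
#' membership. The default aggregation over a gene's reactions is the
#' value of largest magnitude (keeping its sign) — a gene is as
#' metabolically important as its most important reaction; `mean` and
#' `sum` are available. For differential tables the projected columns
#' are `delta_rcc` and `delta_usage_gene` (from `delta_mean_flux`), and
#' the reaction attaining the maximal |flux difference| is carried along
#' as `best_reaction` together with its p-value.
#'
#' @param scores a `reaction_scores` or `differential_reactions` table.
#' @param mapping gene -> reactions list from [gene_reaction_map()].
#' @param aggregation `"max"` (default, max-|value| with sign), `"mean"`
#'   or `"sum"`.
#' @return data frame of class `gene_scores`: one row per gene with a
#'   non-empty reaction set. Plain tables give `rcc_gene`, `usage_gene`;
#'   differential tables give `rcc_gene` (from `delta_rcc`),
#'   `delta_usage_gene`, `best_reaction`, `p_value`. Both carry
#'   `n_reactions` and `reaction_ids` (comma-separated).
#' @export
project_scores <- function(scores, mapping,
                           aggregation = c("max", "mean", "sum")) {
  aggregation <- match.arg(aggregation)
  if (!length(mapping)) stop("empty gene-to-reaction mapping")
  differential <- inherits(scores, "differential_reactions") ||
    "delta_mean_flux" %in% names(scores)
  agg <- function(v) switch(aggregation,
                            max = v[which.max(abs(v))],
                            mean = mean(v),
                            sum = sum(v))
  rows <- lapply(names(mapping), function(g) {
    rxns <- intersect(mapping[[g]], scores$reaction)
    if (!length(rxns)) return(NULL)
    idx <- match(rxns, scores$reaction)
    if (differential) {
      best <- idx[which.max(abs(scores$delta_mean_flux[idx]))]
      data.frame(gene = g,
                 rcc_gene = agg(scores$delta_rcc[idx]),
                 delta_usage_gene = agg(scores$delta_mean_flux[idx]),
                 best_reaction = scores$reaction[best],
                 p_value = scores$p_value[best],
                 n_reactions = length(rxns),
                 reaction_ids = paste(rxns, collapse = ","),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = g,
                 rcc_gene = agg(scores$rcc[idx]),
                 usage_gene = agg(scores$mean_flux[idx]),
                 n_reactions = length(rxns),
                 reaction_ids = paste(rxns, collapse = ","),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene maps to any scored reaction")
  rownames(out) <- NULL
  class(out) <- c("gene_scores", "data.frame")
  out
}

#' Gene x reaction long table
#'
#' The unaggregated projection: one row per (gene, reaction) pair, so no
#' information is lost to the aggregation choice of [project_scores()].
#'
#' @inheritParams project_scores
#' @return data frame with one row per gene-reaction membership joined
#'   to all score columns.
#' @export
gene_reaction_long <- function(scores, mapping) {
  rows <- lapply(names(mapping), function(g) {
    rxns <- intersect(mapping[[g]], scores$reaction)
    if (!length(rxns)) return(NULL)
    cbind(gene = g, scores[match(rxns, scores$reaction), , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select condition-signature genes
#'
#' Keeps genes whose projected flux difference is large and significant:
#' direction `a_over_b` keeps `delta_usage_gene > delta_threshold` and
#' `p_value < p_threshold`; `b_over_a` keeps
#' `delta_usage_gene < -delta_threshold` with the same p rule. The
#' defaults (0.5 flux units, p < 0.05) are the conventional selection
#' thresholds for this analysis.
#'
#' @param diff a differential `gene_scores` table.
#' @param delta_threshold minimal |projected flux difference| (default 0.5).
#' @param p_threshold significance threshold (default 0.05).
#' @param direction `"a_over_b"` or `"b_over_a"`.
#' @return sorted character vector of selected gene ids.
#' @export
select_signature_genes <- function(diff, delta_threshold = 0.5,
                                   p_threshold = 0.05,
                                   direction = c("a_over_b", "b_over_a")) {
  direction <- match.arg(direction)
  if (!"delta_usage_gene" %in% names(diff))
    stop("select_signature_genes needs a differential gene table")
  keep <- if (direction == "a_over_b")
    diff$delta_usage_gene > delta_threshold
  else
    diff$delta_usage_gene < -delta_threshold
  keep <- keep & diff$p_value < p_threshold
  sort(diff$gene[keep])
}
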