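#' MA-plot-like table: expression vs differential metabolic usage
#'
#' One row per gene present in at least one carved model: its mean
#' expression — `log2(CPM + 1)` averaged over all samples of the two
#' compared conditions — against the projected flux-usage difference of
#' its reactions, plus a highlight flag (e.g. a pathway of interest).
#'
#' @param expr an [expression_matrix].
#' @param gene_scores differential `gene_scores` table (with
#'   `delta_usage_gene`).
#' @param conditions character vector of the two compared condition
#'   labels.
#' @param highlight gene ids to flag (default none).
#' @return data frame with columns `gene`, `mean_expression`,
#'   `delta_usage_gene`, `pathway_flag`.
#' @export
build_ma_table <- function(expr, gene_scores, conditions, highlight = character()) {
  stopifnot(length(conditions) == 2L)
  missing_cond <- setdiff(conditions, expr$design$condition)
  if (length(missing_cond))
    stop("condition(s) not in design: ", paste(missing_cond, collapse = ", "))
  samples <- expr$design$sample[expr$design$condition %in% conditions]
  lcpm <- log2(compute_cpm(expr$counts[, samples, drop = FALSE]) + 1)
  me <- rowMeans(lcpm)
  common <- intersect(gene_scores$gene, names(me))
  dropped <- length(gene_scores$gene) - length(common)
  if (!length(common))
    stop("no gene id shared between the count table and the gene scores; ",
         "check that counts are keyed on the model's gene namespace")
  if (dropped > 0)
    message(dropped, " scored gene(s) missing from the count table were dropped")
  idx <- match(common, gene_scores$gene)
  data.frame(gene = common,
             mean_expression = as.numeric(me[common]),
             delta_usage_gene = gene_scores$delta_usage_gene[idx],
             pathway_flag = common %in% highlight,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flux-weighted volcano table
#'
#' Joins an externally produced differential-expression table (columns
#' `gene`, `log2_fc`, `p_value`, optional `adjusted_p`) with the
#' projected metabolic scores: each gene's point size is
#' `|delta_usage_gene|` (0 for genes with no metabolic score), and a
#' flag marks genes passing the fold-change threshold.
#'
#' @param de data frame with at least `gene`, `log2_fc`, `p_value`.
#' @param gene_scores differential `gene_scores` table.
#' @param fc_threshold |log2 fold change| cutoff for the flag (default 1).
#' @param highlight gene ids to flag as pathway members.
#' @return data frame with columns `gene`, `log2_fc`, `p_value`,
#'   `size_weight`, `fc_flag`, `pathway_flag`.
#' @export
build_volcano_table <- function(de, gene_scores, fc_threshold = 1,
                                highlight = character()) {
  need <- c("gene", "log2_fc", "p_value")
  miss <- setdiff(need, names(de))
  if (length(miss))
    stop("DE table is missing required column(s): ", paste(miss, collapse = ", "))
  idx <- match(de$gene, gene_scores$gene)
  size <- abs(gene_scores$delta_usage_gene[idx])
  size[is.na(size)] <- 0
  data.frame(gene = de$gene, log2_fc = de$log2_fc, p_value = de$p_value,
             size_weight = size,
             fc_flag = abs(de$log2_fc) > fc_threshold,
             pathway_flag = de$gene %in% highlight,
             row.names = NULL, stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write the integrated report directory
#'
#' Persists every table of a pipeline run under a fixed layout —
#' `models/`, `samples/`, `scores/`, `enrichment/`, `report/` — together
#' with a machine-readable manifest (`report/manifest.json`) listing the
#' run's inputs with checksums, seeds, thresholds and any omitted
#' optional outputs. Identical inputs and seed give byte-identical
#' outputs.
#'
#' @param run named list of run artifacts; recognized elements:
#'   `models` (named list of [metabolic_model]), `samples` (named list of
#'   `flux_samples`), `reaction_scores` / `gene_scores` (named lists of
#'   data frames), `differential` (data frame), `differential_genes`
#'   (data frame), `signature` (character), `enrichment` (named list of
#'   data frames), `ma_table`, `volcano_table`, `rcc_histograms` (named
#'   list), `convergence` (named list of reports), `config` (list),
#'   `inputs` (named list of input file paths).
#' @param dir output directory (created if needed).
#' @param figures also render static MA / volcano / RCC-histogram PNGs.
#' @return `dir`, invisibly.
#' @export
write_report <- function(run, dir, figures = FALSE) {
  sub <- c("models", "samples", "scores", "enrichment", "report")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create report directory ", dir)
  for (d in sub) dir.create(file.path(dir, d), showWarnings = FALSE)

  manifest <- list(package_version = as.character(utils::packageVersion("carveflux")),
                   config = run$config, omitted = character())
  if (!is.null(run$inputs)) {
    sums <- vapply(run$inputs, function(p)
      if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_,
      character(1L))
    manifest$inputs <- mapply(function(p, s) list(path = p, md5 = s),
                              run$inputs, sums, SIMPLIFY = FALSE)
  }
  for (nm in names(run$models)) {
    write_model(run$models[[nm]], file.path(dir, "models", paste0(nm, ".xml")), "sbml")
    write_model(run$models[[nm]], file.path(dir, "models", paste0(nm, ".json")), "json")
  }
  for (nm in names(run$samples))
    write_flux_samples(run$samples[[nm]],
                       file.path(dir, "samples", paste0(nm, ".tsv")))
  for (nm in names(run$reaction_scores))
    write_tsv(run$reaction_scores[[nm]],
              file.path(dir, "scores", paste0("reactions_", nm, ".tsv")))
  for (nm in names(run$gene_scores))
    write_tsv(run$gene_scores[[nm]],
              file.path(dir, "scores", paste0("genes_", nm, ".tsv")))
  for (nm in names(run$rcc_histograms))
    write_tsv(run$rcc_histograms[[nm]],
              file.path(dir, "report", paste0("rcc_histogram_", nm, ".tsv")))
  if (!is.null(run$differential))
    write_tsv(run$differential, file.path(dir, "scores", "differential_reactions.tsv"))
  if (!is.null(run$differential_genes))
    write_tsv(run$differential_genes, file.path(dir, "scores", "differential_genes.tsv"))
  if (!is.null(run$signature))
    writeLines(run$signature, file.path(dir, "scores", "signature_genes.txt"))
  for (nm in names(run$enrichment))
    write_tsv(run$enrichment[[nm]],
              file.path(dir, "enrichment", paste0(nm, ".tsv")))
  if (!is.null(run$ma_table)) {
    write_tsv(run$ma_table, file.path(dir, "report", "ma_table.tsv"))
  }
  if (is.null(run$volcano_table)) {
    manifest$omitted <- c(manifest$omitted, "volcano_table (no DE table supplied)")
  } else {
    write_tsv(run$volcano_table, file.path(dir, "report", "volcano_table.tsv"))
  }
  if (!is.null(run$convergence))
    jsonlite::write_json(lapply(run$convergence, unclass),
                         file.path(dir, "report", "convergence.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (figures) render_figures(run, file.path(dir, "report"))
  jsonlite::write_json(manifest, file.path(dir, "report", "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

render_figures <- function(run, dir) {
  if (!is.null(run$ma_table)) {
    grDevices::png(file.path(dir, "ma_plot.png"), 900, 700)
    with(run$ma_table, {
      graphics::plot(mean_expression, delta_usage_gene,
           pch = 19, col = ifelse(pathway_flag, "red", "grey40"),
           xlab = "mean expression (log2 CPM + 1)",
           ylab = "differential mean flux of associated reactions")
      graphics::abline(h = 0, lty = 2)
    })
    grDevices::dev.off()
  }
  if (!is.null(run$volcano_table)) {
    grDevices::png(file.path(dir, "volcano_plot.png"), 900, 700)
    with(run$volcano_table, {
      graphics::plot(log2_fc, -log10(p_value),
           cex = 0.5 + 2 * size_weight / max(size_weight, 1e-9),
           pch = 19, col = ifelse(pathway_flag, "red", "grey40"),
           xlab = "log2 fold change", ylab = "-log10 p")
      graphics::abline(v = c(-1, 1), lty = 2)
    })
    grDevices::dev.off()
  }
  for (nm in names(run$rcc_histograms)) {
    h <- run$rcc_histograms[[nm]]
    grDevices::png(file.path(dir, paste0("rcc_histogram_", nm, ".png")), 900, 700)
    graphics::barplot(h$count, names.arg = sprintf("%.2f", h$bin_upper),
                      xlab = "RCC", ylab = "reactions", main = nm)
    grDevices::dev.off()
  }
}
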