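#' Pipeline run configuration
#'
#' Bundles every input path and stage parameter of an end-to-end run.
#' All parameters are serializable to a single JSON config file
#' ([load_run_config()] reads one back, rejecting unknown keys).
#'
#' @param universal_model path to the universal model (SBML or JSON).
#' @param counts,design paths to the count and design TSVs.
#' @param out_dir report directory.
#' @param pair length-2 character vector: the condition pair compared as
#'   A vs B (default: the first two conditions of the design).
#' @param de_table optional DE TSV (`gene`, `log2_fc`, `p_value`).
#' @param medium optional TSV (`reaction`, `lower_bound`) overriding
#'   exchange bounds of the universal model.
#' @param gmt optional GMT file for enrichment.
#' @param biomass optional biomass reaction id when the model file does
#'   not designate one.
#' @param filter a [filter_params()].
#' @param carve a [carve_config()].
#' @param sampler a [sampler_config()].
#' @param delta_threshold,p_threshold,fc_threshold selection thresholds
#'   (defaults 0.5, 0.05, 1).
#' @param aggregation gene-score aggregation (see [project_scores()]).
#' @param seed global seed; per-condition sampler seeds are derived from
#'   it deterministically.
#' @param figures render static figures in the report.
#' @return a list of class `run_config`.
#' @export
run_config <- function(universal_model, counts, design, out_dir,
                       pair = NULL, de_table = NULL, medium = NULL,
                       gmt = NULL, biomass = NULL,
                       filter = filter_params(), carve = carve_config(),
                       sampler = sampler_config(),
                       delta_threshold = 0.5, p_threshold = 0.05,
                       fc_threshold = 1, aggregation = "max",
                       seed = 1, figures = FALSE) {
  structure(list(universal_model = universal_model, counts = counts,
                 design = design, out_dir = out_dir, pair = pair,
                 de_table = de_table, medium = medium, gmt = gmt,
                 biomass = biomass, filter = filter, carve = carve,
                 sampler = sampler, delta_threshold = delta_threshold,
                 p_threshold = p_threshold, fc_threshold = fc_threshold,
                 aggregation = aggregation, seed = as.integer(seed),
                 figures = figures),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON config file.
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), c(known, "filter", "carve", "sampler"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$filter)) raw$filter <- do.call(filter_params, raw$filter)
  if (!is.null(raw$carve)) raw$carve <- do.call(carve_config, raw$carve)
  if (!is.null(raw$sampler)) raw$sampler <- do.call(sampler_config, raw$sampler)
  do.call(run_config, raw)
}

apply_medium <- function(model, medium) {
  idx <- match(medium$reaction, model$reactions$id)
  if (anyNA(idx))
    stop("medium references unknown reaction(s): ",
         paste(medium$reaction[is.na(idx)], collapse = ", "))
  model$reactions$lower_bound[idx] <- medium$lower_bound
  validate_model(model)
  model
}

#' Run the full pipeline
#'
#' filter -> carve -> de-block -> sample (convergence-driven) -> score,
#' per condition of the compared pair; then differential scoring, gene
#' projection, signature selection, optional enrichment, plot-ready
#' tables and the report directory. Deterministic given (inputs, config,
#' seed). With `resume = TRUE` an existing sample matrix in the output
#' directory is reused instead of resampled.
#'
#' @param config a [run_config()].
#' @param resume reuse persisted sample matrices when present.
#' @return the run-artifact list (invisibly), after writing the report
#'   directory.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$universal_model, config$counts, config$design))
    if (!file.exists(p)) stop("input file not found: ", p)
  stage <- function(name, code) {
    message("[", name, "] ", appendLF = FALSE)
    t0 <- Sys.time()
    out <- withCallingHandlers(
      tryCatch(force(code), error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)))
    message(sprintf("done (%.1fs)", as.numeric(Sys.time() - t0, units = "secs")))
    out
  }
  universal <- stage("read_model",
                     read_model(config$universal_model, biomass = config$biomass))
  if (!is.null(config$medium))
    universal <- apply_medium(universal, utils::read.delim(config$medium))
  expr <- stage("read_counts", read_expression(config$counts, config$design))
  pair <- config$pair
  if (is.null(pair)) pair <- utils::head(unique(expr$design$condition), 2L)
  if (length(pair) != 2L) stop("need exactly two conditions to compare")

  run <- list(config = config_as_list(config),
              inputs = Filter(Negate(is.null),
                              list(universal_model = config$universal_model,
                                   counts = config$counts, design = config$design,
                                   de_table = config$de_table, gmt = config$gmt,
                                   medium = config$medium)),
              models = list(), samples = list(), reaction_scores = list(),
              gene_scores = list(), rcc_histograms = list(),
              convergence = list())

  per_cond <- list()
  for (ci in seq_along(pair)) {
    cond <- pair[ci]
    expressed <- stage(paste0("filter:", cond),
                       filter_expressed(expr, cond, config$filter))
    carved <- stage(paste0("carve:", cond), {
      sc <- score_reactions(universal, expressed, config$carve)
      carve(universal, sc, config$carve)
    })
    carved <- stage(paste0("deblock:", cond), remove_blocked(carved))
    carved$id <- cond
    scfg <- config$sampler
    scfg$seed <- (config$seed * 1000L + ci) %% .Machine$integer.max
    sample_path <- file.path(config$out_dir, "samples", paste0(cond, ".tsv"))
    if (resume && file.exists(sample_path)) {
      samples <- stage(paste0("sample:", cond, " (resumed)"),
                       read_flux_samples(sample_path))
      report <- NULL
    } else {
      res <- stage(paste0("sample:", cond),
                   sample_until_converged(carved, scfg))
      samples <- res$samples
      report <- res$report
    }
    scores <- stage(paste0("score:", cond), reaction_scores(samples))
    per_cond[[cond]] <- list(model = carved, samples = samples,
                             scores = scores, expressed = expressed)
    run$models[[cond]] <- carved
    run$samples[[cond]] <- samples
    run$reaction_scores[[cond]] <- scores
    run$rcc_histograms[[cond]] <- rcc_histogram(scores)
    if (!is.null(report)) run$convergence[[cond]] <- report
    mapping <- gene_reaction_map(carved)
    run$gene_scores[[cond]] <- project_scores(scores, mapping,
                                              config$aggregation)
  }

  a <- per_cond[[pair[1L]]]; b <- per_cond[[pair[2L]]]
  diff_rx <- stage("differential", differential_reactions(
    list(scores = a$scores, samples = a$samples),
    list(scores = b$scores, samples = b$samples)))
  mapping <- gene_reaction_map(universal)
  mapping <- mapping[vapply(mapping, function(r)
    any(r %in% diff_rx$reaction), logical(1L))]
  diff_genes <- stage("project", project_scores(diff_rx, mapping,
                                                config$aggregation))
  signature <- stage("select", select_signature_genes(
    diff_genes, config$delta_threshold, config$p_threshold, "a_over_b"))
  run$differential <- diff_rx
  run$differential_genes <- diff_genes
  run$signature <- signature

  if (!is.null(config$gmt)) {
    collection <- read_gmt(config$gmt)
    universe <- sort(union(a$model$genes, b$model$genes))
    run$enrichment <- list(
      ora_signature = stage("ora", ora(intersect(signature, universe),
                                       universe, collection)),
      gsea_delta_usage = stage("gsea", gsea_preranked(
        stats::setNames(diff_genes$delta_usage_gene, diff_genes$gene),
        collection, seed = config$seed)))
  }

  run$ma_table <- stage("ma_table", build_ma_table(expr, diff_genes, pair))
  if (!is.null(config$de_table)) {
    de <- utils::read.delim(config$de_table, stringsAsFactors = FALSE)
    run$volcano_table <- stage("volcano", build_volcano_table(
      de, diff_genes, config$fc_threshold))
  }
  stage("report", write_report(run, config$out_dir, figures = config$figures))
  invisible(run)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$filter <- unclass(out$filter)
  out$carve <- unclass(out$carve)
  out$sampler <- unclass(out$sampler)
  out
}
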