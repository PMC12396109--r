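#' Constraint-based metabolic model container
#'
#' A `metabolic_model` holds the stoichiometry, flux bounds, GPR rules and
#' biomass designation of a genome-scale metabolic model (GEM) — either the
#' universal model or a carved context-specific submodel.
#'
#' @param id model identifier.
#' @param metabolites data frame with columns `id`, `name`, `compartment`
#'   (missing columns are filled with the id / empty strings).
#' @param reactions data frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gpr`, `subsystem` (`gpr` is the rule text, `""` for
#'   none).
#' @param stoich named list, one element per reaction id: a named numeric
#'   vector mapping metabolite ids to stoichiometric coefficients
#'   (negative = consumed).
#' @param biomass_id id of the biomass (objective) reaction.
#' @return an object of class `metabolic_model` with fields `id`,
#'   `metabolites`, `reactions`, `stoich`, `biomass_id` and `genes`
#'   (the union of gene ids over all GPRs, always recomputed).
#' @examples
#' m <- toy_universal_model(toy_spec(n_linear = 3, n_branches = 1, seed = 1))
#' m
#' stoich_matrix(m)[, 1:3]
#' @export
metabolic_model <- function(id, metabolites, reactions, stoich, biomass_id) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- ""
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL

  model <- structure(
    list(id = as.character(id),
         metabolites = metabolites[, c("id", "name", "compartment")],
         reactions = reactions[, c("id", "name", "lower_bound", "upper_bound",
                                   "gpr", "subsystem")],
         stoich = stoich[reactions$id],
         biomass_id = as.character(biomass_id),
         genes = character()),
    class = "metabolic_model")
  model$genes <- model_genes(model)
  validate_model(model)
  model
}

model_genes <- function(model) {
  gs <- lapply(model$reactions$gpr, function(g) gpr_genes(parse_gpr(g)))
  sort(unique(unlist(gs, use.names = FALSE)))
}

validate_model <- function(model) {
  rx <- model$reactions
  mets <- model$metabolites$id
  if (anyDuplicated(rx$id)) stop("duplicate reaction ids")
  if (anyDuplicated(mets)) stop("duplicate metabolite ids")
  if (!identical(names(model$stoich), rx$id))
    stop("stoichiometry list must be named by reaction id, in reaction order")
  ref <- unique(unlist(lapply(model$stoich, names), use.names = FALSE))
  missing <- setdiff(ref, mets)
  if (length(missing))
    stop("stoichiometry references unknown metabolites: ",
         paste(missing, collapse = ", "))
  if (any(rx$lower_bound > rx$upper_bound))
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(rx$id[rx$lower_bound > rx$upper_bound], collapse = ", "))
  if (!model$biomass_id %in% rx$id)
    stop("biomass reaction '", model$biomass_id, "' not found in the model")
  invisible(model)
}

#' @rdname metabolic_model
#' @param model a `metabolic_model`.
#' @return `stoich_matrix()`: the dense stoichiometric matrix S
#'   (metabolites x reactions).
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow = nrow(model$metabolites), ncol = nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (j in seq_along(model$stoich)) {
    sj <- model$stoich[[j]]
    S[names(sj), j] <- sj
  }
  S
}

#' Restrict a model to a subset of its reactions
#'
#' Keeps the named reactions (bounds, stoichiometry and GPRs unchanged)
#' plus every metabolite they reference; all other reactions and then
#' orphaned metabolites are dropped. The biomass reaction is always kept.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids character vector of reaction ids to keep.
#' @param id id for the submodel.
#' @return a `metabolic_model`.
#' @export
subset_model <- function(model, reaction_ids, id = paste0(model$id, "_sub")) {
  reaction_ids <- union(reaction_ids, model$biomass_id)
  keep <- model$reactions$id %in% reaction_ids
  stoich <- model$stoich[keep]
  used <- unique(unlist(lapply(stoich, names), use.names = FALSE))
  metabolic_model(
    id = id,
    metabolites = model$metabolites[model$metabolites$id %in% used, , drop = FALSE],
    reactions = model$reactions[keep, , drop = FALSE],
    stoich = stoich,
    biomass_id = model$biomass_id)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites, %d reactions, %d genes; biomass = %s\n",
              x$id, nrow(x$metabolites), nrow(x$reactions), length(x$genes),
              x$biomass_id))
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  rx <- object$reactions
  no_gpr <- sum(!nzchar(rx$gpr))
  rev <- sum(rx$lower_bound < 0 & rx$upper_bound > 0)
  cat(sprintf("Model %s\n  metabolites: %d\n  reactions:   %d (%d without GPR, %d reversible)\n  genes:       %d\n  biomass:     %s\n",
              object$id, nrow(object$metabolites), nrow(rx), no_gpr, rev,
              length(object$genes), object$biomass_id))
  invisible(object)
}
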