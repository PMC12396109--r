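#' Toy universal model specification
#'
#' Parameters of the self-contained toy universal models used for
#' testing and demonstration: one uptake exchange feeding a linear
#' backbone of single-gene reactions that ends in a biomass reaction and
#' a sink exchange, plus optional alternative routes between backbone
#' metabolites, each labelled with its own gene(s).
#'
#' @param n_linear number of backbone conversion reactions (>= 2).
#' @param n_branches number of alternative routes.
#' @param genes_per_reaction genes per internal reaction (1 = single
#'   gene; 2 alternates `and` complexes and `or` isozymes).
#' @param seed seed for the random branch placement.
#' @param uptake_bound upper bound of the uptake exchange (flux units,
#'   default 10); this is also the model's maximal biomass flux.
#' @param branch_span `"random"` places each branch between two random
#'   backbone metabolites; `"full"` (the default fixture used for
#'   two-condition ground-truth studies) routes every branch from the
#'   first to the last backbone metabolite, so that branch presence does
#'   not change the throughput of the shared backbone ends.
#' @return a list of class `toy_spec`.
#' @export
toy_spec <- function(n_linear = 4, n_branches = 1, genes_per_reaction = 1,
                     seed = 1, uptake_bound = 10,
                     branch_span = c("full", "random")) {
  stopifnot(n_linear >= 2, n_branches >= 0, genes_per_reaction >= 1,
            uptake_bound > 0)
  structure(list(n_linear = n_linear, n_branches = n_branches,
                 genes_per_reaction = genes_per_reaction, seed = seed,
                 uptake_bound = uptake_bound,
                 branch_span = match.arg(branch_span)),
            class = "toy_spec")
}

#' Generate a toy universal metabolic model
#'
#' Builds the model described by [toy_spec()]: metabolites `M1 ... Mk`,
#' an uptake exchange `EX_up` (0 to `uptake_bound`), backbone reactions
#' `r1 ... r<n_linear>` (`Mi -> Mi+1`, one distinct gene each), a biomass
#' reaction `bio` consuming the terminal metabolite into `BIOM`, a sink
#' exchange `EX_bio`, and `n_branches` alternative routes `branch<j>`
#' with their own genes. All stoichiometry is unit, so the maximal
#' biomass flux equals `uptake_bound`. Deterministic given the spec.
#'
#' @param spec a [toy_spec()].
#' @return a [metabolic_model].
#' @export
toy_universal_model <- function(spec = toy_spec()) {
  set.seed(spec$seed)
  nl <- spec$n_linear
  mets <- c(paste0("M", seq_len(nl + 1L)), "BIOM")
  gidx <- 0L
  next_gpr <- function() {
    g <- spec$genes_per_reaction
    ids <- paste0("g", gidx + seq_len(g))
    gidx <<- gidx + g
    if (g == 1L) ids else
      paste(ids, collapse = if (gidx %% (2L * g) == 0L) " and " else " or ")
  }
  rxns <- list(); stoich <- list()
  addr <- function(id, coef, lb, ub, gpr = "", subsystem = "") {
    rxns[[length(rxns) + 1L]] <<- data.frame(
      id = id, name = id, lower_bound = lb, upper_bound = ub, gpr = gpr,
      subsystem = subsystem, stringsAsFactors = FALSE)
    stoich[[id]] <<- coef
  }
  addr("EX_up", c(M1 = 1), 0, spec$uptake_bound, subsystem = "exchange")
  for (i in seq_len(nl)) {
    coef <- stats::setNames(c(-1, 1), c(paste0("M", i), paste0("M", i + 1L)))
    addr(paste0("r", i), coef, 0, 1000, gpr = next_gpr(),
         subsystem = "backbone")
  }
  addr("bio", stats::setNames(c(-1, 1), c(paste0("M", nl + 1L), "BIOM")),
       0, 1000, subsystem = "biomass")
  addr("EX_bio", c(BIOM = -1), 0, 1000, subsystem = "exchange")
  branch_genes <- list()
  for (j in seq_len(spec$n_branches)) {
    if (spec$branch_span == "full") {
      from <- 1L; to <- nl + 1L
    } else {
      from <- sample.int(nl, 1L)
      to <- sample.int(nl + 1L - from, 1L) + from
    }
    gpr <- next_gpr()
    branch_genes[[paste0("branch", j)]] <- gpr_genes(parse_gpr(gpr))
    addr(paste0("branch", j),
         stats::setNames(c(-1, 1), paste0("M", c(from, to))),
         0, 1000, gpr = gpr, subsystem = "branch")
  }
  model <- metabolic_model(
    id = sprintf("toy_l%d_b%d_s%d", nl, spec$n_branches, spec$seed),
    metabolites = data.frame(id = mets, name = mets, compartment = "c",
                             stringsAsFactors = FALSE),
    reactions = do.call(rbind, rxns), stoich = stoich, biomass_id = "bio")
  attr(model, "branch_genes") <- branch_genes
  model
}

#' Random toy models for oracle testing
#'
#' Small random feasible networks (a backbone of 2-4 reactions plus 0-2
#' random-span branches, occasionally reversible), used to exercise the
#' carving and FVA oracles across many seeds.
#'
#' @param seed RNG seed.
#' @return a [metabolic_model] with at most 9 reactions.
#' @export
toy_random_model <- function(seed) {
  set.seed(seed)
  spec <- toy_spec(n_linear = sample(2:4, 1L), n_branches = sample(0:2, 1L),
                   seed = seed, branch_span = "random")
  model <- toy_universal_model(spec)
  # occasionally make one internal reaction reversible
  if (stats::runif(1) < 0.3) {
    i <- sample(which(startsWith(model$reactions$id, "r")), 1L)
    model$reactions$lower_bound[i] <- -1000
  }
  model
}

#' Synthetic UMI count matrix with known expressed sets
#'
#' Draws negative-binomial counts for every model gene in every sample:
#' mean `nb_mean_on` for genes in the sample's condition-specific
#' expressed set, `nb_mean_off` otherwise, shared dispersion. The
#' default on/off separation (200 vs 1) is extreme by design, so that
#' [filter_expressed()] recovers each condition's expressed set
#' essentially always and expression filtering is not the component
#' under stress in end-to-end tests.
#'
#' @param model a [metabolic_model] supplying the gene namespace.
#' @param expressed named list: condition -> expressed gene ids
#'   (subsets of `model$genes`).
#' @param n_samples_per_condition samples per condition (default 3).
#' @param seed RNG seed.
#' @param nb_mean_on,nb_mean_off negative-binomial means for expressed /
#'   silent genes (defaults 200 and 1).
#' @param nb_dispersion NB dispersion (`size` parameter; default 10).
#' @return an [expression_matrix].
#' @export
synthetic_counts <- function(model, expressed, n_samples_per_condition = 3L,
                             seed = 1, nb_mean_on = 200, nb_mean_off = 1,
                             nb_dispersion = 10) {
  stopifnot(is.list(expressed), length(names(expressed)) == length(expressed))
  for (cond in names(expressed)) {
    extra <- setdiff(expressed[[cond]], model$genes)
    if (length(extra))
      stop("expressed set of '", cond, "' contains non-model genes: ",
           paste(extra, collapse = ", "))
  }
  set.seed(seed)
  genes <- model$genes
  conds <- names(expressed)
  sample_ids <- unlist(lapply(conds, function(cn)
    paste0(cn, "_s", seq_len(n_samples_per_condition))))
  design <- data.frame(sample = sample_ids,
                       condition = rep(conds, each = n_samples_per_condition),
                       stringsAsFactors = FALSE)
  counts <- matrix(0L, length(genes), length(sample_ids),
                   dimnames = list(genes, sample_ids))
  for (j in seq_along(sample_ids)) {
    on <- genes %in% expressed[[design$condition[j]]]
    mu <- ifelse(on, nb_mean_on, nb_mean_off)
    counts[, j] <- stats::rnbinom(length(genes), mu = mu, size = nb_dispersion)
  }
  expression_matrix(counts, design)
}

#' The default two-condition ground-truth fixture
#'
#' A toy universal model with one full-span branch plus synthetic counts
#' for two conditions, `condA` expressing every gene and `condB` every
#' gene except the branch gene(s). The ground truth: carved models must
#' differ exactly by the branch reaction, and the branch genes are the
#' `a_over_b` signature.
#'
#' @param seed RNG seed for both the model and the counts.
#' @param n_linear backbone length (default 4).
#' @return list with `model`, `expr` (an [expression_matrix]),
#'   `expressed` (the per-condition truth), `branch_genes` and
#'   `branch_reactions`.
#' @export
two_condition_fixture <- function(seed = 1, n_linear = 4) {
  model <- toy_universal_model(toy_spec(n_linear = n_linear, n_branches = 1,
                                        seed = seed, branch_span = "full"))
  branch_genes <- attr(model, "branch_genes")[["branch1"]]
  expressed <- list(condA = model$genes,
                    condB = setdiff(model$genes, branch_genes))
  expr <- synthetic_counts(model, expressed, seed = seed + 1L)
  list(model = model, expr = expr, expressed = expressed,
       branch_genes = branch_genes, branch_reactions = "branch1")
}
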