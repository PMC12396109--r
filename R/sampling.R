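#' Sampler configuration
#'
#' @param thinning record every `thinning`-th chain step (default 100;
#'   large production runs typically use much higher values, e.g. 10000).
#' @param batch_size samples drawn between convergence checks (default 5000).
#' @param max_samples hard cap on recorded samples (default 150000).
#' @param seed integer seed driving all sampler randomness.
#' @param n_warmup number of warmup vertices (default `2 *` reaction count).
#' @return a list of class `sampler_config`.
#' @export
sampler_config <- function(thinning = 100, batch_size = 5000,
                           max_samples = 150000, seed = 1, n_warmup = NULL) {
  stopifnot(thinning >= 1, batch_size >= 100, max_samples >= batch_size)
  structure(list(thinning = as.integer(thinning),
                 batch_size = as.integer(batch_size),
                 max_samples = as.integer(max_samples),
                 seed = as.integer(seed),
                 n_warmup = if (is.null(n_warmup)) NULL else as.integer(n_warmup)),
            class = "sampler_config")
}

flux_samples <- function(values, reaction_ids, method, thinning, seed) {
  colnames(values) <- reaction_ids
  structure(list(values = values, reaction_ids = reaction_ids,
                 method = method, thinning = as.integer(thinning),
                 seed = as.integer(seed), n_samples = nrow(values)),
            class = "flux_samples")
}

#' @export
print.flux_samples <- function(x, ...) {
  cat(sprintf("<flux_samples> %d samples x %d reactions (method = %s, thinning = %d, seed = %d)\n",
              x$n_samples, length(x$reaction_ids), x$method, x$thinning, x$seed))
  invisible(x)
}

# orthogonal projector onto the null space of S (the steady-state
# subspace is homogeneous, so projection is a plain matrix product)
nullspace_projector <- function(S) {
  n <- ncol(S)
  if (nrow(S) == 0L) return(diag(n))
  sv <- svd(S, nu = 0, nv = n)
  pos <- sv$d > max(dim(S)) * max(sv$d, 0) * 1e-12
  r <- sum(pos)
  if (r == 0) return(diag(n))
  N <- sv$v[, setdiff(seq_len(n), seq_len(r)), drop = FALSE]
  N %*% t(N)
}

#' Warmup vertices for hit-and-run sampling
#'
#' Generates `n` vertices of the flux polytope by linear programming:
#' the first `2 * n_reactions` points are each reaction's flux minimum
#' and maximum (the FVA corners); further points optimize a random
#' `+/-` objective over a randomly chosen reaction.
#'
#' @param model a [metabolic_model] (feasible, de-blocked).
#' @param n number of points.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return an `n x n_reactions` matrix of feasible flux vectors.
#' @export
warmup_points <- function(model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nr <- nrow(model$reactions)
  pts <- matrix(NA_real_, n, nr, dimnames = list(NULL, model$reactions$id))
  for (i in seq_len(n)) {
    if (i <= 2L * nr) {
      j <- ((i - 1L) %/% 2L) + 1L
      maxi <- (i %% 2L) == 0L
    } else {
      j <- sample.int(nr, 1L)
      maxi <- stats::runif(1) < 0.5
    }
    obj <- numeric(nr); obj[j] <- 1
    res <- flux_lp(model, obj, maximize = maxi)
    if (res$status != "optimal")
      stop("warmup LP ", res$status, " for reaction ", model$reactions$id[j])
    pts[i, ] <- res$x
  }
  pts
}

#' Global solution-space sampling (artificial-centering hit-and-run)
#'
#' Uniform-target sampling of the steady-state flux polytope. The chain
#' keeps a running mean of all iterates as its centering point and steps
#' along directions from stored points (warmup vertices plus recorded
#' samples) through that center; every `thinning`-th iterate is recorded.
#' Fully reproducible from `config$seed`.
#'
#' @param model a [metabolic_model]; apply [remove_blocked()] first.
#' @param config a [sampler_config].
#' @param n number of samples to record (default `config$batch_size`,
#'   capped at `config$max_samples`).
#' @param state continuation state from a previous call's `"state"`
#'   attribute; when supplied the chain resumes instead of restarting.
#' @return a `flux_samples` object; attribute `"state"` carries the chain
#'   state for continuation.
#' @export
sample_global <- function(model, config = sampler_config(),
                          n = config$batch_size, state = NULL) {
  n <- min(n, config$max_samples)
  rxids <- model$reactions$id
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (is.null(state)) {
    set.seed(config$seed)
    n_warm <- if (is.null(config$n_warmup)) 2L * length(rxids) else config$n_warmup
    P <- nullspace_projector(stoich_matrix(model))
    warmup <- warmup_points(model, n_warm, seed = NULL)
    warmup <- warmup %*% P
    center <- colMeans(warmup)
    state <- list(warmup = warmup, recorded = matrix(0, 0L, length(rxids)),
                  current = center, center = center,
                  center_count = nrow(warmup), P = P)
  }
  res <- achr_core(state$warmup, state$recorded, state$current, state$center,
                   state$center_count, as.integer(n), config$thinning, lb, ub,
                   state$P)
  samples <- res$samples
  state$recorded <- rbind(state$recorded, samples)
  state$current <- as.vector(res$current %*% state$P)
  state$center <- as.vector(res$center %*% state$P)
  state$center_count <- res$center_count
  out <- flux_samples(state$recorded, rxids, "global", config$thinning,
                      config$seed)
  attr(out, "state") <- state
  out
}

#' Corner (random-objective vertex) sampling
#'
#' Draws `n` boundary points of the flux polytope: each sample is the
#' optimum of an LP whose objective has independent standard-normal
#' coefficients over all reactions. Emphasizes extreme metabolic
#' behaviours rather than the bulk of the solution space.
#'
#' @param model a [metabolic_model] (feasible and bounded).
#' @param n number of samples.
#' @param seed RNG seed.
#' @return a `flux_samples` object with `method = "corner"`.
#' @export
sample_corner <- function(model, n, seed = 1) {
  set.seed(seed)
  nr <- nrow(model$reactions)
  vals <- matrix(NA_real_, n, nr)
  for (i in seq_len(n)) {
    obj <- stats::rnorm(nr)
    res <- flux_lp(model, obj, maximize = TRUE)
    if (res$status != "optimal")
      stop("corner-sampling LP ", res$status, " (objective draw ", i, ")")
    vals[i, ] <- res$x
  }
  flux_samples(vals, model$reactions$id, "corner", 1L, seed)
}

#' Write / read a flux sample matrix as TSV with a JSON sidecar
#'
#' The TSV holds the samples x reactions matrix (header = reaction ids);
#' the sidecar `<path>.json` records method, seed, thinning and sample
#' count (plus the convergence report if one is attached).
#'
#' @param samples a `flux_samples` object.
#' @param path TSV output path.
#' @return the path, invisibly (`read_flux_samples` returns the object).
#' @export
write_flux_samples <- function(samples, path) {
  utils::write.table(as.data.frame(samples$values), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(method = samples$method, seed = samples$seed,
               thinning = samples$thinning, n_samples = samples$n_samples)
  conv <- attr(samples, "convergence")
  if (!is.null(conv)) meta$convergence <- unclass(conv)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_flux_samples
#' @export
read_flux_samples <- function(path) {
  vals <- as.matrix(utils::read.delim(path, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  flux_samples(vals, colnames(vals), meta$method, meta$thinning, meta$seed)
}
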