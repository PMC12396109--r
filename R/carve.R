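#' Carving configuration
#'
#' Parameters of the context-specific model extraction.
#'
#' @param f_min fraction of the universal model's maximal biomass flux the
#'   carved model must sustain (default 0.1).
#' @param penalty_absent objective weight against including a reaction
#'   whose GPR evaluates FALSE on the expressed set (default 1).
#' @param penalty_nogpr small parsimony weight against including
#'   reactions with no GPR (exchanges, biomass, spontaneous; default 0.01).
#' @param flux_activation_eps minimum |flux| an included, gene-supported
#'   reaction must be able to carry at the carve optimum (default 1e-4).
#' @param solver_gap relative optimality gap at which branch-and-bound
#'   stops (default 1e-6).
#' @return a list of class `carve_config`.
#' @export
carve_config <- function(f_min = 0.1, penalty_absent = 1, penalty_nogpr = 0.01,
                         flux_activation_eps = 1e-4, solver_gap = 1e-6) {
  stopifnot(f_min > 0, f_min <= 1, penalty_absent >= 0, penalty_nogpr >= 0,
            flux_activation_eps > 0, solver_gap >= 0)
  structure(list(f_min = f_min, penalty_absent = penalty_absent,
                 penalty_nogpr = penalty_nogpr,
                 flux_activation_eps = flux_activation_eps,
                 solver_gap = solver_gap),
            class = "carve_config")
}

#' Evidence scores for carving
#'
#' Scores every reaction of the universal model against the expressed
#' gene set: `+1` when its GPR evaluates TRUE, `-penalty_absent` when it
#' evaluates FALSE, `0` when the reaction has no GPR (its inclusion is
#' decided by the parsimony penalty and by flux necessity alone).
#'
#' @param model universal [metabolic_model].
#' @param expressed character vector of expressed gene ids; ids not in
#'   the model's gene namespace are ignored (a message reports how many).
#' @param config a [carve_config].
#' @return named numeric vector, one score per reaction.
#' @export
score_reactions <- function(model, expressed, config = carve_config()) {
  expressed <- trimws(as.character(expressed))
  unknown <- setdiff(expressed, model$genes)
  if (length(unknown))
    message(length(unknown), " expressed gene id(s) not in the model were ignored")
  present <- intersect(expressed, model$genes)
  vapply(seq_len(nrow(model$reactions)), function(i) {
    g <- model$reactions$gpr[i]
    if (!nzchar(g)) return(0)
    if (evaluate_gpr(parse_gpr(g), present)) 1 else -config$penalty_absent
  }, numeric(1L)) -> s
  stats::setNames(s, model$reactions$id)
}

#' Carve a context-specific model
#'
#' Extracts the submodel that best fits the expressed-gene evidence while
#' remaining functional. A mixed-integer program selects a reaction subset
#' maximizing
#' \deqn{\sum_{s_r>0} s_r y_r + \sum_{s_r<0} s_r y_r -
#'       p_{nogpr} \sum_{s_r=0} y_r}
#' over inclusion indicators \eqn{y_r}, subject to steady state
#' (`S v = 0`), `lb_r y_r <= v_r <= ub_r y_r`, biomass flux at least
#' `f_min` times the universal optimum, and each included
#' positively-scored reaction carrying at least `flux_activation_eps`
#' absolute flux (so rewarded reactions are genuinely usable). The MIP is
#' solved exactly by branch-and-bound on the inclusion indicators over
#' the LP relaxation; reversible supported reactions get an auxiliary
#' direction indicator to linearize the |flux| activation.
#'
#' @param model universal [metabolic_model] with `max_biomass(model) > 0`.
#' @param scores named score vector from [score_reactions()] (one score
#'   per reaction of `model`).
#' @param config a [carve_config].
#' @return a [metabolic_model] containing exactly the selected reactions
#'   (biomass always included) and the metabolites they use, with
#'   attributes `objective` (MILP optimum) and `carve_report` (data frame
#'   of reaction, score, included flag, flux at the MILP solution).
#' @export
carve <- function(model, scores, config = carve_config()) {
  rx <- model$reactions
  stopifnot(length(scores) == nrow(rx))
  if (!is.null(names(scores))) scores <- scores[rx$id]
  vmax <- max_biomass(model)$value
  if (vmax <= LP_EPS)
    stop("universal model has zero maximal biomass flux; cannot enforce functionality")

  sol <- carve_milp(model, scores, config, vmax)
  if (is.null(sol))
    stop("carve MILP infeasible at f_min = ", config$f_min,
         "; try a lower functionality fraction")
  included <- rx$id[sol$y > 0.5]
  report <- data.frame(reaction = rx$id, score = as.numeric(scores),
                       included = sol$y > 0.5, flux = sol$v,
                       stringsAsFactors = FALSE)
  carved <- subset_model(model, included, id = paste0(model$id, "_carved"))
  attr(carved, "objective") <- sol$objective
  attr(carved, "carve_report") <- report
  carved
}

# Build and solve the carve MIP. Variable layout: x = [v (n), y (n), d (k)]
# where d are direction indicators for reversible positively-scored
# reactions. Returns list(y, v, objective) or NULL when infeasible.
carve_milp <- function(model, scores, config, vmax) {
  rx <- model$reactions
  n <- nrow(rx)
  S <- stoich_matrix(model)
  lb <- rx$lower_bound; ub <- rx$upper_bound
  eps <- config$flux_activation_eps
  bio <- match(model$biomass_id, rx$id)

  pos <- which(scores > 0)
  rev_pos <- pos[lb[pos] < -LP_EPS & ub[pos] > LP_EPS]
  k <- length(rev_pos)
  nv <- 2L * n + k

  obj <- c(rep(0, n), ifelse(scores != 0, scores, -config$penalty_nogpr), rep(0, k))

  # equality rows: S v = 0
  Aeq <- cbind(S, matrix(0, nrow(S), n + k))
  beq <- rep(0, nrow(S))

  rows <- list(); rhs <- numeric()
  add <- function(a, b) { rows[[length(rows) + 1L]] <<- a; rhs[length(rhs) + 1L] <<- b }
  unit <- function(i, val) { a <- numeric(nv); a[i] <- val; a }

  for (i in seq_len(n)) {
    # v_i - ub_i y_i <= 0  and  -v_i + lb_i y_i <= 0
    a <- numeric(nv); a[i] <- 1; a[n + i] <- -ub[i]; add(a, 0)
    a <- numeric(nv); a[i] <- -1; a[n + i] <- lb[i]; add(a, 0)
  }
  add(unit(bio, -1), -config$f_min * vmax)   # v_bio >= f_min vmax
  for (i in pos) {
    if (i %in% rev_pos) next
    if (lb[i] >= -LP_EPS) {                  # forward: v_i >= eps y_i
      a <- numeric(nv); a[i] <- -1; a[n + i] <- eps; add(a, 0)
    } else {                                 # backward-only: v_i <= -eps y_i
      a <- numeric(nv); a[i] <- 1; a[n + i] <- eps; add(a, 0)
    }
  }
  if (k) for (j in seq_len(k)) {
    i <- rev_pos[j]
    # d_j = 1, y_i = 1  =>  v_i >= eps ; d_j = 0, y_i = 1  =>  v_i <= -eps
    Ml <- eps - lb[i]; Mu <- ub[i] + eps
    a <- numeric(nv); a[i] <- -1; a[2L * n + j] <- Ml; a[n + i] <- Ml
    add(a, -eps + 2 * Ml)
    a <- numeric(nv); a[i] <- 1; a[2L * n + j] <- -Mu; a[n + i] <- Mu
    add(a, -eps + Mu)
  }
  Aineq <- do.call(rbind, rows)

  xlb <- c(pmin(lb, 0), rep(0, n + k))
  xub <- c(pmax(ub, 0), rep(1, n + k))
  xlb[n + bio] <- 1                          # biomass always included

  bin_idx <- c(n + seq_len(n), if (k) 2L * n + seq_len(k))

  relax <- function(xlb, xub) {
    solve_lp(obj, Aeq = Aeq, beq = beq, lb = xlb, ub = xub,
             Aineq = Aineq, bineq = rhs, maximize = TRUE)
  }

  best <- NULL
  best_val <- -Inf
  tol_int <- 1e-6
  stack <- list(list(lb = xlb, ub = xub))
  n_nodes <- 0L
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    n_nodes <- n_nodes + 1L
    if (n_nodes > 100000L) stop("carve branch-and-bound exceeded the node limit")
    res <- relax(node$lb, node$ub)
    if (res$status != "optimal") next
    # prune on the LP bound; slack covers only LP arithmetic noise plus
    # the configured relative gap, so enumeration-exact optima survive
    slack <- 1e-9 + config$solver_gap * abs(best_val)
    if (!is.null(best) && res$value <= best_val + slack) next
    xb <- res$x[bin_idx]
    frac <- abs(xb - round(xb))
    if (all(frac <= tol_int)) {
      # near-integral y with big-M bounds can hide real flux (y = 1e-7
      # admits |v| up to 1e-7 * M): verify by re-solving with the
      # binaries fixed at their rounded values before accepting
      fix_lb <- node$lb; fix_ub <- node$ub
      fix_lb[bin_idx] <- round(xb); fix_ub[bin_idx] <- round(xb)
      res2 <- relax(fix_lb, fix_ub)
      if (res2$status == "optimal") {
        val <- sum(obj[bin_idx] * round(xb))
        if (val > best_val) {
          best_val <- val
          best <- res2
        }
        next
      }
      if (max(frac) < 1e-12) next  # genuinely integral yet infeasible: prune
      # else fall through and branch on the offending near-integral binary
    }
    j <- bin_idx[which.max(frac)]
    up <- node; up$lb[j] <- 1
    dn <- node; dn$ub[j] <- 0
    # explore the include branch first (maximization heuristic)
    stack[[length(stack) + 1L]] <- dn
    stack[[length(stack) + 1L]] <- up
  }
  if (is.null(best)) return(NULL)
  list(y = round(best$x[n + seq_len(n)]), v = best$x[seq_len(n)],
       objective = best_val)
}
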