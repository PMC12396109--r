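# Linear-programming layer.
#
# All flux analyses reduce to LPs of the form
#   max / min  obj' x
#   s.t.       Aeq x  = beq
#              Aineq x <= bineq
#              lb <= x <= ub        (all bounds finite)
# solved by a dense two-phase primal simplex with Bland's rule
# (deterministic, cycle-free) after shifting x to nonnegative
# coordinates (z = x - lb); upper bounds become explicit rows. Problem
# sizes here are small (tens of variables), where a dense tableau is
# both robust and fast.

LP_EPS <- 1e-9

# two-phase simplex: min cost' x, A x (= / <=) b, x >= 0.
# rowtype: "eq" or "le". Returns list(status, x, value).
lp_simplex <- function(cost, A, b, rowtype, eps = 1e-9, max_iter = 10000L) {
  m <- nrow(A); n <- ncol(A)
  # normalize to b >= 0
  flip <- b < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b[flip] <- -b[flip]
    rowtype[flip & rowtype == "le"] <- "ge"
  }
  # slack (+1 for le, -1 for ge) and artificial columns
  n_slack <- sum(rowtype != "eq")
  slack_col <- integer(m); art_col <- integer(m)
  Nt <- n + n_slack + m                      # upper bound on columns
  T0 <- matrix(0, m, Nt)
  T0[, seq_len(n)] <- A
  k <- n
  for (i in seq_len(m)) {
    if (rowtype[i] != "eq") {
      k <- k + 1L
      T0[i, k] <- if (rowtype[i] == "le") 1 else -1
      slack_col[i] <- k
    }
  }
  basis <- integer(m)
  n_art <- 0L
  for (i in seq_len(m)) {
    if (rowtype[i] == "le") {
      basis[i] <- slack_col[i]
    } else {
      k <- k + 1L; n_art <- n_art + 1L
      T0[i, k] <- 1
      art_col[i] <- k
      basis[i] <- k
    }
  }
  ncols <- k
  T0 <- T0[, seq_len(ncols), drop = FALSE]
  rhs <- b

  run_phase <- function(T0, rhs, basis, cost_full, active) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(NULL)
      red <- cost_full - as.vector(cost_full[basis] %*% T0)
      red[!active] <- Inf
      ent <- which(red < -eps)
      if (!length(ent)) return(list(T0 = T0, rhs = rhs, basis = basis))
      j <- ent[1L]                            # Bland: smallest index
      col <- T0[, j]
      pos <- which(col > eps)
      if (!length(pos)) return("unbounded")
      ratio <- rhs[pos] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + eps]
      i <- cand[which.min(basis[cand])]       # Bland tie-break
      piv <- T0[i, j]
      T0[i, ] <- T0[i, ] / piv
      rhs[i] <- rhs[i] / piv
      other <- setdiff(seq_len(nrow(T0)), i)
      f <- T0[other, j]
      T0[other, ] <- T0[other, , drop = FALSE] - outer(f, T0[i, ])
      rhs[other] <- rhs[other] - f * rhs[i]
      basis[i] <- j
    }
  }

  active <- rep(TRUE, ncols)
  if (n_art > 0L) {
    c1 <- numeric(ncols)
    c1[art_col[art_col > 0L]] <- 1
    ph1 <- run_phase(T0, rhs, basis, c1, active)
    if (is.null(ph1) || identical(ph1, "unbounded"))
      return(list(status = "maxiter"))
    T0 <- ph1$T0; rhs <- ph1$rhs; basis <- ph1$basis
    if (sum(c1[basis] * rhs) > 1e-7) return(list(status = "infeasible"))
    # pivot remaining artificials out of the basis where possible
    arts <- art_col[art_col > 0L]
    active[arts] <- FALSE
    for (i in which(basis %in% arts)) {
      j <- which(active & abs(T0[i, ]) > eps)[1L]
      if (is.na(j)) next                      # redundant row
      piv <- T0[i, j]
      T0[i, ] <- T0[i, ] / piv
      rhs[i] <- rhs[i] / piv
      other <- setdiff(seq_len(m), i)
      f <- T0[other, j]
      T0[other, ] <- T0[other, , drop = FALSE] - outer(f, T0[i, ])
      rhs[other] <- rhs[other] - f * rhs[i]
      basis[i] <- j
    }
  }
  c2 <- numeric(ncols)
  c2[seq_len(n)] <- cost
  ph2 <- run_phase(T0, rhs, basis, c2, active)
  if (is.null(ph2)) return(list(status = "maxiter"))
  if (identical(ph2, "unbounded")) return(list(status = "unbounded"))
  x <- numeric(ncols)
  x[ph2$basis] <- ph2$rhs
  list(status = "optimal", x = x[seq_len(n)], value = sum(cost * x[seq_len(n)]))
}

solve_lp <- function(obj, Aeq = NULL, beq = NULL, lb, ub,
                     Aineq = NULL, bineq = NULL, maximize = TRUE,
                     n_iter = NULL) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite variable bounds")
  if (any(lb > ub + LP_EPS)) return(list(status = "infeasible"))

  # fold fixed variables (lb == ub) into the right-hand sides
  fixed <- (ub - lb) < 1e-12
  if (any(fixed)) {
    xf <- lb
    free <- !fixed
    if (!any(free)) {
      feas <- TRUE
      if (!is.null(Aeq) && NROW(Aeq) > 0L)
        feas <- feas && all(abs(matrix(Aeq, ncol = n) %*% xf - beq) <= 1e-8)
      if (!is.null(Aineq))
        feas <- feas && all(matrix(Aineq, ncol = n) %*% xf <= bineq + 1e-8)
      return(if (feas) list(status = "optimal", x = xf, value = sum(obj * xf))
             else list(status = "infeasible"))
    }
    sub <- function(A, b) {
      if (is.null(A) || NROW(A) == 0L) return(list(A = NULL, b = NULL))
      A <- matrix(A, ncol = n)
      list(A = A[, free, drop = FALSE],
           b = b - as.vector(A[, fixed, drop = FALSE] %*% xf[fixed]))
    }
    eq <- sub(Aeq, beq); iq <- sub(Aineq, bineq)
    res <- solve_lp(obj[free], eq$A, eq$b, lb[free], ub[free], iq$A, iq$b,
                    maximize, n_iter)
    if (res$status != "optimal") return(res)
    x <- xf; x[free] <- res$x
    return(list(status = "optimal", x = x, value = sum(obj * x)))
  }

  # shift z = x - lb >= 0; assemble rows: equalities, inequalities,
  # upper bounds z <= ub - lb
  rows <- list(); rhs <- numeric(); type <- character()
  if (!is.null(Aeq) && NROW(Aeq) > 0L) {
    Aeq <- matrix(Aeq, ncol = n)
    rows <- c(rows, list(Aeq))
    rhs <- c(rhs, beq - as.vector(Aeq %*% lb))
    type <- c(type, rep("eq", nrow(Aeq)))
  }
  if (!is.null(Aineq) && NROW(Aineq) > 0L) {
    Aineq <- matrix(Aineq, ncol = n)
    rows <- c(rows, list(Aineq))
    rhs <- c(rhs, bineq - as.vector(Aineq %*% lb))
    type <- c(type, rep("le", nrow(Aineq)))
  }
  rows <- c(rows, list(diag(n)))
  rhs <- c(rhs, ub - lb)
  type <- c(type, rep("le", n))
  A <- do.call(rbind, rows)

  cost <- if (maximize) -obj else obj
  res <- lp_simplex(cost, A, rhs, type,
                    max_iter = if (is.null(n_iter)) 10000L else n_iter)
  if (res$status != "optimal") return(res)
  x <- res$x + lb
  x <- pmin(pmax(x, lb), ub)
  list(status = "optimal", x = x, value = sum(obj * x))
}

# flux LP over a model: max/min obj over {Sv = 0, lb <= v <= ub}
flux_lp <- function(model, obj, maximize = TRUE) {
  S <- stoich_matrix(model)
  solve_lp(obj, Aeq = S, beq = rep(0, nrow(S)),
           lb = model$reactions$lower_bound, ub = model$reactions$upper_bound,
           maximize = maximize)
}

#' Flux balance analysis: maximal biomass flux
#'
#' Solves the flux balance LP `max v_biomass` subject to steady state
#' (`S v = 0`) and the model's flux bounds.
#'
#' @param model a [metabolic_model].
#' @return a list with `value` (the biomass optimum) and `fluxes`
#'   (named flux vector at one optimum).
#' @export
max_biomass <- function(model) {
  obj <- as.numeric(model$reactions$id == model$biomass_id)
  res <- flux_lp(model, obj, maximize = TRUE)
  if (res$status != "optimal")
    stop("flux balance LP is ", res$status, " for model '", model$id, "'")
  if (res$value <= LP_EPS)
    warning("maximal biomass flux is 0 for model '", model$id,
            "'; carving will not be constrained by functionality")
  list(value = res$value,
       fluxes = stats::setNames(res$x, model$reactions$id))
}

#' Flux variability analysis
#'
#' Per-reaction minimization and maximization of flux under steady state
#' and bounds, optionally with the biomass flux held at a fraction of its
#' optimum.
#'
#' @param model a [metabolic_model].
#' @param reactions reaction ids to analyse (default: all).
#' @param biomass_frac if > 0, add the constraint
#'   `v_biomass >= biomass_frac * max_biomass(model)`.
#' @return data frame with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, reactions = model$reactions$id,
                             biomass_frac = 0) {
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  Aineq <- NULL; bineq <- NULL
  if (biomass_frac > 0) {
    vmax <- max_biomass(model)$value
    bio <- as.numeric(model$reactions$id == model$biomass_id)
    Aineq <- matrix(-bio, nrow = 1L)
    bineq <- -biomass_frac * vmax
  }
  idx <- match(reactions, model$reactions$id)
  if (anyNA(idx)) stop("unknown reaction(s): ",
                       paste(reactions[is.na(idx)], collapse = ", "))
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(idx)) {
    obj <- numeric(length(lb)); obj[idx[k]] <- 1
    for (dir in c(FALSE, TRUE)) {
      res <- solve_lp(obj, Aeq = S, beq = rep(0, nrow(S)), lb = lb, ub = ub,
                      Aineq = Aineq, bineq = bineq, maximize = dir)
      if (res$status != "optimal")
        stop("FVA LP ", res$status, " for reaction ", reactions[k])
      out[[if (dir) "max" else "min"]][k] <- res$value
    }
  }
  out
}

#' Remove blocked reactions
#'
#' Drops every reaction whose flux-variability interval lies within
#' `[-tol, tol]` (it can carry no steady-state flux), then removes
#' metabolites no longer referenced. Idempotent. Sampling requires this:
#' blocked reactions make the flux polytope degenerate along their axes.
#'
#' @param model a [metabolic_model].
#' @param tol absolute flux tolerance below which a reaction counts as
#'   blocked.
#' @return a [metabolic_model] without blocked reactions.
#' @export
remove_blocked <- function(model, tol = 1e-9) {
  fv <- flux_variability(model)
  blocked <- fv$reaction[abs(fv$min) <= tol & abs(fv$max) <= tol]
  if (!length(blocked)) return(model)
  subset_model(model, setdiff(model$reactions$id, blocked), id = model$id)
}
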