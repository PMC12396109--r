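# In-code fixtures and independent oracles shared across the suite.

# Diamond network: two routes from A to C, one direct, one via B, each
# gene-labelled; 6 reactions, 4 metabolites, 3 genes.
diamond_model <- function(uptake = 10) {
  mets <- c("A", "B", "C", "BIO")
  rx <- data.frame(
    id = c("EX_A", "r1", "r2", "r3", "bio", "EX_bio"),
    name = c("A uptake", "A to B", "B to C", "A to C", "biomass", "biomass sink"),
    lower_bound = 0, upper_bound = c(uptake, 1000, 1000, 1000, 1000, 1000),
    gpr = c("", "g1", "g2", "g3", "", ""),
    subsystem = "", stringsAsFactors = FALSE)
  stoich <- list(EX_A = c(A = 1), r1 = c(A = -1, B = 1), r2 = c(B = -1, C = 1),
                 r3 = c(A = -1, C = 1), bio = c(C = -1, BIO = 1),
                 EX_bio = c(BIO = -1))
  metabolic_model("diamond", data.frame(id = mets, stringsAsFactors = FALSE),
                  rx, stoich, "bio")
}

# single free reaction v in [lb, ub], no mass-balance constraint
interval_model <- function(lb = 0, ub = 1) {
  rx <- data.frame(id = "v1", name = "v1", lower_bound = lb, upper_bound = ub,
                   gpr = "", subsystem = "", stringsAsFactors = FALSE)
  metabolic_model("interval",
                  data.frame(id = character(), name = character(),
                             compartment = character(), stringsAsFactors = FALSE),
                  rx, list(v1 = stats::setNames(numeric(0), character(0))), "v1")
}

# simple uptake -> conversion -> sink chain
chain_model <- function(n_internal = 1, uptake = 10) {
  mets <- paste0("M", seq_len(n_internal + 1L))
  ids <- c("EX_A", paste0("r", seq_len(n_internal)), "bio")
  stoich <- c(list(EX_A = c(M1 = 1)),
              stats::setNames(lapply(seq_len(n_internal), function(i)
                stats::setNames(c(-1, 1), mets[c(i, i + 1L)])),
                paste0("r", seq_len(n_internal))),
              list(bio = stats::setNames(-1, mets[n_internal + 1L])))
  rx <- data.frame(id = ids, name = ids, lower_bound = 0,
                   upper_bound = c(uptake, rep(1000, n_internal + 1L)),
                   gpr = c("", paste0("g", seq_len(n_internal)), ""),
                   subsystem = "", stringsAsFactors = FALSE)
  metabolic_model("chain", data.frame(id = mets, stringsAsFactors = FALSE),
                  rx, stoich, "bio")
}

# --- carve oracle: exhaustive enumeration over reaction subsets ----------
# Feasibility of a subset: an LP over the included reactions with
# biomass >= f_min * vmax and every included positively-scored reaction
# forced to carry >= eps absolute flux (direction enumerated for
# reversible ones). Objective evaluated directly from the scores.
subset_feasible <- function(model, keep, scores, config, vmax) {
  rx <- model$reactions
  n <- nrow(rx)
  lb <- ifelse(keep, rx$lower_bound, 0)
  ub <- ifelse(keep, rx$upper_bound, 0)
  eps <- config$flux_activation_eps
  act <- which(keep & scores > 0)
  rev_act <- act[rx$lower_bound[act] < 0 & rx$upper_bound[act] > 0]
  fwd_act <- setdiff(act, rev_act)
  S <- stoich_matrix(model)
  bio <- as.numeric(rx$id == model$biomass_id)
  check <- function(lb2, ub2) {
    res <- carveflux:::solve_lp(bio, Aeq = S, beq = rep(0, nrow(S)), lb = lb2, ub = ub2,
                    Aineq = matrix(-bio, 1), bineq = -config$f_min * vmax,
                    maximize = TRUE)
    res$status == "optimal"
  }
  lb2 <- lb; ub2 <- ub
  for (i in fwd_act) {
    if (rx$lower_bound[i] >= 0) lb2[i] <- max(lb2[i], eps)
    else ub2[i] <- min(ub2[i], -eps)
  }
  if (!length(rev_act)) return(check(lb2, ub2))
  # enumerate flux directions of included reversible supported reactions
  for (mask in 0:(2^length(rev_act) - 1L)) {
    lb3 <- lb2; ub3 <- ub2
    for (j in seq_along(rev_act)) {
      i <- rev_act[j]
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L))) lb3[i] <- max(lb3[i], eps)
      else ub3[i] <- min(ub3[i], -eps)
    }
    if (check(lb3, ub3)) return(TRUE)
  }
  FALSE
}

# exhaustive optimum; returns the optimal objective and EVERY reaction
# subset attaining it (equally optimal alternate subnetworks can exist)
carve_bruteforce <- function(model, scores, config = carve_config()) {
  rx <- model$reactions
  n <- nrow(rx)
  vmax <- max_biomass(model)$value
  bio_idx <- match(model$biomass_id, rx$id)
  obj_of <- function(keep) sum(ifelse(scores[keep] != 0, scores[keep],
                                      -config$penalty_nogpr))
  best <- list(); best_val <- -Inf
  for (mask in 0:(2^n - 1L)) {
    keep <- as.logical(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)))
    if (!keep[bio_idx]) next
    val <- obj_of(keep)
    if (val < best_val - 1e-9) next
    if (subset_feasible(model, keep, scores, config, vmax)) {
      if (val > best_val + 1e-9) {
        best_val <- val
        best <- list(rx$id[keep])
      } else {
        best <- c(best, list(rx$id[keep]))
      }
    }
  }
  list(optima = best, objective = best_val,
       reactions = if (length(best)) best[[1L]] else NULL)
}

set_in_optima <- function(ids, oracle) {
  any(vapply(oracle$optima, function(o) setequal(o, ids), logical(1)))
}

# --- RCC oracle: O(N^2 n) double loop ------------------------------------
rcc_bruteforce <- function(vals) {
  n <- ncol(vals)
  corr <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xi <- vals[, i]; xj <- vals[, j]
    si <- stats::sd(xi); sj <- stats::sd(xj)
    if (si == 0 || sj == 0) next
    corr[i, j] <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      ((length(xi) - 1) * si * sj)
  }
  sapply(seq_len(n), function(i) sum(abs(corr[i, ])))
}

# --- GSEA running-sum oracle: explicit double loop ------------------------
gsea_es_bruteforce <- function(scores, genes, set) {
  ord <- order(-scores, genes)
  g <- genes[ord]; s <- scores[ord]
  hit <- g %in% set
  nh <- sum(hit); n <- length(g)
  denom <- sum(abs(s[hit]))
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    if (hit[i]) run <- run + (if (denom > 0) abs(s[i]) / denom else 1 / nh)
    else run <- run - 1 / (n - nh)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# hypergeometric upper tail from first principles (choose() sums)
hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# counts table fixture writer for pipeline tests
write_pipeline_inputs <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model(fx$model, file.path(dir, "universal.xml"), "sbml")
  cnt <- data.frame(gene = rownames(fx$expr$counts), fx$expr$counts,
                    check.names = FALSE)
  utils::write.table(cnt, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$expr$design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
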