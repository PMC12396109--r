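#' Geweke stationarity z-score
#'
#' Compares the mean of an early segment of a chain with the mean of a
#' late segment: `z = (mean_first - mean_last) / sqrt(s2_first/n_first +
#' s2_last/n_last)`, where `s2` is an estimate of the spectral density of
#' the segment at frequency zero (a lag-window autocovariance sum with a
#' Bartlett window spanning 4% of the segment; set
#' `spectral = FALSE` for the plain sample variance). For a stationary
#' chain `z` is approximately standard normal; `|z| > 1.96` flags
#' non-stationarity. Two zero-variance segments give `z = 0`.
#'
#' @param chain numeric vector (length >= 20).
#' @param first_frac fraction of the chain in the early segment (default 0.1).
#' @param last_frac fraction in the late segment (default 0.5).
#' @param spectral use the spectral variance estimate (default) or the
#'   plain sample variance.
#' @return z statistic (dimensionless scalar).
#' @export
geweke_z <- function(chain, first_frac = 0.1, last_frac = 0.5,
                     spectral = TRUE) {
  n <- length(chain)
  if (n < 20) stop("Geweke diagnostic needs a chain of length >= 20, got ", n)
  stopifnot(first_frac > 0, last_frac > 0, first_frac + last_frac <= 1)
  a <- chain[seq_len(floor(first_frac * n))]
  b <- chain[seq.int(n - floor(last_frac * n) + 1L, n)]
  va <- spectrum0(a, spectral)
  vb <- spectrum0(b, spectral)
  if (va == 0 && vb == 0) return(0)
  denom <- sqrt(va / length(a) + vb / length(b))
  if (denom == 0) return(0)
  (mean(a) - mean(b)) / denom
}

# spectral density at frequency zero: Bartlett lag-window autocovariance
# sum with window span 4% of the segment length
spectrum0 <- function(x, spectral = TRUE) {
  n <- length(x)
  v <- stats::var(x) * (n - 1) / n
  if (!spectral || v == 0) return(stats::var(x))
  L <- max(1L, floor(0.04 * n))
  ac <- stats::acf(x, lag.max = L, type = "covariance", plot = FALSE,
                   demean = TRUE)$acf[, 1L, 1L]
  w <- 1 - seq_len(L) / (L + 1)
  max(ac[1L] + 2 * sum(w * ac[-1L]), 1e-300 * (ac[1L] > 0))
}

#' Raftery-Lewis required chain length
#'
#' Estimates how many (possibly thinned) samples a chain needs so that
#' the `q`-quantile is estimated within `+/- r` with probability `s`.
#' The chain is binarized at its empirical `q`-quantile, the smallest
#' thinning `k` at which a first-order two-state Markov chain is
#' preferred over a second-order one (by BIC) is found, and with the
#' thinned chain's transition probabilities `alpha` (0 to 1) and `beta`
#' (1 to 0):
#' \deqn{N = k \left\lceil \frac{(2-\alpha-\beta)\alpha\beta}
#'   {(\alpha+\beta)^3} \left(\frac{\Phi^{-1}((s+1)/2)}{r}\right)^2
#'   \right\rceil}
#' For an independent chain this reduces to the independence minimum
#' `qnorm((s+1)/2)^2 q (1-q) / r^2` (about 3746 at the defaults).
#'
#' @param chain numeric vector; must be at least the independence
#'   minimum long.
#' @param q quantile of interest (default 0.025).
#' @param r target accuracy on the quantile probability (default 0.005).
#' @param s coverage probability (default 0.95).
#' @return a list with `nmin` (required samples), `burnin`, `thin_k`
#'   (selected thinning) and `n_independence` (the iid minimum).
#' @export
raftery_lewis_nmin <- function(chain, q = 0.025, r = 0.005, s = 0.95) {
  phi <- stats::qnorm((s + 1) / 2)
  n_ind <- ceiling(phi^2 * q * (1 - q) / r^2)
  n <- length(chain)
  if (n < n_ind)
    stop("chain of length ", n, " is shorter than the Raftery-Lewis ",
         "independence minimum ", n_ind, " for q=", q, ", r=", r, ", s=", s)
  quant <- stats::quantile(chain, probs = q, names = FALSE, type = 7)
  dichot <- as.integer(chain <= quant)
  if (length(unique(dichot)) == 1L)  # constant / degenerate chain
    return(list(nmin = n_ind, burnin = 0L, thin_k = 1L, n_independence = n_ind))

  kthin <- 0L
  bic <- 1
  z <- dichot
  while (bic >= 0) {
    kthin <- kthin + 1L
    z <- dichot[seq.int(1L, n, by = kthin)]
    nz <- length(z)
    if (nz < 8L) break  # too short to test second-order dependence
    tri <- table(factor(z[1:(nz - 2L)], 0:1), factor(z[2:(nz - 1L)], 0:1),
                 factor(z[3:nz], 0:1))
    g2 <- 0
    for (i1 in 1:2) for (i2 in 1:2) for (i3 in 1:2) {
      o <- tri[i1, i2, i3]
      if (o == 0) next
      fitted <- sum(tri[i1, i2, ]) * sum(tri[, i2, i3]) / sum(tri[, i2, ])
      g2 <- g2 + 2 * o * log(o / fitted)
    }
    bic <- g2 - log(nz - 2) * 2
  }
  nz <- length(z)
  tran <- table(factor(z[1:(nz - 1L)], 0:1), factor(z[2:nz], 0:1))
  alpha <- tran[1, 2] / max(tran[1, 1] + tran[1, 2], 1L)
  beta <- tran[2, 1] / max(tran[2, 1] + tran[2, 2], 1L)
  if (alpha == 0 || beta == 0)  # one state (almost) absorbing at this thinning
    return(list(nmin = n_ind * kthin, burnin = 0L, thin_k = kthin,
                n_independence = n_ind))
  eps_b <- 0.001
  burn <- log(eps_b * (alpha + beta) / max(alpha, beta)) /
    log(abs(1 - alpha - beta))
  nmin <- ceiling((2 - alpha - beta) * alpha * beta * phi^2 /
                    ((alpha + beta)^3 * r^2)) * kthin
  list(nmin = as.integer(nmin), burnin = as.integer(ceiling(burn) * kthin),
       thin_k = kthin, n_independence = as.integer(n_ind))
}

#' Sample with convergence-driven stopping
#'
#' Draws hit-and-run batches and, after each batch, runs the Geweke test
#' on every reaction's chain and the Raftery-Lewis test on the monitored
#' reactions (the 50 highest-variance ones). Sampling stops once at
#' least `frac_crit` of the (non-constant) reactions pass `|z| < z_crit`
#' and the recorded chain is at least the largest monitored
#' Raftery-Lewis requirement — or at `config$max_samples`, in which case
#' `converged = FALSE` is reported rather than raised.
#'
#' @param model a [metabolic_model]; apply [remove_blocked()] first.
#' @param config a [sampler_config].
#' @param z_crit Geweke threshold (default 1.96).
#' @param frac_crit required fraction of converged reactions (default 0.95).
#' @param q,r,s Raftery-Lewis parameters (defaults 0.025, 0.005, 0.95).
#' @param n_monitor number of highest-variance reactions monitored by
#'   Raftery-Lewis (default 50).
#' @return list with `samples` (a `flux_samples`, convergence report
#'   attached as attribute `"convergence"`) and `report` (class
#'   `convergence_report`: per-reaction `geweke_z`, `fraction_converged`,
#'   `raftery_lewis_nmin`, `converged`, `n_samples_used`,
#'   `variance_estimator`).
#' @export
sample_until_converged <- function(model, config = sampler_config(),
                                   z_crit = 1.96, frac_crit = 0.95,
                                   q = 0.025, r = 0.005, s = 0.95,
                                   n_monitor = 50L) {
  state <- NULL
  samples <- NULL
  repeat {
    n_next <- min(config$batch_size,
                  config$max_samples - (if (is.null(samples)) 0L else samples$n_samples))
    samples <- sample_global(model, config, n = n_next, state = state)
    state <- attr(samples, "state")
    vals <- samples$values
    nrec <- nrow(vals)

    vars <- apply(vals, 2L, stats::var)
    varying <- vars > 1e-12
    zs <- rep(0, ncol(vals))
    names(zs) <- samples$reaction_ids
    zs[varying] <- apply(vals[, varying, drop = FALSE], 2L, geweke_z)
    frac_ok <- if (any(varying)) mean(abs(zs[varying]) < z_crit) else 1

    monitored <- order(vars, decreasing = TRUE)
    monitored <- monitored[varying[monitored]]
    monitored <- utils::head(monitored, n_monitor)
    phi <- stats::qnorm((s + 1) / 2)
    n_ind <- ceiling(phi^2 * q * (1 - q) / r^2)
    rl_max <- 0L
    rl_known <- nrec >= n_ind
    if (length(monitored) && rl_known)
      rl_max <- max(vapply(monitored, function(j)
        raftery_lewis_nmin(vals[, j], q, r, s)$nmin, numeric(1L)))

    converged <- rl_known && frac_ok >= frac_crit && nrec >= rl_max
    if (converged || nrec >= config$max_samples) {
      report <- structure(
        list(geweke_z = zs, fraction_converged = frac_ok,
             raftery_lewis_nmin = as.integer(rl_max), converged = converged,
             n_samples_used = nrec, variance_estimator = "spectral"),
        class = "convergence_report")
      attr(samples, "convergence") <- report
      return(list(samples = samples, report = report))
    }
  }
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> converged = %s; %d samples; %.1f%% of reactions pass |z| < 1.96; Raftery-Lewis N_min = %d\n",
              x$converged, x$n_samples_used, 100 * x$fraction_converged,
              x$raftery_lewis_nmin))
  invisible(x)
}
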