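as_samples <- function(vals, ids = colnames(vals)) {
  colnames(vals) <- ids
  carveflux:::flux_samples(vals, ids, "global", 1L, 1L)
}

test_that("correlation matrix follows the zero-variance convention", {
  v <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), k = c(5, 5, 5, 5))
  cc <- correlation_matrix(as_samples(v))
  expect_equal(cc["a", "b"], 1)
  expect_equal(unname(cc["k", ]), c(0, 0, 0))
  expect_equal(cc["k", "k"], 0)
  expect_equal(cc["a", "a"], 1)
  expect_equal(cc, t(cc))
  expect_error(correlation_matrix(as_samples(v[1:2, ])), "3 samples")
})

test_that("correlations match a brute-force double loop", {
  set.seed(14)
  v <- matrix(rnorm(400), 50, 8, dimnames = list(NULL, paste0("r", 1:8)))
  cc <- correlation_matrix(as_samples(v))
  for (i in 1:8) for (j in 1:8) {
    xi <- v[, i]; xj <- v[, j]
    ref <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      (49 * sd(xi) * sd(xj))
    expect_equal(unname(cc[i, j]), ref, tolerance = 1e-10)
  }
})

test_that("RCC attains its stated range endpoints", {
  # every sample has all fluxes equal -> all correlations 1 -> rcc = N
  base <- c(1, 5, 2, 8, 3)
  v <- cbind(r1 = base, r2 = base, r3 = base)
  expect_equal(unname(rcc_scores(correlation_matrix(as_samples(v)))),
               c(3, 3, 3))
  # constant-flux reaction -> rcc = 0
  v2 <- cbind(v, r4 = rep(2, 5))
  expect_equal(unname(rcc_scores(correlation_matrix(as_samples(v2)))[4]), 0)
})

test_that("independent reactions approach rcc = 1", {
  set.seed(8)
  v <- cbind(r1 = runif(10000), r2 = runif(10000))
  rcc <- rcc_scores(correlation_matrix(as_samples(v)))
  expect_equal(unname(rcc), c(1, 1), tolerance = 0.05)
})

test_that("rcc_scores equals the O(N^2 n) brute force", {
  set.seed(15)
  v <- matrix(rnorm(1000), 50, 20, dimnames = list(NULL, paste0("r", 1:20)))
  v[, 7] <- 3  # a constant column
  expect_equal(unname(rcc_scores(correlation_matrix(as_samples(v)))),
               rcc_bruteforce(v), tolerance = 1e-8)
})

test_that("mean fluxes are plain column statistics", {
  v <- cbind(r1 = rep(5, 4), r2 = c(0, 10, 0, 10))
  mf <- mean_fluxes(as_samples(v))
  expect_equal(mf$mean_flux, c(5, 5))
  expect_equal(mf$flux_sd, c(0, sd(c(0, 10, 0, 10))))
  set.seed(16)
  v2 <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("r", 1:4)))
  mf2 <- mean_fluxes(as_samples(v2))
  for (j in 1:4) {
    expect_equal(mf2$mean_flux[j], sum(v2[, j]) / 30, tolerance = 1e-10)
    expect_equal(mf2$flux_sd[j], sqrt(sum((v2[, j] - mean(v2[, j]))^2) / 29),
                 tolerance = 1e-10)
  }
})

score_pair <- function(va, vb) {
  a <- as_samples(va); b <- as_samples(vb)
  list(a = list(scores = reaction_scores(a), samples = a),
       b = list(scores = reaction_scores(b), samples = b))
}

test_that("identical conditions show no differential signal", {
  set.seed(17)
  v <- matrix(runif(300), 100, 3, dimnames = list(NULL, c("r1", "r2", "r3")))
  sp <- score_pair(v, v)
  d <- differential_reactions(sp$a, sp$b)
  expect_equal(d$delta_mean_flux, rep(0, 3))
  expect_true(all(d$p_value >= 0.999))
  expect_equal(d$delta_rcc, rep(0, 3))
})

test_that("degenerate constant columns follow the stated conventions", {
  va <- cbind(r1 = rep(5, 50)); vb <- cbind(r1 = rep(0, 50))
  d <- differential_reactions(score_pair(va, vb)$a, score_pair(va, vb)$b)
  expect_equal(d$delta_mean_flux, 5)
  expect_equal(d$p_value, 0)
})

test_that("a reaction absent from one model compares against zero flux", {
  set.seed(18)
  va <- cbind(r1 = runif(200, 4, 6), r2 = runif(200))
  vb <- cbind(r1 = runif(200, 4, 6))
  sp <- score_pair(va, vb)
  d <- differential_reactions(sp$a, sp$b)
  row <- d[d$reaction == "r2", ]
  expect_true(row$in_model_a); expect_false(row$in_model_b)
  expect_equal(row$delta_mean_flux, mean(va[, "r2"]))
  expect_lt(row$p_value, 1e-10)
  expect_error(
    differential_reactions(sp$a, score_pair(cbind(zz = runif(9)), vb)$a),
    "share no reactions")
})

test_that("well-separated uniforms match the closed-form Welch computation", {
  set.seed(19)
  va <- cbind(r1 = runif(1000, 4, 6))
  vb <- cbind(r1 = runif(1000, 0, 1))
  sp <- score_pair(va, vb)
  d <- differential_reactions(sp$a, sp$b, test_stride = 1)
  expect_equal(d$delta_mean_flux, mean(va) - mean(vb), tolerance = 1e-12)
  expect_equal(d$delta_mean_flux, 4.5, tolerance = 0.1)
  tt <- t.test(va[, 1], vb[, 1], var.equal = FALSE)
  expect_equal(d$p_value, tt$p.value, tolerance = 1e-12)
  expect_lt(d$p_value, 1e-10)
})

test_that("differential tables are antisymmetric and RCC is scale-free", {
  set.seed(20)
  va <- matrix(runif(300), 100, 3, dimnames = list(NULL, c("r1", "r2", "r3")))
  vb <- matrix(runif(300, 1, 3), 100, 3, dimnames = list(NULL, c("r1", "r2", "r3")))
  sp <- score_pair(va, vb)
  d_ab <- differential_reactions(sp$a, sp$b)
  d_ba <- differential_reactions(sp$b, sp$a)
  expect_equal(d_ab$delta_mean_flux, -d_ba$delta_mean_flux)
  expect_equal(d_ab$delta_rcc, -d_ba$delta_rcc)

  sc1 <- reaction_scores(as_samples(va))
  sc2 <- reaction_scores(as_samples(va * 7.5))
  expect_equal(sc2$rcc, sc1$rcc, tolerance = 1e-12)
  expect_equal(sc2$mean_flux, 7.5 * sc1$mean_flux, tolerance = 1e-12)
})

test_that("rcc histograms partition all reactions", {
  set.seed(21)
  v <- matrix(runif(500), 50, 10, dimnames = list(NULL, paste0("r", 1:10)))
  h <- rcc_histogram(reaction_scores(as_samples(v)), n_bins = 8)
  expect_equal(sum(h$count), 10)
  expect_equal(nrow(h), 8)
})
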