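test_that("the worked hypergeometric instance gives 76/15504", {
  universe <- paste0("g", 1:20)
  set5 <- paste0("g", 1:5)
  selected <- c(paste0("g", 1:4), "g10")  # overlap 4
  res <- ora(selected, universe, list(S = set5))
  expect_equal(res$p_value, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$overlap, 4)
})

test_that("degenerate ORA cases are certain events", {
  universe <- paste0("g", 1:12)
  expect_equal(ora(c("g1"), universe, list(S = c("g5", "g6")))$p_value, 1)
  expect_equal(ora(universe, universe, list(S = universe))$p_value, 1)
  expect_error(ora(c("gX"), universe, list(S = universe)), "outside the universe")
})

test_that("ORA matches first-principles tails on enumerable instances", {
  set.seed(25)
  for (rep in 1:25) {
    N <- sample(8:30, 1)
    universe <- paste0("g", seq_len(N))
    K <- sample(2:N, 1); n <- sample(1:N, 1)
    set <- sample(universe, K)
    selected <- sample(universe, n)
    k <- length(intersect(set, selected))
    res <- ora(selected, universe, list(S = set))
    expect_equal(res$p_value, hyper_tail(k, K, N, n), tolerance = 1e-12)
  }
})

test_that("BH adjustment is monotone and bounded", {
  set.seed(26)
  universe <- paste0("g", 1:30)
  coll <- lapply(1:8, function(i) sample(universe, sample(3:10, 1)))
  names(coll) <- paste0("set", 1:8)
  res <- ora(sample(universe, 10), universe, coll)
  expect_true(all(res$bh_adjusted_p >= res$p_value))
  expect_true(all(res$bh_adjusted_p <= 1))
  expect_equal(res$bh_adjusted_p,
               p.adjust(res$p_value, "BH"), tolerance = 1e-15)
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
  attr(sets, "descriptions") <- c(alpha = "first", beta = "second")
  p <- tempfile(fileext = ".gmt")
  write_gmt(sets, p)
  back <- read_gmt(p)
  expect_equal(back$alpha, sets$alpha)
  expect_equal(attr(back, "descriptions")[["beta"]], "second")
  writeLines("solo\tno members", p)
  expect_error(read_gmt(p), "without members")
})

test_that("GSEA enrichment scores match the double-loop oracle", {
  set.seed(27)
  genes <- paste0("g", 1:20)
  scores <- setNames(rnorm(20), genes)
  set5 <- sample(genes, 5)
  res <- gsea_preranked(scores, list(S = set5), n_perm = 1000, seed = 3)
  expect_equal(res$es, gsea_es_bruteforce(scores, genes, set5),
               tolerance = 1e-12)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("a set concentrated at the top is positively enriched", {
  genes <- paste0("g", 1:20)
  scores <- setNames(seq(2, -2, length.out = 20), genes)
  res <- gsea_preranked(scores, list(top = genes[1:3]), n_perm = 200, seed = 1)
  expect_gt(res$es, 0)
  expect_lt(res$p_value, 0.2)
})

test_that("the enrichment score is invariant to order-preserving transforms", {
  set.seed(28)
  genes <- paste0("g", 1:15)
  scores <- setNames(sort(runif(15), decreasing = TRUE), genes)
  set4 <- sample(genes, 4)
  es1 <- gsea_preranked(scores, list(S = set4), n_perm = 100, seed = 2)$es
  # monotone transform that also preserves the hit weights' proportions
  es2 <- gsea_preranked(scores * 3, list(S = set4), n_perm = 100, seed = 2)$es
  expect_equal(es1, es2, tolerance = 1e-12)
})

test_that("tiny sets are skipped with a warning", {
  genes <- paste0("g", 1:10)
  scores <- setNames(rnorm(10), genes)
  expect_warning(res <- gsea_preranked(scores, list(tiny = "g1"),
                                       n_perm = 100, seed = 1), "skipped")
  expect_equal(nrow(res), 0)
})

test_that("the running-sum implementation agrees with fgsea", {
  set.seed(29)
  genes <- paste0("g", 1:50)
  scores <- setNames(rnorm(50), genes)
  sets <- list(A = sample(genes, 8), B = sample(genes, 5))
  mine <- gsea_preranked(scores, sets, n_perm = 200, seed = 4)
  ref <- suppressWarnings(fgsea::fgsea(sets, scores, nPermSimple = 200,
                                       scoreType = "std"))
  for (nm in names(sets))
    expect_equal(mine$es[mine$set == nm], ref$ES[ref$pathway == nm],
                 tolerance = 1e-6, label = nm)
})
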