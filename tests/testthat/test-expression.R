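make_expr <- function(counts, conditions) {
  design <- data.frame(sample = colnames(counts), condition = conditions,
                       stringsAsFactors = FALSE)
  expression_matrix(counts, design)
}

test_that("CPM is direct per-column normalization", {
  cnt <- matrix(c(10, 90), 2, 1, dimnames = list(c("gA", "gB"), "s1"))
  expect_equal(as.vector(compute_cpm(cnt)), c(1e5, 9e5))

  cnt2 <- rbind(cnt, gC = 0)
  expect_equal(unname(compute_cpm(cnt2)["gC", ]), 0)

  set.seed(3)
  rc <- matrix(rpois(300, 40), 50, 6,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  expect_equal(unname(colSums(compute_cpm(rc))), rep(1e6, 6), tolerance = 1e-12)

  cnt3 <- cbind(cnt, s2 = c(0, 0))
  expect_error(compute_cpm(cnt3), "s2")
})

test_that("the default filter keeps and drops genes per the documented rule", {
  # 2-sample condition, libraries 1000 each: CPM cutoff = 10/1000*1e6 = 1e4
  cnt <- matrix(c(12, 988, 15, 985), 2, 2,
                dimnames = list(c("gk", "gfill"), c("s1", "s2")))
  ex <- make_expr(cnt, c("c1", "c1"))
  kept <- filter_expressed(ex, "c1")
  expect_true("gk" %in% kept)   # 12000 and 15000 CPM; total 27 >= 15

  cnt2 <- matrix(c(12, 988, 0, 1000), 2, 2,
                 dimnames = list(c("gk", "gfill"), c("s1", "s2")))
  ex2 <- make_expr(cnt2, c("c1", "c1"))
  expect_false("gk" %in% filter_expressed(ex2, "c1"))  # only 1 of 2 samples pass

  cnt3 <- rbind(cnt, gzero = c(0, 0))
  ex3 <- make_expr(cnt3, c("c1", "c1"))
  for (p in list(filter_params(), filter_params(0, 0, 0.5),
                 filter_params(method = "raw_count"),
                 filter_params(method = "cpm")))
    expect_false("gzero" %in% filter_expressed(ex3, "c1", p))
})

test_that("unknown conditions are rejected with the available labels", {
  cnt <- matrix(10, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ex <- make_expr(cnt, c("c1", "c2"))
  expect_error(filter_expressed(ex, "nope"), "c1, c2")
})

test_that("filtering is monotone in min_count and order-invariant", {
  set.seed(9)
  cnt <- matrix(rnbinom(600, mu = 30, size = 2), 100, 6,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  ex <- make_expr(cnt, rep("c1", 6))
  kept10 <- filter_expressed(ex, "c1", filter_params(min_count = 10))
  kept30 <- filter_expressed(ex, "c1", filter_params(min_count = 30))
  expect_true(all(kept30 %in% kept10))

  perm_s <- sample(ncol(cnt)); perm_g <- sample(nrow(cnt))
  ex_perm <- make_expr(cnt[perm_g, perm_s], rep("c1", 6))
  expect_identical(filter_expressed(ex_perm, "c1"), filter_expressed(ex, "c1"))

  all_kept <- filter_expressed(ex, "c1", filter_params(0, 0, 0.0001))
  expect_setequal(all_kept, rownames(cnt)[rowSums(cnt) > 0])
})

test_that("expression matrices validate their invariants", {
  cnt <- matrix(1, 2, 2, dimnames = list(c("g1", "g1"), c("s1", "s2")))
  expect_error(make_expr(cnt, c("a", "a")), "duplicate gene")
  cnt2 <- matrix(-1, 1, 1, dimnames = list("g1", "s1"))
  expect_error(make_expr(cnt2, "a"), "non-negative")
  cnt3 <- matrix(1.5, 1, 1, dimnames = list("g1", "s1"))
  expect_error(make_expr(cnt3, "a"), "integers")
  cnt4 <- matrix(1, 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_error(expression_matrix(cnt4, data.frame(sample = "s1", condition = "a")),
               "missing from design")
})

test_that("count and design TSVs round-trip through read_expression", {
  fx <- two_condition_fixture(seed = 2)
  td <- tempfile(); dir.create(td)
  write_pipeline_inputs(fx, td)
  ex <- read_expression(file.path(td, "counts.tsv"), file.path(td, "design.tsv"))
  expect_equal(ex$counts, fx$expr$counts)
  expect_equal(ex$design, fx$expr$design)
})
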