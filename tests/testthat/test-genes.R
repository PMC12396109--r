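test_that("the gene-to-reaction map mirrors GPR membership", {
  m <- diamond_model()
  m$reactions$gpr[m$reactions$id == "r2"] <- "g1 and g2"
  m <- metabolic_model(m$id, m$metabolites, m$reactions, m$stoich, m$biomass_id)
  mp <- gene_reaction_map(m)
  expect_setequal(mp$g1, c("r1", "r2"))
  expect_setequal(mp$g2, "r2")
  expect_setequal(mp$g3, "r3")
  # GPR-less reactions contribute to no gene
  expect_false(any(c("EX_A", "bio", "EX_bio") %in% unlist(mp)))
  # genes of the universe absent from the model map to the empty set
  mp2 <- gene_reaction_map(m, universe = c("g9", m$genes))
  expect_identical(mp2$g9, character())
})

test_that("the parsed-tree map agrees with a token-scan oracle", {
  m <- toy_universal_model(toy_spec(n_linear = 4, n_branches = 2, seed = 9,
                                    genes_per_reaction = 2,
                                    branch_span = "random"))
  mp <- gene_reaction_map(m)
  for (g in m$genes) {
    toks <- lapply(m$reactions$gpr, function(txt)
      regmatches(txt, gregexpr("[^\\s()]+", txt, perl = TRUE))[[1]])
    ref <- m$reactions$id[vapply(toks, function(tk) g %in% tk, logical(1))]
    expect_setequal(mp[[g]], ref)
  }
})

fake_scores <- function() {
  structure(data.frame(reaction = c("r1", "r2", "r3"),
                       rcc = c(2.5, 1.0, 3.0),
                       mean_flux = c(5, -2, 0.5),
                       flux_sd = c(1, 1, 1), n_samples = 100,
                       stringsAsFactors = FALSE),
            class = c("reaction_scores", "data.frame"))
}

fake_diff <- function() {
  structure(data.frame(reaction = c("r1", "r2", "r3"),
                       delta_mean_flux = c(0.2, -0.9, 0.7),
                       p_value = c(0.5, 0.001, 0.01),
                       delta_rcc = c(1, -2, 0.5),
                       in_model_a = TRUE, in_model_b = TRUE,
                       stringsAsFactors = FALSE),
            class = c("differential_reactions", "data.frame"))
}

test_that("projection aggregates by max magnitude with sign by default", {
  mapping <- list(gA = c("r1"), gB = c("r1", "r2"), gC = c("r2", "r3"))
  gs <- project_scores(fake_scores(), mapping)
  # single-reaction gene inherits the reaction values unchanged
  expect_equal(gs$rcc_gene[gs$gene == "gA"], 2.5)
  expect_equal(gs$usage_gene[gs$gene == "gA"], 5)
  expect_equal(gs$usage_gene[gs$gene == "gB"], 5)
  expect_equal(gs$usage_gene[gs$gene == "gC"], -2)

  d <- project_scores(fake_diff(), mapping)
  expect_equal(d$delta_usage_gene[d$gene == "gB"], -0.9)
  expect_equal(d$best_reaction[d$gene == "gB"], "r2")
  expect_equal(d$p_value[d$gene == "gB"], 0.001)
})

test_that("sum and mean aggregations match brute-force accumulation", {
  set.seed(23)
  mapping <- list(g1 = c("r1", "r2", "r3"), g2 = c("r2"))
  sc <- fake_scores()
  gsum <- project_scores(sc, mapping, aggregation = "sum")
  expect_equal(gsum$rcc_gene[gsum$gene == "g1"], sum(sc$rcc))
  expect_equal(gsum$usage_gene[gsum$gene == "g1"], sum(sc$mean_flux))
  gmean <- project_scores(sc, mapping, aggregation = "mean")
  expect_equal(gmean$usage_gene[gmean$gene == "g1"], mean(sc$mean_flux))
  expect_error(project_scores(sc, mapping, aggregation = "median"))
})

test_that("projection never invents genes and respects the RCC bound", {
  fx <- two_condition_fixture(seed = 3)
  m <- remove_blocked(carve(fx$model, score_reactions(fx$model, fx$model$genes)))
  s <- sample_global(m, sampler_config(seed = 31), n = 1000)
  sc <- reaction_scores(s)
  gs <- project_scores(sc, gene_reaction_map(m))
  expect_true(all(gs$gene %in% fx$model$genes))
  expect_true(all(gs$rcc_gene <= max(sc$rcc) + 1e-12))
  long <- gene_reaction_long(sc, gene_reaction_map(m))
  expect_true(all(long$reaction %in% sc$reaction))
})

test_that("signature selection applies both thresholds and the direction", {
  gs <- structure(data.frame(
    gene = c("gKeep", "gWeakP", "gNeg", "gSmall"),
    rcc_gene = 1, delta_usage_gene = c(0.7, 0.7, -0.7, 0.3),
    best_reaction = "r", p_value = c(0.01, 0.2, 0.01, 0.01),
    n_reactions = 1, reaction_ids = "r", stringsAsFactors = FALSE),
    class = c("gene_scores", "data.frame"))
  expect_equal(select_signature_genes(gs), "gKeep")
  expect_equal(select_signature_genes(gs, direction = "b_over_a"), "gNeg")
  # loosening either threshold never removes a kept gene
  base <- select_signature_genes(gs)
  expect_true(all(base %in% select_signature_genes(gs, delta_threshold = 0.2)))
  expect_true(all(base %in% select_signature_genes(gs, p_threshold = 0.5)))
})
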