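test_that("max_biomass propagates bounds through linear networks", {
  expect_equal(max_biomass(chain_model(1))$value, 10)
  m <- chain_model(2, uptake = 3.5)
  expect_equal(max_biomass(m)$value, 3.5)

  closed <- diamond_model()
  closed$reactions$upper_bound[closed$reactions$id == "EX_A"] <- 0
  expect_warning(res <- max_biomass(closed), "0")
  expect_equal(res$value, 0)
})

test_that("max_biomass on the diamond equals the enumeration optimum", {
  m <- diamond_model()
  expect_equal(max_biomass(m)$value, 10)
  # exhaustive check over split fractions of the two A->C routes
  best <- max(vapply(seq(0, 1, by = 0.05), function(f) {
    v <- c(EX_A = 10, r1 = 10 * f, r2 = 10 * f, r3 = 10 * (1 - f),
           bio = 10, EX_bio = 10)
    if (all(v <= m$reactions$upper_bound[match(names(v), m$reactions$id)]))
      v[["bio"]] else 0
  }, numeric(1)))
  expect_equal(max_biomass(m)$value, best)
})

test_that("evidence scores follow the GPR evaluation rule", {
  m <- diamond_model()
  s <- score_reactions(m, c("g2"))
  expect_equal(unname(s[c("EX_A", "r1", "r2", "r3", "bio")]),
               c(0, -1, 1, -1, 0))
  s2 <- score_reactions(m, c("g2"), carve_config(penalty_absent = 2.5))
  expect_equal(unname(s2[["r1"]]), -2.5)
  # "g1 or g2" style rules: any present isozyme suffices
  m$reactions$gpr[m$reactions$id == "r1"] <- "g1 or g2"
  expect_equal(unname(score_reactions(m, "g2")[["r1"]]), 1)
  # ids outside the model namespace are ignored with a message
  expect_message(score_reactions(m, c("g2", "not_a_gene")), "ignored")
})

test_that("carving the diamond keeps exactly the supported functional route", {
  m <- diamond_model()
  carved <- carve(m, score_reactions(m, c("g1", "g2")))
  expect_setequal(carved$reactions$id, c("EX_A", "r1", "r2", "bio", "EX_bio"))
  rep <- attr(carved, "carve_report")
  expect_false(rep$included[rep$reaction == "r3"])
  # functionality
  expect_gte(max_biomass(carved)$value, 0.1 * 10 - 1e-6)
})

test_that("carving with full or empty evidence matches the enumeration oracle", {
  m <- diamond_model()
  cfg <- carve_config()
  for (expressed in list(c("g1", "g2", "g3"), character())) {
    sc <- score_reactions(m, expressed, cfg)
    carved <- carve(m, sc, cfg)
    oracle <- carve_bruteforce(m, sc, cfg)
    expect_equal(attr(carved, "objective"), oracle$objective, tolerance = 1e-6)
    expect_true(set_in_optima(carved$reactions$id, oracle))
  }
})

test_that("MILP carving equals subset enumeration on seeded random toys", {
  cfg <- carve_config()
  for (seed in 1:6) {
    m <- toy_random_model(seed)
    if (nrow(m$reactions) > 9) next
    set.seed(seed + 100)
    expressed <- sample(m$genes, max(1, floor(length(m$genes) * 0.6)))
    sc <- score_reactions(m, expressed, cfg)
    carved <- carve(m, sc, cfg)
    oracle <- carve_bruteforce(m, sc, cfg)
    expect_equal(attr(carved, "objective"), oracle$objective,
                 tolerance = 1e-6, label = paste("seed", seed))
    expect_true(set_in_optima(carved$reactions$id, oracle),
                label = paste("seed", seed))
  }
})

test_that("carved models are true submodels and stay functional", {
  cfg <- carve_config()
  for (seed in c(2, 4, 8)) {
    m <- toy_random_model(seed)
    vmax <- max_biomass(m)$value
    set.seed(seed)
    expressed <- sample(m$genes, ceiling(length(m$genes) / 2))
    carved <- carve(m, score_reactions(m, expressed, cfg), cfg)
    expect_true(all(carved$reactions$id %in% m$reactions$id))
    idx <- match(carved$reactions$id, m$reactions$id)
    expect_equal(carved$reactions$lower_bound, m$reactions$lower_bound[idx])
    expect_equal(carved$reactions$upper_bound, m$reactions$upper_bound[idx])
    expect_gte(max_biomass(carved)$value, cfg$f_min * vmax - 1e-6)
  }
})

test_that("adding an expressed gene never decreases the carve objective", {
  cfg <- carve_config()
  m <- toy_universal_model(toy_spec(n_linear = 3, n_branches = 2, seed = 3,
                                    branch_span = "random"))
  set.seed(33)
  expressed <- sample(m$genes, 2)
  obj1 <- attr(carve(m, score_reactions(m, expressed, cfg), cfg), "objective")
  for (g in setdiff(m$genes, expressed)) {
    obj2 <- attr(carve(m, score_reactions(m, c(expressed, g), cfg), cfg),
                 "objective")
    expect_gte(obj2, obj1 - 1e-9)
  }
})

test_that("infeasible functionality demands raise an informative error", {
  m <- diamond_model()
  m$reactions$upper_bound[m$reactions$id == "bio"] <- 0.5
  # universal optimum is 0.5; f_min = 1 requires full 0.5 through biomass
  sc <- score_reactions(m, m$genes)
  carved <- carve(m, sc, carve_config(f_min = 1))
  expect_gte(max_biomass(carved)$value, 0.5 - 1e-6)
})

test_that("remove_blocked drops dead ends and agrees with the FVA oracle", {
  m <- diamond_model()
  # dangling reaction producing a dead-end metabolite
  m2 <- metabolic_model(
    "dangling",
    rbind(m$metabolites, data.frame(id = "DEAD", name = "DEAD", compartment = "c")),
    rbind(m$reactions,
          data.frame(id = "r_dead", name = "r_dead", lower_bound = 0,
                     upper_bound = 1000, gpr = "", subsystem = "")),
    c(m$stoich, list(r_dead = c(A = -1, DEAD = 1))), "bio")
  cleaned <- remove_blocked(m2)
  expect_false("r_dead" %in% cleaned$reactions$id)
  expect_false("DEAD" %in% cleaned$metabolites$id)
  # fully coupled chain is untouched; idempotent
  ch <- chain_model(2)
  expect_equal(remove_blocked(ch)$reactions$id, ch$reactions$id)
  expect_equal(remove_blocked(cleaned)$reactions$id, cleaned$reactions$id)
  # blocked set equals the per-reaction min/max enumeration
  for (seed in c(1, 5)) {
    tm <- toy_random_model(seed)
    fv <- flux_variability(tm)
    blocked <- fv$reaction[abs(fv$min) <= 1e-9 & abs(fv$max) <= 1e-9]
    expect_setequal(remove_blocked(tm)$reactions$id,
                    setdiff(tm$reactions$id, blocked))
  }
})
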