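model_equal <- function(a, b) {
  expect_setequal(a$reactions$id, b$reactions$id)
  ib <- match(a$reactions$id, b$reactions$id)
  expect_equal(a$reactions$lower_bound, b$reactions$lower_bound[ib])
  expect_equal(a$reactions$upper_bound, b$reactions$upper_bound[ib])
  expect_equal(a$metabolites$id[order(a$metabolites$id)],
               b$metabolites$id[order(b$metabolites$id)])
  for (rid in a$reactions$id) {
    sa <- a$stoich[[rid]]; sb <- b$stoich[[rid]]
    expect_equal(sa[order(names(sa))], sb[order(names(sb))], label = rid)
  }
  # GPRs equivalent as parsed trees
  for (rid in a$reactions$id) {
    ga <- a$reactions$gpr[a$reactions$id == rid]
    gb <- b$reactions$gpr[b$reactions$id == rid]
    expect_equal(unclass(parse_gpr(ga)), unclass(parse_gpr(gb)), label = rid)
  }
  expect_equal(a$biomass_id, b$biomass_id)
  expect_equal(a$genes, b$genes)
}

test_that("the diamond fixture round-trips through SBML and JSON", {
  m <- diamond_model()
  expect_equal(nrow(m$reactions), 6)
  expect_equal(nrow(m$metabolites), 4)
  expect_equal(length(m$genes), 3)

  for (dialect in c("sbml", "json")) {
    path <- tempfile(fileext = if (dialect == "json") ".json" else ".xml")
    write_model(m, path, dialect)
    m2 <- read_model(path, dialect)
    model_equal(m, m2)
  }
})

test_that("SBML and JSON serializations of one model read back identically", {
  m <- toy_universal_model(toy_spec(n_linear = 3, n_branches = 2, seed = 5,
                                    genes_per_reaction = 2,
                                    branch_span = "random"))
  p1 <- tempfile(fileext = ".xml"); p2 <- tempfile(fileext = ".json")
  write_model(m, p1); write_model(m, p2)
  model_equal(read_model(p1), read_model(p2))
})

test_that("unicode reaction names and subsystems survive a round-trip", {
  m <- diamond_model()
  m$reactions$name[2] <- "conversion α→β"
  m$reactions$subsystem[2] <- "glycolysis & friends"
  for (dialect in c("sbml", "json")) {
    path <- tempfile(fileext = if (dialect == "json") ".json" else ".xml")
    write_model(m, path, dialect)
    m2 <- read_model(path, dialect)
    expect_equal(m2$reactions$name[m2$reactions$id == "r1"],
                 "conversion α→β")
    expect_equal(m2$reactions$subsystem[m2$reactions$id == "r1"],
                 "glycolysis & friends")
  }
})

test_that("a model without GPRs has an empty gene set", {
  m <- chain_model(1)
  m$reactions$gpr <- ""
  m <- metabolic_model(m$id, m$metabolites, m$reactions, m$stoich, m$biomass_id)
  expect_identical(m$genes, character())
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  expect_identical(read_model(path)$genes, character())
})

test_that("files without an objective demand an explicit biomass id", {
  m <- diamond_model()
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  doc <- jsonlite::read_json(path)
  doc$reactions <- lapply(doc$reactions, function(r) {
    r$objective_coefficient <- 0; r
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(path), "--biomass")
  m2 <- read_model(path, biomass = "bio")
  expect_equal(m2$biomass_id, "bio")
})

test_that("unparseable files raise a format error naming the element", {
  p <- tempfile(fileext = ".json")
  writeLines('{"metabolites": []}', p)
  expect_error(read_model(p), "reactions")
  p2 <- tempfile(fileext = ".xml")
  writeLines("<sbml><model>", p2)
  expect_error(read_model(p2), "cannot parse SBML")
  expect_error(read_model(tempfile()), "not found")
})

test_that("written SBML is accepted and agreed with by an independent COBRA reader", {
  m <- diamond_model()
  path <- tempfile(fileext = ".xml")
  write_model(m, path, "sbml")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, cobra",
    "m = cobra.io.read_sbml_model(sys.argv[1])",
    "rx = sorted(r.id for r in m.reactions)",
    "print(len(m.reactions), len(m.metabolites), len(m.genes))",
    "print(','.join(rx))",
    "r1 = m.reactions.get_by_id('r1')",
    "print(r1.lower_bound, r1.upper_bound, r1.gene_reaction_rule)"), script)
  out <- suppressWarnings(
    system2("python", c(script, path), stdout = TRUE, stderr = FALSE))
  expect_equal(out[1], "6 4 3")
  expect_equal(out[2], "EX_A,EX_bio,bio,r1,r2,r3")
  expect_equal(out[3], "0.0 1000.0 g1")
})
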