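test_that("guild construction enforces its structural invariants", {
  g <- single_guild()
  expect_s3_class(g, "guild_model")
  expect_equal(nrow(g$reactions), 2)
  expect_equal(unname(g$exchange), "s")

  # exactly one biomass reaction, which must exist
  expect_error(build_guild("X", list(
    R1 = list(stoich = c(a = -1), lb = 0, ub = 1)), c(a = ""),
    "NOPE", character()), "biomass")

  # lb > ub is rejected
  expect_error(build_guild("X", list(
    R1 = list(stoich = c(a = -1), lb = 2, ub = 1)), c(a = ""),
    "R1", character()), "lower bound exceeds")

  # an exchange touching two metabolites is rejected
  expect_error(build_guild("X", list(
    R1 = list(stoich = c(a = -1, b = 1), lb = 0, ub = 1),
    G = list(stoich = c(b = -1), lb = 0, ub = 1)),
    c(a = "", b = ""), "G", c(R1 = "a")), "exactly one metabolite")

  # uptake-written exchange columns are normalized to secretion-positive
  g2 <- build_guild("X", list(
    EX_a = list(stoich = c(a = 1), lb = 0, ub = 7),  # written as uptake
    G = list(stoich = c(a = -1), lb = 0, ub = Inf)),
    c(a = ""), "G", c(EX_a = "a"))
  i <- match("EX_a", g2$reactions$id)
  expect_equal(as.numeric(g2$S["a", "EX_a"]), -1)
  expect_equal(g2$reactions$lb[i], -7)
  expect_equal(g2$reactions$ub[i], 0)

  # missing bounds default to the +/-1000 convention with a warning
  expect_warning(
    g3 <- build_guild("X", list(
      R1 = list(stoich = c(a = -1), lb = NA, ub = NA),
      G = list(stoich = c(a = 1), lb = 0, ub = 10)),
      c(a = ""), "G", character()),
    "defaulting")
  expect_equal(g3$reactions$lb[g3$reactions$id == "R1"], -1000)
})

test_that("community assembly pools exchanges and rejects conflicts", {
  # two toy guilds sharing one metabolite -> 1 pool metabolite,
  # 2 guild exchanges, 1 uptake, 1 export
  a <- build_guild("A", list(
    EX_ac = list(stoich = c(ac = -1), lb = 0, ub = Inf),
    G = list(stoich = c(ac = 1), lb = 0, ub = 5)),
    c(ac = "C2"), "G", c(EX_ac = "ac"))
  b <- build_guild("B", list(
    EX_ac = list(stoich = c(ac = -1), lb = -5, ub = 0),
    G = list(stoich = c(ac = -2), lb = 0, ub = Inf)),
    c(ac = "C2"), "G", c(EX_ac = "ac"))
  m <- assemble_community(list(a, b))
  expect_equal(m$com_mets, "ac")
  expect_equal(length(m$uptake_bounds), 1)
  expect_equal(length(m$export_bounds), 1)
  expect_equal(sum(vapply(m$guilds, function(g) length(g$exchange), 0L)), 2)

  expect_error(assemble_community(list(a, a)), "duplicate guild_id")

  b2 <- b
  b2$metabolites$formula <- "C3"
  expect_error(assemble_community(list(a, b2)), "conflicting formulas")

  # namespacing is injective across guilds
  ids <- community_reaction_ids(m)
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("validation reports sizes, overlaps, orphans and imbalances", {
  m <- make_toy_community(toy_community_spec())
  v <- validate_community(m)
  expect_equal(v$reaction_count,
               sum(vapply(m$guilds, function(g) nrow(g$reactions), 0L)))
  expect_length(v$unbalanced_reactions, 0)
  expect_length(v$orphan_pool_metabolites, 0)

  # intersection counts equal brute-force set algebra
  sets <- lapply(m$guilds, function(g) unique(unname(g$exchange)))
  for (pair in names(v$shared_exchange_counts$pairwise)) {
    gs <- strsplit(pair, ":")[[1]]
    expect_equal(v$shared_exchange_counts$pairwise[[pair]],
                 length(intersect(sets[[gs[1]]], sets[[gs[2]]])))
  }
  expect_equal(v$shared_exchange_counts$all_guilds,
               length(Reduce(intersect, sets)))
  # triple intersection can never exceed any pairwise intersection
  expect_true(all(v$shared_exchange_counts$all_guilds <=
                  unlist(v$shared_exchange_counts$pairwise)))

  # an orphan pool metabolite is reported, never raised
  m2 <- m
  m2$com_mets <- c(m2$com_mets, "ghost")
  m2$uptake_bounds <- c(m2$uptake_bounds, ghost = 0)
  m2$export_bounds <- c(m2$export_bounds, ghost = 0)
  expect_equal(validate_community(m2)$orphan_pool_metabolites, "ghost")

  # a deliberately carbon-imbalanced internal reaction is caught
  g <- build_guild("X", list(
    BAD = list(stoich = c(a = -1, b = 2), lb = 0, ub = 1),
    G = list(stoich = c(b = -1), lb = 0, ub = 1),
    EX_a = list(stoich = c(a = -1), lb = -1, ub = 0)),
    c(a = "C", b = "C"), "G", c(EX_a = "a"))
  v2 <- validate_community(assemble_community(list(g)))
  expect_equal(v2$unbalanced_reactions, "X__BAD")

  # structural loop candidates: a closed 2-cycle is detected
  v3 <- validate_community(loop_community())
  expect_true(any(vapply(v3$loop_candidates, function(l)
    setequal(l, c("L__CYC1", "L__CYC2")), TRUE)))
})

test_that("SBML round-trip preserves structure, bounds and stoichiometry", {
  m <- make_toy_community(toy_community_spec())
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_community_sbml(f)
  expect_equal(length(m2$com_mets), length(m$com_mets))
  for (gn in names(m$guilds)) {
    a <- m$guilds[[gn]]
    b <- m2$guilds[[gn]]
    expect_setequal(b$reactions$id, a$reactions$id)
    i <- match(a$reactions$id, b$reactions$id)
    expect_equal(b$reactions$lb[i], a$reactions$lb, tolerance = 1e-9)
    expect_equal(b$reactions$ub[i], a$reactions$ub, tolerance = 1e-9)
    expect_equal(as.matrix(b$S)[rownames(a$S), a$reactions$id],
                 as.matrix(a$S), tolerance = 1e-9)
    expect_equal(b$biomass, a$biomass)
  }
  # bounds survive into the solved model
  expect_equal(maximize_growth(m2)$mu, maximize_growth(m)$mu,
               tolerance = 1e-5)

  # guild-level round trip
  fg <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m$guilds$SRB, fg)
  g2 <- load_guild_model(fg, "SRB")
  expect_equal(nrow(g2$reactions), nrow(m$guilds$SRB$reactions))
  expect_mapequal(g2$exchange, m$guilds$SRB$exchange)
})

test_that("SBML reader flags malformed input and missing biomass", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model><oops", f)
  expect_error(load_guild_model(f, "X"), "malformed SBML")

  # a model with no objective and no biomass-like reaction id
  g <- build_guild("X", list(
    EX_a = list(stoich = c(a = -1), lb = -1, ub = 0),
    CONSUME = list(stoich = c(a = -1), lb = 0, ub = 1)),
    c(a = ""), "CONSUME", c(EX_a = "a"))
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(g, f2)
  doc <- xml2::read_xml(f2)
  xml2::xml_remove(xml2::xml_find_all(doc, ".//*[local-name()='listOfObjectives']"))
  xml2::write_xml(doc, f2)
  expect_error(load_guild_model(f2, "X"), "biomass")
  # but an explicit id resolves it
  expect_equal(load_guild_model(f2, "X", biomass = "CONSUME")$biomass,
               "CONSUME")
})
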