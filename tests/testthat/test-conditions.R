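test_that("wastewater conversion applies the default yield and VFA share", {
  spec <- cod_to_substrate_rates(cod_load = 103, sulfate_load = 10,
                                 sulfide_load = 5)
  expect_s3_class(spec, "condition_spec")
  expect_false(spec$zero_condition)
  expect_equal(spec$cell_yield, 0.15)
  # the defaults put the C4:C2 molar uptake ratio at the low-season
  # baseline of 1.29
  expect_equal(spec$community_rates[["but"]] / spec$community_rates[["ac"]],
               1.29, tolerance = 1e-9)

  expect_error(cod_to_substrate_rates(100, vfa_fraction = 1.3),
               "vfa_fraction")
  expect_error(cod_to_substrate_rates(100, vfa_molar_split = c(pyruvate = 1)),
               "unknown VFA")
  z <- cod_to_substrate_rates(0)
  expect_true(z$zero_condition)
  expect_length(z$community_rates, 0)
})

test_that("seasonal fold-changes shift the C4:C2 ratio from 1.29 to 1.54", {
  low <- cod_to_substrate_rates(103)
  r_low <- low$community_rates[["but"]] / low$community_rates[["ac"]]
  # butyrate mass load x1.56 and acetate x1.30 between seasons; the
  # specific-rate ratio scales by the same factors
  r_high <- r_low * 1.56 / 1.30
  expect_equal(round(r_low, 2), 1.29)
  expect_equal(round(r_high, 2), 1.55)
  expect_equal(r_high, 1.548, tolerance = 1e-3)
  # and the shipped presets encode exactly that pair
  pl <- condition_preset("L-OLR")
  ph <- condition_preset("H-OLR")
  expect_equal(pl$community_rates[["but"]] / pl$community_rates[["ac"]],
               1.29, tolerance = 0.005)
  expect_equal(ph$community_rates[["but"]] / ph$community_rates[["ac"]],
               1.548, tolerance = 0.005)
})

test_that("rate arithmetic is linear in the loads at fixed cell mass", {
  a <- cod_to_substrate_rates(103, sulfate_load = 10, sulfide_load = 4)
  b <- cod_to_substrate_rates(103, sulfate_load = 20, sulfide_load = 8)
  expect_equal(b$community_rates[["so4"]], 2 * a$community_rates[["so4"]])
  expect_equal(b$community_rates[["h2s"]], 2 * a$community_rates[["h2s"]])
  # VFA specific rates are invariant to the total COD (the cell mass is
  # proportional to it), so doubling everything leaves them unchanged
  d <- cod_to_substrate_rates(206, sulfate_load = 20, sulfide_load = 8)
  expect_equal(d$community_rates[["but"]], a$community_rates[["but"]])
  expect_equal(d$cell_mass, 2 * a$cell_mass)
})

test_that("applying a condition closes the community boundary", {
  m <- make_toy_community(toy_community_spec())
  # empty condition: everything closed, no growth
  closed <- apply_condition(m, condition_spec("empty"))
  expect_true(all(closed$uptake_bounds == 0))
  expect_true(all(closed$export_bounds == 0))
  expect_length(closed$free_mets, 0)
  expect_equal(maximize_growth(closed)$mu, 0)

  expect_error(apply_condition(m, condition_spec("bad",
                                                 community_rates = c(unobtainium = 1))),
               "absent from the community pool")
})

test_that("granting only acetate reaches an acetate-limited guild", {
  # a MET-like single-guild community fed acetate grows at its FBA rate
  met <- build_guild("M", list(
    EX_ac = list(stoich = c(ac = -1), lb = -20, ub = 0),
    GROW = list(stoich = c(ac = -4), lb = 0, ub = Inf)),
    c(ac = "C2"), "GROW", c(EX_ac = "ac"))
  m <- assemble_community(list(met))
  m <- apply_condition(m, condition_spec("ac-only",
                                         community_rates = c(ac = 2)))
  ref <- fba(met, exchange_lb = c(ac = -2))$objective
  expect_gt(ref, 0)
  expect_equal(maximize_growth(m)$mu, ref, tolerance = 1e-5)
})

test_that("condition specifications survive a TSV round trip", {
  spec <- condition_preset("L-OLR")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_condition_tsv(spec, f)
  back <- read_condition_tsv(f, label = "L-OLR")
  expect_mapequal(back$community_rates, spec$community_rates)
  expect_setequal(back$free_exchange, spec$free_exchange)
  m <- make_toy_community(toy_community_spec())
  expect_equal(maximize_growth(apply_condition(m, back))$mu,
               maximize_growth(apply_condition(m, spec))$mu,
               tolerance = 1e-6)
})
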