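test_that("flux fold change handles ratios, zeros and sign reversals", {
  expect_equal(flux_fold_change(2, 1)$ffc, 1)
  expect_equal(flux_fold_change(2, 1)$flag, "ok")
  for (x in c(0.3, 1, 57)) expect_equal(flux_fold_change(x, x)$ffc, 0)
  expect_equal(flux_fold_change(-1, -2)$ffc, -1)   # same sign, negative

  r <- flux_fold_change(1, 5e-7, zero_threshold = 1e-6)
  expect_equal(r$flag, "zeroed_L")
  expect_true(is.na(r$ffc))
  expect_equal(flux_fold_change(5e-7, 1)$flag, "zeroed_H")
  expect_equal(flux_fold_change(0, 0)$flag, "both_zero")
  expect_equal(flux_fold_change(1, -1)$flag, "sign_discordant")
})

test_that("fold changes are antisymmetric and additive", {
  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10); c <- runif(1, 0.1, 10)
    expect_equal(flux_fold_change(a, b)$ffc, -flux_fold_change(b, a)$ffc)
    expect_equal(flux_fold_change(a, c)$ffc,
                 flux_fold_change(a, b)$ffc + flux_fold_change(b, c)$ffc,
                 tolerance = 1e-12)
  }
})

test_that("the intensity categories split at 0.64 and 2", {
  expect_equal(ffc_category(c(0.3, -0.64, 1.9, 2, -2.4, NA)),
               c("low", "medium", "medium", "high", "high", NA))
})

test_that("min-max normalization maps onto [-1, 1] with signs restored", {
  expect_equal(minmax_normalize(c(1, 2, 3))$values, c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(-1, -2, -4))$values, c(0, -1/3, -1))
  cst <- minmax_normalize(c(5, 5, 5))
  expect_true(cst$constant)
  expect_equal(cst$values, c(0, 0, 0))
  # idempotence on an already-normalized non-constant series
  v <- minmax_normalize(c(2, -3, 7, 0.5))$values
  expect_equal(minmax_normalize(v)$values, v)
  # signs always match the raw series where magnitudes are nonzero
  expect_equal(sign(v)[v != 0], sign(c(2, -3, 7, 0.5))[v != 0])
})

test_that("exchange ratios compare guild fluxes and flag zero denominators", {
  m <- make_toy_community(toy_community_spec())
  sol <- maximize_growth(m)
  r <- exchange_ratio(sol, "ac", "MET", "SOB")
  expect_false(r$infinite)
  ex <- sol$exchange_fluxes
  expect_equal(r$ratio,
               abs(ex$flux[ex$guild == "MET" & ex$metabolite == "ac"]) /
               abs(ex$flux[ex$guild == "SOB" & ex$metabolite == "ac"]))
  # equal fluxes give exactly one
  sol2 <- sol
  sol2$exchange_fluxes$flux[sol2$exchange_fluxes$metabolite == "ac"] <- -1
  expect_equal(exchange_ratio(sol2, "ac", "MET", "SOB")$ratio, 1)
  # a vanishing denominator flags an infinite ratio
  sol2$exchange_fluxes$flux[sol2$exchange_fluxes$guild == "SOB" &
                            sol2$exchange_fluxes$metabolite == "ac"] <- 1e-9
  expect_true(exchange_ratio(sol2, "ac", "MET", "SOB")$infinite)
  # ratios are invariant to rescaling the whole solution
  sol3 <- sol
  sol3$exchange_fluxes$flux <- 3 * sol3$exchange_fluxes$flux
  expect_equal(exchange_ratio(sol3, "ac", "MET", "SOB")$ratio, r$ratio)
})

test_that("reducing-power partition is a flux-ratio percentage", {
  m <- make_toy_community(toy_community_spec())
  sol <- maximize_growth(m)
  fl <- sol$fluxes
  mk <- function(ids, vals) {
    s <- sol
    s$fluxes$flux[match(paste0("SRB.", ids),
                        paste0(s$fluxes$guild, ".", s$fluxes$reaction))] <- vals
    s
  }
  s <- mk(c("SR", "H2EV", "BUTOX", "FDH"), c(1, 1, 4, 0))
  expect_equal(nadh_partition(s, "SRB", c("SR", "H2EV"),
                              c("BUTOX", "FDH"))$percent, 50)
  expect_equal(nadh_partition(s, "SRB", c("SR", "H2EV"),
                              c("SR", "H2EV"))$percent, 100)
  z <- mk(c("BUTOX", "FDH"), c(0, 0))
  expect_true(nadh_partition(z, "SRB", "SR", c("BUTOX", "FDH"))$undefined)
  expect_error(nadh_partition(sol, "SRB", "NOPE", "BUTOX"), "not in guild")
})

test_that("whole-model flux comparisons carry flags and categories", {
  m <- make_toy_community(toy_community_spec())
  sl <- maximize_growth(m, solver_settings(flux_resolution = "parsimonious"))
  sh <- maximize_growth(apply_condition(m, condition_preset("H-OLR")),
                        solver_settings(flux_resolution = "parsimonious"))
  cmp <- flux_comparison(sl, sh)
  expect_s3_class(cmp, "flux_comparison")
  expect_equal(nrow(cmp), nrow(sl$fluxes))
  expect_true(all(is.na(cmp$ffc) == (cmp$flag != "ok")))
  expect_true(all(abs(c(cmp$v_l, cmp$v_h)) == 0 |
                  abs(c(cmp$v_l, cmp$v_h)) >= 1e-6))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ffc_tsv(cmp, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), nrow(cmp))
})
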