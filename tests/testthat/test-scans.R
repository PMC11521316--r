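test_that("a degenerate two-point sweep yields identical solutions", {
  m <- make_toy_community(toy_community_spec())
  sw <- olr_sweep(m, butyrate_range = c(1.606, 1.606),
                  acetate_range = c(1.245, 1.245), n_points = 2)
  sol <- sw$solutions
  expect_equal(nrow(sol), 2)
  expect_equal(sol$mu[1], sol$mu[2], tolerance = 1e-9)
  expect_equal(unlist(sol[1, c("SRB", "MET", "SOB")]),
               unlist(sol[2, c("SRB", "MET", "SOB")]), tolerance = 1e-9)
})

test_that("the loading sweep flips dominance from SOB to MET inside the range", {
  m <- make_toy_community(toy_community_spec())
  sw <- olr_sweep(m, n_points = 9)
  dom <- sw$solutions$dominant
  expect_equal(dom[1], "SOB")
  expect_equal(dom[length(dom)], "MET")
  flip <- which(dom != dom[1])[1]
  expect_true(flip > 1 && flip <= length(dom))
  # growth never decreases along the joint loading relaxation
  expect_true(all(diff(sw$solutions$mu) >= -1e-5))
  # normalized series honour the [-1, 1] envelope with signs kept
  ns <- sw$normalized_series
  expect_true(all(abs(ns$normalized_flux) <= 1 + 1e-12, na.rm = TRUE))
  nz <- !is.na(ns$normalized_flux) & ns$normalized_flux != 0
  expect_true(all(sign(ns$normalized_flux[nz]) == sign(ns$flux[nz])))
})

test_that("every sweep point satisfies the solver invariants", {
  m <- make_toy_community(toy_community_spec())
  for (but in c(0.48, 1.606, 3.61)) {
    ac <- 0.77 + (but - 0.48) / (3.61 - 0.48) * (2.09 - 0.77)
    mm <- apply_condition(m, condition_preset("L-OLR", butyrate = but,
                                              acetate = ac))
    sol <- maximize_growth(mm)
    expect_solution_invariants(mm, sol)
  }
})

test_that("cutting sulfide cross-feeding hands the community to the methanogens", {
  m <- make_toy_community(toy_community_spec())
  # release the methanogens from their forced specific uptake so they
  # can fill the community once the other guilds are starved out
  m <- apply_capacities(m, capacity_set("MET", "ac", "upper", 0))
  cond <- condition_preset("L-OLR")
  cond$community_rates[["h2s"]] <- 0     # no influent sulfide either
  scan <- capacity_scan_2d(m, cond, sob_acetate_lb_range = c(-0.001, -0.0005),
                           srb_sulfide_ub_range = c(0, 0),
                           n_capacity = 2, loading_points = 3)
  ok <- scan$solutions[scan$solutions$status == "optimal", ]
  expect_gt(nrow(ok), 0)
  expect_true(all(ok$dominant == "MET"))
  expect_true(all(ok$SOB < 1e-6))
  # SOB dominance is lost from the very first loading point
  expect_true(all(scan$transitions$transition_butyrate ==
                  min(scan$solutions$butyrate), na.rm = TRUE))
})

test_that("stronger SRB-SOB capacities delay the dominance transition", {
  m <- make_toy_community(toy_community_spec())
  cond <- condition_preset("L-OLR")
  cond$community_rates[["h2s"]] <- 0     # sulfide only via the S cycle
  scan <- capacity_scan_2d(m, cond, sob_acetate_lb_range = c(-1.05, -3.15),
                           srb_sulfide_ub_range = c(4.39, 13.18),
                           n_capacity = 2, loading_points = 7)
  tr <- scan$transitions
  corner <- function(sob, srb) {
    v <- tr$transition_butyrate[tr$sob_acetate_lb == sob &
                                tr$srb_sulfide_ub == srb]
    if (is.na(v)) Inf else v             # never lost within the sweep
  }
  weak <- corner(-1.05, 4.39)
  strong <- corner(-3.15, 13.18)
  expect_true(is.finite(weak))
  expect_gt(strong, weak)
  expect_true("transient" %in% names(scan$solutions))
})

test_that("proton availability favours the sulfide oxidizers", {
  m <- make_toy_community(toy_community_spec())
  sw <- h_plus_sweep(m, n_points = 7)
  sol <- sw$solutions[sw$solutions$status == "optimal", ]
  expect_equal(nrow(sol), 7)
  # at the neutral end the constraint is inactive: matches plain H-OLR
  ref <- maximize_growth(apply_condition(m, condition_preset("H-OLR")))
  expect_equal(sol$mu[1], ref$mu, tolerance = 1e-4)
  expect_equal(sol$SOB[1], ref$abundances[["SOB"]], tolerance = 1e-3)
  # SOB abundance is non-decreasing in proton availability
  expect_true(all(diff(sol$SOB) >= -1e-3))
  # and the methanogens lose ground overall
  expect_lt(sol$MET[nrow(sol)], sol$MET[1])
})

test_that("transition detection finds switches, plateaus and drops", {
  # monotone single-guild scan: nothing to report
  mono <- structure(list(
    axes = list(x = 1:5),
    solutions = data.frame(x = 1:5, mu = seq(0.1, 0.5, by = 0.1),
                           status = "optimal", A = 1,
                           dominant = "A")), class = "scan_result")
  d1 <- detect_transition(mono, "A", axis = "x")
  expect_length(d1$dominance_switch, 0)
  expect_true(is.na(d1$slope_break))
  expect_true(is.na(d1$largest_drop))

  # a hand-constructed step series puts the boundary at the step
  fake <- structure(list(
    axes = list(x = 1:6),
    solutions = data.frame(x = 1:6, mu = 1, status = "optimal",
                           A = c(1, 2, 3, 3, 3, 3) / 10,
                           B = c(5, 5, 5, 2, 2, 2) / 10,
                           dominant = c("B", "B", "B", "A", "A", "A"))),
    class = "scan_result")
  d2 <- detect_transition(fake, "A", axis = "x")
  expect_equal(d2$dominance_switch, 4)
  expect_equal(d2$slope_break, 4)       # growth slope collapses there
  d3 <- detect_transition(fake, "B", axis = "x")
  expect_equal(d3$largest_drop, 4)      # steepest B decline

  # the synthetic sweep yields a dominance switch and a growth plateau,
  # in that scan, with the plateau at or after the first phase
  m <- make_toy_community(toy_community_spec())
  sw <- olr_sweep(m, n_points = 9, track = character())
  dd <- detect_transition(sw, "SOB", axis = "butyrate")
  expect_length(dd$dominance_switch, 1)
  expect_false(is.na(dd$slope_break))
  expect_lte(dd$slope_break, dd$dominance_switch + 1e-9)
})

test_that("scan results serialize to TSV and JSON", {
  m <- make_toy_community(toy_community_spec())
  sw <- olr_sweep(m, n_points = 3, track = "ac")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scan_tsv(sw, f)
  expect_equal(nrow(utils::read.delim(f)), 3)
  fj <- withr::local_tempfile(fileext = ".json")
  write_scan_tsv(sw, fj)
  expect_true(jsonlite::validate(paste(readLines(fj), collapse = "\n")))
})
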