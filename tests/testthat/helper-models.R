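# Small fully-understood communities used as oracles throughout the
# suite. All are built in code; nothing is read from disk.

# one guild growing on a single substrate "s" with yield `yield`
# (biomass flux = yield * uptake); uptake capacity 10 per abundance.
single_guild <- function(id = "A", yield = 0.5, uptake_cap = 10) {
  rx <- list(
    EX_s = list(stoich = c(s = -1), lb = -uptake_cap, ub = 0),
    GROW = list(stoich = c(s = -1 / yield), lb = 0, ub = Inf))
  build_guild(id, rx, c(s = "C"), "GROW", c(EX_s = "s"))
}

single_guild_community <- function(s_influx = 6, yield = 0.5,
                                   uptake_cap = 10) {
  m <- assemble_community(list(single_guild(yield = yield,
                                            uptake_cap = uptake_cap)))
  apply_condition(m, condition_spec("test",
                                    community_rates = c(s = s_influx)))
}

# obligate cross-feeding chain: A grows on "s" and secretes "m";
# B grows only on "m" (which nothing else provides).
chain_community <- function(s_influx = 6) {
  a <- build_guild("A", list(
    EX_s = list(stoich = c(s = -1), lb = -10, ub = 0),
    CONV = list(stoich = c(s = -1, m = 1), lb = 0, ub = Inf),
    EX_m = list(stoich = c(m = -1), lb = 0, ub = Inf),
    GROW_A = list(stoich = c(s = -2), lb = 0, ub = Inf)),
    c(s = "C", m = "C"), "GROW_A", c(EX_s = "s", EX_m = "m"))
  b <- build_guild("B", list(
    EX_m = list(stoich = c(m = -1), lb = -5, ub = 0),
    GROW_B = list(stoich = c(m = -3), lb = 0, ub = Inf)),
    c(m = "C"), "GROW_B", c(EX_m = "m"))
  m <- assemble_community(list(a, b))
  apply_condition(m, condition_spec("test",
                                    community_rates = c(s = s_influx)))
}

# guild containing a free 2-cycle (x <-> y) unrelated to growth
loop_community <- function() {
  g <- build_guild("L", list(
    EX_s = list(stoich = c(s = -1), lb = -4, ub = 0),
    GROW = list(stoich = c(s = -2), lb = 0, ub = Inf),
    CYC1 = list(stoich = c(x = -1, y = 1), lb = -100, ub = 100),
    CYC2 = list(stoich = c(y = -1, x = 1), lb = -100, ub = 100)),
    c(s = "C", x = "C", y = "C"), "GROW", c(EX_s = "s"))
  m <- assemble_community(list(g))
  apply_condition(m, condition_spec("test", community_rates = c(s = 4)))
}

# two alternative routes from substrate to precursor: direct (1 step)
# and detour (2 steps); parsimony must pick the direct one.
altpath_community <- function() {
  g <- build_guild("P", list(
    EX_s = list(stoich = c(s = -1), lb = -6, ub = 0),
    DIRECT = list(stoich = c(s = -1, p = 1), lb = 0, ub = Inf),
    STEP1 = list(stoich = c(s = -1, x = 1), lb = 0, ub = Inf),
    STEP2 = list(stoich = c(x = -1, p = 1), lb = 0, ub = Inf),
    GROW = list(stoich = c(p = -2), lb = 0, ub = Inf)),
    c(s = "C", x = "C", p = "C"), "GROW", c(EX_s = "s"))
  m <- assemble_community(list(g))
  apply_condition(m, condition_spec("test", community_rates = c(s = 6)))
}

# brute-force growth maximization on a mu grid (the independent search
# oracle for the bisection)
grid_search_mu <- function(model, mu_max = 5, coarse = 2e-2, fine = 1e-4) {
  feasible <- function(mu) isTRUE(solve_at_growth(model, mu)$feasible)
  grid <- seq(0, mu_max, by = coarse)
  ok <- vapply(grid, feasible, TRUE)
  if (!any(ok[-1])) return(0)
  lo <- grid[max(which(ok))]
  fine_grid <- seq(lo, min(lo + 2 * coarse, mu_max), by = fine)
  fine_ok <- vapply(fine_grid, feasible, TRUE)
  fine_grid[max(which(fine_ok))]
}

# element totals of a formula string (e.g. "C4G10" -> c(C=4, G=10))
formula_elements <- function(f) guildcom:::parse_formula(f)

expect_solution_invariants <- function(model, sol, tol = 1e-8) {
  expect_equal(sum(sol$abundances), model$x0, tolerance = tol)
  expect_true(all(sol$abundances >= -tol))
  scale <- max(1, max(abs(sol$fluxes$flux)))
  for (g in model$guilds) {
    v <- sol$fluxes$flux[sol$fluxes$guild == g$guild_id]
    resid <- as.numeric(g$S %*% v)
    expect_lt(max(abs(resid)), tol * scale)
    vb <- v[match(g$biomass, g$reactions$id)]
    expect_lt(abs(vb - sol$mu * sol$abundances[[g$guild_id]]), tol * scale)
  }
  for (met in model$com_mets) {
    ex <- sol$exchange_fluxes
    tot <- sum(ex$flux[ex$metabolite == met]) +
      sol$community_uptake[[met]] - sol$community_export[[met]]
    expect_lt(abs(tot), tol * scale)
  }
}
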