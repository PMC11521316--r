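test_that("percent error follows its definition exactly", {
  obs <- c(SRB = 0.2, MET = 0.3, SOB = 0.5)
  expect_equal(percent_error(obs, obs)$per_guild, c(SRB = 0, MET = 0, SOB = 0))
  expect_equal(percent_error(obs, obs)$average, 0)
  expect_equal(percent_error(2 * obs, obs)$per_guild,
               c(SRB = 100, MET = 100, SOB = 100))
  # the average is the unweighted mean of per-guild errors
  pe <- percent_error(obs * (1 + c(0.0031, -0.1079, 0.0561)), obs)
  expect_equal(unname(pe$per_guild), c(0.31, 10.79, 5.61), tolerance = 1e-9)
  expect_equal(round(pe$average, 2), 5.57)

  expect_error(percent_error(obs, c(SRB = 0, MET = 0.5, SOB = 0.5)),
               "undefined")
  expect_error(percent_error(c(MET = 1, SRB = 1, SOB = 1), obs), "ordering")
})

test_that("grid fitting is exhaustive, deterministic and trace-consistent", {
  m <- make_toy_community(toy_community_spec())
  obs <- make_synthetic_observation(m, noise_sd = 0.03, seed = 11)
  axes <- list("SOB.ac.lower" = c(-2.2, -1.5, -1.0),
               "MET.ac.upper" = c(-13, -11.55, -10))
  fit <- fit_exchange_capacities(m, obs, axes)
  expect_equal(fit$status, "ok")
  expect_equal(nrow(fit$search_trace), 9)
  # the reported best is the minimum of the evaluated trace
  expect_equal(fit$average_error,
               min(fit$search_trace$average_error, na.rm = TRUE))
  # rerunning reproduces the identical result
  fit2 <- fit_exchange_capacities(m, obs, axes)
  expect_identical(fit$best_values, fit2$best_values)
  expect_equal(fit$average_error, fit2$average_error)

  # a degenerate one-point grid returns that point regardless of error
  one <- fit_exchange_capacities(m, obs, list("SOB.ac.lower" = -1.2))
  expect_equal(unname(one$best_values), -1.2)

  # embedding the best point in a finer grid never increases the error
  finer <- lapply(seq_along(axes), function(i) {
    sort(unique(c(axes[[i]], fit$best_values[i] * c(0.9, 1, 1.1))))
  })
  names(finer) <- names(axes)
  fit3 <- fit_exchange_capacities(m, obs, finer)
  expect_lte(fit3$average_error, fit$average_error + 1e-9)
})

test_that("capacities planted in the generator are recovered by the fit", {
  m <- make_toy_community(toy_community_spec())
  truth <- capacity_set(c("SOB", "MET"), c("ac", "ac"),
                        c("lower", "upper"), c(-1.5, -11.55))
  obs <- make_synthetic_observation(m, capacities = truth, noise_sd = 0,
                                    seed = 1)
  axes <- list("SOB.ac.lower" = c(-2.5, -2.0, -1.5, -1.1, -0.8),
               "MET.ac.upper" = c(-15, -13, -11.55, -10, -8.5))
  fit <- fit_exchange_capacities(m, obs, axes)
  expect_equal(unname(fit$best_values),
               c(-1.5, -11.55))              # noise-free: exact recovery
  expect_lt(fit$average_error, 1e-4)
})

test_that("sequential refinement handles more than three axes", {
  m <- make_toy_community(toy_community_spec())
  obs <- make_synthetic_observation(m, noise_sd = 0, seed = 1)
  axes <- list("SOB.ac.lower" = c(-2.0, -1.5, -1.0),
               "MET.ac.upper" = c(-13, -11.55, -10),
               "SRB.h2s.upper" = c(5, 6.28, 8),
               "SRB.h.upper" = c(1e-5, 1e-4))
  fit <- fit_exchange_capacities(m, obs, axes, method = "sequential")
  expect_equal(fit$status, "ok")
  expect_lt(fit$average_error, 5)
})

test_that("an unsatisfiable grid is reported, not raised", {
  m <- make_toy_community(toy_community_spec())
  obs <- make_synthetic_observation(m, noise_sd = 0, seed = 1)
  # starving every guild of nitrogen leaves no feasible community
  fit <- fit_exchange_capacities(m, obs,
                                 list("SRB.nh4.lower" = 0,
                                      "MET.nh4.lower" = 0,
                                      "SOB.nh4.lower" = 0))
  expect_null(fit$best)
  expect_match(fit$status, "infeasible")
})
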