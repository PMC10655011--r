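test_that("FBA solves simple chains and closed models", {
  m <- chain_model(uptake = 1)
  sol <- solve_fba(m)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 1, tolerance = 1e-9)
  # all exchanges closed -> zero objective
  closed <- set_bounds(m, exchange_ids(m), lower = 0, upper = 0)
  expect_equal(solve_fba(closed)$objective_value, 0, tolerance = 1e-12)
})

test_that("optimal solutions satisfy steady state and bounds tightly", {
  for (m in list(chain_model(), branched_model())) {
    sol <- solve_fba(m)
    chk <- check_solution(m, sol)
    expect_lt(chk$steady_state_residual, 1e-9)
    expect_lt(chk$bound_violation, 1e-9)
  }
})

test_that("unbounded problems are reported, never as a large optimum", {
  m <- metabolic_model(
    "unb", list(metabolite("a_c")),
    list(reaction("in", c(a_c = 1), 0, Inf),
         reaction("out", c(a_c = -1), 0, Inf)),
    objective = "out")
  m$reactions$upper_bound <- c(Inf, Inf)
  sol <- solve_fba(m)
  expect_identical(sol$status, "unbounded")
})

test_that("branched optimum equals the vertex-enumeration oracle", {
  m <- branched_model()
  sol <- solve_fba(m)
  oracle <- vertex_enumeration_optimum(m, "p_sink")
  expect_equal(sol$objective_value, oracle, tolerance = 1e-6)
  # and for the chain
  m2 <- chain_model()
  expect_equal(solve_fba(m2)$objective_value,
               vertex_enumeration_optimum(m2, "sink"), tolerance = 1e-6)
})

test_that("tightening bounds never increases the optimum (monotonicity)", {
  m <- branched_model()
  base <- solve_fba(m)$objective_value
  set.seed(7)
  problems <- list()
  tightened <- list()
  for (k in 1:8) {
    rid <- sample(reaction_ids(m), 1)
    b <- get_bounds(m, rid)
    m2 <- set_bounds(m, rid, upper = b$upper_bound * runif(1))
    tightened[[k]] <- m2
  }
  for (m2 in tightened) {
    expect_lte(solve_fba(m2)$objective_value, base + 1e-9)
  }
})

test_that("scaling all bounds scales the optimum (homogeneity)", {
  m <- branched_model()
  base <- solve_fba(m)$objective_value
  for (k in c(0.5, 2)) {
    m2 <- m
    m2$reactions$lower_bound <- m$reactions$lower_bound * k
    m2$reactions$upper_bound <- m$reactions$upper_bound * k
    expect_equal(solve_fba(m2)$objective_value, base * k, tolerance = 1e-8)
  }
})

test_that("pFBA suppresses free futile cycles and preserves the optimum", {
  # chain plus a zero-cost reversible loop b <-> d parallel to nothing
  m <- chain_model()
  m <- add_reaction(m, reaction("loop1", c(b_c = -1, d_c = 1), -1000, 1000),
                    new_metabolites = list(metabolite("d_c", formula = "C")))
  m <- add_reaction(m, reaction("loop2", c(d_c = -1, b_c = 1), -1000, 1000))
  fba <- solve_fba(m)
  pfba <- solve_pfba(m)
  expect_equal(pfba$objective_value, fba$objective_value, tolerance = 1e-9)
  expect_lt(abs(pfba$fluxes[["loop1"]]), 1e-8)
  expect_lt(abs(pfba$fluxes[["loop2"]]), 1e-8)
  # total flux of pFBA never exceeds FBA's
  expect_lte(sum(abs(pfba$fluxes)), sum(abs(fba$fluxes)) + 1e-6)
})

test_that("pFBA equals FBA on a model with a unique optimum", {
  m <- chain_model()
  fba <- solve_fba(m)
  pfba <- solve_pfba(m)
  expect_equal(pfba$fluxes, fba$fluxes, tolerance = 1e-8)
})

test_that("pins fix fluxes exactly", {
  m <- branched_model()
  sol <- solve_fba(m, pins = c(step1 = 2))
  expect_equal(sol$fluxes[["step1"]], 2, tolerance = 1e-9)
})

test_that("growth predictions scale linearly with pinned CO2 fixation", {
  m <- toy_model()
  cases <- data.frame(line_label = c("zero", "low", "high"),
                      co2_fixation_rate = c(0, 0.1, 0.2))
  res <- predict_growth_rates(m, cases)
  expect_identical(res$status, rep("optimal", 3))
  expect_equal(res$predicted_growth[1], 0, tolerance = 1e-8)
  expect_equal(res$predicted_growth[3], 2 * res$predicted_growth[2],
               tolerance = 1e-6)
})

test_that("growth prediction supplies nitrogen as 50% nitrate, 50% ammonium", {
  m <- toy_model()
  cases <- data.frame(line_label = "l1", co2_fixation_rate = 0.2,
                      observed_growth = 1)
  res <- predict_growth_rates(m, cases, parsimonious = TRUE)
  expect_identical(res$status, "optimal")
  # recompute the underlying solution to inspect fluxes
  cls <- phytoflux:::.classify_exchanges(m)
  m2 <- set_bounds(m, cls$organic, lower = 0, upper = 0)
  m2 <- set_bounds(m2, cls$photon, lower = 0, upper = 1000)
  sol <- solve_pfba(m2, pins = stats::setNames(0.2, cls$co2),
                    coupling = nitrogen_fifty_fifty(m2))
  no3 <- sol$fluxes[[cls$nitrate]]
  nh4 <- sol$fluxes[[cls$ammonium]]
  expect_equal(no3, nh4, tolerance = 1e-8)
  expect_gt(no3, 0)
})
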