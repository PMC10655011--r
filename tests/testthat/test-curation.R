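test_that("reversibility rules narrow or flip bounds, never widen", {
  m <- branched_model()
  rules <- data.frame(reaction_id = c("back", "step1"),
                      directionality = c("reverse", "forward"),
                      stringsAsFactors = FALSE)
  out <- apply_reversibility_rules(m, rules)
  b <- get_bounds(out, c("back", "step1"))
  expect_equal(b$upper_bound[1], 0)
  expect_equal(b$lower_bound[2], 0)
  expect_error(apply_reversibility_rules(m, data.frame(
    reaction_id = "ghost", directionality = "forward")), "unknown reaction")
})

test_that("the curated toy model has no energy-generating cycles", {
  m <- toy_model()
  for (cur in c("ATP", "NADH", "NADPH")) {
    res <- detect_energy_cycles(m, cur)
    expect_lt(res$max_flux, 1e-8)
    expect_length(res$active_reactions, 0)
  }
})

test_that("an injected cost-free ATP synthesis reaction is detected", {
  m <- toy_model()
  broken <- add_reaction(m, reaction(
    "free_atp", c(adp_c = -1, pi_c = -1, atp_c = 1, h2o_c = 1),
    -1000, 1000))
  res <- detect_energy_cycles(broken, "ATP")
  expect_gt(res$max_flux, 1e-8)
  expect_true("free_atp" %in% res$active_reactions)
})

test_that("an empty model trivially has no cycles", {
  empty <- metabolic_model("empty", list(), list(),
                           objective = NA_character_, validate = FALSE)
  expect_equal(detect_energy_cycles(empty, "ATP")$max_flux, 0)
})

test_that("P/O ratios match the printed respiratory stoichiometry", {
  m <- toy_model()
  expect_equal(compute_po_ratio(m, "NADH"), 1.875, tolerance = 1e-9)
  expect_equal(compute_po_ratio(m, "succinate"), 1.125, tolerance = 1e-9)
})

test_that("a disabled ATP synthase gives a zero P/O ratio", {
  m <- set_bounds(toy_model(), "ATPS_m", lower = 0, upper = 0)
  expect_equal(compute_po_ratio(m, "NADH"), 0, tolerance = 1e-12)
})

test_that("P/O equals (H+ per donor) / (H+ per ATP) for random stoichiometries", {
  set.seed(11)
  for (k in 1:4) {
    h_donor <- sample(6:14, 1)
    h_atp <- sample(c(3, 4, 16 / 3, 14 / 3), 1)
    m <- mini_etc_model(h_donor = h_donor, h_atp = h_atp)
    expect_equal(compute_po_ratio(m, "NADH"), h_donor / h_atp,
                 tolerance = 1e-8)
  }
})

# Gap-filling fixture: linear pathway a -> b -> c with the middle step
# missing; pool candidates include the true fill and decoys.
gapfill_fixture <- function() {
  model <- metabolic_model(
    "gap",
    metabolites = list(metabolite("a_c"), metabolite("b_c"),
                       metabolite("c_c"), metabolite("z_c")),
    reactions = list(
      reaction("A_Cyto_tx", c(a_c = 1), 0, 10),
      reaction("step3", c(b_c = -1, c_c = 1), 0, 1000),
      reaction("z_sink", c(z_c = -1), 0, 1000)),
    objective = "step3")
  pool <- universal_pool(list(
    reaction("fill_true", c(a_c = -1, b_c = 1), 0, 1000),
    reaction("fill_dead1", c(z_c = -1, b_c = 1), 0, 1000),
    reaction("fill_dead2", c(a_c = -1, z_c = 1), 0, 1000),
    reaction("fill_wrongdir", c(b_c = -1, a_c = 1), 0, 1000),
    reaction("fill_noop", c(c_c = -1, c_c = 1)[0])), weights = 1)
  list(model = model, pool = pool)
}

test_that("gap filling recovers the single missing step", {
  fx <- gapfill_fixture()
  pool <- universal_pool(fx$pool$reactions[1:4], weights = 1)
  added <- gapfill_weighted_pfba(fx$model, pool, target = "c_c")
  expect_identical(added, "fill_true")
  oracle <- exhaustive_gapfill(fx$model, pool, "c_c")
  expect_setequal(added, oracle$set)
})

test_that("a producible target needs no gap filling", {
  fx <- gapfill_fixture()
  m <- add_reaction(fx$model, reaction("native", c(a_c = -1, c_c = 1)))
  pool <- universal_pool(fx$pool$reactions[1:4], weights = 1)
  expect_identical(gapfill_weighted_pfba(m, pool, "c_c"), character(0))
})

test_that("weights steer the choice between alternative fills", {
  model <- metabolic_model(
    "alt",
    metabolites = list(metabolite("a_c"), metabolite("c_c")),
    reactions = list(reaction("A_Cyto_tx", c(a_c = 1), 0, 10)),
    objective = "A_Cyto_tx")
  pool <- universal_pool(list(
    reaction("cheap", c(a_c = -1, c_c = 1), 0, 1000),
    reaction("dear", c(a_c = -1, c_c = 1), 0, 1000)),
    weights = c(1, 5))
  expect_identical(gapfill_weighted_pfba(model, pool, "c_c"), "cheap")
  # flipped weights flip the choice
  pool2 <- universal_pool(list(
    reaction("cheap", c(a_c = -1, c_c = 1), 0, 1000),
    reaction("dear", c(a_c = -1, c_c = 1), 0, 1000)),
    weights = c(5, 1))
  expect_identical(gapfill_weighted_pfba(model, pool2, "c_c"), "dear")
})

test_that("gap filling matches exhaustive search on a larger random pool", {
  set.seed(3)
  mets <- lapply(sprintf("m%d_c", 1:6), metabolite)
  model <- metabolic_model(
    "rand",
    metabolites = mets,
    reactions = list(reaction("M1_Cyto_tx", c(m1_c = 1), 0, 10)),
    objective = "M1_Cyto_tx")
  # pool of 8 random conversions between the six species plus the two-step
  # true path m1 -> m3 -> m6
  cand <- list(
    reaction("p1", c(m1_c = -1, m3_c = 1)),
    reaction("p2", c(m3_c = -1, m6_c = 1)),
    reaction("p3", c(m2_c = -1, m6_c = 1)),
    reaction("p4", c(m4_c = -1, m5_c = 1)),
    reaction("p5", c(m1_c = -1, m4_c = 1)),
    reaction("p6", c(m5_c = -1, m2_c = 1)),
    reaction("p7", c(m3_c = -1, m2_c = 1)),
    reaction("p8", c(m6_c = -1, m5_c = 1)))
  weights <- c(1, 1, 1, 2, 2, 2, 1, 1)
  pool <- universal_pool(cand, weights)
  added <- gapfill_weighted_pfba(model, pool, "m6_c")
  oracle <- exhaustive_gapfill(model, pool, "m6_c")
  expect_equal(sum(pool$weights[added]), oracle$weight)
})

test_that("an unfillable gap raises a diagnostic error", {
  fx <- gapfill_fixture()
  pool <- universal_pool(fx$pool$reactions[c(2, 4)], weights = 1)
  expect_error(gapfill_weighted_pfba(fx$model, pool, "c_c"),
               "unfillable gap")
})

test_that("yield checks compare FBA against the reduction-degree bound", {
  m <- toy_model()
  res <- check_max_yield(m, "glc_c", "pyr_c")
  expect_equal(res$theoretical_yield, 2.4, tolerance = 1e-12) # 24 / 10
  expect_true(res$pass)
  expect_lte(res$fba_yield, res$theoretical_yield + 1e-6)
  # a mass-creating bug breaks the bound and is flagged
  broken <- add_reaction(m, reaction("dup", c(pyr_c = -1, pyr_c = 2)[1]))
  broken$stoichiometry$dup <- c(pyr_c = 1)
  res2 <- check_max_yield(broken, "glc_c", "pyr_c")
  expect_false(res2$pass)
})

test_that("yield of a fully oxidized product is undefined", {
  m <- toy_model()
  expect_error(check_max_yield(m, "glc_c", "co2_c"), "reduction degree")
})

test_that("biomass rescaling normalizes the molar mass to 1 g/mmol", {
  glc <- biomass_composition(data.frame(
    component = "glc_c", name = "Glc", coefficient = 5.5507,
    formula = "C6H12O6", stringsAsFactors = FALSE))
  out <- rescale_biomass(glc)
  # 1000 / 180.156 = 5.55075... : scale factor is essentially 1
  expect_equal(out$coefficient, 5.5507, tolerance = 1e-4)
  expect_equal(biomass_molar_mass(out), 1, tolerance = 1e-12)
  # doubling the coefficient halves back on rescale
  doubled <- glc
  doubled$coefficient <- 11.1014
  expect_equal(rescale_biomass(doubled)$coefficient,
               1000 / 180.156, tolerance = 1e-9)
})

test_that("rescale_biomass is idempotent and demands formulas", {
  comp <- get_biomass_composition(toy_model())
  once <- rescale_biomass(comp)
  twice <- rescale_biomass(once)
  expect_equal(once$coefficient, twice$coefficient, tolerance = 1e-12)
  noformula <- comp
  noformula$formula[3] <- NA
  expect_error(rescale_biomass(noformula), "without formula")
})

test_that("the curation report summarizes every check", {
  m <- toy_model()
  path <- withr::local_tempfile()
  rep <- curation_report(m, path = path)
  expect_equal(rep$mass_balance$n_imbalanced, 0)
  expect_equal(rep$energy_cycles$ATP, 0, tolerance = 1e-8)
  expect_equal(rep$po_ratio$NADH, 1.875, tolerance = 1e-9)
  expect_equal(rep$biomass_molar_mass, 1, tolerance = 1e-9)
  expect_true(file.exists(paste0(path, ".json")))
  expect_true(file.exists(paste0(path, ".txt")))
})
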