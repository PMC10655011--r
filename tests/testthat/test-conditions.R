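test_that("condition presets validate their structure", {
  expect_error(condition_spec("soil", photon_bound = 1, sucrose_bound = 0.1),
               "soil preset")
  spec <- condition_spec("in_vitro", photon_bound = 1, sucrose_bound = 0.1,
                         co2_bound = 0.2)
  expect_identical(spec$nitrogen_coupling, "fifty_fifty")
})

test_that("soil simulation is photoautotrophic, in-vitro takes sucrose", {
  sols <- toy_condition_solutions()
  expect_identical(sols$soil$status, "optimal")
  expect_identical(sols$in_vitro$status, "optimal")
  expect_equal(sols$soil$fluxes[["Sucrose_Cyto_tx"]], 0, tolerance = 1e-9)
  expect_equal(sols$soil$fluxes[["Glc_Cyto_tx"]], 0, tolerance = 1e-9)
  expect_gt(sols$in_vitro$fluxes[["Sucrose_Cyto_tx"]], 1e-6)
})

test_that("nitrate and ammonium uptake are equal in both conditions", {
  sols <- toy_condition_solutions()
  for (sol in sols) {
    expect_equal(sol$fluxes[["NO3_Cyto_tx"]], sol$fluxes[["NH4_Cyto_tx"]],
                 tolerance = 1e-8)
    expect_gt(sol$fluxes[["NO3_Cyto_tx"]], 0)
  }
})

test_that("in-vitro growth is slower than soil-grown growth", {
  sols <- toy_condition_solutions()
  expect_lt(sols$in_vitro$objective_value, sols$soil$objective_value)
})

test_that("the directional pathway suite holds on generator defaults", {
  sols <- toy_condition_solutions()
  ps <- summarize_pathways(attr(sols$soil, "model"), sols$soil)
  pv <- summarize_pathways(attr(sols$in_vitro, "model"), sols$in_vitro)
  # primary carbon metabolism down in vitro
  expect_lt(pv$totals$calvin, ps$totals$calvin)
  expect_lt(pv$totals$tca, ps$totals$tca)
  # nitrogen assimilation up in vitro
  expect_gt(pv$totals$gs, ps$totals$gs)
  expect_gt(pv$totals$gogat, ps$totals$gogat)
  # cyclic electron flow carries a larger share in vitro
  expect_gt(pv$cef_lef_ratio, ps$cef_lef_ratio)
})

test_that("per-biomass NADPH production is lower in vitro", {
  sols <- toy_condition_solutions()
  es <- account_energy_redox(attr(sols$soil, "model"), sols$soil)
  ev <- account_energy_redox(attr(sols$in_vitro, "model"), sols$in_vitro)
  expect_true(es$normalized_defined && ev$normalized_defined)
  expect_lt(ev$per_biomass$NADPH_net, es$per_biomass$NADPH_net)
})

test_that("flux comparison classes follow the zero threshold", {
  a <- phytoflux:::.flux_solution("optimal", 1,
                                  c(r1 = 2, r2 = 1, r3 = 0.5, r4 = 0))
  b <- phytoflux:::.flux_solution("optimal", 1,
                                  c(r1 = 2, r2 = 10, r3 = 0, r4 = 0))
  cmp <- compare_fluxes(a, b)
  expect_identical(cmp$class, c("both", "both", "soil_only", "neither"))
  expect_equal(cmp$log10_fc[1], 0)
  expect_equal(cmp$log10_fc[2], 1)
  expect_true(is.na(cmp$log10_fc[3]))
  # a vitro-only reaction
  cmp2 <- compare_fluxes(b, a)
  expect_identical(cmp2$class[3], "vitro_only")
})

test_that("comparison classes partition the reaction set", {
  sols <- toy_condition_solutions()
  cmp <- compare_fluxes(sols$soil, sols$in_vitro)
  expect_equal(nrow(cmp), length(sols$soil$fluxes))
  expect_true(all(cmp$class %in% c("both", "vitro_only", "soil_only",
                                   "neither")))
  expect_true(all(is.na(cmp$log10_fc) == (cmp$class != "both")))
})

test_that("mismatched reaction sets are rejected", {
  a <- phytoflux:::.flux_solution("optimal", 1, c(r1 = 1))
  b <- phytoflux:::.flux_solution("optimal", 1, c(r2 = 1))
  expect_error(compare_fluxes(a, b), "different reaction sets")
})

test_that("comparison TSV and DOT exports are written", {
  sols <- toy_condition_solutions()
  cmp <- compare_fluxes(sols$soil, sols$in_vitro)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_flux_comparison(cmp, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(cmp))
  dot <- withr::local_tempfile(fileext = ".dot")
  write_comparison_dot(cmp, attr(sols$soil, "model"), dot)
  txt <- readLines(dot)
  expect_identical(txt[1], "digraph flux_comparison {")
  expect_true(any(grepl("style=dotted", txt)))
})

test_that("energy accounting sums synthase ATP and normalizes by biomass", {
  m <- metabolic_model(
    "acct",
    metabolites = list(metabolite("atp_p"), metabolite("atp_m"),
                       metabolite("nadh_c")),
    reactions = list(
      reaction("ATPS_p", c(atp_p = 1), 0, 1000,
               subsystem = "atp_synthase_plastid"),
      reaction("ATPS_m", c(atp_m = 1), 0, 1000,
               subsystem = "atp_synthase_mito"),
      reaction("NDH", c(nadh_c = 1), 0, 1000)),
    objective = "NDH", validate = FALSE)
  sol <- phytoflux:::.flux_solution("optimal", 0.5,
                                    c(ATPS_p = 3, ATPS_m = 1, NDH = 2))
  res <- account_energy_redox(m, sol, biomass_flux = 0.5)
  expect_equal(res$raw$ATP_protonpump, 4)
  expect_equal(res$per_biomass$ATP_protonpump, 8)
  expect_equal(res$raw$NADH_net, 2)
  # zero synthase flux -> zero pumped ATP
  sol0 <- phytoflux:::.flux_solution("optimal", 0.5,
                                     c(ATPS_p = 0, ATPS_m = 0, NDH = 0))
  expect_equal(account_energy_redox(m, sol0, 0.5)$raw$ATP_protonpump, 0)
  # non-positive biomass flags undefined normalization
  res0 <- account_energy_redox(m, sol, biomass_flux = 0)
  expect_false(res0$normalized_defined)
  expect_true(is.na(res0$per_biomass$ATP_protonpump))
})

test_that("pathway totals are zero in the dark", {
  m <- toy_model()
  dark <- set_bounds(m, c("PhotonPSII_Cyto_tx", "PhotonPSI_Cyto_tx"),
                     lower = 0, upper = 0)
  sol <- solve_fba(dark)
  summ <- summarize_pathways(dark, sol)
  expect_equal(summ$totals$lef, 0, tolerance = 1e-8)
  expect_equal(summ$totals$cef, 0, tolerance = 1e-8)
  expect_error(summarize_pathways(dark, sol, tags = "nope"), "unknown pathway")
})

test_that("condition specs round-trip through YAML with table references", {
  dir <- withr::local_tempdir()
  cfg <- toy_config()
  model <- toy_model()
  expr <- generate_expression_profiles(model, cfg)
  aa <- generate_amino_acid_tables(cfg)
  write_expression_table(expr$soil, file.path(dir, "expression_soil.tsv"))
  write_amino_acid_table(aa$soil, file.path(dir, "amino_acids_soil.csv"))
  yaml::write_yaml(list(name = "soil", photon_bound = 4.5,
                        sucrose_bound = 0,
                        expression_table = "expression_soil.tsv",
                        amino_acid_table = "amino_acids_soil.csv"),
                   file.path(dir, "soil.yaml"))
  spec <- read_condition_spec(file.path(dir, "soil.yaml"))
  expect_identical(spec$name, "soil")
  expect_equal(spec$photon_bound, 4.5)
  expect_s3_class(spec$expression_table, "expression_table")
  expect_equal(nrow(spec$amino_acid_table$data), 20)
})
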