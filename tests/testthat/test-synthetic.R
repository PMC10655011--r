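test_that("the generated toy model has the declared boundary structure", {
  m <- toy_model()
  expect_length(exchange_ids(m), 22)
  expect_length(biomass_drain_ids(m), 47)
  expect_setequal(names(m$compartments), c("c", "m", "p", "x", "v"))
  # every enzymatic (biochemical) reaction carries a GPR
  enz <- m$reactions[m$reactions$kind == "biochemical", ]
  expect_true(all(nzchar(enz$gpr)))
  # GPR structure mix: single genes, ORs and ANDs all present
  expect_true(any(grepl(" or ", enz$gpr)))
  expect_true(any(grepl(" and ", enz$gpr)))
  expect_true(any(!grepl(" or | and ", enz$gpr)))
})

test_that("generation is bit-reproducible for a fixed seed", {
  cfg <- generator_config(seed = 99L)
  m1 <- generate_toy_plant_model(cfg)
  m2 <- generate_toy_plant_model(cfg)
  expect_identical(m1$reactions, m2$reactions)
  expect_identical(m1$stoichiometry, m2$stoichiometry)
  e1 <- generate_expression_profiles(m1, cfg)
  e2 <- generate_expression_profiles(m2, cfg)
  expect_identical(e1$soil$data, e2$soil$data)
  expect_identical(e1$in_vitro$data, e2$in_vitro$data)
  # a different seed changes the expression draws
  e3 <- generate_expression_profiles(m1, generator_config(seed = 100L))
  expect_false(identical(e1$soil$data, e3$soil$data))
})

test_that("the toy model passes the curation battery without repairs", {
  m <- toy_model()
  expect_length(check_mass_balance(m)$imbalanced, 0)
  expect_lt(detect_energy_cycles(m, "ATP")$max_flux, 1e-8)
  expect_equal(compute_po_ratio(m, "NADH"), 1.875, tolerance = 1e-9)
  expect_equal(compute_po_ratio(m, "succinate"), 1.125, tolerance = 1e-9)
  comp <- get_biomass_composition(m)
  expect_equal(biomass_molar_mass(comp), 1, tolerance = 1e-12)
  expect_equal(rescale_biomass(comp)$coefficient, comp$coefficient,
               tolerance = 1e-12)
})

test_that("soil-preset FBA on the toy model grows", {
  sols <- toy_condition_solutions()
  expect_gt(sols$soil$objective_value, 0)
})

test_that("replicate noise honours the configured CV", {
  cfg0 <- generator_config(seed = 5L, fpkm_cv = 0)
  m <- generate_toy_plant_model(cfg0)
  e <- generate_expression_profiles(m, cfg0)
  vals <- as.matrix(e$soil$data[, c("rep1", "rep2", "rep3")])
  expect_true(all(abs(vals - vals[, 1]) < 1e-12))
  # with noise, replicates differ
  cfgn <- generator_config(seed = 5L, fpkm_cv = 0.3)
  en <- generate_expression_profiles(m, cfgn)
  valsn <- as.matrix(en$soil$data[, c("rep1", "rep2", "rep3")])
  expect_gt(max(abs(valsn - valsn[, 1])), 0)
})

test_that("expression fold changes match the closed form at zero noise", {
  cfg <- generator_config(seed = 7L, fpkm_cv = 0,
                          expression_folds = c(gs = 3))
  m <- generate_toy_plant_model(cfg)
  e <- generate_expression_profiles(m, cfg)
  gene_map <- attr(m, "gene_pathways")
  gs_genes <- names(gene_map)[gene_map == "gs"]
  s_soil <- summarize_expression(e$soil)
  s_vitro <- summarize_expression(e$in_vitro)
  for (g in gs_genes) {
    b <- mean(as.numeric(e$soil$data[e$soil$data$gene_id == g,
                                     c("rep1", "rep2", "rep3")]))
    expect_equal(s_vitro[[g]] / s_soil[[g]],
                 log2(3 * b + 1) / log2(b + 1), tolerance = 1e-9)
  }
  # genes of unlisted pathways keep identical profiles
  other <- names(gene_map)[gene_map == "tca"][1]
  expect_equal(s_vitro[[other]], s_soil[[other]], tolerance = 1e-12)
})

test_that("a fold map naming an unknown pathway tag errors", {
  cfg <- generator_config(expression_folds = c(flying = 2))
  m <- toy_model()
  expect_error(generate_expression_profiles(m, cfg), "unknown pathway tag")
})

test_that("amino-acid tables reproduce the reported fold changes", {
  tabs <- generate_amino_acid_tables(toy_config())
  soil <- stats::setNames(tabs$soil$data$umol_per_g, tabs$soil$data$name)
  vitro <- stats::setNames(tabs$in_vitro$data$umol_per_g,
                           tabs$in_vitro$data$name)
  expect_equal(vitro[["Gln"]] / soil[["Gln"]], 4.92, tolerance = 1e-12)
  expect_equal(vitro[["Asn"]] / soil[["Asn"]], 1.92, tolerance = 1e-12)
  expect_equal(vitro[["Ser"]] / soil[["Ser"]], 1.21, tolerance = 1e-12)
  expect_equal(vitro[["Val"]] / soil[["Val"]], 1.19, tolerance = 1e-12)
  expect_equal(vitro[["Pro"]] / soil[["Pro"]], 0.82, tolerance = 1e-12)
  expect_equal(sum(vitro) / sum(soil), 2, tolerance = 1e-12)
  # the unreported acids share one common fold
  rest <- setdiff(names(soil), c("Gln", "Asn", "Ser", "Val", "Pro"))
  folds <- vitro[rest] / soil[rest]
  expect_lt(diff(range(folds)), 1e-12)
})

test_that("an identity fold map reproduces the soil table", {
  cfg <- generator_config(amino_acid_folds = c(Gln = 1, Asn = 1, Ser = 1,
                                               Val = 1, Pro = 1),
                          total_aa_ratio = 1)
  tabs <- generate_amino_acid_tables(cfg)
  expect_equal(tabs$in_vitro$data$umol_per_g, tabs$soil$data$umol_per_g,
               tolerance = 1e-12)
})

test_that("unattainable total ratios are rejected", {
  cfg <- generator_config(total_aa_ratio = 1.2)
  expect_error(generate_amino_acid_tables(cfg), "unattainable")
})

test_that("the study input bundle is written completely", {
  dir <- withr::local_tempdir()
  generate_study_inputs(dir, toy_config())
  files <- list.files(dir)
  expect_true(all(c("toy_model.json", "toy_model.xml",
                    "expression_soil.tsv", "expression_in_vitro.tsv",
                    "amino_acids_soil.csv", "amino_acids_in_vitro.csv",
                    "pathway_tags.tsv") %in% files))
  m <- read_model(file.path(dir, "toy_model.json"))
  expect_equal(nrow(m$reactions), nrow(toy_model()$reactions))
})
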