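draft_tables <- function() {
  list(
    reactions = data.frame(
      id = c("r1", "r2", "r3", "r4", "r5"),
      equation = c("glc + atp --> g6p + adp",
                   "g6p <=> f6p",
                   "f6p --> 2 g3p",
                   "g3p --> pyr",
                   "pyr --> "),
      stringsAsFactors = FALSE),
    gprs = data.frame(
      reaction_id = c("r1", "r2", "r3"),
      gpr = c("(g1 or g2) and g3", "g4", "g5 or g6"),
      stringsAsFactors = FALSE))
}

test_that("assemble_draft builds a cytosolic draft from tables", {
  tabs <- draft_tables()
  draft <- assemble_draft(tabs$reactions, tabs$gprs)
  expect_equal(nrow(draft$reactions), 5)
  expect_true(all(draft$metabolites$compartment == "c"))
  expect_true(all(endsWith(draft$metabolites$id, "_c")))
  # GPR parsed as AND(OR(g1, g2), g3)
  expr <- parse_gpr(draft$reactions$gpr[draft$reactions$id == "r1"])
  expect_identical(expr$op, "and")
  expect_identical(expr$args[[1]]$op, "or")
  # reversible arrow becomes reversible bounds
  expect_equal(draft$reactions$lower_bound[draft$reactions$id == "r2"], -1000)
})

test_that("assemble_draft reports malformed rows and warns on empty input", {
  tabs <- draft_tables()
  tabs$reactions$equation[3] <- "f6p -->--> g3p"
  expect_error(assemble_draft(tabs$reactions, tabs$gprs), "row 3")
  expect_warning(
    empty <- assemble_draft(data.frame(id = character(0),
                                       equation = character(0))),
    "empty")
  expect_equal(nrow(empty$reactions), 0)
})

evidence_table <- function() {
  data.frame(
    gene_id = c("g1", "g1", "g4", "g5", "g6"),
    source = c("uniprot", "predictor", "predictor", "related_gem",
               "related_gem"),
    compartment = c("p", "m", "x", "m", "m"),
    stringsAsFactors = FALSE)
}

test_that("compartment assignment follows the evidence cascade", {
  draft <- assemble_draft(draft_tables()$reactions, draft_tables()$gprs)
  out <- assign_compartments(draft, evidence_table())
  loc <- attr(out, "localization")
  # uniprot beats predictor for g1: r1 goes to the plastid
  expect_identical(loc$compartment[loc$reaction == "r1"], "p")
  expect_identical(loc$tier[loc$reaction == "r1"], "uniprot")
  # predictor-only gene g4: peroxisome
  expect_identical(loc$compartment[loc$reaction == "r2"], "x")
  # no evidence: cytosol default
  expect_identical(loc$compartment[loc$reaction == "r4"], "c")
  expect_identical(loc$tier[loc$reaction == "r4"], "default")
  # relocated reaction ids re-suffixed
  expect_true("glc_p" %in% out$metabolites$id)
})

test_that("same-tier conflicts take the first record and are flagged", {
  ev <- rbind(evidence_table(),
              data.frame(gene_id = "g4", source = "predictor",
                         compartment = "v", stringsAsFactors = FALSE))
  draft <- assemble_draft(draft_tables()$reactions, draft_tables()$gprs)
  expect_warning(out <- assign_compartments(draft, ev), "conflicting")
  loc <- attr(out, "localization")
  expect_identical(loc$compartment[loc$reaction == "r2"], "x") # first record
})

test_that("assignment is order-independent given the tie rule", {
  draft <- assemble_draft(draft_tables()$reactions, draft_tables()$gprs)
  ev <- evidence_table()
  out1 <- assign_compartments(draft, ev)
  # permuting rows of different genes (not within-tier duplicates) is neutral
  out2 <- assign_compartments(draft, ev[c(3, 4, 5, 1, 2), ])
  expect_identical(attr(out1, "localization"), attr(out2, "localization"))
})

test_that("multi-compartment evidence duplicates the reaction", {
  draft <- assemble_draft(draft_tables()$reactions, draft_tables()$gprs)
  ev <- data.frame(gene_id = c("g5", "g6"), source = "uniprot",
                   compartment = c("m", "p"), stringsAsFactors = FALSE)
  out <- assign_compartments(draft, ev)
  expect_true(all(c("r3_m", "r3_p") %in% reaction_ids(out)))
  expect_false("r3" %in% reaction_ids(out))
})

test_that("transport reactions are named by compartment and hub-checked", {
  m <- metabolic_model(
    "t", list(metabolite("3pg_p", formula = "C3H7O7P"),
              metabolite("mal_m", formula = "C4H6O5")),
    list(reaction("dummy", c(`3pg_p` = -1, `3pg_p` = 1)[1])),
    objective = "dummy", validate = FALSE)
  tab <- data.frame(species = c("3pg", "mal"), label = c("3PG", "Mal"),
                    compartment = c("p", "m"), stringsAsFactors = FALSE)
  out <- add_transport_reactions(m, tab)
  expect_true(all(c("3PG_pc", "Mal_mc") %in% reaction_ids(out)))
  expect_equal(out$stoichiometry$`3PG_pc`,
               c(`3pg_p` = -1, `3pg_c` = 1))
  expect_identical(
    out$reactions$kind[out$reactions$id == "Mal_mc"], "transport")
  # direct plastid<->mitochondrion transport is rejected
  bad <- data.frame(species = "3pg", compartment = "pm",
                    stringsAsFactors = FALSE)
  expect_error(add_transport_reactions(m, bad), "cytosol")
})

test_that("transport energy costs add ATP hydrolysis stoichiometry", {
  m <- metabolic_model(
    "t", list(metabolite("suc_c", formula = "C12H22O11"),
              metabolite("atp_c"), metabolite("adp_c"),
              metabolite("pi_c"), metabolite("h2o_c")),
    list(reaction("Suc_Cyto_tx", c(suc_c = 1))),
    objective = "Suc_Cyto_tx")
  tab <- data.frame(species = "suc", label = "Suc", compartment = "v",
                    atp_cost = 1, stringsAsFactors = FALSE)
  out <- add_transport_reactions(m, tab)
  st <- out$stoichiometry$Suc_vc
  expect_equal(st[["atp_c"]], -1)
  expect_equal(st[["adp_c"]], 1)
  # energized transport is made irreversible
  expect_equal(out$reactions$lower_bound[out$reactions$id == "Suc_vc"], 0)
})

test_that("the default boundary yields 22 exchanges and 47 drains", {
  m <- toy_model()
  expect_length(exchange_ids(m), 22)
  expect_length(biomass_drain_ids(m), 47)
  expect_true(all(endsWith(exchange_ids(m), "_Cyto_tx")))
  expect_true(all(endsWith(biomass_drain_ids(m), "_biomass")))
})

test_that("boundary application is guarded against duplication", {
  m <- toy_model()
  spec <- phytoflux:::.toy_boundary_spec()
  expect_error(add_boundary(m, spec), "already applied")
})

test_that("an empty boundary spec leaves the model unchanged", {
  m <- chain_model()
  spec <- boundary_spec(
    exchanges = data.frame(label = character(0), species = character(0),
                           direction = character(0), bound = numeric(0)),
    biomass_components = data.frame(name = character(0),
                                    component = character(0),
                                    coefficient = numeric(0)))
  expect_identical(add_boundary(m, spec), m)
})

test_that("boundary specs round-trip through YAML", {
  spec <- phytoflux:::.toy_boundary_spec()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_boundary_spec(spec, path)
  spec2 <- read_boundary_spec(path)
  expect_equal(spec2$exchanges$species, spec$exchanges$species)
  expect_equal(spec2$biomass_components$coefficient,
               spec$biomass_components$coefficient, tolerance = 1e-12)
})
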