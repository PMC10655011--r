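# Shared fixtures: tiny hand-built models and a cached copy of the synthetic
# toy plant model (expensive pieces are computed once per test run).

.cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .cache)) assign(key, fn(), envir = .cache)
  get(key, envir = .cache)
}

toy_config <- function() generator_config(seed = 42L)

toy_model <- function() {
  cached("toy_model", function() generate_toy_plant_model(toy_config()))
}

toy_condition_solutions <- function() {
  cached("toy_solutions", function() {
    model <- toy_model()
    specs <- generate_condition_specs(model, toy_config())
    list(soil = simulate_condition(model, specs$soil),
         in_vitro = simulate_condition(model, specs$in_vitro))
  })
}

# Linear chain: A imported (uptake <= 1), converted to B, drained by the
# objective.  The simplest growing model.
chain_model <- function(uptake = 1) {
  metabolic_model(
    "chain",
    metabolites = list(metabolite("a_c", formula = "C"),
                       metabolite("b_c", formula = "C")),
    reactions = list(
      reaction("A_Cyto_tx", c(a_c = 1), 0, uptake),
      reaction("conv", c(a_c = -1, b_c = 1), 0, 1000),
      reaction("sink", c(b_c = -1), 0, 1000)),
    objective = "sink")
}

# Branched fixture with competing yields: substrate S can go through a
# high-yield 2-step route (1 S -> 1 P) or a lossy direct route
# (2 S -> 1 P); a side route makes Q worth nothing.  8 reactions, used for
# vertex-enumeration cross-checks.
branched_model <- function() {
  metabolic_model(
    "branched",
    metabolites = list(metabolite("s_c", formula = "C2"),
                       metabolite("i_c", formula = "C2"),
                       metabolite("p_c", formula = "C2"),
                       metabolite("q_c", formula = "C2")),
    reactions = list(
      reaction("S_Cyto_tx", c(s_c = 1), 0, 10),
      reaction("direct", c(s_c = -2, p_c = 1), 0, 1000),
      reaction("step1", c(s_c = -1, i_c = 1), 0, 6),
      reaction("step2", c(i_c = -1, p_c = 1), 0, 1000),
      reaction("leak", c(i_c = -1, q_c = 1), 0, 1000),
      reaction("q_sink", c(q_c = -1), 0, 1000),
      reaction("p_sink", c(p_c = -1), 0, 1000),
      reaction("back", c(p_c = -1, i_c = 1), 0, 1000)),
    objective = "p_sink")
}

# Minimal proton-explicit respiratory chain with configurable proton
# stoichiometry: h_donor protons pumped per donor oxidized, h_atp protons
# consumed per ATP.  Used to assert the closed-form P/O property.
mini_etc_model <- function(h_donor = 10, h_atp = 16 / 3) {
  metabolic_model(
    "mini_etc",
    metabolites = list(
      metabolite("nadh_m"), metabolite("nad_m"), metabolite("q_m"),
      metabolite("qh2_m"), metabolite("succ_m"), metabolite("fum_m"),
      metabolite("o2_m"), metabolite("h2o_m"), metabolite("h_m"),
      metabolite("h_im_m"), metabolite("adp_m"), metabolite("atp_m"),
      metabolite("pi_m"), metabolite("o2_c")),
    reactions = list(
      # lumped chain: donor -> O2 with h_donor protons translocated
      reaction("CPLX1_m", c(nadh_m = -1, q_m = -1,
                            h_m = -h_donor, nad_m = 1, qh2_m = 1,
                            h_im_m = h_donor), 0, 1000),
      reaction("SDH_m", c(succ_m = -1, q_m = -1, fum_m = 1, qh2_m = 1),
               0, 1000),
      reaction("QOX_m", c(qh2_m = -1, o2_m = -0.5, q_m = 1, h2o_m = 1),
               0, 1000),
      reaction("ATPS_m", c(adp_m = -1, pi_m = -1, h_im_m = -h_atp,
                           atp_m = 1, h2o_m = 1, h_m = h_atp), 0, 1000),
      reaction("O2_mc", c(o2_c = -1, o2_m = 1), -1000, 1000),
      reaction("O2_Cyto_tx", c(o2_c = 1), -1000, 1000)),
    objective = "ATPS_m")
}

expect_fluxes_close <- function(sol, expected, tol = 1e-6) {
  for (rid in names(expected)) {
    expect_lt(abs(sol$fluxes[[rid]] - expected[[rid]]), tol,
              label = sprintf("flux of %s", rid))
  }
}
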