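# Condition presets (soil-grown vs in-vitro), paired simulation, per-reaction
# flux comparison and energy/redox accounting.

#' Define a growth-condition preset
#'
#' The soil preset is photoautotrophic: photons open, every organic carbon
#' source closed.  The in-vitro preset allows photon influx plus sucrose as
#' carbon and energy input.  Nitrogen is supplied as 50% nitrate / 50%
#' ammonium in both.
#'
#' @param name `"soil"`, `"in_vitro"` or `"custom"`.
#' @param photon_bound Photon exchange upper bound (flux units, >= 0).
#' @param sucrose_bound Sucrose exchange upper bound (must be 0 for the soil
#'   preset).
#' @param co2_bound CO2 exchange availability magnitude, or `NULL` to keep
#'   the E-Flux default of 1.  The in-vitro preset uses a reduced value to
#'   represent the poor gas exchange of a sealed culture vessel.
#' @param expression_table An [expression_table()] for the condition.
#' @param amino_acid_table An [amino_acid_table()] for the condition.
#' @param nitrogen_coupling Only `"fifty_fifty"` is defined.
#' @return A `condition_spec` object.
#' @export
condition_spec <- function(name = c("soil", "in_vitro", "custom"),
                           photon_bound, sucrose_bound = 0,
                           co2_bound = NULL,
                           expression_table = NULL, amino_acid_table = NULL,
                           nitrogen_coupling = "fifty_fifty") {
  name <- match.arg(name)
  stopifnot(photon_bound >= 0, sucrose_bound >= 0,
            is.null(co2_bound) || co2_bound >= 0)
  nitrogen_coupling <- match.arg(nitrogen_coupling, "fifty_fifty")
  if (name == "soil" && sucrose_bound != 0) {
    stop("the soil preset requires sucrose_bound = 0 (no organic energy source)")
  }
  structure(list(name = name, photon_bound = photon_bound,
                 sucrose_bound = sucrose_bound, co2_bound = co2_bound,
                 expression_table = expression_table,
                 amino_acid_table = amino_acid_table,
                 nitrogen_coupling = nitrogen_coupling),
            class = "condition_spec")
}

#' Read a condition spec from YAML
#'
#' The YAML holds `name`, `photon_bound`, `sucrose_bound` and file
#' references `expression_table` / `amino_acid_table` resolved relative to
#' the YAML's directory.
#'
#' @param path YAML file.
#' @return A [condition_spec()].
#' @export
read_condition_spec <- function(path) {
  x <- yaml::read_yaml(path)
  dir <- dirname(path)
  et <- if (!is.null(x$expression_table)) {
    read_expression_table(file.path(dir, x$expression_table),
                          condition = x$name)
  }
  at <- if (!is.null(x$amino_acid_table)) {
    read_amino_acid_table(file.path(dir, x$amino_acid_table),
                          condition = x$name)
  }
  condition_spec(x$name, x$photon_bound, x$sucrose_bound %||% 0,
                 co2_bound = x$co2_bound,
                 expression_table = et, amino_acid_table = at)
}

#' Simulate a growth condition
#'
#' Applies, in order: E-Flux bounds from the condition's expression table,
#' the measured free amino acids folded into the biomass equation, the
#' exchange preset (photons at `photon_bound`, sucrose at `sucrose_bound`,
#' all other organic carbon sources closed), the 50/50 nitrate/ammonium
#' coupling, and finally parsimonious FBA with biomass maximization.
#'
#' @param model A curated `metabolic_model` with GPRs.
#' @param spec A [condition_spec()].
#' @return A `flux_solution`; the contextualized model is attached as
#'   attribute `"model"`.  An infeasible preset is reported with the binding
#'   zero-bound reactions in the error message.
#' @export
simulate_condition <- function(model, spec) {
  stopifnot(inherits(spec, "condition_spec"))
  m <- model
  if (!is.null(spec$expression_table)) {
    m <- apply_eflux(m, spec$expression_table)
  }
  if (!is.null(spec$amino_acid_table)) {
    comp <- incorporate_amino_acids(get_biomass_composition(m),
                                    spec$amino_acid_table)
    m <- set_biomass_composition(m, comp)
  }
  cls <- .classify_exchanges(m)
  m <- set_bounds(m, cls$organic, lower = 0, upper = 0)
  m <- set_bounds(m, cls$photon, lower = 0, upper = spec$photon_bound)
  suc_ex <- Filter(function(rid)
    grepl("^suc_", .exchange_species(m, rid)), cls$organic)
  if (spec$sucrose_bound > 0) {
    if (!length(suc_ex)) stop("model has no sucrose exchange")
    m <- set_bounds(m, suc_ex[[1]], lower = 0, upper = spec$sucrose_bound)
  }
  if (!is.null(spec$co2_bound)) {
    if (!length(cls$co2)) stop("model has no CO2 exchange")
    m <- set_bounds(m, cls$co2, lower = -spec$co2_bound,
                    upper = spec$co2_bound)
  }
  coupling <- nitrogen_fifty_fifty(m)
  sol <- solve_pfba(m, coupling = coupling)
  if (sol$status != "optimal") {
    zeroed <- m$reactions$id[m$reactions$upper_bound == 0 &
                               m$reactions$lower_bound == 0 &
                               model$reactions$upper_bound != 0]
    stop(sprintf(
      "condition '%s' is %s; bounds closed by the preset/E-Flux: %s",
      spec$name, sol$status,
      paste(utils::head(zeroed, 10), collapse = ", ")))
  }
  attr(sol, "model") <- m
  attr(sol, "condition") <- spec$name
  sol
}

#' Compare two flux distributions reaction by reaction
#'
#' Classifies each reaction by whether it carries flux (|v| > `threshold`)
#' under each condition and computes `log10(|v_vitro| / |v_soil|)` where both
#' do.
#'
#' @param sol_soil,sol_vitro Optimal `flux_solution`s over the same reaction
#'   set (soil-grown and in-vitro by convention).
#' @param threshold Zero-flux threshold (default 1e-8).
#' @return Data frame with columns `reaction`, `flux_soil`, `flux_vitro`,
#'   `class` (`both`, `vitro_only`, `soil_only`, `neither`) and `log10_fc`
#'   (`NA` unless `class == "both"`).
#' @export
compare_fluxes <- function(sol_soil, sol_vitro, threshold = 1e-8) {
  stopifnot(inherits(sol_soil, "flux_solution"),
            inherits(sol_vitro, "flux_solution"))
  if (!setequal(names(sol_soil$fluxes), names(sol_vitro$fluxes))) {
    stop("flux solutions cover different reaction sets")
  }
  ids <- names(sol_soil$fluxes)
  vs <- sol_soil$fluxes[ids]
  vv <- sol_vitro$fluxes[ids]
  on_s <- abs(vs) > threshold
  on_v <- abs(vv) > threshold
  cls <- ifelse(on_s & on_v, "both",
                ifelse(on_v, "vitro_only",
                       ifelse(on_s, "soil_only", "neither")))
  fc <- ifelse(cls == "both", log10(abs(vv) / abs(vs)), NA_real_)
  data.frame(reaction = ids, flux_soil = unname(vs), flux_vitro = unname(vv),
             class = unname(cls), log10_fc = unname(fc),
             stringsAsFactors = FALSE)
}

#' Write a flux comparison to TSV
#' @param comparison Output of [compare_fluxes()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_flux_comparison <- function(comparison, path) {
  utils::write.table(comparison, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export classed reactions as a DOT graph
#'
#' Produces a Graphviz DOT rendering of the reactions that carry flux in at
#' least one condition: solid bold edges for in-vitro-only reactions, dotted
#' edges for soil-only ones, plain edges for shared ones (mirroring the
#' bold/dotted arrow convention of pathway-map figures).
#'
#' @param comparison Output of [compare_fluxes()].
#' @param model The `metabolic_model` the solutions came from.
#' @param path Output `.dot` path.
#' @return The path, invisibly.
#' @export
write_comparison_dot <- function(comparison, model, path) {
  used <- comparison[comparison$class != "neither", , drop = FALSE]
  lines <- c("digraph flux_comparison {", "  rankdir=LR;")
  style <- c(both = "solid", vitro_only = "bold", soil_only = "dotted")
  for (k in seq_len(nrow(used))) {
    rid <- used$reaction[k]
    st <- model$stoichiometry[[rid]]
    subs <- names(st)[st < 0]
    prods <- names(st)[st > 0]
    if (!length(subs) || !length(prods)) next
    for (s in subs) for (p in prods) {
      lines <- c(lines, sprintf('  "%s" -> "%s" [style=%s, label="%s"];',
                                s, p, style[[used$class[k]]], rid))
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Energy and redox accounting of a flux solution
#'
#' Sums gross ATP production by the proton-pumping ATP synthases (reactions
#' whose subsystem matches `synthase_pattern`) and gross NADH/NADPH
#' production over all reactions, raw and normalized by the biomass rate.
#' Production is counted gross: positive formation only, since net turnover
#' of a balanced cofactor is zero at steady state.
#'
#' @param model A `metabolic_model`.
#' @param sol An optimal `flux_solution` on `model`.
#' @param biomass_flux Biomass rate used for normalization; defaults to the
#'   solution's objective value.
#' @param synthase_pattern Regex selecting ATP-synthase subsystems.
#' @return List with `raw` and `per_biomass`, each holding `ATP_protonpump`,
#'   `NADH_net` and `NADPH_net`; `per_biomass` is `NA` (flagged via
#'   `normalized_defined = FALSE`) when `biomass_flux <= 0`.
#' @export
account_energy_redox <- function(model, sol, biomass_flux = NULL,
                                 synthase_pattern = "atp_synthase") {
  stopifnot(inherits(sol, "flux_solution"), sol$status == "optimal")
  if (is.null(biomass_flux)) biomass_flux <- sol$objective_value
  synthases <- model$reactions$id[grepl(synthase_pattern,
                                        model$reactions$subsystem)]
  gross_production <- function(species_regex, rids = model$reactions$id) {
    met_ids <- model$metabolites$id[grepl(species_regex, model$metabolites$id)]
    total <- 0
    for (rid in rids) {
      st <- model$stoichiometry[[rid]]
      hit <- intersect(names(st), met_ids)
      if (length(hit)) {
        prod <- sum(st[hit]) * sol$fluxes[[rid]]
        if (prod > 0) total <- total + prod
      }
    }
    total
  }
  atp <- gross_production("^atp_", rids = synthases)
  nadh <- gross_production("^nadh_")
  nadph <- gross_production("^nadph_")
  raw <- c(ATP_protonpump = atp, NADH_net = nadh, NADPH_net = nadph)
  defined <- is.finite(biomass_flux) && biomass_flux > 0
  list(raw = as.list(raw),
       per_biomass = if (defined) as.list(raw / biomass_flux) else
         as.list(stats::setNames(rep(NA_real_, 3), names(raw))),
       biomass_flux = biomass_flux,
       normalized_defined = defined)
}

#' Pathway-level flux totals
#'
#' Sums absolute fluxes over each pathway of the model's membership map and
#' reports the cyclic/linear electron flow and GS/GOGAT flux ratios.
#'
#' @param model A `metabolic_model` with a `pathways` map (tag -> reaction
#'   ids).
#' @param sol An optimal `flux_solution`.
#' @param tags Pathway tags to report; defaults to all mapped tags.  Unknown
#'   tags raise an error.
#' @return List with `totals` (named numeric), `cef_lef_ratio` and
#'   `gs_gogat_ratio` (`NA` when a denominator is zero).
#' @export
summarize_pathways <- function(model, sol, tags = NULL) {
  stopifnot(inherits(sol, "flux_solution"), sol$status == "optimal")
  if (is.null(model$pathways)) stop("model has no pathway membership map")
  if (is.null(tags)) tags <- names(model$pathways)
  unknown <- setdiff(tags, names(model$pathways))
  if (length(unknown)) {
    stop(sprintf("unknown pathway tag(s): %s", paste(unknown, collapse = ", ")))
  }
  totals <- vapply(tags, function(tag) {
    sum(abs(sol$fluxes[model$pathways[[tag]]]))
  }, numeric(1))
  ratio <- function(num, den) {
    if (!num %in% tags || !den %in% tags || totals[[den]] <= 0) NA_real_
    else totals[[num]] / totals[[den]]
  }
  list(totals = as.list(totals),
       cef_lef_ratio = ratio("cef", "lef"),
       gs_gogat_ratio = ratio("gs", "gogat"))
}

#' Write a pathway summary to JSON
#' @param summary Output of [summarize_pathways()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pathway_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
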