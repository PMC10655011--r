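# Model curation battery: reversibility rules, energy-generating-cycle
# detection, P/O ratio enforcement, weighted-pFBA gap-filling,
# reduction-degree yield checks and biomass molecular-weight rescaling.

#' Apply reversibility rules
#'
#' Each rule narrows (or flips) a reaction's bounds: `forward` clamps the
#' lower bound to >= 0, `reverse` clamps the upper bound to <= 0,
#' `reversible` restores the default reversible bounds `[-1000, 1000]`.
#' Rules never widen bounds beyond the defaults.
#'
#' @param model A `metabolic_model`.
#' @param rules Data frame with columns `reaction_id` and `directionality`
#'   (`forward`, `reverse` or `reversible`).
#' @return The modified model.
#' @export
apply_reversibility_rules <- function(model, rules) {
  stopifnot(is.data.frame(rules),
            all(c("reaction_id", "directionality") %in% names(rules)))
  for (k in seq_len(nrow(rules))) {
    rid <- rules$reaction_id[k]
    dir <- match.arg(rules$directionality[k],
                     c("forward", "reverse", "reversible"))
    idx <- match(rid, model$reactions$id)
    if (is.na(idx)) stop(sprintf("reversibility rule for unknown reaction '%s'", rid))
    lb <- model$reactions$lower_bound[idx]
    ub <- model$reactions$upper_bound[idx]
    new <- switch(dir,
                  forward = c(max(lb, 0), max(ub, 0)),
                  reverse = c(min(lb, 0), min(ub, 0)),
                  reversible = c(-1000, 1000))
    model$reactions$lower_bound[idx] <- new[1]
    model$reactions$upper_bound[idx] <- new[2]
  }
  model
}

# Species id for a currency-metabolite root in a compartment, erroring when
# absent.
.currency_species <- function(model, root, compartment) {
  id <- paste0(root, "_", compartment)
  if (!id %in% model$metabolites$id) {
    stop(sprintf("currency metabolite '%s' not present in the model", id))
  }
  id
}

#' Detect energy-generating cycles
#'
#' Closes every exchange reaction, adds a dissipation reaction for the given
#' currency metabolite (ATP hydrolysis, or NAD(P)H oxidation) and maximizes
#' its flux.  Any positive optimum demonstrates a thermodynamically
#' impossible energy/reducing-power generating cycle; the minimal active
#' reaction set of the parsimonious solution localizes it.
#'
#' @param model A `metabolic_model`.
#' @param currency `"ATP"`, `"NADH"` or `"NADPH"`.
#' @param compartment Compartment in which to dissipate (default cytosol).
#' @param threshold Production below this is treated as zero (default 1e-8).
#' @return List with `max_flux` (the dissipation optimum; 0 for a clean
#'   model) and `active_reactions` (minimal participating set, empty when
#'   clean).
#' @export
detect_energy_cycles <- function(model, currency = c("ATP", "NADH", "NADPH"),
                                 compartment = "c", threshold = 1e-8) {
  currency <- match.arg(currency)
  if (nrow(model$reactions) == 0L) {
    return(list(max_flux = 0, active_reactions = character(0)))
  }
  st <- switch(currency,
    ATP = {
      ids <- vapply(c("atp", "h2o", "adp", "pi"), .currency_species,
                    character(1), model = model, compartment = compartment)
      stats::setNames(c(-1, -1, 1, 1), ids)
    },
    NADH = {
      ids <- vapply(c("nadh", "nad"), .currency_species, character(1),
                    model = model, compartment = compartment)
      stats::setNames(c(-1, 1), ids)
    },
    NADPH = {
      ids <- vapply(c("nadph", "nadp"), .currency_species, character(1),
                    model = model, compartment = compartment)
      stats::setNames(c(-1, 1), ids)
    })
  m <- set_bounds(model, exchange_ids(model), lower = 0, upper = 0)
  diss_id <- sprintf("dissipation_%s_%s", tolower(currency), compartment)
  m <- add_reaction(m, reaction(diss_id, st, lower_bound = 0,
                                upper_bound = 1000,
                                name = sprintf("%s dissipation (diagnostic)",
                                               currency)))
  sol <- solve_fba(m, objective = diss_id, sense = "max")
  max_flux <- if (sol$status == "optimal") sol$objective_value else Inf
  active <- character(0)
  if (is.finite(max_flux) && max_flux > threshold) {
    psol <- solve_pfba(m, objective = diss_id, sense = "max")
    if (psol$status == "optimal") {
      active <- setdiff(names(psol$fluxes)[abs(psol$fluxes) > threshold],
                        diss_id)
    }
  }
  if (!is.finite(max_flux)) max_flux <- Inf
  list(max_flux = max_flux, active_reactions = active)
}

# Locate respiratory-chain reactions by their stoichiometric signature.
.find_etc_reactions <- function(model) {
  find_one <- function(pred, what) {
    hits <- Filter(function(rid) pred(model$stoichiometry[[rid]]),
                   model$reactions$id)
    if (length(hits) == 0L) {
      stop(sprintf("cannot locate %s in the model", what))
    }
    hits[[1]]
  }
  has <- function(st, id, sign) {
    id %in% names(st) && sign * st[[id]] > 0
  }
  list(
    complex1 = find_one(function(st) {
      has(st, "nadh_m", -1) && has(st, "q_m", -1) && has(st, "qh2_m", 1)
    }, "complex I (NADH:ubiquinone oxidoreductase)"),
    complex2 = find_one(function(st) {
      has(st, "succ_m", -1) && has(st, "q_m", -1) && has(st, "qh2_m", 1)
    }, "complex II (succinate dehydrogenase)"),
    synthase = find_one(function(st) {
      has(st, "atp_m", 1) && has(st, "h_im_m", -1)
    }, "the mitochondrial ATP synthase"))
}

#' Compute the respiratory P/O ratio
#'
#' Fixes the oxidation flux of the electron donor to 1, closes all
#' exchanges, supplies the donor and oxygen through diagnostic
#' pseudo-reactions, and maximizes the mitochondrial ATP synthase flux.
#' On a proton-explicit electron transport chain the optimum equals
#' (protons translocated per donor) / (protons consumed per ATP).
#'
#' @param model A `metabolic_model` with a proton-explicit mitochondrial
#'   respiratory chain (matrix protons `h_m`, intermembrane protons
#'   `h_im_m`).
#' @param donor `"NADH"` or `"succinate"`.
#' @return Mol ATP per mol donor oxidized.
#' @export
compute_po_ratio <- function(model, donor = c("NADH", "succinate")) {
  donor <- match.arg(donor)
  etc <- .find_etc_reactions(model)
  m <- set_bounds(model, exchange_ids(model), lower = 0, upper = 0)
  if (donor == "NADH") {
    src <- stats::setNames(c(-1, 1),
                           c(.currency_species(m, "nad", "m"),
                             .currency_species(m, "nadh", "m")))
    pinned <- etc$complex1
  } else {
    src <- stats::setNames(c(-1, 1),
                           c(.currency_species(m, "fum", "m"),
                             .currency_species(m, "succ", "m")))
    pinned <- etc$complex2
  }
  # the donor supply is capped at the pinned oxidation flux so the chain is
  # the only sink of exactly one reducing equivalent
  m <- add_reaction(m, reaction("po_donor_source", src, 0, 1))
  m <- add_reaction(m, reaction(
    "po_o2_source", stats::setNames(1, .currency_species(m, "o2", "m")),
    0, 1000))
  m <- add_reaction(m, reaction(
    "po_h2o_sink", stats::setNames(-1, .currency_species(m, "h2o", "m")),
    0, 1000))
  m <- add_reaction(m, reaction(
    "po_atp_dissipation",
    stats::setNames(c(-1, -1, 1, 1),
                    c(.currency_species(m, "atp", "m"),
                      .currency_species(m, "h2o", "m"),
                      .currency_species(m, "adp", "m"),
                      .currency_species(m, "pi", "m"))),
    0, 1000))
  # donor oxidation is capped (not pinned) at unit flux: ATP synthesis is
  # monotone in donor throughput, so the optimum is ATP per donor molecule,
  # and a blocked chain yields 0 rather than an infeasibility
  m <- set_bounds(m, pinned, lower = 0, upper = 1)
  sol <- solve_fba(m, objective = etc$synthase, sense = "max")
  if (sol$status != "optimal") {
    stop(sprintf(
      "P/O computation failed (%s): the electron transport chain around %s appears blocked",
      sol$status, pinned))
  }
  sol$objective_value
}

# ---- gap filling ----------------------------------------------------------

#' Define a universal reaction pool for gap-filling
#'
#' @param reactions List of [reaction()] objects (the candidates).
#' @param weights Positive numeric vector of per-candidate weights, recycled.
#' @return A `universal_pool` object.
#' @export
universal_pool <- function(reactions, weights = 1) {
  stopifnot(length(reactions) >= 1L)
  weights <- rep_len(weights, length(reactions))
  if (any(weights <= 0)) stop("pool weights must be > 0")
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate candidate ids in pool")
  structure(list(reactions = reactions,
                 weights = stats::setNames(weights, ids)),
            class = "universal_pool")
}

# FBA maximum production of `target` in `model` through a temporary sink.
.max_production <- function(model, target) {
  sink_id <- ".production_sink"
  m <- add_reaction(model, reaction(sink_id, stats::setNames(-1, target),
                                    0, 1000))
  sol <- solve_fba(m, objective = sink_id, sense = "max")
  if (sol$status != "optimal") return(0)
  sol$objective_value
}

#' Weighted-pFBA gap filling
#'
#' Finds a minimal-weight set of candidate reactions whose addition makes a
#' target metabolite producible.  Solves `min sum_pool w_j |v_j|` over the
#' merged model subject to steady state, bounds and a production constraint
#' `>= min_production`, keeps candidates carrying flux, and verifies the set
#' is irreducible by re-solving with each member removed.
#'
#' @param model A `metabolic_model` in which `target` is not (sufficiently)
#'   producible.
#' @param pool A [universal_pool()] of candidate reactions with weights.
#' @param target Metabolite id to make producible.
#' @param min_production Minimum production flux to certify (default 1e-3).
#' @param threshold Flux magnitude above which a candidate counts as used.
#' @return Character vector of added candidate reaction ids (empty when the
#'   target is already producible).
#' @export
gapfill_weighted_pfba <- function(model, pool, target, min_production = 1e-3,
                                  threshold = 1e-8) {
  stopifnot(inherits(pool, "universal_pool"))
  if (!target %in% model$metabolites$id) {
    stop(sprintf("target metabolite '%s' not in model", target))
  }
  clash <- intersect(names(pool$weights), model$reactions$id)
  if (length(clash)) {
    stop(sprintf("pool candidate ids already present in model: %s",
                 paste(clash, collapse = ", ")))
  }
  if (.max_production(model, target) >= min_production) {
    return(character(0))
  }
  merged <- model
  for (r in pool$reactions) merged <- add_reaction(merged, r)
  sink_id <- ".gapfill_sink"
  merged <- add_reaction(merged, reaction(
    sink_id, stats::setNames(-1, target), min_production, 1000))
  sol <- .min_weighted_l1(merged, weights = pool$weights)
  if (sol$status != "optimal") {
    dead <- .dead_end_precursors(merged, target, threshold = min_production)
    stop(sprintf(
      "unfillable gap: '%s' remains non-producible with the full pool%s",
      target,
      if (length(dead)) paste0("; dead-end precursor(s): ",
                               paste(dead, collapse = ", ")) else ""))
  }
  added <- names(pool$weights)[abs(sol$x[names(pool$weights)]) > threshold]
  # irreducibility: drop any member whose removal leaves the target producible
  repeat {
    redundant <- NULL
    for (rid in added) {
      trial <- model
      for (r in pool$reactions) {
        if (r$id %in% setdiff(added, rid)) trial <- add_reaction(trial, r)
      }
      if (.max_production(trial, target) >= min_production) {
        redundant <- rid
        break
      }
    }
    if (is.null(redundant)) break
    added <- setdiff(added, redundant)
  }
  added
}

# Metabolites consumed by reactions able to produce `target` that are
# themselves non-producible (one level of diagnosis for gap-fill failures).
.dead_end_precursors <- function(model, target, threshold = 1e-3) {
  producers <- Filter(function(rid) {
    st <- model$stoichiometry[[rid]]
    target %in% names(st) && st[[target]] > 0
  }, model$reactions$id)
  precursors <- unique(unlist(lapply(producers, function(rid) {
    st <- model$stoichiometry[[rid]]
    names(st)[st < 0]
  })))
  Filter(function(met) .max_production(model, met) < threshold, precursors)
}

#' Check a production pathway against its theoretical maximum yield
#'
#' The theoretical yield is the ratio of the degrees of reduction of
#' substrate and product ([reduction_degree()]).  The FBA yield is the
#' maximum product formation per unit substrate uptake with all other
#' electron sources (organic carbon, photons, nitrate) closed.
#'
#' @param model A `metabolic_model` with an exchange for the substrate.
#' @param substrate Metabolite id of the substrate (must have an exchange).
#' @param product Metabolite id of the product.
#' @param tol Slack added to the theoretical yield before flagging (1e-6).
#' @return List with `fba_yield`, `theoretical_yield` and `pass`.
#' @export
check_max_yield <- function(model, substrate, product, tol = 1e-6) {
  met_formula <- function(id) {
    f <- model$metabolites$formula[match(id, model$metabolites$id)]
    if (length(f) == 0L || is.na(f)) {
      stop(sprintf("metabolite '%s' lacks a formula", id))
    }
    f
  }
  gamma_s <- reduction_degree(met_formula(substrate))
  gamma_p <- reduction_degree(met_formula(product))
  if (gamma_p <= 0) {
    stop(sprintf("product '%s' has non-positive reduction degree: yield undefined",
                 product))
  }
  theoretical <- gamma_s / gamma_p
  cls <- .classify_exchanges(model)
  sub_ex <- Filter(function(rid) .exchange_species(model, rid) == substrate,
                   exchange_ids(model))
  if (!length(sub_ex)) {
    stop(sprintf("no exchange reaction imports substrate '%s'", substrate))
  }
  m <- set_bounds(model, exchange_ids(model), lower = 0, upper = 0)
  inorganic <- setdiff(exchange_ids(model),
                       c(cls$organic, cls$photon, cls$nitrate))
  m <- set_bounds(m, inorganic, lower = -1000, upper = 1000)
  m <- set_bounds(m, sub_ex[[1]], lower = 1, upper = 1)
  sink_id <- ".yield_sink"
  m <- add_reaction(m, reaction(sink_id, stats::setNames(-1, product),
                                0, 1000))
  sol <- solve_fba(m, objective = sink_id, sense = "max")
  fba_yield <- if (sol$status == "optimal") sol$objective_value else 0
  list(fba_yield = fba_yield, theoretical_yield = theoretical,
       pass = fba_yield <= theoretical + tol)
}

# ---- biomass molecular weight --------------------------------------------

#' Construct a biomass composition
#'
#' @param components Data frame with columns `component` (metabolite id),
#'   `name` (human label, e.g. the amino-acid code), `coefficient`
#'   (mmol/gDW, > 0) and `formula` (elemental formula).
#' @return A `biomass_composition` object.
#' @export
biomass_composition <- function(components) {
  stopifnot(is.data.frame(components),
            all(c("component", "coefficient", "formula") %in% names(components)))
  if (!"name" %in% names(components)) components$name <- components$component
  if (any(components$coefficient <= 0)) {
    stop("biomass coefficients must be > 0")
  }
  if (anyDuplicated(components$component)) {
    stop("duplicate biomass components")
  }
  rownames(components) <- NULL
  structure(components[, c("component", "name", "coefficient", "formula")],
            class = c("biomass_composition", "data.frame"))
}

#' Molar mass of the biomass pseudo-metabolite
#'
#' `sum_i coefficient_i x MW_i / 1000` in g/mmol; a consistent biomass
#' equation has molar mass 1 g/mmol, so that the biomass flux is a specific
#' growth rate in 1/time.
#'
#' @param composition A [biomass_composition()].
#' @return Molar mass in g/mmol.
#' @export
biomass_molar_mass <- function(composition) {
  missing <- composition$name[is.na(composition$formula) |
                                !nzchar(composition$formula)]
  if (length(missing)) {
    stop(sprintf("component(s) without formula: %s",
                 paste(missing, collapse = ", ")))
  }
  mw <- vapply(composition$formula, formula_mw, numeric(1))
  sum(composition$coefficient * mw) / 1000
}

#' Rescale a biomass composition to 1 g/mmol
#'
#' Uniformly scales all coefficients by the inverse of the current biomass
#' molar mass so the weighted sum of component molecular weights is exactly
#' 1 g/mmol.  Idempotent.
#'
#' @param composition A [biomass_composition()].
#' @return The rescaled composition.
#' @export
rescale_biomass <- function(composition) {
  m <- biomass_molar_mass(composition)
  composition$coefficient <- composition$coefficient / m
  composition
}

#' Extract the biomass composition of a model
#'
#' Reads the coefficients of the biomass reaction together with the source
#' species consumed by the matching `_biomass` drains.
#'
#' @param model A `metabolic_model` with a biomass reaction and drains.
#' @return A [biomass_composition()].
#' @export
get_biomass_composition <- function(model) {
  bm_id <- model$reactions$id[model$reactions$kind == "biomass"]
  if (length(bm_id) != 1L) stop("model must have exactly one biomass reaction")
  bm <- model$stoichiometry[[bm_id]]
  pools <- names(bm)[bm < 0]
  drains <- biomass_drain_ids(model)
  rows <- lapply(pools, function(pool) {
    drain <- Filter(function(rid) {
      st <- model$stoichiometry[[rid]]
      pool %in% names(st) && st[[pool]] > 0
    }, drains)
    if (!length(drain)) {
      stop(sprintf("no biomass drain produces pool species '%s'", pool))
    }
    st <- model$stoichiometry[[drain[[1]]]]
    source <- names(st)[st < 0]
    data.frame(component = source,
               name = sub("_biomass$", "", drain[[1]]),
               coefficient = -bm[[pool]],
               formula = model$metabolites$formula[
                 match(source, model$metabolites$id)],
               stringsAsFactors = FALSE)
  })
  biomass_composition(do.call(rbind, rows))
}

#' Write a biomass composition into a model
#'
#' Replaces the biomass reaction coefficients with the composition's (each
#' drain pool consumed at `coefficient` mmol/gDW).
#'
#' @param model A `metabolic_model`.
#' @param composition A [biomass_composition()] whose components match the
#'   model's biomass drains.
#' @return The modified model.
#' @export
set_biomass_composition <- function(model, composition) {
  bm_id <- model$reactions$id[model$reactions$kind == "biomass"]
  if (length(bm_id) != 1L) stop("model must have exactly one biomass reaction")
  current <- get_biomass_composition(model)
  idx <- match(composition$component, current$component)
  if (anyNA(idx)) {
    stop(sprintf("composition component(s) not in the model biomass: %s",
                 paste(composition$component[is.na(idx)], collapse = ", ")))
  }
  bm <- model$stoichiometry[[bm_id]]
  # pool species follow the drain naming: <name>_bm_c
  for (k in seq_len(nrow(composition))) {
    pool <- paste0(tolower(composition$name[k]), "_bm_c")
    if (!pool %in% names(bm)) {
      stop(sprintf("no biomass pool species '%s' in the biomass reaction", pool))
    }
    bm[[pool]] <- -composition$coefficient[k]
  }
  model$stoichiometry[[bm_id]] <- bm
  model
}

#' Run the full curation battery
#'
#' Executes, in order: elemental mass balance, energy-cycle detection for
#' ATP/NADH/NADPH, P/O ratios for NADH and succinate (when a respiratory
#' chain is present) and the biomass molar-mass check.
#'
#' @param model A `metabolic_model`.
#' @param path Optional path prefix; when given, writes `<path>.json` and a
#'   human-readable `<path>.txt` report.
#' @return List of check results.
#' @export
curation_report <- function(model, path = NULL) {
  mb <- check_mass_balance(model)
  cycles <- lapply(c(ATP = "ATP", NADH = "NADH", NADPH = "NADPH"),
                   function(cur) detect_energy_cycles(model, cur))
  po <- tryCatch(
    list(NADH = compute_po_ratio(model, "NADH"),
         succinate = compute_po_ratio(model, "succinate")),
    error = function(e) conditionMessage(e))
  bm <- tryCatch(biomass_molar_mass(get_biomass_composition(model)),
                 error = function(e) conditionMessage(e))
  report <- list(
    model = model$id,
    mass_balance = list(n_imbalanced = length(mb$imbalanced),
                        imbalanced = names(mb$imbalanced),
                        n_skipped = length(mb$skipped)),
    energy_cycles = lapply(cycles, function(x) x$max_flux),
    po_ratio = po,
    biomass_molar_mass = bm)
  if (!is.null(path)) {
    jsonlite::write_json(report, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    txt <- c(sprintf("Curation report for model '%s'", model$id),
             sprintf("  imbalanced reactions: %d (unchecked: %d)",
                     length(mb$imbalanced), length(mb$skipped)),
             sprintf("  energy-cycle optima: ATP %.3g, NADH %.3g, NADPH %.3g",
                     cycles$ATP$max_flux, cycles$NADH$max_flux,
                     cycles$NADPH$max_flux),
             if (is.list(po)) sprintf("  P/O ratios: NADH %.4f, succinate %.4f",
                                      po$NADH, po$succinate)
             else sprintf("  P/O ratios: %s", po),
             if (is.numeric(bm)) sprintf("  biomass molar mass: %.9f g/mmol", bm)
             else sprintf("  biomass molar mass: %s", bm))
    writeLines(txt, paste0(path, ".txt"))
  }
  report
}
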