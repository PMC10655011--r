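# Core domain types: compartmentalized metabolites, reactions and models.
#
# A `metabolic_model` is an S3 list with
#   * `id`            model identifier
#   * `compartments`  named character vector, code -> human name
#   * `metabolites`   data.frame(id, name, formula, charge, compartment)
#   * `reactions`     data.frame(id, name, lower_bound, upper_bound, kind,
#                      subsystem, gpr)
#   * `stoichiometry` named list: reaction id -> named numeric vector of
#                      metabolite coefficients (negative = consumed)
#   * `objective`     reaction id
#   * `pathways`      optional named list: pathway tag -> reaction ids
#
# Conventions (documented in the JSON dialect):
#   * metabolite ids end in "_<code>" for their compartment;
#   * exchange reactions end in "_Cyto_tx", have exactly one (cytosolic)
#     metabolite with coefficient +1, and are written import-positive:
#     positive flux means uptake, bounds encode availability;
#   * biomass drain reactions end in "_biomass";
#   * external/boundary species are not represented: an exchange's single
#     metabolite row is its intracellular face.

COMPARTMENT_CODES <- c(
  c = "cytosol", m = "mitochondrion", p = "plastid",
  x = "peroxisome", v = "vacuole"
)

#' Construct a metabolite
#'
#' @param id Metabolite id; must end in `"_<code>"` where `<code>` is the
#'   compartment code (`c`, `m`, `p`, `x`, `v`).
#' @param name Human-readable name (defaults to the id).
#' @param formula Elemental formula string or `NA` when unknown (photons,
#'   generic pools).
#' @param charge Integer charge or `NA`.
#' @param compartment Compartment code; inferred from the id suffix when
#'   missing.
#' @return A `metabolite` object (named list).
#' @export
metabolite <- function(id, name = id, formula = NA_character_,
                       charge = NA_integer_, compartment = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.null(compartment)) {
    compartment <- sub("^.*_([a-z])$", "\\1", id)
  }
  if (!compartment %in% names(COMPARTMENT_CODES)) {
    stop(sprintf("metabolite '%s': unknown compartment '%s'", id, compartment))
  }
  if (!endsWith(id, paste0("_", compartment))) {
    stop(sprintf("metabolite id '%s' does not end in '_%s'", id, compartment))
  }
  if (!is.na(formula)) parse_formula(formula) # validates
  structure(list(id = id, name = name, formula = as.character(formula),
                 charge = as.integer(charge), compartment = compartment),
            class = "metabolite")
}

#' Construct a reaction
#'
#' @param id Reaction id.  Ids ending `"_Cyto_tx"` are exchanges, ids ending
#'   `"_biomass"` are biomass drains.
#' @param stoichiometry Named numeric vector of metabolite coefficients
#'   (negative = consumed, positive = produced).
#' @param lower_bound,upper_bound Flux bounds.  Defaults: irreversible
#'   `[0, 1000]`; pass `lower_bound = -1000` for reversible reactions.
#' @param gpr GPR string or parsed tree ([parse_gpr()]); `""`/`NULL` = none.
#' @param name Human-readable name.
#' @param subsystem Pathway/subsystem label.
#' @param kind One of `biochemical`, `transport`, `exchange`, `biomass_drain`,
#'   `biomass`.  Derived from the id suffix and stoichiometry when `NULL`;
#'   only `kind = "biomass"` normally needs to be stated.
#' @return A `reaction` object (named list).
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     gpr = "", name = id, subsystem = "", kind = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(stoichiometry) || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry)))) {
    stop(sprintf("reaction '%s': stoichiometry must be a named numeric vector", id))
  }
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (anyDuplicated(names(stoichiometry))) {
    stop(sprintf("reaction '%s': duplicated metabolite in stoichiometry", id))
  }
  if (!is.numeric(lower_bound) || !is.numeric(upper_bound) ||
      lower_bound > upper_bound) {
    stop(sprintf("reaction '%s': requires lower_bound <= upper_bound", id))
  }
  gpr_str <- if (is.character(gpr) || is.null(gpr)) {
    if (is.null(gpr) || length(gpr) == 0L || is.na(gpr)) "" else gpr
  } else {
    gpr_to_string(gpr)
  }
  if (nzchar(gpr_str)) parse_gpr(gpr_str) # validates
  if (is.null(kind)) kind <- .derive_reaction_kind(id, stoichiometry)
  kind <- match.arg(kind, c("biochemical", "transport", "exchange",
                            "biomass_drain", "biomass"))
  structure(list(id = id, name = name, stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gpr = gpr_str, subsystem = subsystem, kind = kind),
            class = "reaction")
}

.met_compartment <- function(met_id) sub("^.*_([a-z])$", "\\1", met_id)

.derive_reaction_kind <- function(id, stoichiometry) {
  if (endsWith(id, "_Cyto_tx")) return("exchange")
  if (endsWith(id, "_biomass")) return("biomass_drain")
  comps <- unique(.met_compartment(names(stoichiometry)))
  if (length(comps) >= 2L) "transport" else "biochemical"
}

#' Construct a metabolic model
#'
#' @param id Model identifier.
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @param objective Reaction id of the objective (usually the biomass
#'   reaction).
#' @param compartments Named character vector of compartment codes; defaults
#'   to the codes used by the metabolites.
#' @param pathways Optional named list mapping pathway tags to reaction ids.
#' @param validate Run [validate_model()] on the result (default `TRUE`).
#' @return A `metabolic_model` object.
#' @export
metabolic_model <- function(id, metabolites, reactions, objective,
                            compartments = NULL, pathways = NULL,
                            validate = TRUE) {
  mets <- do.call(rbind, lapply(metabolites, function(m) {
    data.frame(id = m$id, name = m$name, formula = m$formula,
               charge = m$charge, compartment = m$compartment,
               stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(reactions, function(r) {
    data.frame(id = r$id, name = r$name, lower_bound = r$lower_bound,
               upper_bound = r$upper_bound, kind = r$kind,
               subsystem = r$subsystem, gpr = r$gpr, stringsAsFactors = FALSE)
  }))
  stoich <- lapply(reactions, function(r) r$stoichiometry)
  names(stoich) <- if (is.null(rxns)) character(0) else rxns$id
  if (is.null(mets)) {
    mets <- data.frame(id = character(0), name = character(0),
                       formula = character(0), charge = integer(0),
                       compartment = character(0), stringsAsFactors = FALSE)
  }
  if (is.null(rxns)) {
    rxns <- data.frame(id = character(0), name = character(0),
                       lower_bound = numeric(0), upper_bound = numeric(0),
                       kind = character(0), subsystem = character(0),
                       gpr = character(0), stringsAsFactors = FALSE)
  }
  if (is.null(compartments)) {
    codes <- sort(unique(mets$compartment))
    compartments <- COMPARTMENT_CODES[codes]
  }
  rownames(mets) <- NULL
  rownames(rxns) <- NULL
  model <- structure(list(id = id, compartments = compartments,
                          metabolites = mets, reactions = rxns,
                          stoichiometry = stoich, objective = objective,
                          pathways = pathways),
                     class = "metabolic_model")
  if (validate) validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique metabolite/reaction ids, every
#' stoichiometry key declared, compartment suffixes consistent, bounds
#' ordered, exchange reactions single-metabolite with the `_Cyto_tx` suffix
#' convention (and vice versa), transport reactions spanning exactly two
#' compartments of which one is the cytosol, and an existing objective.
#'
#' @param model A `metabolic_model`.
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    stop(sprintf("duplicate metabolite id(s): %s",
                 paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")))
  }
  if (anyDuplicated(rxns$id)) {
    stop(sprintf("duplicate reaction id(s): %s",
                 paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", ")))
  }
  bad_suffix <- mets$id[!mapply(endsWith, mets$id, paste0("_", mets$compartment))]
  if (length(bad_suffix)) {
    stop(sprintf("metabolite id(s) without matching compartment suffix: %s",
                 paste(bad_suffix, collapse = ", ")))
  }
  if (any(rxns$lower_bound > rxns$upper_bound)) {
    stop("reaction(s) with lower_bound > upper_bound")
  }
  if (!setequal(names(model$stoichiometry), rxns$id)) {
    stop("stoichiometry list does not match reaction table")
  }
  for (rid in rxns$id) {
    missing <- setdiff(names(model$stoichiometry[[rid]]), mets$id)
    if (length(missing)) {
      stop(sprintf("reaction '%s' references undeclared metabolite(s): %s",
                   rid, paste(missing, collapse = ", ")))
    }
  }
  is_tx <- endsWith(rxns$id, "_Cyto_tx")
  if (any(is_tx != (rxns$kind == "exchange"))) {
    stop("kind 'exchange' must coincide with the '_Cyto_tx' id suffix")
  }
  is_drain <- endsWith(rxns$id, "_biomass")
  if (any(is_drain != (rxns$kind == "biomass_drain"))) {
    stop("kind 'biomass_drain' must coincide with the '_biomass' id suffix")
  }
  for (rid in rxns$id[is_tx]) {
    if (length(model$stoichiometry[[rid]]) != 1L) {
      stop(sprintf("exchange reaction '%s' must have exactly one metabolite", rid))
    }
  }
  for (rid in rxns$id[rxns$kind == "transport"]) {
    comps <- unique(.met_compartment(names(model$stoichiometry[[rid]])))
    if (length(comps) != 2L || !"c" %in% comps) {
      stop(sprintf(
        "transport reaction '%s' must span exactly two compartments, one of which is the cytosol",
        rid))
    }
  }
  if (!model$objective %in% rxns$id) {
    stop(sprintf("objective reaction '%s' not present in the model", model$objective))
  }
  if (!is.null(model$pathways)) {
    unknown <- setdiff(unlist(model$pathways), rxns$id)
    if (length(unknown)) {
      stop(sprintf("pathway map references unknown reaction(s): %s",
                   paste(unknown, collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s\n", x$id))
  cat(sprintf("  %d metabolites, %d reactions, %d compartments\n",
              nrow(x$metabolites), nrow(x$reactions), length(x$compartments)))
  kinds <- table(x$reactions$kind)
  cat("  ", paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  objective: %s\n", x$objective))
  invisible(x)
}

# ---- small accessors / editors -------------------------------------------

#' Reaction ids of a model
#' @param model A `metabolic_model`.
#' @return Character vector.
#' @export
reaction_ids <- function(model) model$reactions$id

#' Metabolite ids of a model
#' @param model A `metabolic_model`.
#' @return Character vector.
#' @export
metabolite_ids <- function(model) model$metabolites$id

#' Exchange reaction ids of a model
#' @param model A `metabolic_model`.
#' @return Character vector of reactions ending in `_Cyto_tx`.
#' @export
exchange_ids <- function(model) {
  model$reactions$id[model$reactions$kind == "exchange"]
}

#' Biomass drain reaction ids of a model
#' @param model A `metabolic_model`.
#' @return Character vector of reactions ending in `_biomass`.
#' @export
biomass_drain_ids <- function(model) {
  model$reactions$id[model$reactions$kind == "biomass_drain"]
}

#' Get or set flux bounds
#'
#' @param model A `metabolic_model`.
#' @param id Reaction id(s).
#' @param lower,upper Replacement bounds, recycled along `id`; `NULL` leaves
#'   the respective bound unchanged.
#' @return `get_bounds()`: data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`.  `set_bounds()`: the modified model.
#' @export
set_bounds <- function(model, id, lower = NULL, upper = NULL) {
  idx <- match(id, model$reactions$id)
  if (anyNA(idx)) {
    stop(sprintf("unknown reaction id(s): %s",
                 paste(id[is.na(idx)], collapse = ", ")))
  }
  if (!is.null(lower)) model$reactions$lower_bound[idx] <- rep(lower, length.out = length(idx))
  if (!is.null(upper)) model$reactions$upper_bound[idx] <- rep(upper, length.out = length(idx))
  bad <- model$reactions$lower_bound[idx] > model$reactions$upper_bound[idx]
  if (any(bad)) {
    stop(sprintf("lower_bound > upper_bound for: %s",
                 paste(id[bad], collapse = ", ")))
  }
  model
}

#' @rdname set_bounds
#' @export
get_bounds <- function(model, id = reaction_ids(model)) {
  idx <- match(id, model$reactions$id)
  if (anyNA(idx)) {
    stop(sprintf("unknown reaction id(s): %s",
                 paste(id[is.na(idx)], collapse = ", ")))
  }
  data.frame(id = id, lower_bound = model$reactions$lower_bound[idx],
             upper_bound = model$reactions$upper_bound[idx],
             stringsAsFactors = FALSE)
}

#' Add a reaction (and any new metabolites) to a model
#'
#' @param model A `metabolic_model`.
#' @param rxn A [reaction()].
#' @param new_metabolites Optional list of [metabolite()] objects to declare
#'   alongside; metabolites already present are ignored.
#' @return The modified model.
#' @export
add_reaction <- function(model, rxn, new_metabolites = list()) {
  stopifnot(inherits(rxn, "reaction"))
  if (rxn$id %in% model$reactions$id) {
    stop(sprintf("reaction '%s' already present", rxn$id))
  }
  for (m in new_metabolites) {
    if (!m$id %in% model$metabolites$id) {
      model$metabolites <- rbind(model$metabolites, data.frame(
        id = m$id, name = m$name, formula = m$formula, charge = m$charge,
        compartment = m$compartment, stringsAsFactors = FALSE))
    }
  }
  model$reactions <- rbind(model$reactions, data.frame(
    id = rxn$id, name = rxn$name, lower_bound = rxn$lower_bound,
    upper_bound = rxn$upper_bound, kind = rxn$kind, subsystem = rxn$subsystem,
    gpr = rxn$gpr, stringsAsFactors = FALSE))
  model$stoichiometry[[rxn$id]] <- rxn$stoichiometry
  model
}

#' Remove reactions from a model
#'
#' @param model A `metabolic_model`.
#' @param ids Reaction ids to drop.
#' @return The modified model.
#' @export
remove_reactions <- function(model, ids) {
  keep <- !model$reactions$id %in% ids
  model$reactions <- model$reactions[keep, , drop = FALSE]
  rownames(model$reactions) <- NULL
  model$stoichiometry <- model$stoichiometry[model$reactions$id]
  if (!is.null(model$pathways)) {
    model$pathways <- lapply(model$pathways, setdiff, y = ids)
  }
  model
}

# Parsed GPR tree for one reaction (NULL when absent).
.reaction_gpr <- function(model, rid) {
  gpr <- model$reactions$gpr[match(rid, model$reactions$id)]
  parse_gpr(gpr)
}
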