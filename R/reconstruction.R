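# Draft-model assembly: reaction/GPR tables, compartment assignment from
# localization evidence, intracellular transporters and the boundary
# structure (exchanges, biomass drains, biomass reaction).

#' Assemble a single-compartment draft model from tables
#'
#' Every metabolite is placed in the cytosol; species names in the equation
#' column are suffixed `_c` automatically unless they already carry a
#' compartment suffix.
#'
#' @param reaction_table Path to a TSV (or a data frame) with columns `id`,
#'   `equation` and optionally `name`, `lower_bound`, `upper_bound`,
#'   `subsystem`.
#' @param gpr_table Path to a TSV (or data frame) with columns `reaction_id`
#'   and `gpr`; may be `NULL`.
#' @param metabolite_table Optional TSV/data frame with columns `id` (bare
#'   species name) and `formula` supplying elemental formulas.
#' @return A `metabolic_model` draft (objective set to the last reaction).
#' @export
assemble_draft <- function(reaction_table, gpr_table = NULL,
                           metabolite_table = NULL) {
  rtab <- if (is.data.frame(reaction_table)) reaction_table else
    .read_tsv(reaction_table)
  gtab <- if (is.null(gpr_table)) {
    data.frame(reaction_id = character(0), gpr = character(0))
  } else if (is.data.frame(gpr_table)) gpr_table else .read_tsv(gpr_table)
  mtab <- if (is.null(metabolite_table)) NULL else
    if (is.data.frame(metabolite_table)) metabolite_table else
      .read_tsv(metabolite_table)
  if (nrow(rtab) == 0L) {
    warning("empty reaction table: returning an empty draft model")
    return(metabolic_model("draft", list(), list(),
                           objective = NA_character_, validate = FALSE))
  }
  gpr_map <- stats::setNames(as.character(gtab$gpr), gtab$reaction_id)
  formula_map <- if (is.null(mtab)) character(0) else
    stats::setNames(as.character(mtab$formula), mtab$id)
  suffix_c <- function(sp) {
    ifelse(grepl("_[cmpxv]$", sp), sp, paste0(sp, "_c"))
  }
  met_ids <- character(0)
  rxns <- vector("list", nrow(rtab))
  for (k in seq_len(nrow(rtab))) {
    eq <- tryCatch(parse_reaction_equation(rtab$equation[k]),
                   error = function(e) stop(sprintf(
                     "reaction table row %d ('%s'): %s", k, rtab$id[k],
                     conditionMessage(e))))
    st <- eq$stoichiometry
    names(st) <- suffix_c(names(st))
    lb <- if ("lower_bound" %in% names(rtab) && !is.na(rtab$lower_bound[k]))
      rtab$lower_bound[k] else if (eq$reversible) -1000 else 0
    ub <- if ("upper_bound" %in% names(rtab) && !is.na(rtab$upper_bound[k]))
      rtab$upper_bound[k] else 1000
    g <- gpr_map[rtab$id[k]]
    rxns[[k]] <- reaction(
      rtab$id[k], st, lower_bound = lb, upper_bound = ub,
      gpr = if (is.na(g)) "" else unname(g),
      subsystem = if ("subsystem" %in% names(rtab) &&
                      !is.na(rtab$subsystem[k])) rtab$subsystem[k] else "")
    met_ids <- union(met_ids, names(st))
  }
  mets <- lapply(met_ids, function(id) {
    bare <- sub("_c$", "", id)
    f <- formula_map[bare]
    metabolite(id, formula = if (length(f) && !is.na(f)) unname(f)
               else NA_character_)
  })
  metabolic_model("draft", mets, rxns, objective = rtab$id[nrow(rtab)])
}

#' Read a localization-evidence table
#'
#' @param path TSV with columns `gene_id`, `source` (one of `uniprot`,
#'   `related_gem`, `predictor`) and `compartment` (a compartment code).
#' @return Validated data frame.
#' @export
read_localization_evidence <- function(path) {
  tab <- if (is.data.frame(path)) path else .read_tsv(path)
  stopifnot(all(c("gene_id", "source", "compartment") %in% names(tab)))
  bad <- setdiff(unique(tab$source), c("uniprot", "related_gem", "predictor"))
  if (length(bad)) {
    stop(sprintf("unknown evidence source(s): %s", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(tab$compartment), names(COMPARTMENT_CODES))
  if (length(bad)) {
    stop(sprintf("unknown compartment code(s): %s", paste(bad, collapse = ", ")))
  }
  tab
}

.EVIDENCE_TIERS <- c("uniprot", "related_gem", "predictor")

# Per-gene winning compartment: strict tier priority; within a tier the
# first record in file order wins and conflicts are collected.
.resolve_evidence <- function(evidence) {
  out <- list()
  conflicts <- character(0)
  for (gene in unique(evidence$gene_id)) {
    rows <- evidence[evidence$gene_id == gene, , drop = FALSE]
    for (tier in .EVIDENCE_TIERS) {
      hits <- rows[rows$source == tier, , drop = FALSE]
      if (nrow(hits)) {
        if (length(unique(hits$compartment)) > 1L) {
          conflicts <- c(conflicts, gene)
        }
        out[[gene]] <- list(compartment = hits$compartment[1], tier = tier)
        break
      }
    }
  }
  list(assignment = out, conflicts = unique(conflicts))
}

# Move a reaction's metabolites from the cytosol to `comp`.
.relocate_stoich <- function(st, comp) {
  ids <- sub("_c$", paste0("_", comp), names(st))
  stats::setNames(unname(st), ids)
}

#' Assign subcellular compartments from localization evidence
#'
#' Each gene-associated reaction is relocated using the strict evidence
#' priority `uniprot > related_gem > predictor`; reactions without evidence
#' stay in the cytosol (the default compartment).  When the winning tier
#' names several compartments across a reaction's genes, the reaction is
#' duplicated per compartment with an id suffix.  Within one tier and gene,
#' the first record wins and the conflict is reported.
#'
#' @param model A single-compartment (cytosolic) draft model.
#' @param evidence Evidence table (see [read_localization_evidence()]).
#' @return The compartmentalized model, with a `localization` attribute
#'   (data frame `reaction`, `compartment`, `tier`) and a `conflicts`
#'   attribute naming genes with intra-tier disagreements.
#' @export
assign_compartments <- function(model, evidence) {
  evidence <- read_localization_evidence(evidence)
  res <- .resolve_evidence(evidence)
  if (length(res$conflicts)) {
    warning(sprintf("conflicting same-tier evidence for gene(s): %s",
                    paste(res$conflicts, collapse = ", ")))
  }
  prov <- list()
  new_rxns <- list()
  new_mets <- list()
  seen_mets <- character(0)
  for (k in seq_len(nrow(model$reactions))) {
    row <- model$reactions[k, ]
    st <- model$stoichiometry[[row$id]]
    genes <- gpr_genes(parse_gpr(row$gpr))
    assigned <- res$assignment[intersect(genes, names(res$assignment))]
    target <- "c"
    tier <- "default"
    comps <- "c"
    if (length(assigned)) {
      tiers <- vapply(assigned, `[[`, character(1), "tier")
      best <- .EVIDENCE_TIERS[min(match(tiers, .EVIDENCE_TIERS))]
      comps <- unique(vapply(assigned[tiers == best], `[[`, character(1),
                             "compartment"))
      tier <- best
    }
    for (comp in comps) {
      rid <- if (length(comps) > 1L) paste0(row$id, "_", comp) else row$id
      st_new <- if (comp == "c") st else .relocate_stoich(st, comp)
      for (mid in setdiff(names(st_new), seen_mets)) {
        src <- sub(paste0("_", comp, "$"), "_c", mid)
        midx <- match(src, model$metabolites$id)
        new_mets <- c(new_mets, list(metabolite(
          mid,
          name = if (!is.na(midx)) model$metabolites$name[midx] else mid,
          formula = if (!is.na(midx)) model$metabolites$formula[midx]
          else NA_character_)))
        seen_mets <- c(seen_mets, mid)
      }
      new_rxns <- c(new_rxns, list(reaction(
        rid, st_new, lower_bound = row$lower_bound,
        upper_bound = row$upper_bound, gpr = row$gpr, name = row$name,
        subsystem = row$subsystem)))
      prov[[rid]] <- data.frame(reaction = rid, compartment = comp,
                                tier = tier, stringsAsFactors = FALSE)
    }
  }
  objective <- model$objective
  if (!objective %in% vapply(new_rxns, `[[`, character(1), "id")) {
    objective <- new_rxns[[length(new_rxns)]]$id
  }
  out <- metabolic_model(model$id, new_mets, new_rxns, objective = objective,
                         pathways = NULL)
  attr(out, "localization") <- do.call(rbind, unname(prov))
  attr(out, "conflicts") <- res$conflicts
  out
}

#' Add intracellular transport reactions
#'
#' All metabolite exchange between compartments passes through the cytosol:
#' each table row creates one reaction `<Species>_<comp>c` (e.g. `3PG_pc`)
#' moving the species between a non-cytosolic compartment and the cytosol,
#' optionally co-consuming ATP or co-transporting protons as an energy cost.
#'
#' @param model A `metabolic_model`.
#' @param transporter_table Data frame (or TSV path) with columns `species`
#'   (bare species name, e.g. `"3pg"`), `label` (id prefix, e.g. `"3PG"`;
#'   defaults to `species`), `compartment` (one of `m`, `p`, `x`, `v`),
#'   `reversible` (logical, default `TRUE`), `atp_cost` and `proton_cost`
#'   (per transported molecule, default 0).  A request between two
#'   non-cytosolic compartments is rejected.
#' @return The modified model.
#' @export
add_transport_reactions <- function(model, transporter_table) {
  tab <- if (is.data.frame(transporter_table)) transporter_table else
    .read_tsv(transporter_table)
  stopifnot(all(c("species", "compartment") %in% names(tab)))
  for (k in seq_len(nrow(tab))) {
    comp <- tab$compartment[k]
    if (!comp %in% c("m", "p", "x", "v")) {
      stop(sprintf(
        "transporter row %d: compartment '%s' invalid; transport must link a non-cytosolic compartment to the cytosol",
        k, comp))
    }
    sp <- tab$species[k]
    label <- if ("label" %in% names(tab) && !is.na(tab$label[k]))
      tab$label[k] else sp
    rid <- paste0(label, "_", comp, "c")
    from <- paste0(sp, "_", comp)
    to <- paste0(sp, "_c")
    st <- stats::setNames(c(-1, 1), c(from, to))
    atp_cost <- if ("atp_cost" %in% names(tab) && !is.na(tab$atp_cost[k]))
      tab$atp_cost[k] else 0
    proton_cost <- if ("proton_cost" %in% names(tab) &&
                       !is.na(tab$proton_cost[k])) tab$proton_cost[k] else 0
    reversible <- if ("reversible" %in% names(tab) &&
                      !is.na(tab$reversible[k])) isTRUE(as.logical(tab$reversible[k]))
      else TRUE
    if (atp_cost > 0) {
      st <- c(st, stats::setNames(c(-atp_cost, -atp_cost, atp_cost, atp_cost),
                                  c("atp_c", "h2o_c", "adp_c", "pi_c")))
      reversible <- FALSE # energized transport runs one way
    }
    if (proton_cost > 0) {
      st <- c(st, stats::setNames(c(-proton_cost, proton_cost),
                                  c("h_c", paste0("h_", comp))))
    }
    missing_ids <- setdiff(names(st), model$metabolites$id)
    new_mets <- lapply(missing_ids, function(mid) {
      # inherit name/formula from the species' cytosolic form when present
      base <- sub("_[cmpxv]$", "_c", mid)
      midx <- match(base, model$metabolites$id)
      metabolite(mid,
                 name = if (!is.na(midx)) model$metabolites$name[midx] else mid,
                 formula = if (!is.na(midx)) model$metabolites$formula[midx]
                 else NA_character_)
    })
    model <- add_reaction(model, reaction(
      rid, st, lower_bound = if (reversible) -1000 else 0, upper_bound = 1000,
      subsystem = "transport"), new_metabolites = new_mets)
  }
  model
}

#' Define the boundary structure of a model
#'
#' @param exchanges Data frame with columns `label` (e.g. `"Sucrose"`),
#'   `species` (cytosolic metabolite id, e.g. `"suc_c"`), `direction`
#'   (`import`, `export` or `both`) and `bound` (availability magnitude).
#' @param biomass_components Data frame with columns `name` (pool label,
#'   e.g. `"Ala"`), `component` (cytosolic metabolite id) and `coefficient`
#'   (mmol/gDW).
#' @return A `boundary_spec` object.
#' @export
boundary_spec <- function(exchanges, biomass_components) {
  stopifnot(all(c("label", "species", "direction", "bound") %in%
                  names(exchanges)),
            all(c("name", "component", "coefficient") %in%
                  names(biomass_components)))
  if (anyDuplicated(exchanges$species)) {
    stop("duplicate species in exchange spec")
  }
  if (anyDuplicated(biomass_components$component)) {
    stop("duplicate species in biomass spec")
  }
  structure(list(exchanges = exchanges,
                 biomass_components = biomass_components),
            class = "boundary_spec")
}

#' Read/write a boundary spec as YAML
#'
#' @param path YAML file.
#' @return `read_boundary_spec()`: a [boundary_spec()]; the writer returns
#'   the path invisibly.
#' @export
read_boundary_spec <- function(path) {
  x <- yaml::read_yaml(path)
  boundary_spec(
    exchanges = do.call(rbind, lapply(x$exchanges, function(e)
      data.frame(label = e$label, species = e$species,
                 direction = e$direction, bound = e$bound,
                 stringsAsFactors = FALSE))),
    biomass_components = do.call(rbind, lapply(x$biomass_components,
                                               function(b)
      data.frame(name = b$name, component = b$component,
                 coefficient = b$coefficient, stringsAsFactors = FALSE))))
}

#' @rdname read_boundary_spec
#' @param spec A [boundary_spec()].
#' @export
write_boundary_spec <- function(spec, path) {
  x <- list(
    exchanges = lapply(seq_len(nrow(spec$exchanges)), function(k)
      as.list(spec$exchanges[k, ])),
    biomass_components = lapply(seq_len(nrow(spec$biomass_components)),
                                function(k)
      as.list(spec$biomass_components[k, ])))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Attach the boundary structure to a model
#'
#' Adds one import-positive exchange reaction `<Label>_Cyto_tx` per exchange
#' row, one drain `<Name>_biomass` per biomass component (converting the
#' component into a pool species `<name>_bm_c`), and a single biomass
#' reaction consuming every pool at its coefficient; the biomass reaction
#' becomes the model objective.  Applying a spec twice raises an error
#' rather than duplicating reactions.
#'
#' @param model A `metabolic_model`.
#' @param spec A [boundary_spec()].
#' @param biomass_id Id of the biomass reaction (default
#'   `"Biomass_synthesis"`).
#' @return The modified model.
#' @export
add_boundary <- function(model, spec, biomass_id = "Biomass_synthesis") {
  stopifnot(inherits(spec, "boundary_spec"))
  ex <- spec$exchanges
  bc <- spec$biomass_components
  if (nrow(ex) == 0L && nrow(bc) == 0L) return(model)
  new_ids <- c(paste0(ex$label, "_Cyto_tx"), paste0(bc$name, "_biomass"),
               if (nrow(bc)) biomass_id)
  clash <- intersect(new_ids, model$reactions$id)
  if (length(clash)) {
    stop(sprintf("boundary already applied: reaction(s) exist: %s",
                 paste(clash, collapse = ", ")))
  }
  for (k in seq_len(nrow(ex))) {
    species <- ex$species[k]
    if (!species %in% model$metabolites$id) {
      stop(sprintf("exchange species '%s' not declared in the model", species))
    }
    bounds <- switch(match.arg(ex$direction[k], c("import", "export", "both")),
                     import = c(0, ex$bound[k]),
                     export = c(-ex$bound[k], 0),
                     both = c(-ex$bound[k], ex$bound[k]))
    model <- add_reaction(model, reaction(
      paste0(ex$label[k], "_Cyto_tx"), stats::setNames(1, species),
      lower_bound = bounds[1], upper_bound = bounds[2],
      subsystem = "exchange"))
  }
  if (nrow(bc)) {
    bm_st <- numeric(0)
    for (k in seq_len(nrow(bc))) {
      comp_id <- bc$component[k]
      if (!comp_id %in% model$metabolites$id) {
        stop(sprintf("biomass component '%s' not declared in the model",
                     comp_id))
      }
      midx <- match(comp_id, model$metabolites$id)
      pool <- paste0(tolower(bc$name[k]), "_bm_c")
      model <- add_reaction(model, reaction(
        paste0(bc$name[k], "_biomass"),
        stats::setNames(c(-1, 1), c(comp_id, pool)),
        lower_bound = 0, upper_bound = 1000, subsystem = "biomass"),
        new_metabolites = list(metabolite(
          pool, name = paste0(bc$name[k], " biomass pool"),
          formula = model$metabolites$formula[midx])))
      bm_st[pool] <- -bc$coefficient[k]
    }
    model <- add_reaction(model, reaction(
      biomass_id, bm_st, lower_bound = 0, upper_bound = 1000,
      subsystem = "biomass", kind = "biomass"))
    model$objective <- biomass_id
  }
  validate_model(model)
  model
}
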