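# SBML Level 3 Version 1 + fbc-v2 interchange.
#
# COBRA-style id mangling is applied so that identifiers starting with a
# digit (e.g. "3PG_pc") remain valid SBML SIds: metabolites gain an "M_"
# prefix, reactions "R_", gene products "G_".  The JSON dialect, not SBML, is
# the bit-exact native format: SBML carries ids, names, formulas, charges,
# compartments, stoichiometry, bounds, GPRs and the objective, but not the
# subsystem/pathway annotations.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.sbml_mangle <- function(id, prefix) paste0(prefix, gsub("[^A-Za-z0-9_]", "__", id))
.sbml_unmangle <- function(id, prefix) sub(paste0("^", prefix), "", id)

.write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = .SBML_NS, "xmlns:fbc" = .FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = .sbml_mangle(model$id, ""),
                             "fbc:strict" = "true")

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (code in names(model$compartments)) {
    xml2::xml_add_child(comps, "compartment", id = code,
                        name = unname(model$compartments[code]),
                        constant = "true")
  }

  species <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (k in seq_len(nrow(model$metabolites))) {
    row <- model$metabolites[k, ]
    node <- xml2::xml_add_child(
      species, "species", id = .sbml_mangle(row$id, "M_"), name = row$name,
      compartment = row$compartment, hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
    if (!is.na(row$formula)) {
      xml2::xml_set_attr(node, "fbc:chemicalFormula", row$formula)
    }
    if (!is.na(row$charge)) {
      xml2::xml_set_attr(node, "fbc:charge", as.character(row$charge))
    }
  }

  bounds <- unique(c(model$reactions$lower_bound, model$reactions$upper_bound))
  bound_id <- function(v) {
    s <- gsub("-", "minus_", gsub("\\.", "_", format(v, trim = TRUE,
                                                     scientific = FALSE,
                                                     digits = 17)))
    paste0("bnd_", s)
  }
  params <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in bounds) {
    xml2::xml_add_child(params, "parameter", id = bound_id(v),
                        value = format(v, digits = 17, scientific = FALSE),
                        constant = "true")
  }

  rxns_node <- xml2::xml_add_child(mdl, "listOfReactions")
  for (k in seq_len(nrow(model$reactions))) {
    row <- model$reactions[k, ]
    st <- model$stoichiometry[[row$id]]
    rn <- xml2::xml_add_child(
      rxns_node, "reaction", id = .sbml_mangle(row$id, "R_"), name = row$name,
      reversible = if (row$lower_bound < 0) "true" else "false",
      fast = "false")
    xml2::xml_set_attr(rn, "fbc:lowerFluxBound", bound_id(row$lower_bound))
    xml2::xml_set_attr(rn, "fbc:upperFluxBound", bound_id(row$upper_bound))
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      lor <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(reac)) {
        xml2::xml_add_child(lor, "speciesReference",
                            species = .sbml_mangle(m, "M_"),
                            stoichiometry = format(-reac[[m]], digits = 17,
                                                   scientific = FALSE),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lop <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(prod)) {
        xml2::xml_add_child(lop, "speciesReference",
                            species = .sbml_mangle(m, "M_"),
                            stoichiometry = format(prod[[m]], digits = 17,
                                                   scientific = FALSE),
                            constant = "true")
      }
    }
    if (nzchar(row$gpr)) {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      .sbml_write_gpr(gpa, parse_gpr(row$gpr))
    }
  }

  objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  obj <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                             "fbc:type" = "maximize")
  lof <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lof, "fbc:fluxObjective",
                      "fbc:reaction" = .sbml_mangle(model$objective, "R_"),
                      "fbc:coefficient" = "1")

  genes <- sort(unique(unlist(lapply(model$reactions$gpr[nzchar(model$reactions$gpr)],
                                     function(g) gpr_genes(parse_gpr(g))))))
  if (length(genes)) {
    logp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(logp, "fbc:geneProduct",
                          "fbc:id" = .sbml_mangle(g, "G_"),
                          "fbc:label" = g)
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

.sbml_write_gpr <- function(parent, expr) {
  if (!is.null(expr$gene)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = .sbml_mangle(expr$gene, "G_"))
    return(invisible(NULL))
  }
  node <- xml2::xml_add_child(parent,
                              if (expr$op == "and") "fbc:and" else "fbc:or")
  for (a in expr$args) .sbml_write_gpr(node, a)
  invisible(NULL)
}

.sbml_read_gpr <- function(node, gene_labels) {
  name <- xml2::xml_name(node)
  if (name == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    label <- gene_labels[ref]
    return(list(gene = if (is.na(label)) .sbml_unmangle(ref, "G_") else unname(label)))
  }
  if (name %in% c("and", "or")) {
    kids <- xml2::xml_children(node)
    args <- lapply(kids, .sbml_read_gpr, gene_labels = gene_labels)
    return(list(op = name, args = args))
  }
  stop(sprintf("unsupported element <%s> in geneProductAssociation", name))
}

.read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf(
                    "failed to parse SBML file '%s': %s", path,
                    conditionMessage(e))))
  xml2::xml_ns_strip(doc) # work on local names; fbc attrs keep their prefix
  mdl <- xml2::xml_find_first(doc, "./model")
  if (inherits(mdl, "xml_missing")) stop("no <model> element found")

  comp_nodes <- xml2::xml_find_all(mdl, "./listOfCompartments/compartment")
  compartments <- stats::setNames(
    xml2::xml_attr(comp_nodes, "name"), xml2::xml_attr(comp_nodes, "id"))
  compartments[is.na(compartments)] <- names(compartments)[is.na(compartments)]

  sp_nodes <- xml2::xml_find_all(mdl, "./listOfSpecies/species")
  mets <- lapply(sp_nodes, function(n) {
    id <- .sbml_unmangle(xml2::xml_attr(n, "id"), "M_")
    charge <- xml2::xml_attr(n, "charge")
    metabolite(id,
               name = {
                 nm <- xml2::xml_attr(n, "name"); if (is.na(nm)) id else nm
               },
               formula = xml2::xml_attr(n, "chemicalFormula"),
               charge = if (is.na(charge)) NA_integer_ else as.integer(charge),
               compartment = xml2::xml_attr(n, "compartment"))
  })

  par_nodes <- xml2::xml_find_all(mdl, "./listOfParameters/parameter")
  par_vals <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                              xml2::xml_attr(par_nodes, "id"))

  gp_nodes <- xml2::xml_find_all(mdl, "./*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gene_labels <- stats::setNames(xml2::xml_attr(gp_nodes, "label"),
                                 xml2::xml_attr(gp_nodes, "id"))

  rxn_nodes <- xml2::xml_find_all(mdl, "./listOfReactions/reaction")
  rxns <- lapply(rxn_nodes, function(n) {
    id <- .sbml_unmangle(xml2::xml_attr(n, "id"), "R_")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(n, "./listOfReactants/speciesReference")) {
      met <- .sbml_unmangle(xml2::xml_attr(sr, "species"), "M_")
      st[met] <- -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(n, "./listOfProducts/speciesReference")) {
      met <- .sbml_unmangle(xml2::xml_attr(sr, "species"), "M_")
      st[met] <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    lb_ref <- xml2::xml_attr(n, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(n, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(par_vals)) par_vals[[lb_ref]]
      else if (identical(xml2::xml_attr(n, "reversible"), "true")) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(par_vals)) par_vals[[ub_ref]]
      else 1000
    gpa <- xml2::xml_find_first(n, "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) "" else {
      gpr_to_string(.sbml_read_gpr(xml2::xml_child(gpa), gene_labels))
    }
    nm <- xml2::xml_attr(n, "name")
    reaction(id, st, lower_bound = lb, upper_bound = ub, gpr = gpr,
             name = if (is.na(nm)) id else nm)
  })

  obj_node <- xml2::xml_find_first(
    mdl, paste0("./*[local-name()='listOfObjectives']/*[local-name()='objective']/",
                "*[local-name()='listOfFluxObjectives']/*[local-name()='fluxObjective']"))
  objective <- if (inherits(obj_node, "xml_missing")) {
    rxns[[length(rxns)]]$id
  } else {
    .sbml_unmangle(xml2::xml_attr(obj_node, "reaction"), "R_")
  }

  mid <- xml2::xml_attr(mdl, "id")
  metabolic_model(id = if (is.na(mid)) "model" else mid, metabolites = mets,
                  reactions = rxns, objective = objective,
                  compartments = compartments)
}
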