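# Native JSON dialect: a faithful, bit-exact serialization of the model.
#
# Layout (all fields mirror the in-memory types):
# {
#   "id": "...",
#   "compartments": {"c": "cytosol", ...},
#   "metabolites": [{"id","name","formula","charge","compartment"}, ...],
#   "reactions":   [{"id","name","stoichiometry": {"<met>": coeff, ...},
#                    "lower_bound","upper_bound","gpr","subsystem","kind"}, ...],
#   "objective": "...",
#   "pathways": {"<tag>": ["<rid>", ...], ...}   (optional)
# }
# Exchange reactions are import-positive: positive flux = uptake.

.model_to_json_list <- function(model) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(k) {
    row <- model$metabolites[k, ]
    list(id = row$id, name = row$name,
         formula = if (is.na(row$formula)) NULL else row$formula,
         charge = if (is.na(row$charge)) NULL else row$charge,
         compartment = row$compartment)
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(k) {
    row <- model$reactions[k, ]
    list(id = row$id, name = row$name,
         stoichiometry = as.list(model$stoichiometry[[row$id]]),
         lower_bound = row$lower_bound, upper_bound = row$upper_bound,
         gpr = row$gpr, subsystem = row$subsystem, kind = row$kind)
  })
  out <- list(id = model$id, compartments = as.list(model$compartments),
              metabolites = mets, reactions = rxns,
              objective = model$objective)
  if (!is.null(model$pathways)) out$pathways <- model$pathways
  out
}

.model_from_json_list <- function(x) {
  mets <- lapply(x$metabolites, function(m) {
    metabolite(m$id, name = m$name %||% m$id,
               formula = m$formula %||% NA_character_,
               charge = m$charge %||% NA_integer_,
               compartment = m$compartment %||% NULL)
  })
  rxns <- lapply(x$reactions, function(r) {
    st <- vapply(r$stoichiometry, as.numeric, numeric(1))
    reaction(r$id, stoichiometry = st, lower_bound = r$lower_bound,
             upper_bound = r$upper_bound, gpr = r$gpr %||% "",
             name = r$name %||% r$id, subsystem = r$subsystem %||% "",
             kind = r$kind %||% NULL)
  })
  metabolic_model(id = x$id %||% "model", metabolites = mets, reactions = rxns,
                  objective = x$objective,
                  compartments = unlist(x$compartments),
                  pathways = lapply(x$pathways, unlist))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_model_json <- function(model, path) {
  # digits = I(17): full IEEE round-trip precision, so write -> read is the
  # identity on stoichiometries and bounds
  jsonlite::write_json(.model_to_json_list(model), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

.read_model_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop(sprintf(
                  "failed to parse JSON model '%s': %s", path,
                  conditionMessage(e))))
  .model_from_json_list(x)
}

#' Read a metabolic model
#'
#' @param path File path.
#' @param format One of `"json"` (the native dialect, bit-exact round trip),
#'   `"sbml_fbc"` (SBML Level 3 + FBC interchange) or `"tsv_tables"` (a
#'   directory holding `metabolites.tsv`, `reactions.tsv`, `gprs.tsv` for
#'   human editing).  Guessed from the path when omitted.
#' @return A `metabolic_model`.
#' @export
read_model <- function(path, format = c("guess", "json", "sbml_fbc",
                                        "tsv_tables")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (dir.exists(path)) "tsv_tables"
      else switch(tolower(tools::file_ext(path)),
                  json = "json", xml = "sbml_fbc", sbml = "sbml_fbc",
                  stop(sprintf("cannot guess model format of '%s'", path)))
  }
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  switch(format,
         json = .read_model_json(path),
         sbml_fbc = .read_model_sbml(path),
         tsv_tables = .read_model_tsv(path))
}

#' Write a metabolic model
#'
#' @param model A `metabolic_model`.
#' @param path Output file (or directory for `tsv_tables`).
#' @param format See [read_model()].
#' @return The path, invisibly.
#' @export
write_model <- function(model, path, format = c("guess", "json", "sbml_fbc",
                                                "tsv_tables")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", xml = "sbml_fbc", sbml = "sbml_fbc",
                     "tsv_tables")
  }
  validate_model(model)
  switch(format,
         json = .write_model_json(model, path),
         sbml_fbc = .write_model_sbml(model, path),
         tsv_tables = .write_model_tsv(model, path))
}
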