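# Synthetic two-condition replicate FPKM tables and free amino-acid tables
# matched to the toy model.

#' Generate paired soil / in-vitro expression profiles
#'
#' Draws a log-normal base FPKM per gene, multiplies the in-vitro mean by
#' the fold change of the gene's pathway tag (photosynthesis, Calvin, TCA
#' and glycolysis tags down; GS/GOGAT and sucrose tags up), and adds
#' multiplicative mean-preserving log-normal replicate noise at the
#' configured coefficient of variation.  All draws are fixed by the config
#' seed.
#'
#' @param model A model from [generate_toy_plant_model()] (its
#'   `gene_pathways` attribute supplies the gene -> tag map).
#' @param config A [generator_config()].
#' @param n_replicates Number of replicates per condition (default 3).
#' @return List of two [expression_table()]s named `soil` and `in_vitro`.
#' @export
generate_expression_profiles <- function(model, config = generator_config(),
                                         n_replicates = 3L) {
  gene_map <- attr(model, "gene_pathways")
  if (is.null(gene_map) || !length(gene_map)) {
    stop("model carries no gene_pathways attribute; generate it with generate_toy_plant_model()")
  }
  folds <- config$expression_folds
  unknown <- setdiff(names(folds), unique(gene_map))
  if (length(unknown)) {
    stop(sprintf("expression fold map names unknown pathway tag(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  genes <- names(gene_map)
  .with_seed(config$seed + 1L, function() {
    base <- stats::rlnorm(length(genes), config$fpkm_meanlog,
                          config$fpkm_sdlog)
    fold <- ifelse(gene_map[genes] %in% names(folds),
                   folds[gene_map[genes]], 1)
    means <- list(soil = base, in_vitro = base * fold)
    cv <- config$fpkm_cv
    sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
    out <- lapply(names(means), function(cond) {
      reps <- vapply(seq_len(n_replicates), function(k) {
        noise <- if (sdlog > 0) {
          stats::rlnorm(length(genes), -sdlog^2 / 2, sdlog)
        } else {
          rep(1, length(genes))
        }
        means[[cond]] * noise
      }, numeric(length(genes)))
      df <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
      for (k in seq_len(n_replicates)) df[[paste0("rep", k)]] <- reps[, k]
      expression_table(cond, df)
    })
    names(out) <- names(means)
    out
  })
}

#' Generate paired soil / in-vitro free amino-acid tables
#'
#' The soil table holds the fixed default pool (100 umol/gDW total, top five
#' Gln > Ser > Asn > Pro > Val).  The in-vitro table multiplies the five
#' reported acids by their printed folds (Gln 4.92, Asn 1.92, Ser 1.21,
#' Val 1.19, Pro 0.82) and assigns the remaining fifteen acids a common
#' fold solved at run time so the total concentration ratio equals
#' `total_aa_ratio` exactly.
#'
#' @param config A [generator_config()].
#' @return List of two [amino_acid_table()]s named `soil` and `in_vitro`.
#' @export
generate_amino_acid_tables <- function(config = generator_config()) {
  soil <- .toy_aa_soil
  folds <- config$amino_acid_folds
  unknown <- setdiff(names(folds), names(soil))
  if (length(unknown)) {
    stop(sprintf("unknown amino acid(s) in fold map: %s",
                 paste(unknown, collapse = ", ")))
  }
  named <- names(folds)
  rest <- setdiff(names(soil), named)
  total_soil <- sum(soil)
  target <- config$total_aa_ratio * total_soil
  fixed_part <- sum(soil[named] * folds[named])
  if (length(rest)) {
    common <- (target - fixed_part) / sum(soil[rest])
    if (common <= 0) {
      stop("total_aa_ratio is unattainable: the reported folds already exceed the target total")
    }
  }
  vitro <- soil
  vitro[named] <- soil[named] * folds[named]
  if (length(rest)) vitro[rest] <- soil[rest] * common
  as_table <- function(cond, values) {
    amino_acid_table(cond, data.frame(name = names(values),
                                      umol_per_g = unname(values),
                                      stringsAsFactors = FALSE))
  }
  list(soil = as_table("soil", soil), in_vitro = as_table("in_vitro", vitro))
}

#' Generate the paired condition presets for the synthetic study
#'
#' Wires the generated expression and amino-acid tables into soil-grown and
#' in-vitro [condition_spec()]s with the configured photon and sucrose
#' bounds.
#'
#' @param model A model from [generate_toy_plant_model()].
#' @param config A [generator_config()].
#' @return List of two `condition_spec`s named `soil` and `in_vitro`.
#' @export
generate_condition_specs <- function(model, config = generator_config()) {
  expr <- generate_expression_profiles(model, config)
  aa <- generate_amino_acid_tables(config)
  list(
    soil = condition_spec("soil",
                          photon_bound = config$photon_bounds[["soil"]],
                          sucrose_bound = config$sucrose_bounds[["soil"]],
                          co2_bound = config$co2_bounds[["soil"]],
                          expression_table = expr$soil,
                          amino_acid_table = aa$soil),
    in_vitro = condition_spec("in_vitro",
                              photon_bound = config$photon_bounds[["in_vitro"]],
                              sucrose_bound = config$sucrose_bounds[["in_vitro"]],
                              co2_bound = config$co2_bounds[["in_vitro"]],
                              expression_table = expr$in_vitro,
                              amino_acid_table = aa$in_vitro))
}

#' Write the full synthetic input bundle to a directory
#'
#' Emits the toy model (JSON and SBML), the expression TSVs, the amino-acid
#' CSVs and the pathway tag map, i.e. every input the analysis pipeline
#' consumes.
#'
#' @param dir Output directory (created if needed).
#' @param config A [generator_config()].
#' @return The directory path, invisibly.
#' @export
generate_study_inputs <- function(dir, config = generator_config()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  model <- generate_toy_plant_model(config)
  write_model(model, file.path(dir, "toy_model.json"), format = "json")
  write_model(model, file.path(dir, "toy_model.xml"), format = "sbml_fbc")
  expr <- generate_expression_profiles(model, config)
  for (cond in names(expr)) {
    write_expression_table(expr[[cond]],
                           file.path(dir, sprintf("expression_%s.tsv", cond)))
  }
  aa <- generate_amino_acid_tables(config)
  for (cond in names(aa)) {
    write_amino_acid_table(aa[[cond]],
                           file.path(dir, sprintf("amino_acids_%s.csv", cond)))
  }
  tags <- data.frame(
    pathway = rep(names(model$pathways),
                  vapply(model$pathways, length, integer(1))),
    reaction = unlist(model$pathways, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(tags, file.path(dir, "pathway_tags.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
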