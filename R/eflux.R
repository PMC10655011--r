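# E-Flux contextualization: replicate FPKM tables -> GPR activity scores ->
# expression-scaled reaction bounds; free amino-acid measurements -> biomass
# coefficients.

AMINO_ACIDS_20 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                    "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                    "Thr", "Trp", "Tyr", "Val")

#' Construct an expression table
#'
#' @param condition Condition label (e.g. `"soil"`).
#' @param data Data frame with a `gene_id` column and one numeric FPKM
#'   column per replicate.
#' @return An `expression_table` object.
#' @export
expression_table <- function(condition, data) {
  stopifnot(is.data.frame(data), "gene_id" %in% names(data))
  reps <- setdiff(names(data), "gene_id")
  if (length(reps) < 1L) stop("need at least one replicate column")
  vals <- as.matrix(data[reps])
  if (!is.numeric(vals)) stop("replicate columns must be numeric")
  if (anyNA(vals) || any(vals < 0)) {
    stop("FPKM values must be non-negative and non-missing")
  }
  if (anyDuplicated(data$gene_id)) stop("duplicate gene ids")
  structure(list(condition = condition, data = data, replicates = reps),
            class = "expression_table")
}

#' Read an expression table from TSV
#'
#' @param path TSV with `gene_id` and replicate FPKM columns.
#' @param condition Condition label; defaults to the file name.
#' @return An [expression_table()].
#' @export
read_expression_table <- function(path, condition = NULL) {
  if (is.null(condition)) {
    condition <- sub("^expression_", "",
                     tools::file_path_sans_ext(basename(path)))
  }
  expression_table(condition, .read_tsv(path))
}

#' Write an expression table to TSV
#' @param table An [expression_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_table <- function(table, path) {
  utils::write.table(table$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Summarize expression into per-gene activity scores
#'
#' `score(g) = log2(mean(FPKM replicates) + 1)`: replicates are averaged
#' first, then log-transformed.
#'
#' @param table An [expression_table()].
#' @return Named numeric vector, gene id -> activity score.
#' @export
summarize_expression <- function(table) {
  stopifnot(inherits(table, "expression_table"))
  vals <- as.matrix(table$data[table$replicates])
  stats::setNames(log2(rowMeans(vals) + 1), table$data$gene_id)
}

#' Score a GPR expression against gene activities
#'
#' OR nodes sum their children (isoenzymes add capacity); AND nodes take the
#' minimum (complex subunits limit capacity); leaves look up the gene score.
#' Genes absent from `scores` are treated as unexpressed (score 0) with a
#' warning.  An empty GPR returns `NA` ("no constraint"), never zero.
#'
#' @param expr GPR tree ([parse_gpr()]) or `NULL`.
#' @param scores Named numeric vector of gene activity scores.
#' @param warn_missing Warn about genes missing from `scores`.
#' @return Numeric activity value, or `NA` for an empty GPR.
#' @export
score_gpr <- function(expr, scores, warn_missing = TRUE) {
  if (is.null(expr)) return(NA_real_)
  if (!is.null(expr$gene)) {
    if (!expr$gene %in% names(scores)) {
      if (warn_missing) {
        warning(sprintf("gene '%s' absent from expression data; scored 0",
                        expr$gene))
      }
      return(0)
    }
    return(unname(scores[[expr$gene]]))
  }
  vals <- vapply(expr$args, score_gpr, numeric(1), scores = scores,
                 warn_missing = warn_missing)
  if (expr$op == "or") sum(vals) else min(vals)
}

#' Contextualize a model with E-Flux bounds
#'
#' Computes per-reaction GPR activity values from the expression table,
#' normalizes them by the condition maximum (so values lie in \[0, 1\]) and
#' scales each GPR-carrying reaction's default bounds by its normalized
#' value: `ub' = s * |ub|`, `lb' = -s * |lb|` when reversible, 0 otherwise.
#' Reactions without a GPR are untouched.  Exchange reactions are reset to
#' availability magnitude `exchange_bound` (paper convention -1/1, i.e.
#' uptake and export of at most one flux unit) before any condition preset
#' is applied.
#'
#' @param model A `metabolic_model`.
#' @param table An [expression_table()].
#' @param exchange_bound Availability magnitude for exchange reactions
#'   (default 1).
#' @return The contextualized model, with attribute `eflux_scores` (named
#'   vector of normalized per-reaction values).
#' @export
apply_eflux <- function(model, table, exchange_bound = 1) {
  scores <- summarize_expression(table)
  rxns <- model$reactions
  has_gpr <- nzchar(rxns$gpr)
  if (!any(has_gpr)) stop("model has no GPR associations")
  missing <- setdiff(
    unique(unlist(lapply(rxns$gpr[has_gpr],
                         function(g) gpr_genes(parse_gpr(g))))),
    names(scores))
  if (length(missing)) {
    warning(sprintf(
      "%d gene(s) absent from expression data treated as unexpressed: %s",
      length(missing), paste(utils::head(missing, 5), collapse = ", ")))
  }
  raw <- vapply(rxns$id[has_gpr], function(rid) {
    score_gpr(.reaction_gpr(model, rid), scores, warn_missing = FALSE)
  }, numeric(1))
  max_val <- max(raw)
  if (max_val <= 0) {
    stop("all GPR activity values are zero: normalization undefined")
  }
  s <- raw / max_val
  idx <- match(names(s), rxns$id)
  lb <- rxns$lower_bound[idx]
  ub <- rxns$upper_bound[idx]
  model$reactions$upper_bound[idx] <- s * abs(ub)
  model$reactions$lower_bound[idx] <- ifelse(lb < 0, -s * abs(lb), 0)
  ex <- exchange_ids(model)
  ex_idx <- match(ex, model$reactions$id)
  model$reactions$upper_bound[ex_idx] <- exchange_bound
  model$reactions$lower_bound[ex_idx] <-
    ifelse(rxns$lower_bound[ex_idx] < 0, -exchange_bound, 0)
  attr(model, "eflux_scores") <- s
  attr(model, "eflux_condition") <- table$condition
  model
}

#' Construct a free amino-acid concentration table
#'
#' @param condition Condition label.
#' @param data Data frame with columns `name` (three-letter amino-acid code)
#'   and `umol_per_g` (concentration in umol per gram dry weight).
#' @return An `amino_acid_table` object.
#' @export
amino_acid_table <- function(condition, data) {
  stopifnot(is.data.frame(data),
            all(c("name", "umol_per_g") %in% names(data)))
  unknown <- setdiff(data$name, AMINO_ACIDS_20)
  if (length(unknown)) {
    stop(sprintf("unknown amino acid name(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(data$name)) stop("duplicate amino acid entries")
  if (any(data$umol_per_g < 0)) stop("concentrations must be >= 0")
  structure(list(condition = condition,
                 data = data[, c("name", "umol_per_g")]),
            class = "amino_acid_table")
}

#' Read an amino-acid table from CSV
#' @param path CSV with columns `name` and `umol_per_g`.
#' @param condition Condition label; defaults to the file name.
#' @return An [amino_acid_table()].
#' @export
read_amino_acid_table <- function(path, condition = NULL) {
  if (is.null(condition)) {
    condition <- sub("^amino_acids_", "",
                     tools::file_path_sans_ext(basename(path)))
  }
  amino_acid_table(condition, utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write an amino-acid table to CSV
#' @param table An [amino_acid_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_amino_acid_table <- function(table, path) {
  utils::write.csv(table$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fold measured free amino acids into the biomass composition
#'
#' Replaces the 20 amino-acid drain coefficients by the measured
#' concentrations converted to mmol/gDW (umol/g divided by 1000), then
#' re-runs [rescale_biomass()] so the biomass molar mass returns to exactly
#' 1 g/mmol.
#'
#' @param composition A [biomass_composition()] whose amino-acid components
#'   are named by their three-letter codes.
#' @param table An [amino_acid_table()].
#' @return The updated, rescaled composition.
#' @export
incorporate_amino_acids <- function(composition, table) {
  stopifnot(inherits(table, "amino_acid_table"))
  idx <- match(table$data$name, composition$name)
  if (anyNA(idx)) {
    stop(sprintf("amino acid(s) not present as biomass components: %s",
                 paste(table$data$name[is.na(idx)], collapse = ", ")))
  }
  composition$coefficient[idx] <- table$data$umol_per_g / 1000
  if (any(composition$coefficient <= 0)) {
    stop("zero amino-acid concentration would remove a biomass component")
  }
  rescale_biomass(composition)
}
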