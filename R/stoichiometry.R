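# Stoichiometric matrix construction and elemental mass balance checking.

#' Build the stoichiometric matrix of a model
#'
#' Returns the sparse matrix `S` (metabolites x reactions) with
#' `S[i, j]` the coefficient of metabolite `i` in reaction `j`, together
#' with the index maps between ids and row/column positions.
#'
#' @param model A `metabolic_model`.
#' @return List with elements `S` (a `dgCMatrix`), `met_index` and
#'   `rxn_index` (named integer vectors mapping ids to rows/columns).
#' @export
build_stoichiometric_matrix <- function(model) {
  validate_model(model)
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  met_index <- stats::setNames(seq_along(met_ids), met_ids)
  rxn_index <- stats::setNames(seq_along(rxn_ids), rxn_ids)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(rxn_ids)) {
    st <- model$stoichiometry[[rxn_ids[k]]]
    if (length(st)) {
      i <- c(i, met_index[names(st)])
      j <- c(j, rep.int(k, length(st)))
      x <- c(x, unname(st))
    }
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(met_ids), length(rxn_ids)),
                            dimnames = list(met_ids, rxn_ids))
  list(S = S, met_index = met_index, rxn_index = rxn_index)
}

#' Check elemental mass balance of a model
#'
#' A biochemical or transport reaction is balanced iff, for every element,
#' the coefficient-weighted sum of atom counts over its metabolites is zero.
#' Exchange, biomass-drain and biomass reactions are boundary pseudo-reactions
#' and are exempt.  Reactions touching any metabolite without a formula
#' (photons, lumped pools) cannot be judged and are reported separately, as
#' are metabolites whose formula fails to parse.
#'
#' @param model A `metabolic_model`.
#' @param tol Absolute tolerance on per-element residuals (default `1e-9`).
#' @return List with
#'   * `imbalanced`: named list, reaction id -> named numeric vector of
#'      nonzero per-element residuals (produced minus consumed atoms);
#'   * `skipped`: character vector of reactions containing formula-less
#'      metabolites;
#'   * `formula_errors`: named character vector, metabolite id -> parse error.
#' @export
check_mass_balance <- function(model, tol = 1e-9) {
  mets <- model$metabolites
  formulas <- vector("list", nrow(mets))
  names(formulas) <- mets$id
  formula_errors <- character(0)
  for (k in seq_len(nrow(mets))) {
    res <- tryCatch(parse_formula(mets$formula[k]), error = function(e) e)
    if (inherits(res, "error")) {
      formula_errors[mets$id[k]] <- conditionMessage(res)
      formulas[k] <- list(NA)
    } else {
      formulas[k] <- list(res) # NULL when absent
    }
  }
  checkable <- model$reactions$kind %in% c("biochemical", "transport")
  imbalanced <- list()
  skipped <- character(0)
  for (rid in model$reactions$id[checkable]) {
    st <- model$stoichiometry[[rid]]
    fs <- formulas[names(st)]
    if (any(vapply(fs, function(f) is.null(f) || identical(f, NA), logical(1)))) {
      skipped <- c(skipped, rid)
      next
    }
    elements <- unique(unlist(lapply(fs, names)))
    resid <- stats::setNames(numeric(length(elements)), elements)
    for (k in seq_along(st)) {
      f <- fs[[k]]
      resid[names(f)] <- resid[names(f)] + st[k] * f
    }
    resid <- resid[abs(resid) > tol]
    if (length(resid)) imbalanced[[rid]] <- resid
  }
  list(imbalanced = imbalanced, skipped = skipped,
       formula_errors = formula_errors)
}
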