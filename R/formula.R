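# Elemental formula handling: parsing, molecular weight, degree of reduction.

# Conventional atomic masses (g/mol) for the elements that occur in plant
# primary metabolism plus the mineral nutrients of a standard growth medium.
.atomic_mass <- c(
  C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  Mg = 24.305, Fe = 55.845, K = 39.098, Ca = 40.078, Cl = 35.45,
  Mn = 54.938, Zn = 65.38, Cu = 63.546, Mo = 95.95, Na = 22.990
)

# Electrons made available per atom relative to the combustion references
# (CO2, H2O, NH3, H3PO4, H2SO4).  Nitrogen is counted as -3 (ammonia
# reference), matching ammonium-based nitrogen assimilation in plants.
.reduction_degree_per_atom <- c(
  C = 4, H = 1, O = -2, N = -3, P = 5, S = 6
)

#' Parse an elemental formula
#'
#' Parses a Hill-style elemental formula such as `"C6H12O6"` into a named
#' vector of non-negative integer element counts.
#'
#' @param formula Character scalar, e.g. `"C6H12O6"`. `NA` or `""` denote an
#'   absent formula and return `NULL`.
#' @return Named integer vector of element counts, or `NULL` when no formula
#'   is present.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L) stop("`formula` must be a single string")
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop(sprintf("cannot parse formula '%s'", formula))
  }
  el <- sub("[0-9]+$", "", tokens)
  n <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                         sub("^[A-Za-z]+", "", tokens), "1"))
  counts <- tapply(n, el, sum)
  storage.mode(counts) <- "integer"
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Molecular weight from an elemental formula
#'
#' @param formula Character scalar formula (see [parse_formula()]).
#' @return Molecular weight in g/mol.
#' @examples
#' formula_mw("C6H12O6") # 180.156
#' @export
formula_mw <- function(formula) {
  counts <- parse_formula(formula)
  if (is.null(counts)) stop("missing formula: molecular weight undefined")
  unknown <- setdiff(names(counts), names(.atomic_mass))
  if (length(unknown)) {
    stop(sprintf("no atomic mass for element(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  sum(.atomic_mass[names(counts)] * counts)
}

#' Degree of reduction of a compound
#'
#' Electrons available per molecule under the convention C = 4, H = 1,
#' O = -2, N = -3, P = 5, S = 6.  Elements outside this table (mineral ions)
#' contribute zero.  Used to bound theoretical product yields by the ratio of
#' substrate to product reduction degrees.
#'
#' @param formula Character scalar formula.
#' @return Numeric degree of reduction (electrons per molecule).
#' @examples
#' reduction_degree("C6H12O6") # 24
#' @export
reduction_degree <- function(formula) {
  counts <- parse_formula(formula)
  if (is.null(counts)) stop("missing formula: reduction degree undefined")
  keep <- intersect(names(counts), names(.reduction_degree_per_atom))
  sum(.reduction_degree_per_atom[keep] * counts[keep])
}
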