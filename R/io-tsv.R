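# TSV triple (metabolites.tsv, reactions.tsv, gprs.tsv) for human editing.
#
# reactions.tsv carries the stoichiometry as an equation string, e.g.
#   "glc_c + atp_c --> g6p_c + adp_c"   (irreversible)
#   "2 h2o2_x <=> 2 h2o_x + o2_x"       (reversible)
# Coefficients default to 1.  Explicit lower_bound/upper_bound columns, when
# present, override the arrow's default bounds ([0, 1000] for -->,
# [-1000, 1000] for <=>).

#' Parse a reaction equation string
#'
#' @param equation Equation such as `"a_c + 2 b_c --> c_c"`.  Arrows `-->`,
#'   `->`, `=>` (irreversible) and `<=>`, `<->` (reversible) are accepted.
#' @return List with `stoichiometry` (named numeric) and `reversible`
#'   (logical).
#' @export
parse_reaction_equation <- function(equation) {
  stopifnot(is.character(equation), length(equation) == 1L)
  rev_arrow <- regexpr("<=>|<->", equation) > 0
  parts <- strsplit(equation, "<=>|<->|-->|->|=>")[[1]]
  if (length(parts) != 2L) {
    stop(sprintf("cannot parse reaction equation '%s': need exactly one arrow",
                 equation))
  }
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, "\\s\\+\\s|^\\+\\s|\\s\\+$")[[1]])
    terms <- terms[nzchar(terms)]
    st <- numeric(0)
    for (term in terms) {
      toks <- strsplit(term, "\\s+")[[1]]
      if (length(toks) == 1L) {
        coeff <- 1; met <- toks[1]
      } else if (length(toks) == 2L) {
        coeff <- suppressWarnings(as.numeric(toks[1])); met <- toks[2]
        if (is.na(coeff)) {
          stop(sprintf("bad coefficient in term '%s' of '%s'", term, equation))
        }
      } else {
        stop(sprintf("cannot parse term '%s' of '%s'", term, equation))
      }
      prev <- if (met %in% names(st)) st[[met]] else 0
      st[met] <- prev + sign * coeff
    }
    st
  }
  lhs <- parse_side(parts[1], -1)
  rhs <- parse_side(parts[2], +1)
  st <- c(lhs, rhs)
  st <- tapply(st, names(st), sum)
  out <- as.numeric(st); names(out) <- names(st)
  list(stoichiometry = out[out != 0], reversible = rev_arrow)
}

#' Format a stoichiometry vector as an equation string
#'
#' @param stoichiometry Named numeric vector (negative = consumed).
#' @param reversible Use a `<=>` arrow.
#' @return Character scalar.
#' @export
format_reaction_equation <- function(stoichiometry, reversible = FALSE) {
  fmt <- function(ids, coeffs) {
    if (!length(ids)) return("")
    paste(ifelse(coeffs == 1, ids, paste(format(coeffs, trim = TRUE,
                                                scientific = FALSE), ids)),
          collapse = " + ")
  }
  neg <- stoichiometry < 0
  lhs <- fmt(names(stoichiometry)[neg], -stoichiometry[neg])
  rhs <- fmt(names(stoichiometry)[!neg], stoichiometry[!neg])
  paste(lhs, if (reversible) "<=>" else "-->", rhs)
}

.write_model_tsv <- function(model, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  utils::write.table(model$metabolites, file.path(path, "metabolites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  rxns <- model$reactions
  eqs <- vapply(rxns$id, function(rid) {
    format_reaction_equation(model$stoichiometry[[rid]],
                             reversible = rxns$lower_bound[match(rid, rxns$id)] < 0)
  }, character(1))
  rtab <- data.frame(id = rxns$id, name = rxns$name, equation = eqs,
                     lower_bound = rxns$lower_bound,
                     upper_bound = rxns$upper_bound,
                     subsystem = rxns$subsystem, kind = rxns$kind,
                     objective = as.integer(rxns$id == model$objective),
                     stringsAsFactors = FALSE)
  utils::write.table(rtab, file.path(path, "reactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  gtab <- data.frame(reaction_id = rxns$id, gpr = rxns$gpr,
                     stringsAsFactors = FALSE)
  utils::write.table(gtab[nzchar(gtab$gpr), , drop = FALSE],
                     file.path(path, "gprs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                    check.names = FALSE)
}

.read_model_tsv <- function(path) {
  met_path <- file.path(path, "metabolites.tsv")
  rxn_path <- file.path(path, "reactions.tsv")
  gpr_path <- file.path(path, "gprs.tsv")
  for (p in c(met_path, rxn_path)) {
    if (!file.exists(p)) stop(sprintf("missing table '%s'", p))
  }
  mtab <- .read_tsv(met_path)
  rtab <- .read_tsv(rxn_path)
  gtab <- if (file.exists(gpr_path)) .read_tsv(gpr_path) else
    data.frame(reaction_id = character(0), gpr = character(0))
  gpr_map <- stats::setNames(as.character(gtab$gpr), gtab$reaction_id)
  mets <- lapply(seq_len(nrow(mtab)), function(k) {
    metabolite(mtab$id[k],
               name = if ("name" %in% names(mtab) && !is.na(mtab$name[k])) mtab$name[k] else mtab$id[k],
               formula = if ("formula" %in% names(mtab)) mtab$formula[k] else NA_character_,
               charge = if ("charge" %in% names(mtab)) mtab$charge[k] else NA_integer_)
  })
  rxns <- lapply(seq_len(nrow(rtab)), function(k) {
    eq <- tryCatch(parse_reaction_equation(rtab$equation[k]),
                   error = function(e) stop(sprintf(
                     "reactions.tsv row %d (%s): %s", k, rtab$id[k],
                     conditionMessage(e))))
    lb <- if ("lower_bound" %in% names(rtab) && !is.na(rtab$lower_bound[k])) {
      rtab$lower_bound[k]
    } else if (eq$reversible) -1000 else 0
    ub <- if ("upper_bound" %in% names(rtab) && !is.na(rtab$upper_bound[k])) {
      rtab$upper_bound[k]
    } else 1000
    gpr_k <- gpr_map[rtab$id[k]]
    if (is.na(gpr_k) || length(gpr_k) == 0L) gpr_k <- ""
    reaction(rtab$id[k], eq$stoichiometry, lower_bound = lb, upper_bound = ub,
             gpr = unname(gpr_k),
             name = if ("name" %in% names(rtab) && !is.na(rtab$name[k])) rtab$name[k] else rtab$id[k],
             subsystem = if ("subsystem" %in% names(rtab) && !is.na(rtab$subsystem[k])) rtab$subsystem[k] else "",
             kind = if ("kind" %in% names(rtab) && !is.na(rtab$kind[k])) rtab$kind[k] else NULL)
  })
  objective <- if ("objective" %in% names(rtab) && any(rtab$objective == 1)) {
    rtab$id[which(rtab$objective == 1)[1]]
  } else {
    rtab$id[nrow(rtab)]
  }
  metabolic_model(id = basename(normalizePath(path, mustWork = FALSE)),
                  metabolites = mets, reactions = rxns, objective = objective)
}
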