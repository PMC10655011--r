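# Flux balance analysis core: FBA, parsimonious FBA, growth-rate validation.

#' Construct a flux_solution object
#' @keywords internal
.flux_solution <- function(status, objective_value, fluxes) {
  structure(list(status = status, objective_value = objective_value,
                 fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status: %s, objective: %s\n", x$status,
              format(x$objective_value)))
  if (x$status == "optimal") {
    nz <- sum(abs(x$fluxes) > 1e-8)
    cat(sprintf("  %d/%d reactions carry flux (|v| > 1e-8)\n", nz,
                length(x$fluxes)))
  }
  invisible(x)
}

# Build the steady-state LP for a model.
#
# objective: named numeric vector of reaction coefficients (or a single
# reaction id).  pins: named numeric vector fixing fluxes (lb = ub = value).
# coupling: list of extra linear equalities, each list(coeffs = named numeric
# over reaction ids, rhs = scalar).
.fba_problem <- function(model, objective, maximize, pins = NULL,
                         coupling = NULL) {
  rxn_ids <- model$reactions$id
  n <- length(rxn_ids)
  if (is.character(objective)) {
    if (!objective %in% rxn_ids) {
      stop(sprintf("objective reaction '%s' not in model", objective))
    }
    obj <- stats::setNames(numeric(n), rxn_ids)
    obj[objective] <- 1
  } else {
    obj <- stats::setNames(numeric(n), rxn_ids)
    obj[names(objective)] <- objective
  }
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (length(pins)) {
    idx <- match(names(pins), rxn_ids)
    if (anyNA(idx)) {
      stop(sprintf("pinned reaction(s) not in model: %s",
                   paste(names(pins)[is.na(idx)], collapse = ", ")))
    }
    lb[idx] <- pins
    ub[idx] <- pins
  }
  sm <- build_stoichiometric_matrix(model)
  trip <- Matrix::mat2triplet(sm$S)
  eq <- list(i = trip$i, j = trip$j, x = trip$x,
             rhs = numeric(nrow(model$metabolites)))
  m <- length(eq$rhs)
  for (cp in coupling) {
    m <- m + 1L
    idx <- match(names(cp$coeffs), rxn_ids)
    if (anyNA(idx)) stop("coupling constraint references unknown reaction")
    eq$i <- c(eq$i, rep.int(m, length(idx)))
    eq$j <- c(eq$j, idx)
    eq$x <- c(eq$x, unname(cp$coeffs))
    eq$rhs <- c(eq$rhs, cp$rhs)
  }
  list(problem = lp_problem(unname(obj), lb, ub, maximize = maximize, eq = eq),
       rxn_ids = rxn_ids, objective = obj)
}

#' Flux balance analysis
#'
#' Solves `max/min c'v` subject to steady state (`S v = 0` over all declared
#' metabolites), the reaction bounds, optional pinned fluxes and optional
#' extra linear couplings (e.g. a 50/50 nitrate/ammonium constraint).
#'
#' @param model A `metabolic_model`.
#' @param objective Reaction id, or a named numeric vector of objective
#'   coefficients over reaction ids.  Defaults to the model objective.
#' @param sense `"max"` or `"min"`.
#' @param pins Named numeric vector of fluxes to fix (`lb = ub = value`).
#' @param coupling List of extra equality constraints, each
#'   `list(coeffs = c(rxn = coeff, ...), rhs = value)`.
#' @return A `flux_solution` with `status` (`optimal`, `infeasible`,
#'   `unbounded`), `objective_value` and the flux vector `fluxes` (named by
#'   reaction id).  Unbounded problems are reported as such, never as a large
#'   finite optimum.
#' @export
solve_fba <- function(model, objective = model$objective,
                      sense = c("max", "min"), pins = NULL, coupling = NULL) {
  sense <- match.arg(sense)
  fp <- .fba_problem(model, objective, maximize = sense == "max",
                     pins = pins, coupling = coupling)
  sol <- lp_solve(fp$problem)
  fluxes <- if (sol$status == "optimal") {
    stats::setNames(sol$x, fp$rxn_ids)
  } else {
    stats::setNames(rep(NA_real_, length(fp$rxn_ids)), fp$rxn_ids)
  }
  .flux_solution(sol$status, sol$objective, fluxes)
}

# Minimize sum_j w_j |v_j| subject to steady state, bounds, pins, coupling
# and extra equality rows fixing previously attained objectives.
# weights: named vector over reaction ids (absent = weight 0 = free).
.min_weighted_l1 <- function(model, weights, pins = NULL, coupling = NULL,
                             fixed = NULL) {
  fp <- .fba_problem(model, objective = model$objective, maximize = FALSE,
                     pins = pins, coupling = coupling)
  n <- length(fp$rxn_ids)
  lb <- fp$problem$lb
  ub <- fp$problem$ub
  w <- stats::setNames(numeric(n), fp$rxn_ids)
  w[names(weights)] <- weights
  # reactions that cannot go negative contribute |v| = v directly;
  # the rest get an auxiliary t_j >= |v_j|
  need_aux <- which(w > 0 & lb < 0)
  direct <- which(w > 0 & lb >= 0)
  n_aux <- length(need_aux)
  obj <- numeric(n + n_aux)
  obj[direct] <- w[direct]
  if (n_aux) obj[n + seq_len(n_aux)] <- w[need_aux]
  lb_full <- c(lb, rep(0, n_aux))
  ub_full <- c(ub, pmax(abs(lb[need_aux]), abs(ub[need_aux])))
  eq <- fp$problem$eq
  for (fx in fixed) {
    idx <- match(names(fx$coeffs), fp$rxn_ids)
    row <- max(eq$i, 0L) + 1L
    eq$i <- c(eq$i, rep.int(row, length(idx)))
    eq$j <- c(eq$j, idx)
    eq$x <- c(eq$x, unname(fx$coeffs))
    eq$rhs <- c(eq$rhs, fx$rhs)
  }
  # t_j >= v_j and t_j >= -v_j  <=>  v_j - t_j <= 0 and -v_j - t_j <= 0
  leq <- list(i = integer(0), j = integer(0), x = numeric(0), rhs = numeric(0))
  for (k in seq_len(n_aux)) {
    j_v <- need_aux[k]; j_t <- n + k
    r1 <- length(leq$rhs) + 1L; r2 <- r1 + 1L
    leq$i <- c(leq$i, r1, r1, r2, r2)
    leq$j <- c(leq$j, j_v, j_t, j_v, j_t)
    leq$x <- c(leq$x, 1, -1, -1, -1)
    leq$rhs <- c(leq$rhs, 0, 0)
  }
  prob <- lp_problem(obj, lb_full, ub_full, maximize = FALSE, eq = eq,
                     leq = leq)
  sol <- lp_solve(prob)
  if (sol$status == "optimal") {
    sol$x <- sol$x[seq_len(n)]
    names(sol$x) <- fp$rxn_ids
  }
  sol
}

#' Parsimonious flux balance analysis
#'
#' First solves the FBA problem, then, with the objective pinned at its
#' optimum, minimizes the total absolute flux.  The returned flux vector
#' attains both optima.  Because plain FBA optima are typically degenerate,
#' all reported flux distributions in condition comparisons come from pFBA.
#'
#' @inheritParams solve_fba
#' @param objective_tol Relative slack granted to the primary objective when
#'   pinning it for the parsimony stage (default `0`, i.e. exact pin).
#' @return A `flux_solution`; `objective_value` is the primary FBA optimum.
#' @export
solve_pfba <- function(model, objective = model$objective,
                       sense = c("max", "min"), pins = NULL, coupling = NULL,
                       objective_tol = 0) {
  sense <- match.arg(sense)
  fba <- solve_fba(model, objective, sense = sense, pins = pins,
                   coupling = coupling)
  if (fba$status != "optimal") return(fba)
  fp <- .fba_problem(model, objective, maximize = TRUE, pins = pins)
  obj_coeffs <- fp$objective[fp$objective != 0]
  target <- fba$objective_value
  if (objective_tol > 0) target <- target * (1 - sign(target) * objective_tol)
  weights <- stats::setNames(rep(1, length(fp$rxn_ids)), fp$rxn_ids)
  sol <- .min_weighted_l1(model, weights, pins = pins, coupling = coupling,
                          fixed = list(list(coeffs = obj_coeffs,
                                            rhs = target)))
  if (sol$status != "optimal") {
    # numerically exact pin can fail on ill-conditioned problems; retry with
    # a tiny relative slack
    if (objective_tol == 0) {
      return(solve_pfba(model, objective, sense = sense, pins = pins,
                        coupling = coupling, objective_tol = 1e-9))
    }
    return(.flux_solution(sol$status, NA_real_,
                          stats::setNames(rep(NA_real_, length(fp$rxn_ids)),
                                          fp$rxn_ids)))
  }
  .flux_solution("optimal", fba$objective_value, sol$x)
}

#' Verify a flux solution against its model
#'
#' Checks the steady-state residual `max_i |sum_j S_ij v_j|` and bound
#' violations of an optimal solution.
#'
#' @param model A `metabolic_model`.
#' @param solution A `flux_solution`.
#' @return List with `steady_state_residual` and `bound_violation` (both
#'   infinity norms).
#' @export
check_solution <- function(model, solution) {
  stopifnot(inherits(solution, "flux_solution"),
            solution$status == "optimal")
  sm <- build_stoichiometric_matrix(model)
  v <- solution$fluxes[colnames(sm$S)]
  resid <- max(abs(as.numeric(sm$S %*% v)))
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  viol <- max(c(0, lb - v, v - ub))
  list(steady_state_residual = resid, bound_violation = viol)
}

# ---- growth-rate validation ----------------------------------------------

.exchange_species <- function(model, rid) {
  names(model$stoichiometry[[rid]])[1]
}

# Classify exchange reactions by the species they import.
.classify_exchanges <- function(model) {
  ex <- exchange_ids(model)
  species <- vapply(ex, function(rid) .exchange_species(model, rid),
                    character(1))
  formulas <- model$metabolites$formula[match(species, model$metabolites$id)]
  has_c <- vapply(formulas, function(f) {
    counts <- tryCatch(parse_formula(f), error = function(e) NULL)
    !is.null(counts) && "C" %in% names(counts)
  }, logical(1))
  is_photon <- grepl("^photon", species, ignore.case = TRUE)
  is_co2 <- grepl("^co2_", species, ignore.case = TRUE)
  list(all = ex,
       photon = ex[is_photon],
       co2 = ex[is_co2],
       nitrate = ex[grepl("^no3_", species, ignore.case = TRUE)],
       ammonium = ex[grepl("^nh4_", species, ignore.case = TRUE)],
       organic = ex[has_c & !is_co2 & !is_photon])
}

#' Equal nitrate/ammonium coupling constraint
#'
#' Returns the coupling constraint `v_NO3 - v_NH4 = 0`, implementing a
#' nitrogen supply of 50% nitrate and 50% ammonium while letting the total
#' nitrogen uptake float with growth.
#'
#' @param model A `metabolic_model` with nitrate and ammonium exchanges.
#' @return A list suitable for the `coupling` argument of [solve_fba()].
#' @export
nitrogen_fifty_fifty <- function(model) {
  cls <- .classify_exchanges(model)
  if (length(cls$nitrate) != 1L || length(cls$ammonium) != 1L) {
    stop("model must have exactly one nitrate and one ammonium exchange")
  }
  list(list(coeffs = stats::setNames(c(1, -1), c(cls$nitrate, cls$ammonium)),
            rhs = 0))
}

#' Predict growth rates under CO2-fixation constraints
#'
#' For each validation case, closes all organic-carbon exchanges, opens the
#' photon inputs, couples nitrogen uptake to 50% nitrate / 50% ammonium,
#' pins the CO2 exchange flux to the case's fixation rate and maximizes
#' biomass.
#'
#' @param model A `metabolic_model`.
#' @param cases Data frame with columns `line_label`, `co2_fixation_rate` and
#'   optionally `observed_growth`.
#' @param photon_open Upper bound opened on photon exchanges (default 1000).
#' @param parsimonious Use pFBA for the reported fluxes (default `FALSE`;
#'   only the objective value is reported here).
#' @return Data frame `(line_label, co2_fixation_rate, predicted_growth,
#'   status)`; when `observed_growth` is present the Pearson correlation
#'   between predictions and observations is attached as attribute
#'   `"correlation"`.
#' @export
predict_growth_rates <- function(model, cases, photon_open = 1000,
                                 parsimonious = FALSE) {
  stopifnot(is.data.frame(cases),
            all(c("line_label", "co2_fixation_rate") %in% names(cases)))
  if (any(cases$co2_fixation_rate < 0)) {
    stop("co2_fixation_rate must be >= 0")
  }
  cls <- .classify_exchanges(model)
  if (!length(cls$co2)) stop("model has no CO2 exchange")
  if (!length(cls$photon)) stop("model has no photon exchange")
  m <- model
  m <- set_bounds(m, cls$organic, lower = 0, upper = 0)
  m <- set_bounds(m, cls$photon, lower = 0, upper = photon_open)
  coupling <- nitrogen_fifty_fifty(m)
  solver <- if (parsimonious) solve_pfba else solve_fba
  res <- lapply(seq_len(nrow(cases)), function(k) {
    pins <- stats::setNames(cases$co2_fixation_rate[k], cls$co2[1])
    sol <- solver(m, pins = pins, coupling = coupling)
    data.frame(line_label = cases$line_label[k],
               co2_fixation_rate = cases$co2_fixation_rate[k],
               predicted_growth = if (sol$status == "optimal")
                 sol$objective_value else NA_real_,
               status = sol$status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if ("observed_growth" %in% names(cases)) {
    ok <- !is.na(out$predicted_growth) & !is.na(cases$observed_growth)
    if (sum(ok) >= 3 && stats::sd(out$predicted_growth[ok]) > 0) {
      attr(out, "correlation") <- stats::cor(out$predicted_growth[ok],
                                             cases$observed_growth[ok])
    }
  }
  out
}
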