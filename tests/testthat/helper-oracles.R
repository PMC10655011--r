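# Independent oracles kept deliberately naive: exhaustive vertex enumeration
# for small LPs and a brute-force stoichiometric matrix builder.

# Enumerate all basic feasible solutions of {S v = 0, lb <= v <= ub} by
# fixing every subset of n - rank(S) variables at a bound and solving the
# remaining square system.  Returns the maximum of c'v over all vertices.
vertex_enumeration_optimum <- function(model, objective,
                                       sense = c("max", "min"), tol = 1e-8) {
  sense <- match.arg(sense)
  sm <- build_stoichiometric_matrix(model)
  S <- as.matrix(sm$S)
  rxns <- model$reactions
  n <- nrow(rxns)
  lb <- rxns$lower_bound
  ub <- rxns$upper_bound
  cc <- stats::setNames(numeric(n), rxns$id)
  cc[objective] <- 1
  r <- qr(S)$rank
  n_fix <- n - r
  best <- NA_real_
  consider <- function(v) {
    if (any(v < lb - tol) || any(v > ub + tol)) return()
    if (max(abs(S %*% v)) > tol) return()
    val <- sum(cc * v)
    if (is.na(best) || (sense == "max" && val > best) ||
        (sense == "min" && val < best)) best <<- val
  }
  if (n_fix == 0) {
    return(NA_real_)
  }
  fix_sets <- utils::combn(n, n_fix, simplify = FALSE)
  for (fx in fix_sets) {
    free <- setdiff(seq_len(n), fx)
    S_free <- S[, free, drop = FALSE]
    if (qr(S_free)$rank < length(free)) next
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), n_fix))
    for (g in seq_len(nrow(grid))) {
      v <- numeric(n)
      v[fx] <- ifelse(unlist(grid[g, ]), ub[fx], lb[fx])
      rhs <- -S[, fx, drop = FALSE] %*% v[fx]
      sol <- tryCatch(qr.solve(S_free, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      v[free] <- sol
      consider(v)
    }
  }
  best
}

# Naive double loop over reaction stoichiometries.
brute_force_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (rid in rxn_ids) {
    st <- model$stoichiometry[[rid]]
    for (mid in names(st)) {
      S[mid, rid] <- S[mid, rid] + st[[mid]]
    }
  }
  S
}

# Exhaustive subset search for minimal-weight gap fills: smallest total
# weight subset of the pool whose addition makes the target producible.
exhaustive_gapfill <- function(model, pool, target, min_production = 1e-3) {
  ids <- names(pool$weights)
  best <- NULL
  best_w <- Inf
  for (size in 0:length(ids)) {
    for (subset in utils::combn(length(ids), size, simplify = FALSE)) {
      sel <- ids[subset]
      w <- sum(pool$weights[sel])
      if (w >= best_w) next
      trial <- model
      for (r in pool$reactions) {
        if (r$id %in% sel) trial <- add_reaction(trial, r)
      }
      sink <- reaction(".oracle_sink", stats::setNames(-1, target), 0, 1000)
      trial <- add_reaction(trial, sink)
      sol <- solve_fba(trial, objective = ".oracle_sink", sense = "max")
      if (sol$status == "optimal" && sol$objective_value >= min_production) {
        best <- sel
        best_w <- w
      }
    }
  }
  list(set = best, weight = best_w)
}
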