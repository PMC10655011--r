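# Pluggable linear-programming backend.
#
# All constraint-based analyses reduce to LPs of the form
#   minimize c'x  s.t.  A_eq x = b_eq,  A_ub x <= b_ub,  lb <= x <= ub.
# The production backend delegates to the HiGHS solver through
# scipy.optimize.linprog, invoked as a python subprocess with JSON I/O and
# batch support (one interpreter start-up per batch).  Tests cross-check the
# results against exhaustive vertex enumeration on small fixtures.

#' Construct an LP problem
#'
#' @param objective Objective coefficient vector (length `n`).
#' @param lb,ub Variable bounds (length `n`); `NA` entries are unbounded.
#' @param maximize Maximize instead of minimize (default `FALSE`).
#' @param eq Optional equality constraints: list with sparse triplets
#'   `i`, `j` (1-based), `x` and right-hand side `rhs`.
#' @param leq Optional `<=` inequality constraints in the same triplet form.
#' @return An `lp_problem` object.
#' @keywords internal
#' @export
lp_problem <- function(objective, lb, ub, maximize = FALSE,
                       eq = NULL, leq = NULL) {
  n <- length(objective)
  stopifnot(length(lb) == n, length(ub) == n)
  structure(list(n = n, objective = as.numeric(objective),
                 lb = as.numeric(lb), ub = as.numeric(ub),
                 maximize = isTRUE(maximize), eq = eq, leq = leq),
            class = "lp_problem")
}

.lp_python <- function() {
  opt <- getOption("phytoflux.python", NULL)
  if (!is.null(opt)) return(opt)
  for (cand in c("python", "python3")) {
    path <- Sys.which(cand)
    if (nzchar(path)) return(unname(path))
  }
  stop("no python interpreter found for the LP backend; ",
       "set options(phytoflux.python = ...)")
}

.lp_script <- function() {
  path <- system.file("python", "solve_lp.py", package = "phytoflux")
  if (!nzchar(path)) stop("LP helper script not found; is phytoflux installed?")
  path
}

.lp_problem_to_list <- function(p) {
  na2null <- function(v) lapply(v, function(x) if (is.na(x) || is.infinite(x)) NULL else x)
  out <- list(n = p$n,
              c = if (p$maximize) -p$objective else p$objective,
              lb = na2null(p$lb), ub = na2null(p$ub))
  if (!is.null(p$eq) && length(p$eq$rhs)) {
    out$eq_i <- as.integer(p$eq$i) - 1L
    out$eq_j <- as.integer(p$eq$j) - 1L
    out$eq_x <- as.numeric(p$eq$x)
    out$eq_rhs <- as.numeric(p$eq$rhs)
  }
  if (!is.null(p$leq) && length(p$leq$rhs)) {
    out$ub_i <- as.integer(p$leq$i) - 1L
    out$ub_j <- as.integer(p$leq$j) - 1L
    out$ub_x <- as.numeric(p$leq$x)
    out$ub_rhs <- as.numeric(p$leq$rhs)
  }
  out
}

#' Solve a batch of LP problems
#'
#' @param problems A single `lp_problem` or a list of them.
#' @return For a single problem, a list with `status`
#'   (`optimal`/`infeasible`/`unbounded`/`failed`), `objective` (on the
#'   original max/min scale) and `x`; for a list input, a list of such
#'   results.
#' @keywords internal
#' @export
lp_solve <- function(problems) {
  single <- inherits(problems, "lp_problem")
  if (single) problems <- list(problems)
  stopifnot(all(vapply(problems, inherits, logical(1), "lp_problem")))
  payload <- lapply(problems, .lp_problem_to_list)
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2(.lp_python(), c(.lp_script(), infile, outfile),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(outfile)) {
    stop(sprintf("LP backend failed (exit status %s)", status))
  }
  raw <- jsonlite::read_json(outfile)
  sols <- lapply(seq_along(raw), function(k) {
    s <- raw[[k]]
    out <- list(status = s$status, objective = NA_real_, x = NULL)
    if (identical(s$status, "optimal")) {
      obj <- s$objective
      out$objective <- if (problems[[k]]$maximize) -obj else obj
      out$x <- as.numeric(unlist(s$x))
    }
    out
  })
  if (single) sols[[1]] else sols
}
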