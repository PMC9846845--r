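.python_bin <- function() {
  opt <- getOption("redoxmip.python", NULL)
  if (!is.null(opt)) return(opt)
  for (cand in c("python", "python3"))
    if (nzchar(Sys.which(cand))) return(Sys.which(cand))
  stop("no python interpreter found on PATH (needed for the HiGHS solver ",
       "bridge); set options(redoxmip.python = ...)", call. = FALSE)
}

.bridge_script <- function() {
  p <- system.file("python", "mip_bridge.py", package = "redoxmip")
  if (!nzchar(p)) stop("solver bridge script not found", call. = FALSE)
  p
}

.problem_payload <- function(problem, maximize = FALSE, time_limit = NULL,
                             extra_rows = list()) {
  vars <- problem@variables
  idx <- setNames(seq_len(nrow(vars)), vars$name)
  obj <- rep(0, nrow(vars))
  if (length(problem@objective))
    obj[idx[names(problem@objective)]] <- unname(problem@objective)
  rows <- c(problem@linear, extra_rows)
  i <- integer(); j <- integer(); v <- numeric()
  rel <- character(length(rows)); rhs <- numeric(length(rows))
  for (k in seq_along(rows)) {
    r <- rows[[k]]
    i <- c(i, rep(k, length(r$coef)))
    j <- c(j, unname(idx[names(r$coef)]))
    v <- c(v, unname(r$coef))
    rel[k] <- r$rel; rhs[k] <- r$rhs
  }
  enc_num <- function(x) ifelse(is.finite(x), x,
                                ifelse(x > 0, "inf", "-inf"))
  list(n = nrow(vars), obj = obj,
       lb = as.list(enc_num(vars$lb)), ub = as.list(enc_num(vars$ub)),
       integrality = as.integer(vars$kind == "binary"),
       rows = list(i = i, j = j, v = v),
       rel = rel, rhs = as.list(enc_num(rhs)),
       maximize = maximize, time_limit = time_limit)
}

## Solve a list of payloads in one python subprocess; returns list of
## list(status, objective, x).
.bridge_solve <- function(payloads) {
  if (!length(payloads)) return(list())
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(list(problems = payloads), fin, auto_unbox = TRUE,
                       digits = NA, null = "null")
  status <- system2(.python_bin(), c(.bridge_script(), fin, fout),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout))
    stop("solver bridge failed:\n", paste(status, collapse = "\n"),
         call. = FALSE)
  jsonlite::read_json(fout, simplifyVector = FALSE)$solutions
}

#' Solve a mixed-integer program to proven optimality
#'
#' A bilinear-encoded problem is first passed through [linearize()].  The
#' backend (HiGHS) is deterministic for a fixed problem, so repeated calls
#' with the same seed reproduce the same solution bit for bit.
#'
#' @param problem a [MipProblem-class].
#' @param time_limit optional wall-clock limit in seconds; when hit, the best
#'   incumbent is returned with status `"feasible-time-limit"`.
#' @param seed integer seed recorded with the solution (the exact backend
#'   needs no randomness; the seed keys downstream tie-break enumeration).
#' @return list with `status` (`"optimal"`, `"infeasible"`,
#'   `"feasible-time-limit"`), `objective`, and `assignment` (named numeric
#'   over all registered variables; `NULL` when infeasible).
#' @export
solveMip <- function(problem, time_limit = NULL, seed = 1L) {
  lp <- if (problem@encoding == "bilinear") linearize(problem) else problem
  if (!nrow(lp@variables))
    return(list(status = "optimal", objective = 0,
                assignment = setNames(numeric(), character()), seed = seed))
  sol <- .bridge_solve(list(.problem_payload(lp, time_limit = time_limit)))[[1]]
  assignment <- NULL
  if (!is.null(sol$x)) {
    assignment <- setNames(unlist(sol$x), lp@variables$name)
    bin <- lp@variables$kind == "binary"
    assignment[bin] <- round(assignment[bin])
    assignment <- assignment[problem@variables$name]
  }
  obj <- if (is.null(sol$objective)) NA_real_ else sol$objective
  list(status = sol$status, objective = obj, assignment = assignment,
       seed = seed)
}

## Batch interface used by tests and the acceptance script: solves many
## MipProblems in one subprocess call.
.solve_batch <- function(problems, time_limit = NULL) {
  lps <- lapply(problems, function(p)
    if (p@encoding == "bilinear") linearize(p) else p)
  payloads <- lapply(lps, .problem_payload, time_limit = time_limit)
  sols <- .bridge_solve(payloads)
  lapply(seq_along(sols), function(k) {
    sol <- sols[[k]]; lp <- lps[[k]]
    assignment <- NULL
    if (!is.null(sol$x)) {
      assignment <- setNames(unlist(sol$x), lp@variables$name)
      bin <- lp@variables$kind == "binary"
      assignment[bin] <- round(assignment[bin])
      assignment <- assignment[problems[[k]]@variables$name]
    }
    list(status = sol$status,
         objective = if (is.null(sol$objective)) NA_real_ else sol$objective,
         assignment = assignment)
  })
}

## Solve a pure LP described directly by bounds/rows; used by the FBA module.
.solve_lp <- function(obj, lb, ub, rows, maximize = FALSE) {
  n <- length(obj)
  i <- integer(); j <- integer(); v <- numeric()
  rel <- character(length(rows)); rhs <- numeric(length(rows))
  for (k in seq_along(rows)) {
    r <- rows[[k]]
    i <- c(i, rep(k, length(r$j))); j <- c(j, r$j); v <- c(v, r$v)
    rel[k] <- r$rel; rhs[k] <- r$rhs
  }
  enc <- function(x) ifelse(is.finite(x), x, ifelse(x > 0, "inf", "-inf"))
  payload <- list(n = n, obj = obj, lb = as.list(enc(lb)),
                  ub = as.list(enc(ub)), integrality = rep(0L, n),
                  rows = list(i = i, j = j, v = v), rel = rel,
                  rhs = as.list(enc(rhs)), maximize = maximize)
  sol <- .bridge_solve(list(payload))[[1]]
  list(status = sol$status,
       objective = if (is.null(sol$objective)) NA_real_ else sol$objective,
       x = if (is.null(sol$x)) NULL else unlist(sol$x))
}
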