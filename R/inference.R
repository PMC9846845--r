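#' Extract the inferred cell-state-specific network from a solution
#'
#' Maps the optimal variable assignment back to node states, edge occurrence,
#' enzyme states, reaction statuses (a reaction is blocked when it carries no
#' net flux and either its enzyme is off or thermodynamics forbids its
#' declared direction), fluxes and predicted metabolite ratios, and fills in
#' the fit metrics.
#'
#' @param solution a solution from [solveMip()].
#' @param problem the [MipProblem-class] that was solved.
#' @param network the [IntegratedNetwork-class].
#' @param measurements the [MeasurementSet-class].
#' @param metric metabolite error metric, see [metaboliteError()].
#' @param flux_tol tolerance below which a flux counts as zero.
#' @return an [InferenceResult-class].
#' @export
extractResult <- function(solution, problem, network, measurements,
                          metric = "log2_mae", flux_tol = 1e-6) {
  if (!solution$status %in% c("optimal", "feasible-time-limit"))
    stop("no solution to extract (status ", solution$status, ")",
         call. = FALSE)
  vm <- problem@varMap
  asg <- solution$assignment
  g <- function(nms) if (length(nms)) setNames(asg[unname(nms)], names(nms))
                     else setNames(numeric(), character())

  node_states <- as.integer(round(g(vm$x)))
  names(node_states) <- names(vm$x)
  edge_occ <- as.character(ifelse(round(g(vm$y)) == 1, "occurred", "removed"))
  names(edge_occ) <- names(vm$y)
  enz_states <- as.integer(round(g(vm$b)))
  names(enz_states) <- names(vm$b)
  fluxes <- g(vm$v)
  cpred <- g(vm$c)

  rx <- network@reactions
  status <- setNames(character(nrow(rx)), rx$id)
  for (i in seq_len(nrow(rx))) {
    rid <- rx$id[i]
    v <- fluxes[[rid]]
    enz_off <- !is.na(rx$enzyme[i]) && enz_states[[rx$enzyme[i]]] == 0L
    thermo_blocked <- identical(unname(vm$thermoForced[rid]), "blocked")
    status[rid] <-
      if (abs(v) <= flux_tol && (enz_off || thermo_blocked)) "blocked"
      else if (v < -flux_tol) "backward"
      else "forward"
  }

  res <- new("InferenceResult",
             nodeStates = node_states, edgeOccurrence = edge_occ,
             enzymeStates = enz_states, reactionStatus = status,
             fluxes = fluxes, metabolitePredictions = cpred,
             objective = solution$objective,
             signalingPrecision = NA_real_, metaboliteError = NA_real_,
             metaboliteErrorMetric = metric,
             solverStatus = solution$status, solution = asg)
  ft <- problem@options$fold_threshold
  prot <- proteinRatios(measurements)
  known <- .binarized_states(prot, ft)
  if (any(!is.na(known)))
    res@signalingPrecision <- signalingPrecision(res, measurements, ft)
  if (nrow(metaboliteRatios(measurements)))
    res@metaboliteError <- metaboliteError(res, measurements, metric)
  res
}

#' Fitting precision on measured signaling proteins
#'
#' The fraction of measured nodes whose inferred binary state equals the
#' binarized measurement.  Measurements inside the dead band (unknown state)
#' are excluded from both numerator and denominator.
#'
#' @param result an [InferenceResult-class].
#' @param measurements a [MeasurementSet-class].
#' @param fold_threshold binarization threshold (see [binarizeRatio()]).
#' @return fraction in `[0, 1]`.
#' @export
signalingPrecision <- function(result, measurements, fold_threshold = 1.5) {
  states <- .binarized_states(proteinRatios(measurements), fold_threshold)
  states <- states[!is.na(states)]
  if (!length(states))
    stop("no measured signaling node binarizes to a known state; ",
         "precision is undefined", call. = FALSE)
  predicted <- c(result@nodeStates,
                 result@enzymeStates[setdiff(names(result@enzymeStates),
                                             names(result@nodeStates))])
  ids <- names(states)
  missing <- setdiff(ids, names(predicted))
  if (length(missing))
    stop("no inferred state for measured id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  mean(predicted[ids] == states)
}

#' Prediction error on measured metabolites
#'
#' Default metric is the mean absolute difference between predicted and
#' measured fold-change ratios on the log2 scale; linear-scale MAE and RMSE
#' are selectable.  The metric name is recorded alongside the value in
#' [extractResult()].
#'
#' @param result an [InferenceResult-class].
#' @param measurements a [MeasurementSet-class].
#' @param metric one of `"log2_mae"`, `"mae"`, `"rmse"`.
#' @return non-negative error.
#' @export
metaboliteError <- function(result, measurements,
                            metric = c("log2_mae", "mae", "rmse")) {
  metric <- match.arg(metric)
  mm <- metaboliteRatios(measurements)
  if (!nrow(mm))
    stop("no measured metabolites; error is undefined", call. = FALSE)
  pred <- result@metabolitePredictions[mm$id]
  if (anyNA(pred))
    stop("no prediction for measured metabolite(s): ",
         paste(mm$id[is.na(pred)], collapse = ", "), call. = FALSE)
  switch(metric,
         log2_mae = mean(abs(log2(pred) - log2(mm$ratio))),
         mae = mean(abs(pred - mm$ratio)),
         rmse = sqrt(mean((pred - mm$ratio)^2)))
}

#' Solve and extract in one step
#'
#' @inheritParams extractResult
#' @inheritParams solveMip
#' @return an [InferenceResult-class]; errors when the model is infeasible.
#' @export
infer <- function(problem, network, measurements, time_limit = NULL,
                  seed = 1L, metric = "log2_mae") {
  sol <- solveMip(problem, time_limit = time_limit, seed = seed)
  if (sol$status == "infeasible")
    stop("model is infeasible", call. = FALSE)
  extractResult(sol, problem, network, measurements, metric = metric)
}

#' Enumerate alternate optima
#'
#' Repeatedly re-solves with a no-good cut on the free binary assignment of
#' each previously found optimum, collecting up to `k` solutions whose
#' objective lies within `tol` of the optimum.  Surfacing degenerate optima
#' flags headline numbers (removed edges, blocked reactions) that are not
#' unique.
#'
#' @param problem a [MipProblem-class].
#' @param k maximum number of optima to return (>= 1).
#' @param tol objective tolerance for counting a solution as optimal.
#' @param time_limit per-solve limit in seconds.
#' @return list of solutions as returned by [solveMip()], deduplicated.
#' @export
enumerateOptima <- function(problem, k = 10, tol = 1e-6, time_limit = NULL) {
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  lp <- if (problem@encoding == "bilinear") linearize(problem) else problem
  vars <- lp@variables
  free_bin <- vars$name[vars$kind == "binary" & vars$lb < vars$ub]
  first <- solveMip(lp)
  if (first$status != "optimal") return(list())
  opt <- first$objective
  out <- list(first)
  if (!length(free_bin)) return(out)
  cuts <- list()
  while (length(out) < k) {
    prev <- out[[length(out)]]$assignment[free_bin]
    ones <- free_bin[prev > 0.5]; zeros <- free_bin[prev <= 0.5]
    cuts[[length(cuts) + 1L]] <- list(
      coef = setNames(c(rep(-1, length(ones)), rep(1, length(zeros))),
                      c(ones, zeros)),
      rel = ">=", rhs = 1 - length(ones),
      name = paste0("nogood_", length(cuts) + 1L))
    cut_lp <- lp
    cut_lp@linear <- c(lp@linear, cuts)
    sol <- solveMip(cut_lp, time_limit = time_limit)
    if (sol$status != "optimal" || sol$objective > opt + tol) break
    out[[length(out) + 1L]] <- sol
  }
  out
}

#' Post-solve physical audit of a solution
#'
#' Verifies, on the reported solution, that (i) steady-state mass balance
#' holds on every non-boundary metabolite, (ii) no flux runs against the
#' Gibbs-energy sign rule, and (iii) every reaction whose enzyme is off
#' carries no flux and has all its products predicted down (ratio <= 1).
#'
#' @param result an [InferenceResult-class].
#' @param network the [IntegratedNetwork-class].
#' @param tau the Gibbs tolerance the problem was built with.
#' @param tol numeric tolerance (default 1e-6).
#' @return list with `ok` (logical), `mass_residual` (max abs row residual),
#'   and `violations` (character, empty when ok).
#' @export
auditSolution <- function(result, network, tau = 0, tol = 1e-6) {
  viol <- character()
  rx <- network@reactions
  fluxes <- result@fluxes[rx$id]
  S <- stoichiometricMatrix(network, "exclude")
  mass_residual <- if (nrow(S) && length(fluxes))
    max(abs(as.numeric(S %*% fluxes[colnames(S)])))
  else 0
  if (mass_residual > tol)
    viol <- c(viol, sprintf("mass-balance residual %.3g > %.3g",
                            mass_residual, tol))
  for (i in seq_len(nrow(rx))) {
    rid <- rx$id[i]; v <- fluxes[[rid]]; dg <- rx$delta_g[i]
    if (!is.na(dg) && dg > tau && v > tol)
      viol <- c(viol, sprintf("%s: forward flux %.3g against delta_g=%.3g",
                              rid, v, dg))
    if (!is.na(dg) && dg < -tau && v < -tol)
      viol <- c(viol, sprintf("%s: backward flux %.3g against delta_g=%.3g",
                              rid, v, dg))
    z <- rx$enzyme[i]
    if (!is.na(z) && result@enzymeStates[[z]] == 0L) {
      if (abs(v) > tol)
        viol <- c(viol, sprintf("%s: flux %.3g with enzyme %s off", rid, v, z))
      st <- network@stoichiometry[[rid]]
      prods <- names(st)[st > 0]
      bad <- prods[result@metabolitePredictions[prods] > 1 + tol]
      if (length(bad))
        viol <- c(viol, sprintf("%s: product(s) %s above 1 with enzyme off",
                                rid, paste(bad, collapse = ",")))
    }
  }
  list(ok = !length(viol), mass_residual = mass_residual, violations = viol)
}

#' Objective decomposition of an inference result
#'
#' Recomputes `w1 * mismatches + w2 * metabolite L1 error + w3 * retained
#' edges` from the extracted fields, for verification against the solver's
#' reported objective.
#'
#' @param result an [InferenceResult-class].
#' @param problem the [MipProblem-class] solved.
#' @param measurements the [MeasurementSet-class] used.
#' @return named numeric: `misfit`, `metabolite_l1`, `edges`, `total`.
#' @export
objectiveBreakdown <- function(result, problem, measurements) {
  w <- problem@weights
  ft <- problem@options$fold_threshold
  states <- .binarized_states(proteinRatios(measurements), ft)
  states <- states[!is.na(states)]
  predicted <- c(result@nodeStates,
                 result@enzymeStates[setdiff(names(result@enzymeStates),
                                             names(result@nodeStates))])
  mis <- if (length(states)) sum(predicted[names(states)] != states) else 0
  mm <- metaboliteRatios(measurements)
  l1 <- if (nrow(mm))
    sum(abs(result@metabolitePredictions[mm$id] - mm$ratio)) else 0
  kept <- sum(result@edgeOccurrence == "occurred")
  c(misfit = unname(w["w1"]) * mis, metabolite_l1 = unname(w["w2"]) * l1,
    edges = unname(w["w3"]) * kept,
    total = unname(w["w1"]) * mis + unname(w["w2"]) * l1 +
      unname(w["w3"]) * kept)
}
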