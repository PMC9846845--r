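#' @import methods
#' @importFrom stats setNames rnorm runif rbinom
#' @importFrom utils head read.delim write.table modifyList
NULL

.NODE_KINDS <- c("signaling-protein", "dual-function-enzyme", "redox-hub")
.REDOX_EFFECTS <- c("oxidation-activates", "oxidation-inhibits", "none")
.EDGE_SIGNS <- c("activation", "inhibition")

#' IntegratedNetwork: a joint signaling + metabolic network
#'
#' Container for the generic redox-regulated map: a directed signaling graph
#' of proteins with activation/inhibition edges, a metabolic reaction network
#' with stoichiometry, reversibility and standard Gibbs energies, and the
#' dual-function enzymes that connect the two layers.  A single optional
#' redox-hub node (intracellular H2O2) modulates redox-sensitive proteins via
#' ordinary signed edges.
#'
#' @slot nodes data.frame with columns `id`, `name`, `kind` (one of
#'   signaling-protein, dual-function-enzyme, redox-hub) and `redox_effect`.
#' @slot edges data.frame with columns `id`, `source`, `target`, `sign`
#'   (activation/inhibition) and `removable`.
#' @slot metabolites data.frame with columns `id`, `name`, `boundary`.
#' @slot reactions data.frame with columns `id`, `reversible`, `delta_g`
#'   (kJ/mol, may be NA), `enzyme` (may be NA) and `flux_bound`.
#' @slot stoichiometry named list (by reaction id) of named numeric vectors:
#'   negative coefficients are substrates, positive are products.
#' @slot standaloneEnzymes character: enzyme ids that catalyze reactions but
#'   are not signaling nodes.
#' @slot interface character: dual-function enzymes that both receive
#'   signaling edges and catalyze reactions.
#'
#' @export
setClass("IntegratedNetwork", representation(
  nodes = "data.frame",
  edges = "data.frame",
  metabolites = "data.frame",
  reactions = "data.frame",
  stoichiometry = "list",
  standaloneEnzymes = "character",
  interface = "character"
))

setValidity("IntegratedNetwork", function(object) {
  msg <- character()
  nd <- object@nodes; ed <- object@edges
  mt <- object@metabolites; rx <- object@reactions
  if (anyDuplicated(nd$id)) msg <- c(msg, "duplicated node ids")
  if (anyDuplicated(mt$id)) msg <- c(msg, "duplicated metabolite ids")
  if (anyDuplicated(rx$id)) msg <- c(msg, "duplicated reaction ids")
  if (sum(nd$kind == "redox-hub") > 1)
    msg <- c(msg, "more than one redox-hub node")
  if (nrow(ed)) {
    if (any(ed$source == ed$target)) msg <- c(msg, "self-loop edge")
    if (anyDuplicated(ed[, c("source", "target", "sign")]))
      msg <- c(msg, "duplicated (source, target, sign) edge")
    bad <- setdiff(c(ed$source, ed$target), nd$id)
    if (length(bad)) msg <- c(msg, paste("edge endpoint(s) not nodes:",
                                         paste(bad, collapse = ", ")))
  }
  if (nrow(rx)) {
    if (any(!is.na(rx$flux_bound) & rx$flux_bound <= 0))
      msg <- c(msg, "flux_bound must be > 0")
    allmets <- unique(unlist(lapply(object@stoichiometry, names)))
    bad <- setdiff(allmets, mt$id)
    if (length(bad)) msg <- c(msg, paste("unknown metabolite(s) in stoichiometry:",
                                         paste(bad, collapse = ", ")))
    for (rid in rx$id) {
      st <- object@stoichiometry[[rid]]
      if (is.null(st) || !length(st))
        msg <- c(msg, paste0("reaction ", rid, " has empty stoichiometry"))
      else if (!(any(st < 0) && any(st > 0)) && !isTRUE(rx$exchange[rx$id == rid]))
        msg <- c(msg, paste0("reaction ", rid,
                             " lacks both substrate and product and is not an exchange"))
    }
    enz <- rx$enzyme[!is.na(rx$enzyme)]
    bad <- setdiff(enz, c(nd$id, object@standaloneEnzymes))
    if (length(bad)) msg <- c(msg, paste("unresolved enzyme id(s):",
                                         paste(bad, collapse = ", ")))
  }
  badi <- setdiff(object@interface, nd$id[nd$kind == "dual-function-enzyme"])
  if (length(badi)) msg <- c(msg, "interface ids must be dual-function-enzyme nodes")
  if (length(msg)) msg else TRUE
})

#' MeasurementSet: fold-change ratios with significance flags
#'
#' Ratios are fold changes of the resistant relative to the sensitive cell
#' state; strictly positive.  Binarization to up/down/unknown states happens
#' on demand via [binarizeRatio()].
#'
#' @slot proteins data.frame with columns `id`, `ratio`, `significant`.
#' @slot metabolites data.frame with columns `id`, `ratio`, `significant`.
#' @export
setClass("MeasurementSet", representation(
  proteins = "data.frame",
  metabolites = "data.frame"
))

setValidity("MeasurementSet", function(object) {
  msg <- character()
  for (nm in c("proteins", "metabolites")) {
    df <- slot(object, nm)
    if (nrow(df)) {
      if (any(df$ratio <= 0)) msg <- c(msg, paste(nm, "ratios must be > 0"))
      if (anyDuplicated(df$id)) msg <- c(msg, paste("duplicated", nm, "ids"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' MipProblem: the mixed-integer program
#'
#' Variable registry plus linear and (optionally) bilinear constraint rows and
#' a weighted objective.  Bilinear rows each couple one binary to one
#' continuous variable; [linearize()] rewrites them exactly with big-M rows.
#'
#' @slot variables data.frame: `name`, `kind` (binary/continuous), `lb`, `ub`.
#' @slot linear list of rows, each `list(coef = named numeric, rel, rhs, name)`.
#' @slot bilinear list of rows, each adding `terms`: a data.frame with columns
#'   `binary`, `continuous`, `coef` for the product terms.
#' @slot objective named numeric of linear objective coefficients.
#' @slot weights numeric `c(w1, w2, w3)`: signaling misfit, metabolite error,
#'   topology complexity.
#' @slot bigM positive numeric used by the big-M rows.
#' @slot encoding "bilinear" or "big-M".
#' @slot varMap bookkeeping from network elements to variable names.
#' @slot options the build options the problem was encoded with.
#' @export
setClass("MipProblem", representation(
  variables = "data.frame",
  linear = "list",
  bilinear = "list",
  objective = "numeric",
  weights = "numeric",
  bigM = "numeric",
  encoding = "character",
  varMap = "list",
  options = "list"
))

setValidity("MipProblem", function(object) {
  msg <- character()
  v <- object@variables
  if (nrow(v) && anyDuplicated(v$name)) msg <- c(msg, "duplicated variable names")
  if (!object@encoding %in% c("bilinear", "big-M"))
    msg <- c(msg, "encoding must be 'bilinear' or 'big-M'")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
  refd <- unique(c(
    names(object@objective),
    unlist(lapply(object@linear, function(r) names(r$coef))),
    unlist(lapply(object@bilinear, function(r)
      c(names(r$coef), r$terms$binary, r$terms$continuous)))
  ))
  bad <- setdiff(refd, v$name)
  if (length(bad)) msg <- c(msg, paste("unregistered variable(s):",
                                       paste(head(bad, 5), collapse = ", ")))
  cont <- v$kind == "continuous"
  if (any(cont) && length(object@bigM) == 1) {
    finite_ub <- v$ub[cont][is.finite(v$ub[cont])]
    if (length(finite_ub) && object@bigM < max(finite_ub))
      msg <- c(msg, "bigM smaller than a continuous upper bound")
  }
  if (length(msg)) msg else TRUE
})

#' InferenceResult: the optimized cell-state-specific network
#'
#' @slot nodeStates named integer (0/1) per signaling node.
#' @slot edgeOccurrence named character per edge: "occurred" or "removed".
#' @slot enzymeStates named integer (0/1) per enzyme.
#' @slot reactionStatus named character: "blocked", "forward" or "backward".
#' @slot fluxes named numeric per reaction.
#' @slot metabolitePredictions named numeric predicted fold-change ratios.
#' @slot objective numeric optimal objective value.
#' @slot signalingPrecision fraction of measured nodes predicted correctly.
#' @slot metaboliteError prediction error on measured metabolites.
#' @slot metaboliteErrorMetric name of the error metric used.
#' @slot solverStatus "optimal", "feasible-time-limit" or "infeasible".
#' @slot solution the full variable assignment (for audits).
#' @export
setClass("InferenceResult", representation(
  nodeStates = "integer",
  edgeOccurrence = "character",
  enzymeStates = "integer",
  reactionStatus = "character",
  fluxes = "numeric",
  metabolitePredictions = "numeric",
  objective = "numeric",
  signalingPrecision = "numeric",
  metaboliteError = "numeric",
  metaboliteErrorMetric = "character",
  solverStatus = "character",
  solution = "numeric"
))

#' FluxModel: a constraint-based metabolic model for FBA
#'
#' @slot metabolites data.frame `id`, `boundary`.
#' @slot reactions data.frame `id`, `reversible`, `lb`, `ub`.
#' @slot stoichiometry named list of named numeric vectors.
#' @slot gpr named character of gene-protein-reaction association strings
#'   (boolean expressions over gene ids), possibly empty.
#' @export
setClass("FluxModel", representation(
  metabolites = "data.frame",
  reactions = "data.frame",
  stoichiometry = "list",
  gpr = "character"
))

setValidity("FluxModel", function(object) {
  msg <- character()
  rx <- object@reactions
  if (nrow(rx)) {
    if (any(!is.finite(rx$lb)) || any(!is.finite(rx$ub)))
      msg <- c(msg, "flux bounds must be finite")
    if (any(rx$lb > rx$ub)) msg <- c(msg, "lower bound exceeds upper bound")
  }
  bad <- setdiff(unique(unlist(lapply(object@stoichiometry, names))),
                 object@metabolites$id)
  if (length(bad)) msg <- c(msg, paste("unknown metabolite(s):",
                                       paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ContributionReport: fractional attribution of cofactor production
#'
#' @slot cofactor the target metabolite id.
#' @slot maxProduction maximal net production flux (the sink optimum).
#' @slot producers data.frame `reaction`, `flux`, `production`, `fraction`;
#'   fractions are non-negative and sum to 1 over producers.
#' @slot consumers data.frame `reaction`, `flux`, `consumption`.
#' @slot uniqueOptimum logical: FALSE when an alternate optimal vertex gives
#'   materially different fractions.
#' @export
setClass("ContributionReport", representation(
  cofactor = "character",
  maxProduction = "numeric",
  producers = "data.frame",
  consumers = "data.frame",
  uniqueOptimum = "logical"
))

setValidity("ContributionReport", function(object) {
  msg <- character()
  pr <- object@producers
  if (nrow(pr)) {
    if (any(pr$fraction < -1e-9)) msg <- c(msg, "negative fraction")
    if (object@maxProduction > 0 && abs(sum(pr$fraction) - 1) > 1e-9)
      msg <- c(msg, "fractions do not sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' PlantedTruth: ground truth of a synthetic instance
#'
#' @slot nodeStates named integer planted signaling states.
#' @slot edgeOccurrence named integer planted edge occurrence (all 1 by
#'   construction; pruning by the complexity term is expected downstream).
#' @slot enzymeStates named integer planted enzyme activation states.
#' @slot reactionActivity named integer planted reaction activity indicators.
#' @slot fluxes named numeric planted flux vector (feasible by construction).
#' @slot nodeRatios named numeric planted protein fold changes, consistent
#'   with the planted states under the default binarization.
#' @slot metaboliteRatios named numeric planted metabolite fold changes.
#' @slot params generator parameters, including the seed.
#' @export
setClass("PlantedTruth", representation(
  nodeStates = "integer",
  edgeOccurrence = "integer",
  enzymeStates = "integer",
  reactionActivity = "integer",
  fluxes = "numeric",
  nodeRatios = "numeric",
  metaboliteRatios = "numeric",
  params = "list"
))
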