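#' @describeIn IntegratedNetwork-accessors signaling node table
#' @export
setGeneric("signalingNodes", function(x) standardGeneric("signalingNodes"))

#' @describeIn IntegratedNetwork-accessors signaling edge table
#' @export
setGeneric("signalingEdges", function(x) standardGeneric("signalingEdges"))

#' @describeIn IntegratedNetwork-accessors metabolite table
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))

#' @describeIn IntegratedNetwork-accessors reaction table
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @describeIn IntegratedNetwork-accessors per-reaction stoichiometry list
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' @describeIn IntegratedNetwork-accessors dual-function enzymes bridging the
#'   signaling and metabolic layers
#' @export
setGeneric("interfaceNodes", function(x) standardGeneric("interfaceNodes"))

#' @describeIn IntegratedNetwork-accessors id of the redox hub (H2O2) node, or
#'   a zero-length character when the network has none
#' @export
setGeneric("redoxHub", function(x) standardGeneric("redoxHub"))

#' @describeIn MeasurementSet-accessors protein fold-change table
#' @export
setGeneric("proteinRatios", function(x) standardGeneric("proteinRatios"))

#' @describeIn MeasurementSet-accessors metabolite fold-change table
#' @export
setGeneric("metaboliteRatios", function(x) standardGeneric("metaboliteRatios"))

#' Accessors for IntegratedNetwork
#'
#' @param x an [IntegratedNetwork-class] object.
#' @name IntegratedNetwork-accessors
#' @aliases signalingNodes signalingEdges metabolites reactions
#'   stoichiometry interfaceNodes redoxHub
NULL

#' Accessors for MeasurementSet
#'
#' @param x a [MeasurementSet-class] object.
#' @name MeasurementSet-accessors
#' @aliases proteinRatios metaboliteRatios
NULL

setMethod("signalingNodes", "IntegratedNetwork", function(x) x@nodes)
setMethod("signalingEdges", "IntegratedNetwork", function(x) x@edges)
setMethod("metabolites", "IntegratedNetwork", function(x) x@metabolites)
setMethod("reactions", "IntegratedNetwork", function(x) x@reactions)
setMethod("stoichiometry", "IntegratedNetwork", function(x) x@stoichiometry)
setMethod("interfaceNodes", "IntegratedNetwork", function(x) x@interface)
setMethod("redoxHub", "IntegratedNetwork", function(x)
  x@nodes$id[x@nodes$kind == "redox-hub"])
setMethod("proteinRatios", "MeasurementSet", function(x) x@proteins)
setMethod("metaboliteRatios", "MeasurementSet", function(x) x@metabolites)
setMethod("metabolites", "FluxModel", function(x) x@metabolites)
setMethod("reactions", "FluxModel", function(x) x@reactions)
setMethod("stoichiometry", "FluxModel", function(x) x@stoichiometry)

setMethod("show", "IntegratedNetwork", function(object) {
  cat("IntegratedNetwork:",
      nrow(object@nodes), "signaling nodes,",
      nrow(object@edges), "edges,",
      nrow(object@metabolites), "metabolites,",
      nrow(object@reactions), "reactions\n")
  hub <- redoxHub(object)
  if (length(hub)) cat("  redox hub:", hub, "\n")
  if (length(object@interface))
    cat("  interface enzymes:", paste(object@interface, collapse = ", "), "\n")
  if (length(object@standaloneEnzymes))
    cat("  standalone enzymes:",
        paste(object@standaloneEnzymes, collapse = ", "), "\n")
})

setMethod("show", "MeasurementSet", function(object) {
  cat("MeasurementSet:", nrow(object@proteins), "protein ratios,",
      nrow(object@metabolites), "metabolite ratios\n")
})

setMethod("show", "MipProblem", function(object) {
  sz <- modelSize(object)
  cat(sprintf("MipProblem (%s encoding): %d variables, %d constraints (%d bilinear, %d linear)\n",
              object@encoding, sz["n_variables"], sz["n_constraints"],
              sz["n_bilinear"], sz["n_linear"]))
})

setMethod("show", "InferenceResult", function(object) {
  cat("InferenceResult:", object@solverStatus,
      "| objective", format(object@objective, digits = 6), "\n")
  cat("  edges removed:", sum(object@edgeOccurrence == "removed"),
      "/", length(object@edgeOccurrence), "\n")
  cat("  reactions blocked:", sum(object@reactionStatus == "blocked"),
      "/", length(object@reactionStatus), "\n")
  if (is.finite(object@signalingPrecision))
    cat("  signaling precision:",
        format(object@signalingPrecision, digits = 4), "\n")
  if (is.finite(object@metaboliteError))
    cat("  metabolite error (", object@metaboliteErrorMetric, "): ",
        format(object@metaboliteError, digits = 4), "\n", sep = "")
})

setMethod("show", "FluxModel", function(object) {
  cat("FluxModel:", nrow(object@reactions), "reactions,",
      nrow(object@metabolites), "metabolites",
      if (length(object@gpr)) paste0("(", length(object@gpr), " GPR rules)"),
      "\n")
})

setMethod("show", "ContributionReport", function(object) {
  cat("ContributionReport for", object@cofactor, "\n")
  cat("  max production:", format(object@maxProduction, digits = 6),
      if (!object@uniqueOptimum) "(non-unique optimum)", "\n")
  pr <- object@producers[order(-object@producers$fraction), ]
  for (i in seq_len(min(nrow(pr), 8)))
    cat(sprintf("  %-12s %6.1f%%\n", pr$reaction[i], 100 * pr$fraction[i]))
})

setMethod("show", "PlantedTruth", function(object) {
  cat("PlantedTruth:", length(object@nodeStates), "node states,",
      length(object@fluxes), "fluxes (seed",
      object@params$seed, ")\n")
})
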