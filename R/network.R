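#' Binarize a fold-change ratio to an up/down/unknown state
#'
#' A measurement maps to state 1 (up in the resistant state) when it is
#' significant and the ratio is at least `fold_threshold`, to 0 (down) when
#' significant and at most `1/fold_threshold`, and to `NA` (unknown; the
#' corresponding state is left free in the optimization) otherwise.
#'
#' @param ratio positive fold-change ratio(s), resistant relative to
#'   sensitive.
#' @param significant logical significance flag(s).
#' @param fold_threshold dead-band threshold, `>= 1` (default 1.5).
#' @return integer vector of 1, 0 or `NA`.
#' @examples
#' binarizeRatio(6.3, TRUE)        # 1: upregulated
#' binarizeRatio(1.0, TRUE)        # NA: inside the dead band
#' binarizeRatio(0.4, TRUE)        # 0: downregulated
#' @export
binarizeRatio <- function(ratio, significant, fold_threshold = 1.5) {
  if (length(fold_threshold) != 1 || is.na(fold_threshold) ||
      fold_threshold < 1)
    stop("fold_threshold must be a single value >= 1", call. = FALSE)
  if (any(is.na(ratio)) || any(ratio <= 0))
    stop("ratios must be strictly positive", call. = FALSE)
  out <- rep(NA_integer_, length(ratio))
  out[significant & ratio >= fold_threshold] <- 1L
  out[significant & ratio <= 1 / fold_threshold] <- 0L
  out
}

.binarized_states <- function(df, fold_threshold) {
  if (!nrow(df)) return(setNames(integer(), character()))
  setNames(binarizeRatio(df$ratio, df$significant, fold_threshold), df$id)
}

#' Assemble an integrated signaling + metabolic network
#'
#' Resolves all cross-references between the signaling edge list, the
#' reaction table and optional redox annotations, derives node kinds
#' (dual-function enzymes are signaling nodes that catalyze reactions), the
#' interface set, and auto-flags boundary metabolites.  Redox annotations are
#' materialized as ordinary non-removable signed edges from the redox-hub
#' node, so the optimization needs no special-case redox machinery.
#'
#' @param edges signaling edge data.frame ([readSignalingEdges()]).
#' @param reactions list with `reactions`, `stoichiometry`, `metabolites`
#'   ([readReactionTable()]), or `NULL` for a signaling-only network.
#' @param measurements optional [MeasurementSet-class]; ids are validated
#'   against the assembled network.
#' @param redox_annotations optional data.frame with columns `id` (target
#'   node) and `effect` (`oxidation-activates` or `oxidation-inhibits`).
#' @param hub_id id of the redox-hub node (default `"H2O2"`); the node is
#'   created if absent and annotations are present.
#' @param boundary_override optional character vector of metabolite ids to
#'   force as boundary regardless of the auto-flag rule.
#' @return an [IntegratedNetwork-class].
#' @details A metabolite is auto-flagged boundary (exempt from steady-state
#'   balance) when it appears only as substrate or only as product across all
#'   reactions; reversible reactions count for both sides.
#' @export
assembleNetwork <- function(edges = NULL, reactions = NULL,
                            measurements = NULL, redox_annotations = NULL,
                            hub_id = "H2O2", boundary_override = NULL) {
  if (is.null(edges))
    edges <- data.frame(id = character(), source = character(),
                        target = character(), sign = character(),
                        removable = logical())
  rx <- if (is.null(reactions)) {
    list(reactions = data.frame(id = character(), reversible = logical(),
                                delta_g = numeric(), enzyme = character(),
                                flux_bound = numeric(), exchange = logical()),
         stoichiometry = list(),
         metabolites = data.frame(id = character(), name = character(),
                                  boundary = logical()))
  } else reactions

  has_annot <- !is.null(redox_annotations) && nrow(redox_annotations) > 0
  if (has_annot) {
    bad <- setdiff(redox_annotations$effect,
                   c("oxidation-activates", "oxidation-inhibits"))
    if (length(bad))
      stop("unknown redox effect(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    hub_edges <- data.frame(
      id = paste0("redox", seq_len(nrow(redox_annotations))),
      source = hub_id,
      target = redox_annotations$id,
      sign = ifelse(redox_annotations$effect == "oxidation-activates",
                    "activation", "inhibition"),
      removable = FALSE)
    edges <- rbind(edges, hub_edges)
  }

  node_ids <- unique(c(edges$source, edges$target))
  enzymes <- unique(rx$reactions$enzyme[!is.na(rx$reactions$enzyme)])
  dual <- intersect(enzymes, node_ids)
  standalone <- setdiff(enzymes, node_ids)

  kind <- ifelse(node_ids == hub_id & has_annot, "redox-hub",
                 ifelse(node_ids %in% dual, "dual-function-enzyme",
                        "signaling-protein"))
  # a node named like the hub is the hub even without annotations, if present
  if (!has_annot && hub_id %in% node_ids)
    kind[node_ids == hub_id] <- "redox-hub"
  redox_effect <- rep("none", length(node_ids))
  if (has_annot) {
    idx <- match(redox_annotations$id, node_ids)
    if (anyNA(idx))
      stop("redox annotation(s) for unknown node(s): ",
           paste(redox_annotations$id[is.na(idx)], collapse = ", "),
           call. = FALSE)
    redox_effect[idx] <- redox_annotations$effect
  }
  nodes <- data.frame(id = node_ids, name = node_ids, kind = kind,
                      redox_effect = redox_effect)

  mets <- rx$metabolites
  if (nrow(mets)) {
    st <- rx$stoichiometry
    rev <- setNames(rx$reactions$reversible, rx$reactions$id)
    as_sub <- as_prod <- setNames(rep(FALSE, nrow(mets)), mets$id)
    for (rid in names(st)) {
      s <- st[[rid]]
      subs <- names(s)[s < 0]; prods <- names(s)[s > 0]
      if (rev[rid]) { subs <- names(s); prods <- names(s) }
      as_sub[subs] <- TRUE; as_prod[prods] <- TRUE
    }
    auto_boundary <- !(as_sub & as_prod)
    mets$boundary <- ifelse(mets$id %in% boundary_override, TRUE,
                            auto_boundary[mets$id])
  }

  # interface: dual-function enzymes that also receive signaling edges
  interface <- dual[dual %in% edges$target]

  net <- new("IntegratedNetwork", nodes = nodes, edges = edges,
             metabolites = mets, reactions = rx$reactions,
             stoichiometry = rx$stoichiometry,
             standaloneEnzymes = standalone, interface = interface)

  if (!is.null(measurements)) {
    unknown <- c(setdiff(proteinRatios(measurements)$id,
                         c(nodes$id, standalone)),
                 setdiff(metaboliteRatios(measurements)$id, mets$id))
    if (length(unknown))
      stop("measurement id(s) not in the network: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  net
}

#' Stoichiometric matrix of the metabolic subnetwork
#'
#' Entry (m, r) is the signed stoichiometric coefficient of metabolite m in
#' reaction r.  Row and column orders are deterministic (sorted by id).
#'
#' @param network an [IntegratedNetwork-class] or [FluxModel-class].
#' @param boundary `"exclude"` (default; rows are the steady-state balanced,
#'   non-boundary metabolites) or `"include"` (all metabolites).
#' @return a sparse [Matrix::sparseMatrix()] with dimnames.
#' @export
stoichiometricMatrix <- function(network, boundary = c("exclude", "include")) {
  boundary <- match.arg(boundary)
  mets <- metabolites(network)
  keep <- if (boundary == "exclude") mets$id[!mets$boundary] else mets$id
  keep <- sort(keep)
  rids <- sort(reactions(network)$id)
  st <- stoichiometry(network)
  i <- integer(); j <- integer(); x <- numeric()
  for (k in seq_along(rids)) {
    s <- st[[rids[k]]]
    s <- s[names(s) %in% keep]
    if (length(s)) {
      i <- c(i, match(names(s), keep))
      j <- c(j, rep(k, length(s)))
      x <- c(x, unname(s))
    }
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(keep), length(rids)),
                       dimnames = list(keep, rids))
}
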