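.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Feasible metabolite interval implied by planted enzyme states and
## reaction activities; mirrors the coupling semantics.
.planted_intervals <- function(network, b, q, c_lo, c_hi) {
  mets <- network@metabolites$id
  lo <- setNames(rep(c_lo, length(mets)), mets)
  hi <- setNames(rep(c_hi, length(mets)), mets)
  rx <- network@reactions
  for (i in seq_len(nrow(rx))) {
    z <- rx$enzyme[i]
    if (is.na(z) || b[[z]] == 1L) next
    st <- network@stoichiometry[[rx$id[i]]]
    hi[names(st)[st > 0]] <- pmin(hi[names(st)[st > 0]], 1)
    lo[names(st)[st < 0]] <- pmax(lo[names(st)[st < 0]], 1)
  }
  prod_map <- .producers(network)
  for (m in mets[!network@metabolites$boundary]) {
    prs <- prod_map[[m]]
    if (!is.null(prs) && all(prs %in% names(q)) && all(q[prs] == 0L))
      hi[m] <- min(hi[m], 1)
  }
  list(lo = lo, hi = hi)
}

#' Generate a random integrated network with planted ground truth
#'
#' The signaling layer is acyclic by construction (a topological order is
#' sampled first and edges only run forward); a redox-hub node is wired to a
#' random subset of nodes through non-removable signed edges.  The metabolic
#' layer is a connected chain (plus optional shortcut reactions and
#' side-metabolites) whose endpoints and side-metabolites auto-flag as
#' boundary.  A subset of nodes act as dual-function enzymes catalyzing
#' reactions.  The planted assignment — node states by forward evaluation of
#' the logic gate, a feasible flux vector along the chain, and metabolite
#' ratios drawn inside their feasibility intervals — satisfies every
#' constraint of the formulation by construction.
#'
#' @param n_signaling,n_edges,n_metabolites,n_reactions sizes (all >= 1;
#'   `n_edges` at most `n_signaling * (n_signaling - 1) / 2`).
#' @param p_inhibition probability that a signaling edge is inhibitory.
#' @param seed integer seed; a single stream in stated order drives all
#'   draws, so regeneration is bit-for-bit reproducible.
#' @param n_enzymes number of dual-function enzymes (default ~18% of nodes,
#'   mirroring 10 enzymes among 54 proteins).
#' @param p_enzyme probability that a reaction is enzyme-catalyzed.
#' @param p_reversible probability that a reaction is reversible (reversible
#'   reactions carry no Gibbs energy, leaving their direction free).
#' @param n_redox number of redox-hub targets (default min(3, n_signaling)).
#' @param flux_bound reaction capacity U.
#' @param fold_threshold dead band used when drawing state-consistent ratios.
#' @return list with `network` ([IntegratedNetwork-class]) and `truth`
#'   ([PlantedTruth-class]).
#' @export
generateNetwork <- function(n_signaling, n_edges, n_metabolites, n_reactions,
                            p_inhibition = 0.25, seed = 1L,
                            n_enzymes = max(1L, round(0.18 * n_signaling)),
                            p_enzyme = 0.7, p_reversible = 0.3,
                            n_redox = min(3L, n_signaling),
                            flux_bound = 1000, fold_threshold = 1.5) {
  stopifnot(n_signaling >= 1, n_metabolites >= 2, n_reactions >= 1,
            n_edges >= 0, p_inhibition >= 0, p_inhibition <= 1)
  max_edges <- n_signaling * (n_signaling - 1) / 2
  if (n_edges > max_edges)
    stop("n_edges (", n_edges, ") exceeds the acyclic simple-graph maximum (",
         max_edges, ")", call. = FALSE)
  .with_seed(seed, {
    sn <- sprintf("s%02d", seq_len(n_signaling))
    ## edges among forward pairs of the sampled topological order
    edges <- data.frame(id = character(), source = character(),
                        target = character(), sign = character(),
                        removable = logical())
    if (n_edges > 0) {
      pairs <- which(upper.tri(matrix(TRUE, n_signaling, n_signaling)),
                     arr.ind = TRUE)
      pick <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
      edges <- data.frame(
        id = paste0("e", seq_len(n_edges)),
        source = sn[pick[, 1]], target = sn[pick[, 2]],
        sign = ifelse(runif(n_edges) < p_inhibition, "inhibition",
                      "activation"),
        removable = TRUE)
    }
    annot <- data.frame(
      id = sample(sn, n_redox),
      effect = ifelse(runif(n_redox) < 0.5, "oxidation-inhibits",
                      "oxidation-activates"))

    ## metabolic chain + shortcuts + side metabolites
    mn <- sprintf("m%03d", seq_len(n_metabolites))
    L <- min(n_reactions, n_metabolites - 1)
    stoich <- list(); rows <- list()
    enzyme_pool <- sample(sn, min(n_enzymes, n_signaling))
    for (i in seq_len(n_reactions)) {
      rid <- sprintf("R%02d", i)
      if (i <= L) {
        st <- setNames(c(-1, 1), c(mn[i], mn[i + 1]))
      } else {
        jk <- sort(sample.int(L + 1, 2))
        st <- setNames(c(-1, 1), c(mn[jk[1]], mn[jk[2]]))
      }
      rev <- runif(1) < p_reversible
      dg <- if (rev) NA_real_ else runif(1, -40, -5)
      z <- if (runif(1) < p_enzyme) sample(enzyme_pool, 1) else NA_character_
      stoich[[rid]] <- st
      rows[[i]] <- data.frame(id = rid, reversible = rev, delta_g = dg,
                              enzyme = z, flux_bound = flux_bound,
                              exchange = FALSE)
    }
    extra <- if (n_metabolites > L + 1) mn[(L + 2):n_metabolites]
             else character()
    for (m in extra) {
      rid <- sprintf("R%02d", sample.int(n_reactions, 1))
      side <- if (runif(1) < 0.5) 1 else -1
      stoich[[rid]][m] <- side
    }
    rx <- do.call(rbind, rows)

    ## chain endpoints and side metabolites exchange with the environment,
    ## so the planted chain flux satisfies every internal balance
    network <- assembleNetwork(
      edges = edges,
      reactions = list(reactions = rx, stoichiometry = stoich,
                       metabolites = data.frame(id = mn, name = mn,
                                                boundary = NA)),
      redox_annotations = annot, hub_id = "H2O2",
      boundary_override = c(mn[1], mn[L + 1], extra))

    ## planted states by forward evaluation in topological order; nodes
    ## touching no edge, annotation or reaction are not part of the
    ## assembled network and carry no planted state
    present <- c(network@nodes$id, network@standaloneEnzymes)
    ids <- intersect(c("H2O2", sn), present)
    x <- setNames(integer(length(ids)), ids)
    all_edges <- network@edges
    for (v in ids) {
      ein <- all_edges[all_edges$target == v, , drop = FALSE]
      if (!nrow(ein)) {
        x[v] <- if (v == "H2O2") 1L else rbinom(1, 1, 0.5)
        next
      }
      live <- x[ein$source] == 1L
      if (any(live & ein$sign == "inhibition")) x[v] <- 0L
      else if (any(live & ein$sign == "activation")) x[v] <- 1L
      else if (any(ein$sign == "activation")) x[v] <- 0L
      else x[v] <- 1L  # basal activity for inhibitor-only targets
    }
    enz <- unique(rx$enzyme[!is.na(rx$enzyme)])
    b <- setNames(x[enz], enz)

    ## feasible fluxes: the chain runs iff no chain reaction is gated off
    chain <- rx$id[seq_len(L)]
    chain_on <- all(vapply(chain, function(rid) {
      z <- rx$enzyme[rx$id == rid]
      is.na(z) || b[[z]] == 1L
    }, TRUE))
    f <- if (chain_on) 0.01 * flux_bound else 0
    fluxes <- setNames(rep(0, n_reactions), rx$id)
    fluxes[chain] <- f
    q_ids <- rx$id[!is.na(rx$enzyme)]
    q <- setNames(as.integer(q_ids %in% chain & f > 0), q_ids)

    ## metabolite ratios drawn inside the implied feasibility interval
    iv <- .planted_intervals(network, b, q, 0.01, 100)
    lo <- pmax(iv$lo, 1 / 8); hi <- pmin(iv$hi, 8)
    ratios <- setNames(numeric(n_metabolites), mn)
    for (m in mn) {
      if (lo[m] >= hi[m]) ratios[m] <- 1
      else ratios[m] <- 2^runif(1, log2(lo[m]), log2(hi[m]))
    }

    ## protein ratios consistent with the planted states
    prot_ids <- setdiff(ids, "H2O2")  # the hub is chemistry, not a protein
    lfc <- runif(length(prot_ids), log2(fold_threshold) + 0.6, 3)
    node_ratios <- setNames(ifelse(x[prot_ids] == 1L, 2^lfc, 2^-lfc),
                            prot_ids)

    truth <- new("PlantedTruth",
                 nodeStates = x,
                 edgeOccurrence = setNames(rep(1L, nrow(all_edges)),
                                           all_edges$id),
                 enzymeStates = b, reactionActivity = q, fluxes = fluxes,
                 nodeRatios = node_ratios, metaboliteRatios = ratios,
                 params = list(seed = seed, n_signaling = n_signaling,
                               n_edges = n_edges,
                               n_metabolites = n_metabolites,
                               n_reactions = n_reactions,
                               p_inhibition = p_inhibition,
                               chain = chain, chain_flux = f,
                               directions = setNames(rep(1L, n_reactions),
                                                     rx$id),
                               fold_threshold = fold_threshold))
    list(network = network, truth = truth)
  })
}

#' Generate noisy, partially observed measurements from a planted truth
#'
#' Each measured ratio is the true ratio times `2^eps` with `eps ~ N(0,
#' noise_sd)`; a fixed fraction of ids is dropped uniformly at random
#' (exactly `round(missing_fraction * n)` per layer), and the significance
#' flag is set when the measured log2 ratio exceeds the binarization dead
#' band.
#'
#' @param truth a [PlantedTruth-class].
#' @param noise_sd log2-scale standard deviation of the measurement noise.
#' @param missing_fraction fraction of ids dropped per layer, in `[0, 1)`.
#'   A length-2 vector applies separate fractions to proteins and
#'   metabolites (emulating, e.g., 22/54 proteins and 38/107 metabolites
#'   measured).
#' @param seed integer seed.
#' @param fold_threshold dead band used for the significance flag.
#' @return a [MeasurementSet-class].
#' @export
generateMeasurements <- function(truth, noise_sd = 0, missing_fraction = 0,
                                 seed = 1L, fold_threshold = 1.5) {
  if (any(missing_fraction < 0) || any(missing_fraction >= 1))
    stop("missing_fraction must be in [0, 1)", call. = FALSE)
  mf <- rep(missing_fraction, length.out = 2)
  .with_seed(seed, {
    layer <- function(ratios, frac) {
      ids <- names(ratios)
      n_drop <- round(frac * length(ids))
      if (n_drop > 0) ids <- setdiff(ids, sample(names(ratios), n_drop))
      if (!length(ids))
        return(data.frame(id = character(), ratio = numeric(),
                          significant = logical()))
      measured <- ratios[ids] * 2^rnorm(length(ids), 0, noise_sd)
      data.frame(id = ids, ratio = unname(measured),
                 significant = abs(log2(measured)) >=
                   log2(fold_threshold) - 1e-12)
    }
    new("MeasurementSet",
        proteins = layer(truth@nodeRatios, mf[1]),
        metabolites = layer(truth@metaboliteRatios, mf[2]))
  })
}

#' Ready-made synthetic study conditions
#'
#' `"paper-scale"` emulates the dimensions of the generic redox map: 54
#' signaling proteins (22 measured), 87 regulatory edges, 10 dual-function
#' enzymes, 74 reactions and 107 metabolites (38 measured).  `"tiny"` is a
#' 6-node instance small enough for the brute-force oracle.
#'
#' @param preset `"paper-scale"` or `"tiny"`.
#' @param seed integer seed.
#' @param noise_sd,... passed to [generateMeasurements()].
#' @return list with `network`, `truth`, `measurements`.
#' @export
syntheticPreset <- function(preset = c("paper-scale", "tiny"), seed = 1L,
                            noise_sd = 0, ...) {
  preset <- match.arg(preset)
  gen <- switch(preset,
    "paper-scale" = generateNetwork(54, 87, 107, 74, p_inhibition = 0.25,
                                    seed = seed, n_enzymes = 10),
    "tiny" = generateNetwork(6, 5, 5, 3, p_inhibition = 0.25, seed = seed,
                             n_enzymes = 2, n_redox = 1))
  mf <- switch(preset,
    "paper-scale" = c(1 - 22 / 54, 1 - 38 / 107),
    "tiny" = c(0, 0))
  meas <- generateMeasurements(gen$truth, noise_sd = noise_sd,
                               missing_fraction = mf, seed = seed + 1L, ...)
  list(network = gen$network, truth = gen$truth, measurements = meas)
}
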