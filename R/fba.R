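#' Load a constraint-based flux model
#'
#' Reads either an SBML Level 3 (FBC) file (`.xml`/`.sbml`) or the native
#' five-column reaction TSV (see [readReactionTable()]; bounds derive from
#' the capacity column: `[-U, U]` for reversible reactions, `[0, U]`
#' otherwise, with a default capacity of 1000).
#'
#' @param path model file.
#' @param default_bound capacity used when none is given.
#' @return a [FluxModel-class].
#' @export
loadFluxModel <- function(path, default_bound = 1000) {
  if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
    return(readSBML(path, default_bound = default_bound))
  tbl <- readReactionTable(path)
  rx <- tbl$reactions
  ub <- ifelse(is.na(rx$flux_bound), default_bound, rx$flux_bound)
  mets <- tbl$metabolites
  ## exchange with the environment via one-sided reactions; a metabolite
  ## seen only as substrate or only as product is additionally boundary
  seen_sub <- seen_prod <- setNames(rep(FALSE, nrow(mets)), mets$id)
  for (rid in names(tbl$stoichiometry)) {
    s <- tbl$stoichiometry[[rid]]
    rev <- rx$reversible[rx$id == rid]
    subs <- if (rev) names(s) else names(s)[s < 0]
    prods <- if (rev) names(s) else names(s)[s > 0]
    seen_sub[subs] <- TRUE; seen_prod[prods] <- TRUE
  }
  mets$boundary <- !(seen_sub & seen_prod)
  new("FluxModel",
      metabolites = mets[, c("id", "boundary")],
      reactions = data.frame(id = rx$id, reversible = rx$reversible,
                             lb = ifelse(rx$reversible, -ub, 0), ub = ub),
      stoichiometry = tbl$stoichiometry,
      gpr = setNames(character(), character()))
}

#' Scale flux capacities by expression ratios
#'
#' Each matched reaction's upper flux bound is multiplied by its expression
#' ratio (the default Vmax-limit rule: relative transcript changes populate
#' relative capacity limits).  Ratios may be keyed by reaction id or by gene
#' id; gene keys are resolved through the model's gene-protein-reaction
#' associations, taking the maximum ratio across isozymes (OR) and the
#' minimum across complex subunits (AND).
#'
#' @param model a [FluxModel-class].
#' @param ratios named positive numeric vector of expression ratios.
#' @param rule only `"multiply"` is currently defined; the argument keeps the
#'   rule pluggable.
#' @return the model with updated bounds; the attribute `"bounds_log"`
#'   records every change (reaction, old and new bound, the ratio applied).
#' @export
applyExpressionBounds <- function(model, ratios, rule = "multiply") {
  rule <- match.arg(rule, "multiply")
  if (any(ratios <= 0)) stop("expression ratios must be positive",
                             call. = FALSE)
  rx <- model@reactions
  gpr_genes <- lapply(model@gpr, .gpr_genes)
  matched <- logical(length(ratios)); names(matched) <- names(ratios)
  log <- list()
  for (i in seq_len(nrow(rx))) {
    rid <- rx$id[i]
    factor <- NA_real_
    if (rid %in% names(ratios)) {
      factor <- ratios[[rid]]
      matched[rid] <- TRUE
    } else if (rid %in% names(model@gpr)) {
      genes <- intersect(gpr_genes[[rid]], names(ratios))
      if (length(genes)) {
        factor <- .gpr_eval(model@gpr[[rid]], ratios)
        matched[genes] <- TRUE
      }
    }
    if (!is.na(factor)) {
      old <- rx$ub[i]
      rx$ub[i] <- old * factor
      log[[length(log) + 1L]] <- data.frame(reaction = rid, old = old,
                                            new = rx$ub[i], ratio = factor)
    }
  }
  if (any(!matched))
    warning("expression ratio(s) for unknown id(s): ",
            paste(names(matched)[!matched], collapse = ", "), call. = FALSE)
  model@reactions <- rx
  attr(model, "bounds_log") <- if (length(log)) do.call(rbind, log)
                               else data.frame()
  model
}

#' Maximize net production of a target cofactor
#'
#' Adds an internal sink reaction consuming one unit of the cofactor and
#' solves the linear program maximizing the sink flux subject to
#' steady-state mass balance on all internal metabolites (the cofactor is
#' always balanced, since the sink carries its accumulation) and the flux
#' bounds.
#'
#' @param model a [FluxModel-class].
#' @param cofactor metabolite id (e.g. `"NADPH"`).
#' @return list with `max_production`, `fluxes` (named, without the sink)
#'   and `status`.
#' @export
maximizeCofactor <- function(model, cofactor) {
  rx <- model@reactions
  st <- model@stoichiometry
  touches <- vapply(st, function(s) cofactor %in% names(s), TRUE)
  if (!any(touches))
    stop("cofactor '", cofactor, "' appears in no reaction", call. = FALSE)
  mets <- model@metabolites
  balanced <- union(mets$id[!mets$boundary], cofactor)
  n <- nrow(rx)
  rows <- list()
  for (m in balanced) {
    j <- integer(); v <- numeric()
    for (k in seq_len(n)) {
      s <- st[[rx$id[k]]]
      if (m %in% names(s)) { j <- c(j, k); v <- c(v, s[[m]]) }
    }
    if (m == cofactor) { j <- c(j, n + 1L); v <- c(v, -1) }
    if (length(j))
      rows[[length(rows) + 1L]] <- list(j = j, v = v, rel = "=", rhs = 0)
  }
  obj <- c(rep(0, n), 1)
  lb <- c(rx$lb, 0); ub <- c(rx$ub, Inf)
  sol <- .solve_lp(obj, lb, ub, rows, maximize = TRUE)
  if (sol$status == "infeasible")
    stop("flux model is infeasible", call. = FALSE)
  if (sol$status == "unbounded") {
    cap <- 1e6
    probe <- .solve_lp(obj, pmax(lb, -cap), pmin(ub, cap), rows,
                       maximize = TRUE)
    runaway <- if (!is.null(probe$x))
      rx$id[abs(probe$x[seq_len(n)]) > 0.99 * cap] else character()
    stop("cofactor production is unbounded",
         if (length(runaway)) paste0(" (unconstrained cycle through: ",
                                     paste(runaway, collapse = ", "), ")"),
         call. = FALSE)
  }
  fluxes <- setNames(sol$x[seq_len(n)], rx$id)
  list(max_production = sol$x[n + 1L], fluxes = fluxes, status = sol$status,
       cofactor = cofactor)
}

.cofactor_flows <- function(model, fluxes, cofactor) {
  rx <- model@reactions
  flow <- vapply(rx$id, function(rid) {
    s <- model@stoichiometry[[rid]]
    if (cofactor %in% names(s)) s[[cofactor]] * fluxes[[rid]] else 0
  }, numeric(1))
  flow
}

#' Attribute fractional shares of cofactor production to reactions
#'
#' At the production optimum, each producing reaction's share is its
#' cofactor production flux divided by the gross production over all
#' producers, so fractions are non-negative and sum to 1.  Consumers are
#' reported separately.  Because LP vertices need not be unique, the report
#' carries a uniqueness flag computed by re-solving with a tiny seeded
#' random objective perturbation at the fixed optimum and comparing
#' fractions at 1e-4.
#'
#' @param model the [FluxModel-class] that was solved.
#' @param fba result of [maximizeCofactor()].
#' @param seed seed for the perturbation solve.
#' @return a [ContributionReport-class].
#' @export
contributionFractions <- function(model, fba, seed = 1L) {
  if (fba$max_production <= 0)
    stop("max production is 0; fractions are undefined", call. = FALSE)
  flow <- .cofactor_flows(model, fba$fluxes, fba$cofactor)
  tol <- 1e-9 * max(1, fba$max_production)
  frac_of <- function(flow) {
    prod <- flow[flow > tol]
    prod / sum(prod)
  }
  prod <- flow[flow > tol]
  cons <- flow[flow < -tol]
  producers <- data.frame(reaction = names(prod),
                          flux = unname(fba$fluxes[names(prod)]),
                          production = unname(prod),
                          fraction = unname(prod / sum(prod)))
  consumers <- data.frame(reaction = names(cons),
                          flux = unname(fba$fluxes[names(cons)]),
                          consumption = unname(-cons))

  ## alternate-vertex probe at the same optimum
  unique_opt <- TRUE
  alt <- .perturbed_resolve(model, fba, seed)
  if (!is.null(alt)) {
    flow2 <- .cofactor_flows(model, alt, fba$cofactor)
    f1 <- frac_of(flow); f2 <- frac_of(flow2)
    ids <- union(names(f1), names(f2))
    g <- function(f) ifelse(ids %in% names(f), f[ids], 0)
    unique_opt <- max(abs(g(f1) - g(f2)), 0) < 1e-4
  }
  new("ContributionReport", cofactor = fba$cofactor,
      maxProduction = fba$max_production, producers = producers,
      consumers = consumers, uniqueOptimum = unique_opt)
}

.perturbed_resolve <- function(model, fba, seed) {
  rx <- model@reactions
  st <- model@stoichiometry
  mets <- model@metabolites
  balanced <- union(mets$id[!mets$boundary], fba$cofactor)
  n <- nrow(rx)
  rows <- list()
  for (m in balanced) {
    j <- integer(); v <- numeric()
    for (k in seq_len(n)) {
      s <- st[[rx$id[k]]]
      if (m %in% names(s)) { j <- c(j, k); v <- c(v, s[[m]]) }
    }
    if (m == fba$cofactor) { j <- c(j, n + 1L); v <- c(v, -1) }
    if (length(j))
      rows[[length(rows) + 1L]] <- list(j = j, v = v, rel = "=", rhs = 0)
  }
  ## hold the sink at the proven optimum, perturb preferences among fluxes
  rows[[length(rows) + 1L]] <- list(j = n + 1L, v = 1, rel = "=",
                                    rhs = fba$max_production)
  obj <- .with_seed(seed, c(runif(n, -1e-6, 1e-6), 0))
  sol <- .solve_lp(obj, c(rx$lb, 0), c(rx$ub, Inf), rows, maximize = TRUE)
  if (is.null(sol$x)) return(NULL)
  setNames(sol$x[seq_len(n)], rx$id)
}
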