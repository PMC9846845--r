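## Exhaustive verification oracle for the optimization core.  Deliberately
## independent of the MIP encoding and of the HiGHS backend: signaling logic
## is checked against the gate truth table directly, metabolite errors come
## from closed-form interval projection, and flux feasibility is decided by
## quadprog (min ||v||^2 over the flux polytope), so agreement with solveMip
## is a genuine cross-check of two implementations.

.oracle_flux_feasible <- function(S, lb, ub) {
  if (any(lb > ub + 1e-12)) return(FALSE)
  n <- length(lb)
  if (!n) return(TRUE)
  if (all(lb <= 0 & ub >= 0)) return(TRUE)  # v = 0 is feasible
  Amat <- cbind(t(S), diag(n), -diag(n))
  bvec <- c(rep(0, nrow(S)), lb, -ub)
  ok <- tryCatch({
    quadprog::solve.QP(Dmat = diag(n), dvec = rep(0, n), Amat = Amat,
                       bvec = bvec, meq = nrow(S))
    TRUE
  }, error = function(e) FALSE)
  ok
}

#' Exhaustive brute-force oracle for the inference problem
#'
#' Enumerates every assignment of the free binary variables (node states,
#' removable-edge occurrences, free enzyme states, flux directions and
#' reaction activities), checks signaling-gate consistency against the truth
#' table, decides flux feasibility with an independent quadratic-programming
#' solver, computes the metabolite L1 error in closed form per metabolite,
#' and returns the global minimum objective together with every attaining
#' assignment.
#'
#' @param network an [IntegratedNetwork-class].
#' @param measurements a [MeasurementSet-class].
#' @param weights `c(w1, w2, w3)` as in [buildProblem()].
#' @param options see [mipOptions()].
#' @param max_binaries refuse to enumerate beyond this many free binaries
#'   (default 20).
#' @return list with `objective`, `assignments` (list of named 0/1 vectors
#'   over the free binaries), `n_free`, `n_enumerated`, `n_feasible`.
#' @export
bruteForceOracle <- function(network, measurements = new("MeasurementSet"),
                             weights = c(1, 1, 0.01), options = mipOptions(),
                             max_binaries = 20) {
  options <- modifyList(mipOptions(), options)
  w1 <- weights[1]; w2 <- weights[2]; w3 <- weights[3]
  nodes <- network@nodes; edges <- network@edges; rx <- network@reactions
  ft <- options$fold_threshold
  node_state <- .binarized_states(proteinRatios(measurements), ft)
  mm <- metaboliteRatios(measurements)
  met_ratio <- if (nrow(mm)) setNames(mm$ratio, mm$id) else numeric()
  c_lo <- min(options$c_lo, met_ratio, 1)
  c_hi <- max(options$c_hi, met_ratio, 1)

  enz <- unique(rx$enzyme[!is.na(rx$enzyme)])
  standalone <- setdiff(enz, nodes$id)
  enz_fixed <- setNames(rep(NA_integer_, length(standalone)), standalone)
  for (z in standalone)
    if (z %in% names(node_state)) enz_fixed[z] <- node_state[[z]]

  thermo <- lapply(seq_len(nrow(rx)), function(i) encodeThermo(rx[i, ],
                                                               options$tau))
  names(thermo) <- rx$id
  needs_d <- rx$id[vapply(thermo, `[[`, TRUE, "needs_direction")]
  enzymatic <- rx$id[!is.na(rx$enzyme)]
  q_ids <- if (options$propagate) enzymatic else character()

  tag <- function(prefix, ids) {
    if (!length(ids)) return(character())
    paste0(prefix, ids)
  }
  free <- c(tag("x:", nodes$id),
            tag("y:", edges$id[edges$removable]),
            tag("b:", standalone[is.na(enz_fixed[standalone])]),
            tag("d:", needs_d),
            tag("q:", q_ids))
  nfree <- length(free)
  if (nfree > max_binaries)
    stop("instance has ", nfree, " free binary variables, above the ",
         "enumeration cap of ", max_binaries, call. = FALSE)

  S <- stoichiometricMatrix(network, "exclude")
  S <- as.matrix(S)
  prod_map <- .producers(network)
  non_boundary <- network@metabolites$id[!network@metabolites$boundary]
  mism_ids <- intersect(names(node_state)[!is.na(node_state)], nodes$id)

  incoming <- split(seq_len(nrow(edges)), edges$target)
  enzyme_of <- setNames(rx$enzyme, rx$id)

  best <- Inf; best_assign <- list(); n_feas <- 0L
  flux_cache <- new.env(parent = emptyenv())
  n_assign <- 2^nfree

  for (code in seq_len(max(n_assign, 1)) - 1L) {
    bits <- if (nfree) as.integer(intToBits(code))[seq_len(nfree)] else integer()
    val <- setNames(bits, free)
    x <- setNames(rep(0L, nrow(nodes)), nodes$id)
    for (id in nodes$id) x[id] <- val[[paste0("x:", id)]]
    y <- setNames(rep(1L, nrow(edges)), edges$id)
    for (id in edges$id[edges$removable]) y[id] <- val[[paste0("y:", id)]]
    b <- setNames(integer(length(enz)), enz)
    for (z in enz) {
      b[z] <- if (z %in% nodes$id) x[[z]]
              else if (!is.na(enz_fixed[[z]])) enz_fixed[[z]]
              else val[[paste0("b:", z)]]
    }
    dvals <- setNames(rep(1L, length(needs_d)), needs_d)
    for (id in needs_d) dvals[id] <- val[[paste0("d:", id)]]
    q <- setNames(integer(length(q_ids)), q_ids)
    for (id in q_ids) q[id] <- val[[paste0("q:", id)]]

    ## gate truth table
    feasible <- TRUE
    for (v in names(incoming)) {
      ein <- edges[incoming[[v]], , drop = FALSE]
      live <- y[ein$id] == 1L & x[ein$source] == 1L
      fired_act <- any(live & ein$sign == "activation")
      fired_inh <- any(live & ein$sign == "inhibition")
      expected <- if (fired_inh) 0L
                  else if (fired_act) 1L
                  else if (any(ein$sign == "activation")) 0L
                  else NA_integer_
      if (!is.na(expected) && x[[v]] != expected) { feasible <- FALSE; break }
    }
    if (!feasible) next
    ## activity requires the enzyme on
    if (length(q_ids) && any(q == 1L & b[enzyme_of[q_ids]] == 0L)) next

    ## flux polytope feasibility (depends only on b, d, q)
    if (nrow(rx)) {
      key <- paste0("k", paste(c(b, dvals, q), collapse = ""))
      feas <- flux_cache[[key]]
      if (is.null(feas)) {
        lb <- ub <- numeric(nrow(rx))
        for (i in seq_len(nrow(rx))) {
          rid <- rx$id[i]
          lo <- thermo[[rid]]$lb; hi <- thermo[[rid]]$ub
          U <- rx$flux_bound[i]; eps <- options$eps_activity * U
          if (rid %in% needs_d) {
            if (dvals[[rid]] == 1L) lo <- max(lo, 0) else hi <- min(hi, 0)
          }
          if (!is.na(rx$enzyme[i])) {
            if (b[[rx$enzyme[i]]] == 0L) { lo <- 0; hi <- 0 }
            if (rid %in% q_ids) {
              if (q[[rid]] == 0L) { lo <- max(lo, 0); hi <- min(hi, 0) }
              else if (lo >= 0) lo <- max(lo, eps)
              else hi <- min(hi, -eps)
            }
          }
          lb[i] <- lo; ub[i] <- hi
        }
        Sm <- S[, rx$id, drop = FALSE]
        feas <- .oracle_flux_feasible(Sm, lb, ub)
        flux_cache[[key]] <- feas
      }
      if (!feas) next
    }
    n_feas <- n_feas + 1L

    ## closed-form metabolite error
    err <- 0
    if (length(met_ratio)) {
      lo_m <- setNames(rep(c_lo, length(met_ratio)), names(met_ratio))
      hi_m <- setNames(rep(c_hi, length(met_ratio)), names(met_ratio))
      for (i in seq_len(nrow(rx))) {
        z <- rx$enzyme[i]
        if (is.na(z) || b[[z]] == 1L) next
        st <- network@stoichiometry[[rx$id[i]]]
        for (p in intersect(names(st)[st > 0], names(met_ratio)))
          hi_m[p] <- min(hi_m[p], 1)
        for (s in intersect(names(st)[st < 0], names(met_ratio)))
          lo_m[s] <- max(lo_m[s], 1)
      }
      if (options$propagate) {
        for (m in intersect(non_boundary, names(met_ratio))) {
          prs <- prod_map[[m]]
          if (!is.null(prs) && all(prs %in% q_ids) && all(q[prs] == 0L))
            hi_m[m] <- min(hi_m[m], 1)
        }
      }
      err <- sum(pmax(0, met_ratio - hi_m) + pmax(0, lo_m - met_ratio))
    }

    mism <- if (length(mism_ids)) sum(x[mism_ids] != node_state[mism_ids])
            else 0
    obj <- w1 * mism + w2 * err + w3 * sum(y)
    if (obj < best - 1e-9) {
      best <- obj; best_assign <- list(val)
    } else if (obj <= best + 1e-9) {
      best_assign[[length(best_assign) + 1L]] <- val
    }
  }

  list(objective = if (is.finite(best)) best else NA_real_,
       assignments = best_assign, n_free = nfree,
       n_enumerated = n_assign, n_feasible = n_feas)
}
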