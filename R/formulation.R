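## Variable naming scheme (ids are whitespace-free tokens):
##   x_<node>   binary signaling state      y_<edge>  binary edge occurrence
##   a_<edge>   binary "live" indicator     b_<enz>   binary enzyme activation
##   d_<rxn>    binary forward direction    q_<rxn>   binary reaction activity
##   v_<rxn>    continuous net flux         c_<met>   continuous ratio
##   mN_<node>, mM_<met>  non-negative L1 misfit slacks

.vn <- function(prefix, id) {
  if (!length(id)) return(character())
  paste0(prefix, "_", id)
}

#' Default options for the MIP encoding
#'
#' @param fold_threshold dead band for binarization (>= 1).
#' @param tau Gibbs-energy tolerance (kJ/mol) below which a reaction's
#'   direction is treated as unconstrained by thermodynamics.
#' @param c_lo,c_hi box bounds on predicted metabolite fold-change ratios.
#' @param big_m big-M constant; `NULL` sizes it automatically to twice the
#'   largest continuous upper bound.
#' @param encoding `"big-M"` (default) or `"bilinear"`.
#' @param propagate add blockade-propagation constraints so that a metabolite
#'   none of whose producing reactions is active is predicted down (ratio
#'   <= 1), as inactive upstream enzymes block everything downstream.
#' @param eps_activity minimum |flux|, as a fraction of the capacity, for a
#'   reaction to count as active in the propagation constraints.
#' @return named list of options.
#' @export
mipOptions <- function(fold_threshold = 1.5, tau = 0, c_lo = 0.01,
                       c_hi = 100, big_m = NULL, encoding = c("big-M",
                       "bilinear"), propagate = TRUE, eps_activity = 1e-3) {
  list(fold_threshold = fold_threshold, tau = tau, c_lo = c_lo, c_hi = c_hi,
       big_m = big_m, encoding = match.arg(encoding), propagate = propagate,
       eps_activity = eps_activity)
}

.new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$vars <- list(); env$linear <- list(); env$bilinear <- list()
  env$obj <- numeric()
  env
}

.add_var <- function(bld, name, kind, lb, ub) {
  bld$vars[[name]] <- list(name = name, kind = kind, lb = lb, ub = ub)
  name
}

.add_row <- function(bld, coef, rel, rhs, name = "") {
  bld$linear[[length(bld$linear) + 1L]] <-
    list(coef = coef, rel = rel, rhs = rhs, name = name)
}

.add_bilinear <- function(bld, coef, terms, rel, rhs, name = "") {
  bld$bilinear[[length(bld$bilinear) + 1L]] <-
    list(coef = coef, terms = terms, rel = rel, rhs = rhs, name = name)
}

.add_obj <- function(bld, name, w) {
  bld$obj[name] <- if (name %in% names(bld$obj)) bld$obj[[name]] + w else w
}

#' Logic-gate constraints for one signaling node
#'
#' Encodes "a node is active iff some occurred edge from an active activator
#' supports it and no occurred edge from an active inhibitor opposes it":
#' each incoming edge e gets a live indicator `a_e = y_e AND x_source`; an
#' active node needs at least one live activation edge (when it has any
#' incoming activation edge); a live activation edge forces the node active
#' unless a live inhibition edge opposes it; any live inhibition edge forces
#' the node inactive.  Nodes without incoming edges are free inputs.
#'
#' @param node_id node id.
#' @param incoming data.frame of the node's incoming edges (`id`, `source`,
#'   `sign`).
#' @return list of linear constraint rows (`coef`, `rel`, `rhs`, `name`).
#' @export
encodeLogic <- function(node_id, incoming) {
  rows <- list()
  xv <- .vn("x", node_id)
  add <- function(coef, rel, rhs, name)
    rows[[length(rows) + 1L]] <<- list(coef = coef, rel = rel, rhs = rhs,
                                       name = name)
  if (!NROW(incoming)) return(rows)
  for (i in seq_len(nrow(incoming))) {
    e <- incoming[i, ]
    ae <- .vn("a", e$id); ye <- .vn("y", e$id); xu <- .vn("x", e$source)
    add(setNames(c(1, -1), c(ae, ye)), "<=", 0, paste0("live_y_", e$id))
    add(setNames(c(1, -1), c(ae, xu)), "<=", 0, paste0("live_x_", e$id))
    add(setNames(c(1, -1, -1), c(ae, ye, xu)), ">=", -1,
        paste0("live_and_", e$id))
  }
  act <- incoming[incoming$sign == "activation", , drop = FALSE]
  inh <- incoming[incoming$sign == "inhibition", , drop = FALSE]
  a_act <- .vn("a", act$id); a_inh <- .vn("a", inh$id)
  if (nrow(act)) {
    add(setNames(c(1, rep(-1, nrow(act))), c(xv, a_act)), "<=", 0,
        paste0("support_", node_id))
    for (k in seq_len(nrow(act)))
      add(setNames(c(1, -1, rep(1, nrow(inh))), c(xv, a_act[k], a_inh)),
          ">=", 0, paste0("activate_", act$id[k]))
  }
  for (k in seq_len(nrow(inh)))
    add(setNames(c(1, 1), c(xv, a_inh[k])), "<=", 1,
        paste0("inhibit_", inh$id[k]))
  rows
}

#' Steady-state mass-balance constraints
#'
#' One equality `sum_r s_mr v_r = 0` per non-boundary metabolite: at steady
#' state the total amount of any internal compound produced equals the total
#' amount consumed.  Boundary metabolites are exempt.
#'
#' @param network an [IntegratedNetwork-class].
#' @return list of linear constraint rows over the `v_` flux variables.
#' @export
encodeMassBalance <- function(network) {
  S <- stoichiometricMatrix(network, boundary = "exclude")
  rows <- list()
  for (m in rownames(S)) {
    coefs <- S[m, ]
    coefs <- coefs[coefs != 0]
    if (!length(coefs)) next
    rows[[length(rows) + 1L]] <-
      list(coef = setNames(as.numeric(coefs), .vn("v", names(coefs))),
           rel = "=", rhs = 0, name = paste0("mass_", m))
  }
  rows
}

#' Thermodynamic direction constraints for one reaction
#'
#' The net flux direction must be opposite to the sign of the standard
#' transformed Gibbs energy: `delta_g < -tau` permits only forward flux,
#' `delta_g > tau` only backward flux (which blocks a reaction declared
#' irreversible-forward), and `|delta_g| <= tau` or a missing value leaves a
#' reversible reaction's direction free via a binary direction indicator
#' `d_r` (`v_r <= U d_r`, `v_r >= -U (1 - d_r)`).
#'
#' @param reaction one-row data.frame with `id`, `reversible`, `delta_g`,
#'   `flux_bound`.
#' @param tau tolerance in kJ/mol (default 0: strict sign rule).
#' @return list with `lb`, `ub` (flux bounds), `needs_direction` (logical),
#'   `rows` (the `d_r` rows when needed) and `forced` (one of "forward",
#'   "backward", "blocked", "free").
#' @export
encodeThermo <- function(reaction, tau = 0) {
  U <- reaction$flux_bound
  lb <- if (reaction$reversible) -U else 0
  ub <- U
  dg <- reaction$delta_g
  rows <- list(); needs_d <- FALSE; forced <- "free"
  if (!is.na(dg) && dg < -tau) {
    lb <- max(lb, 0); forced <- "forward"
  } else if (!is.na(dg) && dg > tau) {
    ub <- min(ub, 0); forced <- "backward"
    if (!reaction$reversible) { lb <- 0; ub <- 0; forced <- "blocked" }
  } else if (reaction$reversible) {
    needs_d <- TRUE
    dv <- .vn("d", reaction$id); vv <- .vn("v", reaction$id)
    rows <- list(
      list(coef = setNames(c(1, -U), c(vv, dv)), rel = "<=", rhs = 0,
           name = paste0("dir_fwd_", reaction$id)),
      list(coef = setNames(c(1, -U), c(vv, dv)), rel = ">=", rhs = -U,
           name = paste0("dir_bwd_", reaction$id)))
  } else forced <- "forward"
  list(lb = lb, ub = ub, needs_direction = needs_d, rows = rows,
       forced = forced)
}

#' Enzyme-reaction coupling constraints for one reaction
#'
#' The state of the catalyzing enzyme restricts both the flux and the product
#' concentrations of its reaction: (i) `|v_r| <= U b_z` (an inactive enzyme
#' blocks the reaction); (ii) for every product p, enzyme off implies the
#' predicted ratio `c_p <= 1` (downregulated) — `(1 - b_z)(c_p - 1) <= 0` in
#' the bilinear encoding, `c_p <= 1 + M b_z` under big-M; (iii) symmetrically
#' every substrate of a blocked reaction accumulates, `c_s >= 1`.
#'
#' @param reaction one-row reaction data.frame.
#' @param stoich named numeric stoichiometry of the reaction.
#' @param b_var name of the enzyme's binary state variable.
#' @param encoding `"big-M"` or `"bilinear"`.
#' @param big_m the big-M constant (used by the big-M encoding).
#' @return list with `rows` (linear) and `bilinear` rows.
#' @export
encodeEnzymeCoupling <- function(reaction, stoich, b_var,
                                 encoding = "big-M", big_m = 2000) {
  if (is.null(b_var) || is.na(reaction$enzyme))
    stop("reaction ", reaction$id, " has no linked enzyme", call. = FALSE)
  U <- reaction$flux_bound
  vv <- .vn("v", reaction$id)
  rows <- list(); bil <- list()
  rows[[1]] <- list(coef = setNames(c(1, -U), c(vv, b_var)), rel = "<=",
                    rhs = 0, name = paste0("gate_fwd_", reaction$id))
  rows[[2]] <- list(coef = setNames(c(1, U), c(vv, b_var)), rel = ">=",
                    rhs = 0, name = paste0("gate_bwd_", reaction$id))
  prods <- names(stoich)[stoich > 0]
  subs <- names(stoich)[stoich < 0]
  for (p in prods) {
    cp <- .vn("c", p)
    if (encoding == "bilinear")
      bil[[length(bil) + 1L]] <- list(
        coef = setNames(c(1, 1), c(cp, b_var)),
        terms = data.frame(binary = b_var, continuous = cp, coef = -1),
        rel = "<=", rhs = 1, name = paste0("prod_", reaction$id, "_", p))
    else
      rows[[length(rows) + 1L]] <- list(
        coef = setNames(c(1, -big_m), c(cp, b_var)), rel = "<=", rhs = 1,
        name = paste0("prod_", reaction$id, "_", p))
  }
  for (s in subs) {
    cs <- .vn("c", s)
    if (encoding == "bilinear")
      bil[[length(bil) + 1L]] <- list(
        coef = setNames(c(-1, -1), c(cs, b_var)),
        terms = data.frame(binary = b_var, continuous = cs, coef = 1),
        rel = "<=", rhs = -1, name = paste0("sub_", reaction$id, "_", s))
    else
      rows[[length(rows) + 1L]] <- list(
        coef = setNames(c(1, big_m), c(cs, b_var)), rel = ">=", rhs = 1,
        name = paste0("sub_", reaction$id, "_", s))
  }
  list(rows = rows, bilinear = bil)
}

## Identify, for every non-boundary metabolite, the reactions able to produce
## it (forward producers plus reversible consumers running backward).
.producers <- function(network) {
  rx <- network@reactions
  st <- network@stoichiometry
  mets <- network@metabolites
  out <- setNames(vector("list", nrow(mets)), mets$id)
  for (i in seq_len(nrow(rx))) {
    s <- st[[rx$id[i]]]
    prod_side <- names(s)[s > 0]
    if (rx$reversible[i]) prod_side <- names(s)
    for (m in prod_side) out[[m]] <- c(out[[m]], rx$id[i])
  }
  out
}

#' Build the mixed-integer program from a network and measurements
#'
#' Assembles binary state variables for every signaling node, edge and
#' enzyme, continuous fluxes and predicted metabolite ratios, and the five
#' constraint families: node states, signaling logic, steady-state mass
#' balance, thermodynamic flux directions and enzyme-reaction coupling (with
#' blockade propagation to downstream metabolites).  The objective is the
#' weighted sum `w1 * (signaling misfit) + w2 * (metabolite L1 error) +
#' w3 * (retained edges)`; measurements binarize to unknown contribute no
#' misfit term.
#'
#' @param network an assembled [IntegratedNetwork-class].
#' @param measurements a [MeasurementSet-class] (may be empty).
#' @param weights numeric `c(w1, w2, w3)`; defaults `c(1, 1, 0.01)` so data
#'   fit dominates and the complexity term only breaks ties toward sparse
#'   topologies.
#' @param options see [mipOptions()].
#' @return a [MipProblem-class].
#' @export
buildProblem <- function(network, measurements = new("MeasurementSet"),
                         weights = c(1, 1, 0.01), options = mipOptions()) {
  if (length(weights) != 3 || any(is.na(weights)) || any(weights < 0))
    stop("weights must be three non-negative numbers", call. = FALSE)
  options <- modifyList(mipOptions(), options)
  w1 <- weights[1]; w2 <- weights[2]; w3 <- weights[3]
  nodes <- network@nodes; edges <- network@edges
  mets <- network@metabolites; rx <- network@reactions

  has_redox_edge <- any(nodes$redox_effect != "none")
  if (has_redox_edge && !any(nodes$kind == "redox-hub"))
    stop("network has redox annotations but no redox-hub node", call. = FALSE)

  prot <- proteinRatios(measurements)
  metm <- metaboliteRatios(measurements)
  node_state <- .binarized_states(prot, options$fold_threshold)
  met_ratio <- if (nrow(metm)) setNames(metm$ratio, metm$id) else numeric()

  c_lo <- options$c_lo; c_hi <- options$c_hi
  if (length(met_ratio)) {
    lo <- min(met_ratio); hi <- max(met_ratio)
    if (lo < c_lo || hi > c_hi) {
      c_lo <- min(c_lo, lo); c_hi <- max(c_hi, hi)
      warning("measured ratios outside [c_lo, c_hi]; widening the box to [",
              format(c_lo), ", ", format(c_hi), "]", call. = FALSE)
    }
  }
  big_m <- options$big_m
  if (is.null(big_m))
    big_m <- 2 * max(c(c_hi, rx$flux_bound, 1), na.rm = TRUE)

  bld <- .new_builder()
  vm <- list(x = character(), y = character(), a = character(),
             b = character(), d = character(), q = character(),
             v = character(), c = character(),
             mN = character(), mM = character())

  ## -- signaling states ---------------------------------------------------
  for (id in nodes$id) {
    vm$x[id] <- .add_var(bld, .vn("x", id), "binary", 0, 1)
  }
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    ylb <- if (e$removable) 0 else 1
    vm$y[e$id] <- .add_var(bld, .vn("y", e$id), "binary", ylb, 1)
    vm$a[e$id] <- .add_var(bld, .vn("a", e$id), "binary", 0, 1)
    .add_obj(bld, vm$y[e$id], w3)
  }
  for (id in nodes$id) {
    incoming <- edges[edges$target == id, , drop = FALSE]
    for (r in encodeLogic(id, incoming))
      .add_row(bld, r$coef, r$rel, r$rhs, r$name)
  }
  for (id in names(node_state)[!is.na(node_state)]) {
    if (!id %in% nodes$id) next  # standalone enzyme: handled via b below
    s <- node_state[[id]]
    mv <- .add_var(bld, .vn("mN", id), "continuous", 0, 1)
    vm$mN[id] <- mv
    .add_row(bld, setNames(c(1, -1), c(mv, vm$x[id])), ">=", -s,
             paste0("misfit_hi_", id))
    .add_row(bld, setNames(c(1, 1), c(mv, vm$x[id])), ">=", s,
             paste0("misfit_lo_", id))
    .add_obj(bld, mv, w1)
  }

  ## -- enzymes ------------------------------------------------------------
  enzymes <- unique(rx$enzyme[!is.na(rx$enzyme)])
  for (z in enzymes) {
    if (z %in% nodes$id) {
      vm$b[z] <- vm$x[z]  # dual-function enzyme: b_z is the signaling state
    } else {
      s <- if (z %in% names(node_state)) node_state[[z]] else NA_integer_
      lb <- if (!is.na(s)) s else 0
      ub <- if (!is.na(s)) s else 1
      vm$b[z] <- .add_var(bld, .vn("b", z), "binary", lb, ub)
    }
  }

  ## -- metabolite ratios --------------------------------------------------
  for (m in mets$id) {
    vm$c[m] <- .add_var(bld, .vn("c", m), "continuous", c_lo, c_hi)
  }
  for (m in names(met_ratio)) {
    mv <- .add_var(bld, .vn("mM", m), "continuous", 0, Inf)
    vm$mM[m] <- mv
    .add_row(bld, setNames(c(1, -1), c(mv, vm$c[m])), ">=", -met_ratio[[m]],
             paste0("meterr_hi_", m))
    .add_row(bld, setNames(c(1, 1), c(mv, vm$c[m])), ">=", met_ratio[[m]],
             paste0("meterr_lo_", m))
    .add_obj(bld, mv, w2)
  }

  ## -- fluxes, thermodynamics, coupling ------------------------------------
  thermo_forced <- setNames(character(nrow(rx)), rx$id)
  for (i in seq_len(nrow(rx))) {
    r <- rx[i, ]
    th <- encodeThermo(r, options$tau)
    thermo_forced[r$id] <- th$forced
    vm$v[r$id] <- .add_var(bld, .vn("v", r$id), "continuous", th$lb, th$ub)
    if (th$needs_direction) {
      vm$d[r$id] <- .add_var(bld, .vn("d", r$id), "binary", 0, 1)
      for (rr in th$rows) .add_row(bld, rr$coef, rr$rel, rr$rhs, rr$name)
    }
    if (!is.na(r$enzyme)) {
      cpl <- encodeEnzymeCoupling(r, network@stoichiometry[[r$id]],
                                  vm$b[r$enzyme], options$encoding, big_m)
      for (rr in cpl$rows) .add_row(bld, rr$coef, rr$rel, rr$rhs, rr$name)
      for (rr in cpl$bilinear)
        .add_bilinear(bld, rr$coef, rr$terms, rr$rel, rr$rhs, rr$name)
      if (options$propagate) {
        qv <- .add_var(bld, .vn("q", r$id), "binary", 0, 1)
        vm$q[r$id] <- qv
        U <- r$flux_bound; eps <- options$eps_activity * U
        .add_row(bld, setNames(c(1, -1), c(qv, vm$b[r$enzyme])), "<=", 0,
                 paste0("act_enz_", r$id))
        .add_row(bld, setNames(c(1, -U), c(vm$v[r$id], qv)), "<=", 0,
                 paste0("act_fwd_", r$id))
        .add_row(bld, setNames(c(1, U), c(vm$v[r$id], qv)), ">=", 0,
                 paste0("act_bwd_", r$id))
        lbv <- bld$vars[[vm$v[r$id]]]$lb; ubv <- bld$vars[[vm$v[r$id]]]$ub
        if (lbv >= 0) {
          .add_row(bld, setNames(c(1, -eps), c(vm$v[r$id], qv)), ">=", 0,
                   paste0("act_min_", r$id))
        } else if (ubv <= 0) {
          .add_row(bld, setNames(c(-1, -eps), c(vm$v[r$id], qv)), ">=", 0,
                   paste0("act_min_", r$id))
        } else {
          dv <- vm$d[r$id]  # direction-free reversible: d exists
          M2 <- U * (1 + options$eps_activity)
          .add_row(bld, setNames(c(1, -eps, -M2), c(vm$v[r$id], qv, dv)),
                   ">=", -M2, paste0("act_min_fwd_", r$id))
          .add_row(bld, setNames(c(-1, -eps, M2), c(vm$v[r$id], qv, dv)),
                   ">=", 0, paste0("act_min_bwd_", r$id))
        }
      }
    }
  }

  ## -- blockade propagation ------------------------------------------------
  if (options$propagate && nrow(rx)) {
    prod_map <- .producers(network)
    for (m in mets$id[!mets$boundary]) {
      prs <- prod_map[[m]]
      if (is.null(prs) || !all(prs %in% names(vm$q))) next
      coef <- setNames(c(1, rep(-big_m, length(prs))),
                       c(vm$c[m], vm$q[prs]))
      .add_row(bld, coef, "<=", 1, paste0("blockade_", m))
    }
  }

  ## -- mass balance --------------------------------------------------------
  if (nrow(rx))
    for (r in encodeMassBalance(network))
      .add_row(bld, r$coef, r$rel, r$rhs, r$name)

  vars <- do.call(rbind, lapply(bld$vars, function(v)
    data.frame(name = v$name, kind = v$kind, lb = v$lb, ub = v$ub)))
  if (is.null(vars))
    vars <- data.frame(name = character(), kind = character(),
                       lb = numeric(), ub = numeric())
  rownames(vars) <- NULL

  vm$nodeStates <- node_state
  vm$metRatios <- met_ratio
  vm$thermoForced <- thermo_forced
  new("MipProblem", variables = vars, linear = bld$linear,
      bilinear = bld$bilinear, objective = bld$obj,
      weights = c(w1 = w1, w2 = w2, w3 = w3), bigM = big_m,
      encoding = options$encoding, varMap = vm,
      options = modifyList(options, list(c_lo = c_lo, c_hi = c_hi,
                                         big_m = big_m)))
}

#' Model size accounting
#'
#' @param problem a [MipProblem-class].
#' @return named integer vector `n_variables`, `n_constraints`, `n_bilinear`,
#'   `n_linear` (total = bilinear + linear).
#' @export
modelSize <- function(problem) {
  nb <- length(problem@bilinear); nl <- length(problem@linear)
  c(n_variables = nrow(problem@variables), n_constraints = nb + nl,
    n_bilinear = nb, n_linear = nl)
}

#' Exact big-M linearization of the bilinear constraints
#'
#' Replaces every product of a binary `b` and a bounded continuous variable
#' `c` with an auxiliary variable `w = b * c` constrained by the standard
#' exact reformulation (`|w| <= M b`, `c - c_hi (1-b) <= w <= c - c_lo
#' (1-b)`), leaving the optimal objective value unchanged.
#'
#' @param problem a [MipProblem-class] in bilinear encoding.
#' @return an equivalent [MipProblem-class] with `encoding = "big-M"` and no
#'   bilinear rows.
#' @export
linearize <- function(problem) {
  if (!length(problem@bilinear)) {
    problem@encoding <- "big-M"
    return(problem)
  }
  vars <- problem@variables
  M <- problem@bigM
  cont <- vars[vars$kind == "continuous", , drop = FALSE]
  if (nrow(cont)) {
    finite <- c(abs(cont$lb[is.finite(cont$lb)]), cont$ub[is.finite(cont$ub)])
    if (length(finite) && M < max(finite))
      stop("big_m (", format(M), ") is smaller than a continuous variable ",
           "bound (", format(max(finite)), "); increase big_m", call. = FALSE)
  }
  bnd <- function(nm) unlist(vars[vars$name == nm, c("lb", "ub")])
  newvars <- list(); newrows <- problem@linear
  wcache <- character()
  for (row in problem@bilinear) {
    coef <- row$coef
    for (k in seq_len(nrow(row$terms))) {
      b <- row$terms$binary[k]; cc <- row$terms$continuous[k]
      tc <- row$terms$coef[k]
      wname <- paste0("w_", b, "_", cc)
      if (!wname %in% wcache) {
        cb <- bnd(cc)
        newvars[[wname]] <- data.frame(name = wname, kind = "continuous",
                                       lb = min(0, cb[1]), ub = max(0, cb[2]))
        newrows[[length(newrows) + 1L]] <- list(
          coef = setNames(c(1, -M), c(wname, b)), rel = "<=", rhs = 0,
          name = paste0("lin_ub_", wname))
        newrows[[length(newrows) + 1L]] <- list(
          coef = setNames(c(1, M), c(wname, b)), rel = ">=", rhs = 0,
          name = paste0("lin_lb_", wname))
        newrows[[length(newrows) + 1L]] <- list(
          coef = setNames(c(1, -1, -cb[1]), c(wname, cc, b)), rel = "<=",
          rhs = -cb[1], name = paste0("lin_eq1_", wname))
        newrows[[length(newrows) + 1L]] <- list(
          coef = setNames(c(1, -1, -cb[2]), c(wname, cc, b)), rel = ">=",
          rhs = -cb[2], name = paste0("lin_eq2_", wname))
        wcache <- c(wcache, wname)
      }
      coef[wname] <- if (wname %in% names(coef)) coef[[wname]] + tc else tc
    }
    newrows[[length(newrows) + 1L]] <- list(coef = coef, rel = row$rel,
                                            rhs = row$rhs, name = row$name)
  }
  problem@variables <- rbind(vars, do.call(rbind, newvars))
  rownames(problem@variables) <- NULL
  problem@linear <- newrows
  problem@bilinear <- list()
  problem@encoding <- "big-M"
  problem
}
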