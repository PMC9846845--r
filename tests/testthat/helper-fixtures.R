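# Shared hand-built fixtures.  The "toy" instance is small enough that every
# expected value below is derivable by hand:
#
#   signaling   S1 --activates--> S2 --inhibits--> S3
#   metabolic   R1: A -> B  (delta_g = -10, enzyme E1)
#               R2: B -> C  (delta_g unknown, irreversible, no enzyme)
#   measured    S1 up (4x), S2 up (3x), S3 down (0.2x), E1 up (5x), B 2x
#
# The measurements are mutually consistent (S1 = 1 forces S2 = 1, which
# forces S3 = 0), so zero misfit is attainable.  Edge e2 is redundant at the
# optimum: with e2 removed, S3 has no incoming edges and is free to sit at
# its measured state, saving the w3 cost of one edge.  The unique optimum
# therefore keeps e1 only: objective = 0.01.

toy_edges <- function() {
  data.frame(id = c("e1", "e2"), source = c("S1", "S2"),
             target = c("S2", "S3"),
             sign = c("activation", "inhibition"), removable = TRUE)
}

toy_reactions <- function() {
  list(reactions = data.frame(id = c("R1", "R2"), reversible = FALSE,
                              delta_g = c(-10, NA), enzyme = c("E1", NA),
                              flux_bound = 1000, exchange = FALSE),
       stoichiometry = list(R1 = c(A = -1, B = 1), R2 = c(B = -1, C = 1)),
       metabolites = data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                                boundary = NA))
}

toy_measurements <- function() {
  new("MeasurementSet",
      proteins = data.frame(id = c("S1", "S2", "S3", "E1"),
                            ratio = c(4, 3, 0.2, 5), significant = TRUE),
      metabolites = data.frame(id = "B", ratio = 2, significant = TRUE))
}

toy_network <- function(measurements = toy_measurements()) {
  assembleNetwork(toy_edges(), toy_reactions(), measurements = measurements)
}

# The spec-level two-node instances used across modules.
chain_network <- function() {
  assembleNetwork(data.frame(id = "e1", source = "A", target = "B",
                             sign = "activation", removable = TRUE))
}

chain_measurements <- function(ratio_b) {
  new("MeasurementSet",
      proteins = data.frame(id = c("A", "B"), ratio = c(4, ratio_b),
                            significant = TRUE),
      metabolites = data.frame(id = character(), ratio = numeric(),
                               significant = logical()))
}

# Evaluate a set of linear rows at a named 0/1 (or numeric) point.
rows_satisfied <- function(rows, point, tol = 1e-9) {
  all(vapply(rows, function(r) {
    lhs <- sum(r$coef * point[names(r$coef)])
    switch(r$rel,
           "<=" = lhs <= r$rhs + tol,
           ">=" = lhs >= r$rhs - tol,
           "="  = abs(lhs - r$rhs) <= tol)
  }, logical(1)))
}

# Reference gate semantics, independent of the MIP encoding: given edge
# data (sign), live indicators, and the node state, is the combination
# allowed?  live must equal y AND x_source for each edge.
gate_allows <- function(x_v, live, signs) {
  fired_inh <- any(live & signs == "inhibition")
  fired_act <- any(live & signs == "activation")
  if (fired_inh) return(x_v == 0L)
  if (fired_act) return(x_v == 1L)
  if (any(signs == "activation")) return(x_v == 0L)
  TRUE  # inhibitor-only target with no live inhibitor: free
}

# A small NADPH toy for the FBA module: two producers capped at 3 and 1.
nadph_model <- function() {
  new("FluxModel",
      metabolites = data.frame(id = c("X", "NADPH", "Y", "Z"),
                               boundary = c(TRUE, FALSE, TRUE, TRUE)),
      reactions = data.frame(id = c("P1", "P2", "C1"), reversible = FALSE,
                             lb = 0, ub = c(3, 1, 10)),
      stoichiometry = list(P1 = c(X = -1, NADPH = 1, Y = 1),
                           P2 = c(X = -1, NADPH = 1),
                           C1 = c(NADPH = -1, Z = 1)),
      gpr = setNames(character(), character()))
}
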