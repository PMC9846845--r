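---
title: "Methods: joint signaling/metabolic inference as a mixed-integer program"
author: "redoxmip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint signaling/metabolic inference as a mixed-integer program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxmip)
```

## The inference problem

redoxmip infers a *cell-state-specific* network from fold-change
measurements comparing two cell states (for example a drug-resistant line
relative to its sensitive parent). The input is:

* a candidate signaling network: signed directed edges
  (activation/inhibition) between proteins, optionally including a
  redox-hub node whose oxidation activates or inhibits annotated targets;
* a metabolic reaction table: stoichiometries, reversibility, optional
  standard transformed Gibbs energies, flux capacities, and the enzymes
  (signaling nodes or standalone proteins) that catalyze each reaction;
* protein and metabolite fold-change ratios with significance flags.

The output is a single joint assignment: a Boolean state for every protein,
a keep/remove decision for every removable edge, an on/off state for every
enzyme, and a thermodynamically consistent steady-state flux vector with
predicted metabolite fold changes. All decisions are coupled — an inferred
inactive kinase can switch off an enzyme, which blocks a reaction, which
forces its products down — so the problem is solved as one mixed-integer
program (MIP) rather than layer by layer.

## Binarization

A measurement maps to an up/down/unknown state with a multiplicative
dead band (default `fold_threshold = 1.5`): significant and ratio ≥ 1.5 ⟹
state 1; significant and ratio ≤ 1/1.5 ⟹ state 0; anything else
(non-significant, or inside the dead band) ⟹ unknown. Unknown measurements
contribute no misfit term; their variables are free and the optimizer
chooses the state most consistent with the rest of the network. The
shoulders are inclusive:

```{r}
binarizeRatio(c(1.5, 1/1.5, 1.49, 0.2), significant = TRUE)
```

## Variables

For a network with nodes $V$, removable edges $E$, enzymes $Z$, reactions
$R$ and metabolites $M$:

| variable | type | meaning |
|---|---|---|
| $x_v$ | binary | protein $v$ active in the resistant state |
| $y_e$ | binary | edge $e$ occurs (is kept) in this cell state |
| $a_e$ | binary | edge $e$ is *live*: kept and its source active |
| $b_z$ | binary | enzyme $z$ active |
| $d_r$ | binary | direction of a thermodynamically free reversible reaction |
| $q_r$ | binary | reaction $r$ carries non-negligible flux (propagation) |
| $v_r$ | continuous | steady-state flux |
| $c_m$ | continuous | predicted metabolite fold-change ratio, boxed to `[c_lo, c_hi]` |
| misfit slacks | continuous ≥ 0 | L1 deviations from measured states/ratios |

## Constraint families

**Signaling logic.** Each live indicator is the AND of its edge and source:
$a_e \le y_e$, $a_e \le x_{src(e)}$, $a_e \ge y_e + x_{src(e)} - 1$. A node
with incoming activation edges is active iff at least one activation edge
is live and no inhibition edge is live: any live inhibition forces
$x_v = 0$; a live activation forces $x_v = 1$ unless opposed by a live
inhibition; with activation edges present but none live, $x_v = 0$. The
deliberate edge case: a node whose only incoming edges are inhibitions is
*free* when no inhibitor is live (absence of inhibition is not evidence of
activation), and forced off when one is. Nodes with no incoming edges are
free inputs. These semantics are verified exhaustively in the test suite by
enumerating every 0/1 assignment of small gates against a reference truth
table.

**Steady-state mass balance.** $\sum_r s_{mr} v_r = 0$ for every
non-boundary metabolite. A metabolite is auto-flagged boundary when it
appears only as substrate or only as product across all reactions
(reversible reactions count both sides), with an explicit override
available.

**Thermodynamic directions.** The net flux direction must oppose the sign
of the standard transformed Gibbs energy $\Delta G_r$, with tolerance
`tau` (default 0): $\Delta G_r < -\tau$ permits only forward flux,
$\Delta G_r > \tau$ only backward (blocking irreversible-forward
reactions), and $|\Delta G_r| \le \tau$ or a missing value leaves a
reversible reaction free via a direction binary: $v_r \le U d_r$ and
$v_r - U d_r \ge -U$, where $U$ is the flux capacity.

**Enzyme–reaction coupling.** For reaction $r$ catalyzed by enzyme $z$:
(i) $|v_r| \le U b_z$ — an inactive enzyme blocks its reaction;
(ii) enzyme off implies every product ratio $c_p \le 1$; (iii) enzyme off
implies every substrate ratio $c_s \ge 1$ (blocked consumption
accumulates). Conditions (ii)–(iii) are conditional products of a binary
and a continuous variable, available in two encodings (next section).

**Blockade propagation** (`propagate = TRUE`, default). A metabolite none
of whose producing reactions carries non-negligible flux is predicted down
($c_m \le 1$), implemented with per-reaction activity indicators $q_r$
tied to $|v_r| \ge \epsilon U q_r$ (default `eps_activity = 1e-3` of
capacity). This carries an enzyme knockout through to *distal* metabolites
that no surviving pathway can produce, which pure pairwise coupling would
miss.

## Objective

$$\min\; w_1 \sum_{\text{measured proteins}} |x_v - \hat x_v|
      + w_2 \sum_{\text{measured metabolites}} |c_m - \hat c_m|
      + w_3 \sum_{e} y_e$$

with defaults $w = (1, 1, 0.01)$: data fit dominates and the complexity
term only breaks ties toward sparse topologies — a kept edge is never worth
a misfit, because the smallest possible misfit increment (one binarized
protein disagreement) costs 1 while retaining *every* edge of a
paper-scale instance costs well under 1. L1 terms are linearized with
non-negative slack pairs.

## Bilinear vs big-M encodings

The conditional constraints (enzyme-off product/substrate bounds) are
products like $(1 - b_z)(c_p - 1) \le 0$. The package carries both:

* **bilinear** — the rows are stored symbolically as products; useful for
  model inspection and as an independent check;
* **big-M** (default) — $c_p \le 1 + M b_z$ etc., with $M$ sized
  automatically to twice the largest continuous upper bound (so the relaxed
  row is vacuous exactly when intended, without inflating the LP
  relaxation more than necessary).

`linearize()` rewrites a bilinear problem into the exact big-M counterpart;
the test suite solves both encodings on 50 seeded random instances and
requires objective agreement within $10^{-6}$.

## Solver and numerical choices

Problems are solved with HiGHS through `scipy.optimize.milp` in a Python
subprocess (one batched JSON round-trip for many instances), with:

* `mip_rel_gap = 0` — proofs of optimality, not near-optimality, because
  the oracle-equivalence tests compare objectives at $10^{-6}$;
* feasibility/integrality tolerances at $10^{-8}$ — the solver default of
  $10^{-6}$ lets big-M rows shave exactly-$10^{-6}$ slivers off the
  objective, which is indistinguishable from a real disagreement at the
  comparison tolerance; $10^{-9}$ triggers spurious solver errors on some
  instances, so $10^{-8}$ is the usable middle;
* a retry without presolve on unknown solver status, working around a
  presolve bug observed in the bundled HiGHS build.

All randomness lives in the generator; solving is deterministic.

## Verification strategy

* **Exhaustive oracle.** `bruteForceOracle()` enumerates every assignment
  of the free binaries (refusing instances with more than `max_binaries`),
  evaluates gates by truth table, checks flux feasibility with a direct
  quadratic program, and projects metabolite ratios in closed form. The
  MILP must match its optimum exactly on 100 seeded random instances.
* **Planted recovery.** The synthetic generator plants a ground truth
  (states, edges, a feasible flux vector) and emits measurements that
  binarize back to it; noise-free paper-scale instances must be recovered
  with signaling precision 1 and zero measured-metabolite error.
* **Physical audit.** `auditSolution()` re-checks mass-balance residuals,
  the Gibbs sign rule and enzyme-off gating on the extracted solution,
  independently of the solver's own feasibility claim.

## Synthetic generator: realism and limits

`generateNetwork()` draws an acyclic signed signaling layer over sorted
node names, attaches enzymes (dual-function or standalone) to a
stoichiometric reaction chain with side metabolites, optionally wires a
redox hub, then plants a truth by propagating states through the gates and
constructing a feasible flux vector. `generateMeasurements()` multiplies
the planted ratios by log-normal noise, hides a fraction of measurements,
and flags significance.

The `paper-scale` preset produces instances of a realistic published size:

```{r}
ps <- syntheticPreset("paper-scale", seed = 7)
c(removable_edges = sum(ps$network@edges$removable),
  reactions = nrow(ps$network@reactions),
  protein_measurements = nrow(proteinRatios(ps$measurements)),
  metabolite_measurements = nrow(metaboliteRatios(ps$measurements)))
```

Known limits: the signaling layer is acyclic (no feedback loops), gates
are pure AND-of-edge/OR-of-activators (no weighted or k-of-n logic),
thermodynamics uses only the sign of a single standard $\Delta G$ (no
concentration-dependent $\Delta G$), and planted truths are one consistent
assignment — real data may admit multiple optima, which
`enumerateOptima()` exposes rather than hides.

## A worked example

```{r}
ps <- syntheticPreset("tiny", seed = 3)
pr <- buildProblem(ps$network, ps$measurements)
modelSize(pr)
res <- infer(pr, ps$network, ps$measurements)
c(objective = res@objective,
  signaling_precision = res@signalingPrecision,
  metabolite_error = res@metaboliteError)
auditSolution(res, ps$network)$ok
```

Paper-scale instances build to a few hundred binaries and around a
thousand constraints and solve in seconds:

```{r}
ps <- syntheticPreset("paper-scale", seed = 7)
modelSize(buildProblem(ps$network, ps$measurements))
```

## FBA contribution attribution

Independently of the MIP, `maximizeCofactor()` runs flux balance analysis
maximizing net production of a target cofactor and
`contributionFractions()` attributes fractional contributions to producing
reactions, flagging degenerate optima (`uniqueOptimum`) instead of
reporting one arbitrary vertex as the answer:

```{r}
m <- new("FluxModel",
         metabolites = data.frame(id = c("X", "NADPH", "Y", "Z"),
                                  boundary = c(TRUE, FALSE, TRUE, TRUE)),
         reactions = data.frame(id = c("P1", "P2", "C1"), reversible = FALSE,
                                lb = 0, ub = c(3, 1, 10)),
         stoichiometry = list(P1 = c(X = -1, NADPH = 1, Y = 1),
                              P2 = c(X = -1, NADPH = 1),
                              C1 = c(NADPH = -1, Z = 1)),
         gpr = setNames(character(), character()))
fba <- maximizeCofactor(m, "NADPH")
contributionFractions(m, fba)
```

Expression data modulates capacities through gene–protein–reaction rules
(`applyExpressionBounds()`: max over OR branches, min over AND conjuncts,
missing genes neutral), for both SBML Level 3 FBC models and the native
TSV format.
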