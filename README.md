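# redoxmip

Constraint-based joint inference of a cell-state-specific Boolean
signaling network and a thermodynamically constrained metabolic flux
network from fold-change multi-omics measurements.

## The science

Comparing two cell states (for example a drug-resistant cancer line
against its sensitive parent) yields protein and metabolite fold-change
ratios, but not the mechanism: which signaling edges are actually
operative in the resistant state, which enzymes are on, and which fluxes
rewire as a consequence. Treating the layers separately discards the
strongest available evidence — an inferred inactive kinase should switch
off the enzymes it activates, blocking their reactions and forcing their
products down. redoxmip encodes all of those couplings at once and solves
the joint assignment as a mixed-integer program (MIP), with optional
redox-hub annotations so that oxidant signaling (e.g. H2O2) enters the
logic as ordinary signed edges.

## The model

Over nodes *V*, removable edges *E*, enzymes *Z*, reactions *R* and
metabolites *M*, the MIP has binary protein states `x_v`, edge-occurrence
indicators `y_e`, live-edge indicators `a_e`, enzyme states `b_z`,
direction binaries `d_r`, activity indicators `q_r`, and continuous fluxes
`v_r` and predicted metabolite ratios `c_m`. Five constraint families
couple them:

1. **Signaling logic** — a node is active iff some kept edge from an
   active activator supports it and no kept edge from an active inhibitor
   opposes it (inhibitor-only nodes with no live inhibitor are left free);
2. **Steady-state mass balance** — `S v = 0` over non-boundary
   metabolites;
3. **Thermodynamic directions** — net flux must oppose the sign of the
   standard Gibbs energy, within a tolerance `tau`;
4. **Enzyme–reaction coupling** — an inactive enzyme blocks its
   reaction's flux, forces product ratios ≤ 1 and substrate ratios ≥ 1
   (conditional constraints available in exact **bilinear** and **big-M**
   encodings, interconvertible via `linearize()`);
5. **Blockade propagation** — a metabolite with no active producing
   reaction is predicted down, carrying knockouts to distal metabolites.

The objective is `w1·(signaling misfit) + w2·(metabolite L1 error) +
w3·(kept edges)` with defaults `(1, 1, 0.01)`, so data fit dominates and
the complexity term only breaks ties toward sparse topologies.
Measurements are binarized with a multiplicative dead band (default 1.5);
unknowns contribute no misfit.

Correctness is enforced by an exhaustive brute-force oracle
(`bruteForceOracle()` enumerates every free-binary assignment on small
instances), planted-truth recovery on synthetic networks, and an
independent post-solve physical audit (`auditSolution()`). A separate FBA
utility (`maximizeCofactor()` + `contributionFractions()`) attributes
fractional contributions of reactions to the maximal production of a
target cofactor such as NADPH, flagging degenerate optima instead of
silently reporting one.

See the methods vignette (`vignettes/redoxmip-methods.Rmd`) for the full
formulation, encodings, numerical choices and verification strategy.

## Worked example

```r
library(redoxmip)

ps <- syntheticPreset("tiny", seed = 3)     # network + planted truth + data
pr <- buildProblem(ps$network, ps$measurements)
modelSize(pr)
#>   n_variables n_constraints    n_bilinear      n_linear
#>            40            74             0            74

res <- infer(pr, ps$network, ps$measurements)
res
#> InferenceResult: optimal | objective 0.01
#>   edges removed: 5 / 6
#>   reactions blocked: 2 / 3
#>   signaling precision: 1
#>   metabolite error (log2_mae): 3.997e-16

auditSolution(res, ps$network)$ok
#> [1] TRUE
```

Real data enters through three native TSVs — a signed edge list
(`source TAB +/- TAB target`), a reaction table
(`id TAB equation TAB delta_g TAB enzyme TAB flux_bound`) and a
measurement table (`id TAB ratio TAB significant TAB layer`) — read with
`readSignalingEdges()`, `readReactionTable()` and `readMeasurements()`
and combined with `assembleNetwork()`.

A command-line interface is installed at
`system.file("scripts", "redoxmip-cli.R", package = "redoxmip")` with
`simulate`, `infer` and `fba-contrib` subcommands, e.g.:

```sh
Rscript redoxmip-cli.R simulate --preset paper-scale --seed 7 --out data/
Rscript redoxmip-cli.R infer --edges data/edges.tsv \
    --reactions data/reactions.tsv --measurements data/measurements.tsv \
    --out result.json
```

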