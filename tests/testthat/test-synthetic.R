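test_that("generation is reproducible and seed-sensitive", {
  g1 <- generateNetwork(6, 5, 5, 3, seed = 11)
  g2 <- generateNetwork(6, 5, 5, 3, seed = 11)
  g3 <- generateNetwork(6, 5, 5, 3, seed = 12)
  expect_identical(g1$network, g2$network)
  expect_identical(g1$truth, g2$truth)
  expect_false(identical(g1$network@edges, g3$network@edges) &&
               identical(g1$truth@nodeStates, g3$truth@nodeStates))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generateNetwork(4, 3, 4, 2, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("the generator rejects impossible edge counts", {
  expect_error(generateNetwork(3, 4, 4, 2, seed = 1),
               "exceeds the acyclic simple-graph maximum")
})

test_that("generated networks are valid and structurally as requested", {
  gen <- generateNetwork(8, 10, 7, 5, seed = 2, n_redox = 2)
  nw <- gen$network
  expect_true(validObject(nw))
  expect_equal(sum(nw@edges$removable), 10)
  hub_edges <- nw@edges[!nw@edges$removable, ]
  expect_equal(nrow(hub_edges), 2)
  expect_true(all(hub_edges$source == "H2O2"))
  expect_equal(nrow(nw@reactions), 5)
  expect_lte(nrow(nw@metabolites), 7)
  # signaling layer is acyclic: edges only run forward in the node order
  sn <- setdiff(nw@nodes$id, "H2O2")
  removable <- nw@edges[nw@edges$removable, ]
  expect_true(all(match(removable$source, sort(sn)) <
                  match(removable$target, sort(sn))))
})

test_that("every planted state is consistent with the gate semantics", {
  for (seed in 1:5) {
    gen <- generateNetwork(7, 8, 6, 4, seed = seed)
    nw <- gen$network; x <- gen$truth@nodeStates
    for (v in names(x)) {
      ein <- nw@edges[nw@edges$target == v, , drop = FALSE]
      if (!nrow(ein)) next
      expect_true(gate_allows(x[[v]], live = x[ein$source] == 1L,
                              signs = ein$sign),
                  label = paste("seed", seed, "node", v))
    }
  }
})

test_that("planted fluxes satisfy mass balance, capacity and gating", {
  for (seed in 1:5) {
    gen <- generateNetwork(7, 8, 6, 4, seed = seed)
    nw <- gen$network; tr <- gen$truth
    S <- as.matrix(stoichiometricMatrix(nw))
    if (nrow(S))
      expect_lt(max(abs(S %*% tr@fluxes[colnames(S)])), 1e-9)
    rx <- nw@reactions
    expect_true(all(abs(tr@fluxes[rx$id]) <= rx$flux_bound))
    for (i in seq_len(nrow(rx))) {
      z <- rx$enzyme[i]
      if (!is.na(z) && tr@enzymeStates[[z]] == 0L)
        expect_equal(unname(tr@fluxes[rx$id[i]]), 0)
    }
  }
})

test_that("planted ratios binarize back to the planted states", {
  gen <- generateNetwork(10, 12, 6, 4, seed = 4)
  tr <- gen$truth
  states <- binarizeRatio(tr@nodeRatios, rep(TRUE, length(tr@nodeRatios)))
  expect_identical(unname(states),
                   unname(tr@nodeStates[names(tr@nodeRatios)]))
})

test_that("measurements honor noise, missingness and significance rules", {
  gen <- generateNetwork(10, 12, 8, 5, seed = 6)
  # noiseless, complete: measurements equal the truth exactly
  ms0 <- generateMeasurements(gen$truth, seed = 1)
  pr <- proteinRatios(ms0)
  expect_equal(setNames(pr$ratio, pr$id),
               gen$truth@nodeRatios[pr$id])
  # exact drop counts per layer
  n_prot <- length(gen$truth@nodeRatios)
  n_met <- length(gen$truth@metaboliteRatios)
  ms <- generateMeasurements(gen$truth, missing_fraction = c(0.5, 0.25),
                             seed = 2)
  expect_equal(nrow(proteinRatios(ms)), n_prot - round(0.5 * n_prot))
  expect_equal(nrow(metaboliteRatios(ms)), n_met - round(0.25 * n_met))
  # significance flag tracks the dead band of the measured value
  msn <- generateMeasurements(gen$truth, noise_sd = 0.8, seed = 3)
  prn <- proteinRatios(msn)
  expect_equal(prn$significant, abs(log2(prn$ratio)) >= log2(1.5) - 1e-12)
  # same seed reproduces the measurement set exactly
  expect_identical(generateMeasurements(gen$truth, noise_sd = 0.3, seed = 9),
                   generateMeasurements(gen$truth, noise_sd = 0.3, seed = 9))
  expect_error(generateMeasurements(gen$truth, missing_fraction = 1),
               "missing_fraction")
})

test_that("noise-free inference recovers the planted signal exactly", {
  # parameter-recovery invariant on the tiny preset across several seeds
  for (seed in c(1, 2, 3)) {
    ps <- syntheticPreset("tiny", seed = seed)
    pr <- buildProblem(ps$network, ps$measurements)
    res <- infer(pr, ps$network, ps$measurements)
    expect_equal(res@signalingPrecision, 1, label = paste("seed", seed))
    expect_equal(res@metaboliteError, 0, tolerance = 1e-6,
                 label = paste("seed", seed))
    # retained edges are a subset of the planted occurred edges
    kept <- names(res@edgeOccurrence)[res@edgeOccurrence == "occurred"]
    expect_true(all(kept %in%
                    names(ps$truth@edgeOccurrence)[
                      ps$truth@edgeOccurrence == 1L]))
    expect_true(auditSolution(res, ps$network)$ok)
  }
})

test_that("the paper-scale preset matches the published dimensions", {
  ps <- syntheticPreset("paper-scale", seed = 1)
  nw <- ps$network
  expect_equal(nrow(nw@edges[nw@edges$removable, ]), 87)
  expect_equal(nrow(nw@reactions), 74)
  expect_lte(nrow(nw@metabolites), 107)
  expect_equal(nrow(proteinRatios(ps$measurements)), 22)
  expect_equal(nrow(metaboliteRatios(ps$measurements)), 38)
  expect_output(show(ps$truth), "PlantedTruth")
})
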