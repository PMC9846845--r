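test_that("the consistent chain keeps its edge at cost w3", {
  nw <- chain_network()
  ms <- chain_measurements(4)  # A = 1, B = 1: the edge explains B
  res <- infer(buildProblem(nw, ms), nw, ms)
  expect_equal(res@objective, 0.01)
  expect_equal(unname(res@edgeOccurrence["e1"]), "occurred")
  expect_equal(unname(res@nodeStates[c("A", "B")]), c(1L, 1L))
  expect_equal(res@signalingPrecision, 1)
})

test_that("the contradictory toy drops the edge for zero total cost", {
  nw <- chain_network()
  ms <- chain_measurements(0.25)  # A = 1 but B = 0: edge must go
  res <- infer(buildProblem(nw, ms), nw, ms)
  expect_equal(res@objective, 0)
  expect_equal(unname(res@edgeOccurrence["e1"]), "removed")
  expect_equal(unname(res@nodeStates[c("A", "B")]), c(1L, 0L))
  expect_equal(res@signalingPrecision, 1)
})

test_that("the integrated toy reaches its hand-derived optimum", {
  nw <- toy_network(); ms <- toy_measurements()
  pr <- buildProblem(nw, ms)
  sol <- solveMip(pr)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 0.01, tolerance = 1e-7)
  res <- extractResult(sol, pr, nw, ms)
  # e2 is redundant (S3 free once unhooked matches its measurement)
  expect_equal(unname(res@edgeOccurrence[c("e1", "e2")]),
               c("occurred", "removed"))
  expect_equal(unname(res@nodeStates[c("S1", "S2", "S3")]), c(1L, 1L, 0L))
  expect_equal(unname(res@enzymeStates["E1"]), 1L)
  expect_equal(res@signalingPrecision, 1)
  expect_equal(res@metaboliteError, 0, tolerance = 1e-9)
  expect_equal(unname(res@metabolitePredictions["B"]), 2, tolerance = 1e-6)
  # R1 carries flux (enzyme on), so neither reaction is blocked
  expect_true(all(res@reactionStatus %in% c("forward", "backward")))
  expect_output(show(res), "InferenceResult")
})

test_that("an off enzyme blocks its reaction in the extraction", {
  nw <- toy_network()
  ms <- new("MeasurementSet",
            proteins = data.frame(id = "E1", ratio = 0.2,
                                  significant = TRUE),  # enzyme down
            metabolites = data.frame(id = character(), ratio = numeric(),
                                     significant = logical()))
  res <- infer(buildProblem(nw, ms), nw, ms)
  expect_equal(unname(res@enzymeStates["E1"]), 0L)
  expect_equal(unname(res@reactionStatus["R1"]), "blocked")
  expect_equal(unname(res@fluxes["R1"]), 0)
})

test_that("extractResult refuses failed solves", {
  nw <- toy_network(); ms <- toy_measurements()
  pr <- buildProblem(nw, ms)
  expect_error(extractResult(list(status = "infeasible"), pr, nw, ms),
               "no solution to extract")
})

test_that("signalingPrecision counts only decisively measured nodes", {
  res <- new("InferenceResult",
             nodeStates = c(A = 1L, B = 0L, C = 1L),
             edgeOccurrence = character(), enzymeStates = integer(),
             reactionStatus = character(), fluxes = numeric(),
             metabolitePredictions = numeric(), objective = 0,
             signalingPrecision = NA_real_, metaboliteError = NA_real_,
             metaboliteErrorMetric = "log2_mae", solverStatus = "optimal",
             solution = numeric())
  ms <- new("MeasurementSet",
            proteins = data.frame(id = c("A", "B", "C"),
                                  ratio = c(4, 4, 1.1),
                                  significant = c(TRUE, TRUE, TRUE)),
            metabolites = data.frame(id = character(), ratio = numeric(),
                                     significant = logical()))
  # C is in the dead band and must be excluded: A matches, B does not
  expect_equal(signalingPrecision(res, ms), 0.5)
  ms@proteins$ratio <- c(1.1, 1.2, 1.3)  # nothing decisive
  expect_error(signalingPrecision(res, ms), "precision is undefined")
})

test_that("metaboliteError implements its three metrics", {
  res <- new("InferenceResult",
             nodeStates = integer(), edgeOccurrence = character(),
             enzymeStates = integer(), reactionStatus = character(),
             fluxes = numeric(),
             metabolitePredictions = c(m1 = 2, m2 = 1),
             objective = 0, signalingPrecision = NA_real_,
             metaboliteError = NA_real_, metaboliteErrorMetric = "log2_mae",
             solverStatus = "optimal", solution = numeric())
  ms <- new("MeasurementSet",
            proteins = data.frame(id = character(), ratio = numeric(),
                                  significant = logical()),
            metabolites = data.frame(id = c("m1", "m2"), ratio = c(4, 1),
                                     significant = TRUE))
  expect_equal(metaboliteError(res, ms, "log2_mae"),
               mean(abs(log2(c(2, 1)) - log2(c(4, 1)))))
  expect_equal(metaboliteError(res, ms, "mae"), mean(abs(c(2 - 4, 0))))
  expect_equal(metaboliteError(res, ms, "rmse"), sqrt(mean(c(4, 0))))
  # identical vectors give zero error
  res@metabolitePredictions <- c(m1 = 4, m2 = 1)
  expect_equal(metaboliteError(res, ms, "log2_mae"), 0)
})

test_that("enumerateOptima surfaces degenerate optima", {
  # two interchangeable activators of a measured-up node: the optimum keeps
  # exactly one of them, and both choices are optimal
  ed <- data.frame(id = c("e1", "e2"), source = c("U1", "U2"), target = "V",
                   sign = "activation", removable = TRUE)
  nw <- assembleNetwork(ed)
  ms <- new("MeasurementSet",
            proteins = data.frame(id = c("U1", "U2", "V"), ratio = 4,
                                  significant = TRUE),
            metabolites = data.frame(id = character(), ratio = numeric(),
                                     significant = logical()))
  pr <- buildProblem(nw, ms)
  opts <- enumerateOptima(pr, k = 5)
  expect_gte(length(opts), 2)
  objs <- vapply(opts, `[[`, numeric(1), "objective")
  expect_true(all(abs(objs - objs[1]) <= 1e-6))
  kept <- vapply(opts, function(s)
    paste(s$assignment[c("y_e1", "y_e2")], collapse = ""), character(1))
  expect_equal(anyDuplicated(kept), 0L)
  expect_error(enumerateOptima(pr, k = 0), "at least 1")
})

test_that("objectiveBreakdown reconstructs the solver objective", {
  nw <- toy_network(); ms <- toy_measurements()
  pr <- buildProblem(nw, ms)
  res <- infer(pr, nw, ms)
  ob <- objectiveBreakdown(res, pr, ms)
  expect_equal(unname(ob["total"]), res@objective, tolerance = 1e-6)
  expect_equal(unname(ob["misfit"]), 0)
  expect_equal(unname(ob["edges"]), 0.01)
})

test_that("auditSolution passes clean solutions and flags doctored ones", {
  nw <- toy_network(); ms <- toy_measurements()
  res <- infer(buildProblem(nw, ms), nw, ms)
  aud <- auditSolution(res, nw)
  expect_true(aud$ok)
  expect_lte(aud$mass_residual, 1e-6)
  expect_length(aud$violations, 0)

  broken <- res
  broken@fluxes["R1"] <- broken@fluxes["R1"] + 1  # violates mass balance
  expect_false(auditSolution(broken, nw)$ok)

  broken2 <- res
  broken2@enzymeStates["E1"] <- 0L  # flux with enzyme off
  aud2 <- auditSolution(broken2, nw)
  expect_false(aud2$ok)
  expect_true(any(grepl("enzyme E1 off", aud2$violations)))

  broken3 <- res
  broken3@fluxes[c("R1", "R2")] <- -5  # against delta_g = -10 on R1
  aud3 <- auditSolution(broken3, nw)
  expect_true(any(grepl("against delta_g", aud3$violations)))
})
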