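test_that("binarizeRatio maps ratios to up/down/unknown states", {
  expect_identical(binarizeRatio(6.3, TRUE), 1L)
  expect_identical(binarizeRatio(0.4, TRUE), 0L)
  expect_identical(binarizeRatio(1.0, TRUE), NA_integer_)  # dead band
  expect_identical(binarizeRatio(6.3, FALSE), NA_integer_) # not significant
  # thresholds are inclusive on both shoulders
  expect_identical(binarizeRatio(c(1.5, 1 / 1.5, 1.49), c(TRUE, TRUE, TRUE)),
                   c(1L, 0L, NA_integer_))
  # custom threshold
  expect_identical(binarizeRatio(1.8, TRUE, fold_threshold = 2), NA_integer_)
  expect_identical(binarizeRatio(2.0, TRUE, fold_threshold = 2), 1L)
})

test_that("binarizeRatio validates its inputs", {
  expect_error(binarizeRatio(2, TRUE, fold_threshold = 0.9), ">= 1")
  expect_error(binarizeRatio(-1, TRUE), "strictly positive")
  expect_error(binarizeRatio(NA, TRUE), "strictly positive")
})

test_that("assembleNetwork derives kinds, interface and standalone enzymes", {
  nw <- toy_network()
  expect_setequal(nw@nodes$id, c("S1", "S2", "S3"))
  expect_true(all(nw@nodes$kind == "signaling-protein"))
  expect_equal(nw@standaloneEnzymes, "E1")
  expect_equal(nw@interface, character())

  # an enzyme that is also a signaling node becomes dual-function; if it
  # receives edges it is an interface node
  rx <- toy_reactions()
  rx$reactions$enzyme[1] <- "S2"
  nw2 <- assembleNetwork(toy_edges(), rx)
  expect_equal(nw2@nodes$kind[nw2@nodes$id == "S2"], "dual-function-enzyme")
  expect_equal(nw2@interface, "S2")
  expect_equal(nw2@standaloneEnzymes, character())
})

test_that("redox annotations become non-removable hub edges", {
  annot <- data.frame(id = c("S1", "S3"),
                      effect = c("oxidation-activates", "oxidation-inhibits"))
  nw <- assembleNetwork(toy_edges(), redox_annotations = annot)
  hub <- nw@edges[nw@edges$source == "H2O2", ]
  expect_equal(nrow(hub), 2)
  expect_false(any(hub$removable))
  expect_equal(hub$sign[hub$target == "S1"], "activation")
  expect_equal(hub$sign[hub$target == "S3"], "inhibition")
  expect_equal(nw@nodes$kind[nw@nodes$id == "H2O2"], "redox-hub")
  expect_equal(redoxHub(nw), "H2O2")

  bad <- data.frame(id = "S1", effect = "oxidation-destroys")
  expect_error(assembleNetwork(toy_edges(), redox_annotations = bad),
               "unknown redox effect")
})

test_that("measurement ids are validated at assembly", {
  ms <- new("MeasurementSet",
            proteins = data.frame(id = "NOPE", ratio = 2, significant = TRUE),
            metabolites = data.frame(id = character(), ratio = numeric(),
                                     significant = logical()))
  expect_error(assembleNetwork(toy_edges(), toy_reactions(),
                               measurements = ms),
               "measurement id\\(s\\) not in the network: NOPE")
})

test_that("boundary metabolites are auto-flagged, overridable", {
  nw <- toy_network()
  bd <- setNames(nw@metabolites$boundary, nw@metabolites$id)
  # A only consumed, C only produced -> boundary; B both -> internal
  expect_true(bd[["A"]]); expect_true(bd[["C"]]); expect_false(bd[["B"]])

  # a reversible reaction counts both sides, making its metabolites internal
  rx <- toy_reactions()
  rx$reactions$reversible[2] <- TRUE
  nw2 <- assembleNetwork(toy_edges(), rx)
  bd2 <- setNames(nw2@metabolites$boundary, nw2@metabolites$id)
  expect_false(bd2[["C"]])

  nw3 <- assembleNetwork(toy_edges(), rx, boundary_override = c("B", "C"))
  bd3 <- setNames(nw3@metabolites$boundary, nw3@metabolites$id)
  expect_true(bd3[["B"]]); expect_true(bd3[["C"]])
})

test_that("network validity catches structural errors", {
  nw <- toy_network()
  bad <- nw; bad@edges$target[1] <- "S1"
  expect_error(validObject(bad), "self-loop")
  bad <- nw; bad@nodes <- rbind(bad@nodes, bad@nodes[1, ])
  expect_error(validObject(bad), "duplicated node ids")
  bad <- nw; bad@nodes$kind <- "redox-hub"
  expect_error(validObject(bad), "more than one redox-hub")
  bad <- nw; bad@stoichiometry$R1 <- c(A = -1, UNKNOWN = 1)
  expect_error(validObject(bad), "unknown metabolite")
  bad <- nw; bad@reactions$enzyme[2] <- "GHOST"
  expect_error(validObject(bad), "unresolved enzyme")
})

test_that("stoichiometricMatrix is sorted, sparse and boundary-aware", {
  nw <- toy_network()
  S <- stoichiometricMatrix(nw)               # exclude boundary
  expect_s4_class(S, "sparseMatrix")
  expect_equal(rownames(S), "B")
  expect_equal(colnames(S), c("R1", "R2"))
  expect_equal(as.numeric(S["B", ]), c(1, -1))
  Sall <- stoichiometricMatrix(nw, "include")
  expect_equal(rownames(Sall), c("A", "B", "C"))
  expect_equal(as.numeric(Sall["A", ]), c(-1, 0))
  expect_equal(as.numeric(Sall["C", ]), c(0, 1))
})

test_that("accessors and show methods work", {
  nw <- toy_network()
  expect_equal(signalingNodes(nw), nw@nodes)
  expect_equal(signalingEdges(nw), nw@edges)
  expect_equal(metabolites(nw), nw@metabolites)
  expect_equal(reactions(nw), nw@reactions)
  expect_equal(stoichiometry(nw), nw@stoichiometry)
  expect_output(show(nw), "IntegratedNetwork")
  expect_output(show(toy_measurements()), "MeasurementSet")
})
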