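test_that("loadFluxModel reads the native TSV with derived bounds", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("R1\ta -> b\t\t\t200",
               "R2\tb <=> c\t\t\t"), f)
  m <- loadFluxModel(f)
  rx <- m@reactions
  expect_equal(rx$lb, c(0, -1000))
  expect_equal(rx$ub, c(200, 1000))
  bd <- setNames(m@metabolites$boundary, m@metabolites$id)
  # b is produced and consumed; a touches only one side; c is internal
  # because the reversible R2 counts it on both sides
  expect_false(bd[["b"]]); expect_true(bd[["a"]]); expect_false(bd[["c"]])
})

test_that("two capped producers split production 3:1", {
  m <- nadph_model()
  fba <- maximizeCofactor(m, "NADPH")
  expect_equal(fba$status, "optimal")
  expect_equal(fba$max_production, 4, tolerance = 1e-9)
  rep <- contributionFractions(m, fba)
  fr <- setNames(rep@producers$fraction, rep@producers$reaction)
  expect_equal(unname(fr["P1"]), 0.75, tolerance = 1e-9)
  expect_equal(unname(fr["P2"]), 0.25, tolerance = 1e-9)
  expect_equal(sum(rep@producers$fraction), 1, tolerance = 1e-12)
  expect_true(rep@uniqueOptimum)
  expect_equal(rep@maxProduction, 4)
  expect_output(show(rep), "ContributionReport")
})

test_that("consumers are reported separately from producers", {
  m <- nadph_model()
  # force consumption through C1 by balancing Z internally against a drain
  m@metabolites$boundary[m@metabolites$id == "Z"] <- TRUE
  m@reactions$lb[m@reactions$id == "C1"] <- 2
  fba <- maximizeCofactor(m, "NADPH")
  rep <- contributionFractions(m, fba)
  expect_equal(rep@consumers$reaction, "C1")
  expect_equal(rep@consumers$consumption, 2, tolerance = 1e-9)
  # fractions still sum to 1 over gross production
  expect_equal(sum(rep@producers$fraction), 1, tolerance = 1e-12)
})

test_that("degenerate optima are flagged as non-unique", {
  m <- new("FluxModel",
           metabolites = data.frame(id = c("X", "NADPH"),
                                    boundary = c(FALSE, FALSE)),
           reactions = data.frame(id = c("S1", "P1", "P2"),
                                  reversible = FALSE, lb = 0,
                                  ub = c(10, 10, 10)),
           stoichiometry = list(S1 = c(X = 1),
                                P1 = c(X = -1, NADPH = 1),
                                P2 = c(X = -1, NADPH = 1)),
           gpr = setNames(character(), character()))
  fba <- maximizeCofactor(m, "NADPH")
  expect_equal(fba$max_production, 10, tolerance = 1e-9)
  # P1 and P2 are interchangeable: the split among them is arbitrary
  rep <- contributionFractions(m, fba)
  expect_false(rep@uniqueOptimum)
})

test_that("maximizeCofactor validates the target and infeasible models", {
  expect_error(maximizeCofactor(nadph_model(), "missing"),
               "appears in no reaction")
  m <- nadph_model()
  # contradictory bounds on the producers make the polytope empty
  m@metabolites$boundary[m@metabolites$id == "NADPH"] <- FALSE
  m@reactions$lb[m@reactions$id == "P1"] <- 3
  m@reactions$ub[m@reactions$id == "C1"] <- 1
  expect_error(maximizeCofactor(m, "Z"), "infeasible")
})

test_that("contributionFractions refuses a zero-production optimum", {
  m <- nadph_model()
  m@reactions$ub[1:2] <- c(0, 0)
  m@reactions$lb[1:2] <- c(0, 0)
  fba <- maximizeCofactor(m, "NADPH")
  expect_equal(fba$max_production, 0)
  expect_error(contributionFractions(m, fba), "fractions are undefined")
})

test_that("expression ratios scale reaction capacities", {
  m <- sbml_toy <- new("FluxModel",
    metabolites = data.frame(id = c("a", "b"), boundary = c(TRUE, TRUE)),
    reactions = data.frame(id = c("R1", "R2"), reversible = FALSE,
                           lb = 0, ub = c(100, 100)),
    stoichiometry = list(R1 = c(a = -1, b = 1), R2 = c(a = -1, b = 1)),
    gpr = c(R1 = "g1 or g2", R2 = "g3 and g4"))
  m2 <- applyExpressionBounds(m, c(g1 = 6.3, g2 = 0.5, g3 = 2, g4 = 0.25))
  ub <- setNames(m2@reactions$ub, m2@reactions$id)
  expect_equal(unname(ub["R1"]), 630)  # max over isozymes
  expect_equal(unname(ub["R2"]), 25)   # min over complex subunits
  log <- attr(m2, "bounds_log")
  expect_equal(nrow(log), 2)
  # direct reaction-id keys work without GPR
  m3 <- applyExpressionBounds(m, c(R1 = 2))
  expect_equal(m3@reactions$ub, c(200, 100))
  expect_warning(applyExpressionBounds(m, c(nope = 2)), "unknown id")
  expect_error(applyExpressionBounds(m, c(g1 = -1)), "must be positive")
})

test_that("an SBML model runs through the full FBA pipeline", {
  f <- withr::local_tempfile(fileext = ".xml")
  m <- new("FluxModel",
           metabolites = data.frame(id = c("X", "NADPH", "Y", "Z"),
                                    boundary = c(TRUE, FALSE, TRUE, TRUE)),
           reactions = data.frame(id = c("P1", "P2", "C1"),
                                  reversible = FALSE,
                                  lb = 0, ub = c(3, 1, 10)),
           stoichiometry = list(P1 = c(X = -1, NADPH = 1, Y = 1),
                                P2 = c(X = -1, NADPH = 1),
                                C1 = c(NADPH = -1, Z = 1)),
           gpr = c(P1 = "gA", P2 = "gB"))
  writeSBML(m, f)
  m2 <- loadFluxModel(f)
  m2 <- applyExpressionBounds(m2, c(gA = 2))  # P1 capacity 3 -> 6
  fba <- maximizeCofactor(m2, "NADPH")
  expect_equal(fba$max_production, 7, tolerance = 1e-9)
  rep <- contributionFractions(m2, fba)
  fr <- setNames(rep@producers$fraction, rep@producers$reaction)
  expect_equal(unname(fr["P1"]), 6 / 7, tolerance = 1e-9)
})
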