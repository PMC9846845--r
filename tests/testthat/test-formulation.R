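# The logic encoding is checked exhaustively against the reference gate
# semantics: over every 0/1 assignment of (y_e, x_source, a_e) per edge plus
# the node state, the linear rows must be satisfiable exactly when a_e =
# y_e AND x_source for all edges and the gate allows the node state.
check_gate_exhaustively <- function(incoming) {
  rows <- encodeLogic("V", incoming)
  n_e <- nrow(incoming)
  vars <- c("x_V", paste0("y_", incoming$id), paste0("a_", incoming$id),
            paste0("x_", unique(incoming$source)))
  grid <- expand.grid(rep(list(0:1), length(vars)))
  names(grid) <- vars
  for (g in seq_len(nrow(grid))) {
    point <- unlist(grid[g, ])
    y <- point[paste0("y_", incoming$id)]
    a <- point[paste0("a_", incoming$id)]
    xs <- point[paste0("x_", incoming$source)]
    ok_and <- all(a == (y & xs))
    expected <- ok_and &&
      gate_allows(point[["x_V"]], live = a == 1, signs = incoming$sign)
    expect_identical(rows_satisfied(rows, point), expected,
                     label = paste("assignment", paste(point, collapse = "")))
  }
}

test_that("logic gate: single activation edge", {
  check_gate_exhaustively(data.frame(id = "e1", source = "U",
                                     sign = "activation"))
})

test_that("logic gate: activation vetoed by inhibition", {
  check_gate_exhaustively(data.frame(id = c("e1", "e2"),
                                     source = c("U1", "U2"),
                                     sign = c("activation", "inhibition")))
})

test_that("logic gate: two activators, one inhibitor", {
  check_gate_exhaustively(data.frame(id = c("e1", "e2", "e3"),
                                     source = c("U1", "U2", "U3"),
                                     sign = c("activation", "activation",
                                              "inhibition")))
})

test_that("logic gate: inhibitor-only target is free unless inhibited", {
  check_gate_exhaustively(data.frame(id = "e1", source = "U",
                                     sign = "inhibition"))
})

test_that("nodes without incoming edges get no gate rows", {
  expect_length(encodeLogic("V", data.frame(id = character(),
                                            source = character(),
                                            sign = character())), 0)
})

test_that("thermodynamic rule forces directions by the Gibbs sign", {
  r <- function(rev, dg) data.frame(id = "R", reversible = rev,
                                    delta_g = dg, flux_bound = 100)
  fwd <- encodeThermo(r(TRUE, -8))
  expect_equal(fwd$forced, "forward")
  expect_equal(c(fwd$lb, fwd$ub), c(0, 100))
  bwd <- encodeThermo(r(TRUE, 8))
  expect_equal(bwd$forced, "backward")
  expect_equal(c(bwd$lb, bwd$ub), c(-100, 0))
  blk <- encodeThermo(r(FALSE, 8))
  expect_equal(blk$forced, "blocked")
  expect_equal(c(blk$lb, blk$ub), c(0, 0))
  # unknown dg + reversible: free direction via binary d
  fr <- encodeThermo(r(TRUE, NA))
  expect_true(fr$needs_direction)
  expect_length(fr$rows, 2)
  # the tolerance widens the dead band
  expect_equal(encodeThermo(r(TRUE, -8), tau = 10)$needs_direction, TRUE)
  expect_equal(encodeThermo(r(FALSE, NA))$forced, "forward")
})

test_that("thermo direction rows enforce v sign against d", {
  r <- data.frame(id = "R", reversible = TRUE, delta_g = NA, flux_bound = 10)
  rows <- encodeThermo(r)$rows
  # d = 1: only forward flux allowed
  expect_true(rows_satisfied(rows, c(v_R = 5, d_R = 1)))
  expect_false(rows_satisfied(rows, c(v_R = -5, d_R = 1)))
  # d = 0: only backward
  expect_true(rows_satisfied(rows, c(v_R = -5, d_R = 0)))
  expect_false(rows_satisfied(rows, c(v_R = 5, d_R = 0)))
})

test_that("enzyme coupling gates flux and product/substrate ratios", {
  r <- data.frame(id = "R", reversible = FALSE, delta_g = -5, enzyme = "E",
                  flux_bound = 100)
  st <- c(A = -1, B = 1)
  cpl <- encodeEnzymeCoupling(r, st, "b_E", encoding = "big-M", big_m = 200)
  expect_length(cpl$bilinear, 0)
  rows <- cpl$rows
  # enzyme off: no flux, product down, substrate up
  expect_true(rows_satisfied(rows, c(v_R = 0, b_E = 0, c_B = 0.5, c_A = 2)))
  expect_false(rows_satisfied(rows, c(v_R = 1, b_E = 0, c_B = 0.5, c_A = 2)))
  expect_false(rows_satisfied(rows, c(v_R = 0, b_E = 0, c_B = 2, c_A = 2)))
  expect_false(rows_satisfied(rows, c(v_R = 0, b_E = 0, c_B = 0.5, c_A = 0.5)))
  # enzyme on: everything free within bounds
  expect_true(rows_satisfied(rows, c(v_R = 50, b_E = 1, c_B = 3, c_A = 0.2)))

  bil <- encodeEnzymeCoupling(r, st, "b_E", encoding = "bilinear")
  expect_length(bil$bilinear, 2)
  expect_length(bil$rows, 2)  # flux gating stays linear
  expect_error(encodeEnzymeCoupling(
    data.frame(id = "R", reversible = FALSE, delta_g = NA,
               enzyme = NA_character_, flux_bound = 1), st, NULL),
    "no linked enzyme")
})

test_that("mass balance covers exactly the internal metabolites", {
  rows <- encodeMassBalance(toy_network())
  expect_length(rows, 1)
  expect_equal(rows[[1]]$name, "mass_B")
  expect_equal(rows[[1]]$rel, "=")
  expect_equal(sort(rows[[1]]$coef), sort(c(v_R1 = 1, v_R2 = -1)))
})

test_that("buildProblem assembles the hand-counted toy model", {
  pr <- buildProblem(toy_network(), toy_measurements())
  # 3 x + 2 y + 2 a + 3 mN + 1 b + 3 c + 1 mM + 2 v + 1 q = 18 variables;
  # 9 gate + 6 misfit + 2 metabolite-error + 4 coupling + 4 activity +
  # 1 blockade + 1 mass balance = 27 rows
  expect_equal(modelSize(pr),
               c(n_variables = 18, n_constraints = 27, n_bilinear = 0,
                 n_linear = 27))
  expect_s4_class(pr, "MipProblem")
  expect_output(show(pr), "18 variables")
  # measured standalone enzyme is hard-fixed through its bounds
  v <- pr@variables
  expect_equal(unlist(v[v$name == "b_E1", c("lb", "ub")]),
               c(lb = 1, ub = 1))
  # non-removable edges are fixed on
  annot <- data.frame(id = "S1", effect = "oxidation-inhibits")
  nw <- assembleNetwork(toy_edges(), toy_reactions(),
                        redox_annotations = annot)
  pr2 <- buildProblem(nw)
  v2 <- pr2@variables
  expect_equal(unlist(v2[v2$name == "y_redox1", c("lb", "ub")]),
               c(lb = 1, ub = 1))
})

test_that("buildProblem validates weights and widens the ratio box", {
  nw <- toy_network()
  expect_error(buildProblem(nw, weights = c(1, 1)), "three non-negative")
  expect_error(buildProblem(nw, weights = c(1, -1, 0)), "three non-negative")
  ms <- new("MeasurementSet",
            proteins = data.frame(id = character(), ratio = numeric(),
                                  significant = logical()),
            metabolites = data.frame(id = "B", ratio = 500,
                                     significant = TRUE))
  expect_warning(pr <- buildProblem(nw, ms), "widening the box")
  expect_gte(pr@options$c_hi, 500)
})

test_that("bilinear encoding records product terms; linearize is exact", {
  pr <- buildProblem(toy_network(), toy_measurements(),
                     options = mipOptions(encoding = "bilinear"))
  expect_gt(length(pr@bilinear), 0)
  lin <- linearize(pr)
  expect_length(lin@bilinear, 0)
  expect_equal(lin@encoding, "big-M")
  # auxiliary w variables registered once per (binary, continuous) pair
  expect_true(any(grepl("^w_", lin@variables$name)))
  # linearize refuses an M below a continuous bound
  small <- pr
  small@bigM <- 1
  expect_error(linearize(small), "increase big_m")
  # no-op on an already linear problem
  prl <- buildProblem(toy_network(), toy_measurements())
  expect_identical(linearize(prl)@linear, prl@linear)
})

test_that("mipOptions defaults match the documented model parameters", {
  o <- mipOptions()
  expect_equal(o$fold_threshold, 1.5)
  expect_equal(o$tau, 0)
  expect_equal(o$c_lo, 0.01)
  expect_equal(o$c_hi, 100)
  expect_equal(o$encoding, "big-M")
  expect_true(o$propagate)
  expect_equal(o$eps_activity, 1e-3)
  expect_error(mipOptions(encoding = "quadratic"))
})
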