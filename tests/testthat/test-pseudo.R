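test_that("the near-optimal region records the threshold constraint", {
  toy <- make_toy_model(toy_spec(n_pathways = 2, yields = c(1, 1),
                                 uptake_limit = 10))
  reg <- build_near_optimal_region(toy$model, 0.90)
  expect_equal(reg$wild_type_optimum, 10, tolerance = 1e-6)
  expect_equal(unname(reg$lower[toy$model$biomass]), 9, tolerance = 1e-6)
  # threshold 1: only the optimal face remains, and it is still feasible
  reg1 <- build_near_optimal_region(toy$model, 1.0)
  lp <- linear_problem(rep(0, length(reg1$lower)), "minimize",
                       Aeq = as.matrix(toy$model$S),
                       beq = rep(0, length(toy$model$metabolites)),
                       lower = reg1$lower, upper = reg1$upper)
  expect_equal(solve_lp(lp)$status, "optimal")

  m0 <- toy$model
  m0$lower["EX_glc"] <- 0
  m0$upper["EX_glc"] <- 0
  expect_error(build_near_optimal_region(m0, 0.9), "zero")
})

test_that("the quadratic encoding has the block structure and 0/2 eigenvalues", {
  toy <- make_toy_model(toy_spec(n_pathways = 2, yields = c(1, 0.4),
                                 uptake_limit = 10))
  reg <- build_near_optimal_region(toy$model, 0.9)
  mm <- apply_mutation(toy$model, mutation("PWY1"))
  qp <- encode_pseudo_qp(reg, mm)
  n <- length(toy$model$reactions)
  expect_equal(dim(qp$Q), c(2 * n, 2 * n))
  ev <- eigen(qp$Q, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(abs(ev) < 1e-9 | abs(ev - 2) < 1e-9))
  # n = 1 special case printed in closed form
  ev1 <- eigen(matrix(c(1, -1, -1, 1), 2), only.values = TRUE)$values
  expect_equal(sort(ev1), c(0, 2))
  # objective arithmetic: ||p - q||^2 at chosen points
  z_same <- rep(1, 2 * n)
  expect_equal(as.numeric(t(z_same) %*% qp$Q %*% z_same), 0)
  z_unit <- c(1, rep(0, 2 * n - 1))
  expect_equal(as.numeric(t(z_unit) %*% qp$Q %*% z_unit), 1)
  # equality block is [[S,0],[0,S]]
  S <- as.matrix(toy$model$S)
  m <- nrow(S)
  expect_equal(qp$Aeq[1:m, 1:n], S, ignore_attr = TRUE)
  expect_equal(qp$Aeq[(m + 1):(2 * m), (n + 1):(2 * n)], S, ignore_attr = TRUE)
  expect_true(all(qp$Aeq[1:m, (n + 1):(2 * n)] == 0))
})

test_that("overlap is diagnosed by distance zero when the mutant stays near-optimal", {
  toy <- make_toy_model(toy_spec(n_pathways = 2, yields = c(1, 1),
                                 uptake_limit = 10))
  sol <- pseudo(toy$model, mutation("PWY1"))
  expect_true(sol$overlap)
  expect_equal(sol$distance, 0)
  expect_gte(sol$growth, 0.9 * 10 - 1e-6)
  # the full quadratic solve, without the LP pre-check, lands at ~0 too
  sol_forced <- pseudo(toy$model, mutation("PWY1"), overlap_check = FALSE)
  expect_lt(sol_forced$distance, 1e-4)
})

test_that("polytope distances match the alternating-projection oracle", {
  for (toy in toy_fixture_family(10)) {
    m <- toy$model
    reg <- build_near_optimal_region(m, 0.9)
    mm <- apply_mutation(m, mutation("PWY1"))
    sol <- pseudo(m, mm, 0.9, overlap_check = FALSE)
    orc <- oracle_pseudo_distance(as.matrix(m$S), reg$lower, reg$upper,
                                  as.matrix(mm$S), mm$lower, mm$upper,
                                  start = fba(mm)$flux)
    expect_equal(sol$distance, orc$distance, tolerance = 1e-4)
    # feasibility of both returned points
    expect_lt(max(abs(as.matrix(m$S) %*% sol$p)), 1e-6)
    expect_lt(max(abs(as.matrix(mm$S) %*% sol$q)), 1e-6)
    expect_true(all(sol$p >= reg$lower - 1e-6 & sol$p <= reg$upper + 1e-6))
    expect_true(all(sol$q >= mm$lower - 1e-6 & sol$q <= mm$upper + 1e-6))
    expect_equal(sol$distance, sqrt(sum((sol$p - sol$q)^2)), tolerance = 1e-6)
  }
})

test_that("quadratic and conic formulations agree to 1e-6 relative", {
  for (toy in toy_fixture_family(10)) {
    m <- toy$model
    dq <- pseudo(m, mutation("PWY1"), formulation = "qp")$distance
    ds <- pseudo(m, mutation("PWY1"), formulation = "socp")$distance
    expect_lt(abs(dq - ds), 1e-6 * max(1, dq))
  }
})

test_that("distance grows with the threshold and vanishes below the mutant ratio", {
  toy <- make_toy_model(toy_spec(n_pathways = 2, yields = c(1, 0.85),
                                 uptake_limit = 10, secretion = FALSE))
  # mutant optimum ratio = 0.85: thresholds below overlap, above separate
  d_low <- pseudo(toy$model, mutation("PWY1"), threshold = 0.80)
  d_mid <- pseudo(toy$model, mutation("PWY1"), threshold = 0.90)
  d_high <- pseudo(toy$model, mutation("PWY1"), threshold = 0.95)
  expect_true(d_low$overlap)
  expect_false(d_mid$overlap)
  expect_gt(d_high$distance, d_mid$distance - 1e-9)
  expect_gt(d_mid$distance, 0)
})

test_that("growth predictions sandwich between MOMA and FBA across the suite", {
  for (toy in toy_fixture_family(10)) {
    m <- toy$model
    wt <- fba(m, parsimonious = TRUE)
    for (tag in names(make_mutation_suite(toy, 0.9))) {
      mut <- make_mutation_suite(toy, 0.9)[[tag]]$mutation
      mm <- apply_mutation(m, mut)
      g_fba <- fba(mm)$growth
      if (!is.finite(g_fba)) next  # infeasible mutant: no growth to order
      g_moma <- moma(mm, wt$flux)$growth
      g_pseudo <- pseudo(m, mm, 0.9)$growth
      expect_lte(g_moma, g_pseudo + 1e-5)
      expect_lte(g_pseudo, g_fba + 1e-5)
    }
  }
})

test_that("the polytope distance never exceeds the MOMA distance", {
  # the MOMA target (parsimonious WT point) lies inside the near-optimal
  # region, so projecting the whole region cannot do worse
  for (toy in toy_fixture_family(6)) {
    m <- toy$model
    wt <- fba(m, parsimonious = TRUE)$flux
    mm <- apply_mutation(m, mutation("PWY1"))
    d_moma <- moma(mm, wt)$distance
    d_pseudo <- pseudo(m, mm, 0.9)$distance
    expect_lte(d_pseudo, d_moma + 1e-6)
  }
})

test_that("an infeasible mutant polytope surfaces as status infeasible", {
  m <- chain_model()
  m$lower["BIOMASS"] <- 5
  sol <- pseudo(m, mutation("EX_glc"))
  expect_equal(sol$status, "infeasible")
})

test_that("flux normalisation rescales the prediction by the uptake rate", {
  toy <- make_toy_model(toy_spec(n_pathways = 2, yields = c(1, 0.4),
                                 uptake_limit = 10))
  raw <- pseudo(toy$model, mutation("PWY1"))
  nrm <- pseudo(toy$model, mutation("PWY1"), normalize = "EX_glc")
  rate <- abs(raw$q[["EX_glc"]])
  expect_equal(unname(nrm$q), unname(raw$q) / rate, tolerance = 1e-8)
})
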