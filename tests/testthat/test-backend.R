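test_that("linear programs solve box, equality, and infeasible cases", {
  # max x over [0, 10]
  lp <- linear_problem(1, "maximize", lower = 0, upper = 10)
  res <- solve_lp(lp)
  expect_equal(res$status, "optimal")
  expect_equal(res$objective, 10, tolerance = 1e-8)

  # x - y = 0, maximize x, y in [0, 3]
  lp2 <- linear_problem(c(1, 0), "maximize", Aeq = matrix(c(1, -1), 1, 2),
                        beq = 0, lower = c(0, 0), upper = c(10, 3))
  res2 <- solve_lp(lp2)
  expect_equal(res2$objective, 3, tolerance = 1e-8)
  expect_equal(res2$x[1], res2$x[2], tolerance = 1e-8)

  # contradictory equalities
  lp3 <- linear_problem(c(1, 0), "maximize",
                        Aeq = rbind(c(1, 1), c(1, 1)), beq = c(1, 2),
                        lower = c(0, 0), upper = c(5, 5))
  expect_equal(solve_lp(lp3)$status, "infeasible")
})

test_that("linear problems validate their inputs", {
  expect_error(linear_problem(1, lower = 0, upper = Inf), "finite")
  expect_error(linear_problem(1, lower = 2, upper = 1), "exceeds")
  expect_error(linear_problem(c(1, 1), Aeq = matrix(1, 1, 1), beq = 1,
                              lower = c(0, 0), upper = c(1, 1)), "column count")
})

test_that("quadratic programs reproduce closed-form projections", {
  # min (x-3)^2 over [0,10]: objective x^2 - 6x + 9 -> Q=1, c=-6 (constant dropped)
  qp <- quadratic_problem(matrix(1), c = -6, lower = 0, upper = 10)
  res <- solve_qp(qp)
  expect_equal(res$x, 3, tolerance = 1e-7)

  # active bound: min (x-3)^2 over [0,2] -> x=2, (x-3)^2 = 1
  qp2 <- quadratic_problem(matrix(1), c = -6, lower = 0, upper = 2)
  res2 <- solve_qp(qp2)
  expect_equal(res2$x, 2, tolerance = 1e-7)
  expect_equal(res2$objective + 9, 1, tolerance = 1e-7)

  expect_error(quadratic_problem(matrix(c(1, 0, 0, -1), 2), lower = c(0, 0),
                                 upper = c(1, 1)), "positive semidefinite")
})

test_that("box QPs match constructed-solution oracles over random instances", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 5
    # diagonal case: the box-constrained minimiser is the coordinate-wise clamp
    d <- runif(n, 0.5, 3)
    target <- runif(n, -2, 3)
    lo <- rep(0, n)
    up <- rep(1, n)
    qp <- quadratic_problem(diag(d), c = -2 * d * target, lower = lo, upper = up)
    res <- solve_qp(qp)
    expect_equal(res$x, pmin(pmax(target, lo), up), tolerance = 1e-6)

    # dense PD case with interior optimum constructed to land inside the box
    A <- matrix(rnorm(n * n), n)
    Q <- crossprod(A) + diag(n)
    xstar <- runif(n, 0.2, 0.8)
    qp2 <- quadratic_problem(Q, c = -2 * as.numeric(Q %*% xstar),
                             lower = lo, upper = up)
    res2 <- solve_qp(qp2)
    expect_equal(res2$x, xstar, tolerance = 1e-6)
  }
})

test_that("the conic epigraph solve matches interval geometry and the QP route", {
  # 1-D: p in [0,1], q in [2,3] -> distance 1
  enc <- conic_encoding(1, Aeq_p = matrix(0, 0, 1), beq_p = numeric(0),
                        Aeq_q = matrix(0, 0, 1), beq_q = numeric(0),
                        lower_p = 0, upper_p = 1, lower_q = 2, upper_q = 3)
  res <- solve_socp(enc)
  expect_equal(res$status, "optimal")
  expect_equal(res$objective, 1, tolerance = 1e-7)

  # cross-formulation on a random 2-D instance with separated boxes
  for (seed in 1:5) {
    set.seed(seed)
    sep <- runif(2, 2, 4)
    enc2 <- conic_encoding(2, Aeq_p = matrix(0, 0, 2), beq_p = numeric(0),
                           Aeq_q = matrix(0, 0, 2), beq_q = numeric(0),
                           lower_p = c(0, 0), upper_p = c(1, 1),
                           lower_q = sep, upper_q = sep + 1)
    socp_d <- solve_socp(enc2)$objective
    I2 <- diag(2)
    qp <- quadratic_problem(rbind(cbind(I2, -I2), cbind(-I2, I2)),
                            lower = c(0, 0, sep), upper = c(1, 1, sep + 1))
    qp_d <- sqrt(max(solve_qp(qp)$objective, 0))
    expect_equal(socp_d, qp_d, tolerance = 1e-6)
  }
})
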