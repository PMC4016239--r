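#' @importFrom stats median quantile rnorm runif sd setNames cor pnorm
#' @importFrom utils head modifyList write.csv read.csv
NULL

# ---------------------------------------------------------------------------
# A uniform contract over the three problem classes the method needs: linear
# programs (growth maximisation, 1-norm pass, variability), convex quadratic
# programs (projection and polytope-distance objectives), and the equivalent
# second-order-cone formulation. Science modules never talk to a solver
# directly; they build one of these problem objects and call solve_*().
# ---------------------------------------------------------------------------

#' Construct a linear program
#'
#' Encodes `optimise c'x subject to Aeq x = beq, lower <= x <= upper`.
#' All inequality structure needed by the flux models (growth thresholds,
#' variability floors, pinned fluxes) reduces to variable bounds, so the
#' contract carries equalities and bounds only.
#'
#' @param objective numeric vector of objective coefficients.
#' @param sense `"maximize"` or `"minimize"`.
#' @param Aeq equality constraint matrix (may have zero rows).
#' @param beq equality right-hand side.
#' @param lower,upper finite variable bounds.
#' @return an object of class `linear_problem`.
#' @export
linear_problem <- function(objective, sense = c("maximize", "minimize"),
                           Aeq = NULL, beq = NULL, lower, upper) {
  sense <- match.arg(sense)
  n <- length(objective)
  if (is.null(Aeq)) {
    Aeq <- matrix(0, 0, n)
    beq <- numeric(0)
  }
  Aeq <- as.matrix(Aeq)
  if (ncol(Aeq) != n) stop("Aeq column count must equal objective length")
  if (nrow(Aeq) != length(beq)) stop("beq length must equal nrow(Aeq)")
  if (length(lower) != n || length(upper) != n) stop("bounds must have length n")
  if (any(!is.finite(c(lower, upper)))) {
    stop("linear_problem requires finite bounds; apply a default bound first")
  }
  if (any(lower > upper + 1e-12)) stop("lower bound exceeds upper bound")
  if (any(!is.finite(beq))) stop("equality rhs must be finite")
  structure(list(objective = as.numeric(objective), sense = sense,
                 Aeq = Aeq, beq = as.numeric(beq),
                 lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "linear_problem")
}

# Euclidean projection of a point onto {Aeq x = beq, lower <= x <= upper},
# via the dual active-set method. Returns NULL when the solver reports an
# inconsistent constraint system (infeasible, or numerically degenerate
# when projecting from far away — callers retry from closer).
qp_project <- function(pt, Amat, bvec, meq) {
  n <- length(pt)
  tryCatch(quadprog::solve.QP(Dmat = diag(2, n), dvec = 2 * pt,
                              Amat = Amat, bvec = bvec, meq = meq)$solution,
           error = function(e) NULL)
}

#' Solve a linear program
#'
#' Backed by the proximal-point algorithm over the dual active-set quadratic
#' solver of `quadprog`: each step projects `x_k - t * c` back onto the
#' feasible polytope, which for a polyhedral objective converges to an exact
#' optimum in finitely many steps. The step `t` adapts downward when a
#' projection from far away hits degenerate faces.
#'
#' @param problem a [linear_problem()].
#' @param tol relative step tolerance declaring convergence.
#' @param maxiter proximal iteration cap.
#' @return a `solve_result` with fields `status` (one of `optimal`,
#'   `infeasible`, `numeric_failure`), `x`, `objective`, `diagnostics`.
#' @export
solve_lp <- function(problem, tol = 1e-10, maxiter = 500L) {
  stopifnot(inherits(problem, "linear_problem"))
  cc <- problem$objective
  if (problem$sense == "maximize") cc <- -cc
  full_n <- length(cc)
  # substitute out variables pinned by their bounds: smaller, much better
  # conditioned subproblems for the active-set inner solver
  fixed <- (problem$upper - problem$lower) < 1e-12
  x_full <- problem$lower
  if (any(fixed)) {
    free <- which(!fixed)
    if (!length(free)) {
      resid <- if (nrow(problem$Aeq))
        max(abs(problem$Aeq %*% x_full - problem$beq)) else 0
      if (resid > 1e-8 * max(1, max(abs(problem$beq)))) {
        return(solve_result("infeasible"))
      }
      return(solve_result("optimal", x = x_full,
                          objective = sum(problem$objective * x_full),
                          diagnostics = list(equality_residual = resid)))
    }
    beq <- problem$beq -
      as.numeric(problem$Aeq[, fixed, drop = FALSE] %*% x_full[fixed])
    Aeq <- problem$Aeq[, free, drop = FALSE]
    cc <- cc[free]
    l <- problem$lower[free]
    u <- problem$upper[free]
  } else {
    free <- seq_len(full_n)
    Aeq <- problem$Aeq
    beq <- problem$beq
    l <- problem$lower
    u <- problem$upper
  }
  n <- length(cc)
  Amat <- cbind(t(Aeq), diag(n), -diag(n))
  bvec <- c(beq, l, -u)
  meq <- nrow(Aeq)

  # phase 1: find a feasible point by projecting a few candidate starts
  x <- NULL
  for (start in list(pmin(pmax(rep(0, n), l), u), (l + u) / 2, l, u)) {
    x <- qp_project(start, Amat, bvec, meq)
    if (!is.null(x)) break
  }
  if (is.null(x)) return(solve_result("infeasible"))

  finish <- function(x) {
    x_full[free] <- x
    pmin(pmax(x_full, problem$lower), problem$upper)
  }

  radius <- max(abs(c(l, u))) + 1
  t_step <- 100 * radius / max(1, max(abs(cc)))
  it <- 0L
  shrink <- 0L
  step <- Inf
  while (it < maxiter) {
    it <- it + 1L
    xn <- qp_project(x - t_step * cc, Amat, bvec, meq)
    if (is.null(xn)) {
      t_step <- t_step / 10
      shrink <- shrink + 1L
      if (shrink > 24L) {
        return(solve_result("numeric_failure",
                            diagnostics = list(message = "projection failed at all step sizes")))
      }
      next
    }
    step <- sqrt(sum((xn - x)^2))
    x <- xn
    if (step < tol * (1 + sqrt(sum(x^2)))) break
  }
  if (step >= 1e-6 * (1 + sqrt(sum(x^2)))) {
    return(solve_result("numeric_failure",
                        diagnostics = list(message = "proximal iteration did not converge",
                                           iterations = it, last_step = step)))
  }
  xf <- finish(x)
  resid <- if (nrow(problem$Aeq))
    max(abs(problem$Aeq %*% xf - problem$beq)) else 0
  solve_result("optimal", x = xf, objective = sum(problem$objective * xf),
               diagnostics = list(equality_residual = resid, iterations = it,
                                  step_shrinks = shrink))
}

#' Construct a convex quadratic program
#'
#' Encodes `minimize x'Qx + c'x subject to Aeq x = beq, lower <= x <= upper`,
#' with `Q` symmetric positive semidefinite. The polytope-distance objective
#' uses the block matrix `[[I,-I],[-I,I]]` whose eigenvalues are only 0 and 2;
#' semidefiniteness is checked, not assumed.
#'
#' @param Q symmetric PSD matrix (the objective is `x'Qx + c'x`, no 1/2).
#' @param c linear coefficient vector.
#' @inheritParams linear_problem
#' @param psd_tol eigenvalue tolerance below which `Q` is rejected as
#'   indefinite.
#' @return an object of class `quadratic_problem`.
#' @export
quadratic_problem <- function(Q, c = NULL, Aeq = NULL, beq = NULL,
                              lower, upper, psd_tol = 1e-8) {
  Q <- as.matrix(Q)
  n <- nrow(Q)
  if (is.null(c)) c <- numeric(n)
  if (max(abs(Q - t(Q))) > 1e-10) stop("quadratic matrix must be symmetric")
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -psd_tol * max(1, max(abs(ev)))) {
    stop("quadratic matrix is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")")
  }
  if (is.null(Aeq)) {
    Aeq <- matrix(0, 0, n)
    beq <- numeric(0)
  }
  Aeq <- as.matrix(Aeq)
  stopifnot(ncol(Aeq) == n, nrow(Aeq) == length(beq),
            length(lower) == n, length(upper) == n)
  structure(list(Q = Q, c = as.numeric(c), Aeq = Aeq, beq = as.numeric(beq),
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 eigenvalues = ev),
            class = "quadratic_problem")
}

#' Solve a convex quadratic program
#'
#' A proximal-point outer loop around the dual active-set method of
#' `quadprog::solve.QP`: each iterate solves the strictly convex problem
#' `x'Qx + c'x + rho * ||x - x_k||^2`, whose fixed points are exactly the
#' minimisers of the original program — including semidefinite-but-singular
#' objectives such as the polytope-distance matrix, which has a null space.
#' `rho` escalates automatically when the inner solver struggles on
#' degenerate faces; any positive value converges. Convergence is checked on
#' the iterate step.
#'
#' @param problem a [quadratic_problem()].
#' @param tol optimality tolerance on the proximal step norm.
#' @param rho proximal regularisation weight for singular objectives.
#' @param max_prox maximum proximal iterations.
#' @param start optional starting point for the proximal loop.
#' @return a `solve_result`; `objective` is `x'Qx + c'x` at the solution.
#' @export
solve_qp <- function(problem, tol = 1e-10, rho = 1e-6, max_prox = 500L,
                     start = NULL) {
  stopifnot(inherits(problem, "quadratic_problem"))
  full_n <- nrow(problem$Q)
  ev_max <- max(abs(problem$eigenvalues))

  # substitute out variables pinned by their bounds (knockouts, maintenance)
  fixed <- is.finite(problem$lower) & is.finite(problem$upper) &
    (problem$upper - problem$lower) < 1e-12
  free <- which(!fixed)
  x_full <- ifelse(fixed, problem$lower, NA_real_)
  if (!length(free)) {
    resid <- if (nrow(problem$Aeq))
      max(abs(problem$Aeq %*% problem$lower - problem$beq)) else 0
    if (resid > 1e-8 * max(1, max(abs(problem$beq)))) {
      return(solve_result("infeasible"))
    }
    x <- problem$lower
    return(solve_result("optimal", x = x,
                        objective = as.numeric(t(x) %*% problem$Q %*% x + sum(problem$c * x))))
  }
  Q <- problem$Q[free, free, drop = FALSE]
  cc <- problem$c[free]
  if (any(fixed)) {
    v <- problem$lower[fixed]
    cc <- cc + 2 * as.numeric(problem$Q[free, fixed, drop = FALSE] %*% v)
    Aeq <- problem$Aeq[, free, drop = FALSE]
    beq <- problem$beq -
      as.numeric(problem$Aeq[, fixed, drop = FALSE] %*% v)
  } else {
    Aeq <- problem$Aeq
    beq <- problem$beq
  }
  n <- length(free)
  lo <- problem$lower[free]
  up <- problem$upper[free]
  keep_lo <- is.finite(lo)
  keep_up <- is.finite(up)
  Amat <- cbind(t(Aeq),
                diag(n)[, keep_lo, drop = FALSE],
                -diag(n)[, keep_up, drop = FALSE])
  bvec <- c(beq, lo[keep_lo], -up[keep_up])
  meq <- nrow(Aeq)

  qp_once <- function(D, d) {
    tryCatch(quadprog::solve.QP(Dmat = D, dvec = d, Amat = Amat,
                                bvec = bvec, meq = meq)$solution,
             error = function(e) NULL)
  }
  obj_val <- function(x) as.numeric(t(x) %*% problem$Q %*% x + sum(problem$c * x))

  # establish feasibility first: a failed projection from several starts
  # distinguishes an empty polytope from mere numerical degeneracy
  x_k <- if (!is.null(start)) {
    qp_project(as.numeric(start)[free], Amat, bvec, meq)
  } else NULL
  if (is.null(x_k)) {
    lo_f <- ifelse(keep_lo, lo, -1)
    up_f <- ifelse(keep_up, up, 1)
    for (s in list(pmin(pmax(rep(0, n), lo_f), up_f), (lo_f + up_f) / 2, lo_f)) {
      x_k <- qp_project(s, Amat, bvec, meq)
      if (!is.null(x_k)) break
    }
  }
  if (is.null(x_k)) return(solve_result("infeasible"))

  # proximal-point iteration: x_{k+1} minimises x'Qx + c'x + rho||x - x_k||^2
  # (strictly convex for any rho > 0); its fixed points are exactly the
  # minimisers of the original PSD program. rho escalates on numerical
  # failure — any positive value converges, larger values condition better.
  rho_k <- rho * max(1, ev_max)
  it <- 0L
  escal <- 0L
  step <- Inf
  while (it < max_prox) {
    it <- it + 1L
    xn <- qp_once(2 * Q + 2 * rho_k * diag(n), -cc + 2 * rho_k * x_k)
    if (is.null(xn)) {
      rho_k <- rho_k * 10
      escal <- escal + 1L
      if (escal > 12L) {
        return(solve_result("numeric_failure",
                            diagnostics = list(message = "proximal QP failed at all regularisations")))
      }
      next
    }
    step <- sqrt(sum((xn - x_k)^2))
    x_k <- xn
    if (step <= tol * (1 + sqrt(sum(x_k^2)))) break
  }
  if (step > 1e-6 * (1 + sqrt(sum(x_k^2)))) {
    return(solve_result("numeric_failure",
                        diagnostics = list(message = "proximal iteration did not converge",
                                           iterations = it, last_step = step)))
  }
  x_full[free] <- x_k
  x_full <- pmin(pmax(x_full, problem$lower), problem$upper)
  solve_result("optimal", x = x_full, objective = obj_val(x_full),
               diagnostics = list(iterations = it, last_step = step,
                                  rho = rho_k,
                                  equality_residual = eq_residual(problem, x_full)))
}

eq_residual <- function(problem, x) {
  if (nrow(problem$Aeq) == 0) return(0)
  max(abs(problem$Aeq %*% x - problem$beq))
}

#' Construct a second-order-cone encoding of a polytope-distance problem
#'
#' Variables are two flux vectors `p` and `q` (each constrained by its own
#' equalities and bounds), a difference vector `x = p - q`, and a scalar
#' `z_dist` constrained to the quadratic cone `z_dist >= ||x||`. Minimising
#' `z_dist` yields the Euclidean distance directly, with no square root. The
#' linkage `x = p - q` is exact, so `x` is eliminated by substitution before
#' the solve; the cone constraint is kept on `(p - q, z_dist)`.
#'
#' @param n flux dimension (length of `p` and of `q`).
#' @param Aeq_p,beq_p equality constraints on `p` (mass balance).
#' @param Aeq_q,beq_q equality constraints on `q`.
#' @param lower_p,upper_p,lower_q,upper_q bounds.
#' @param start_p,start_q optional feasible starting points.
#' @return an object of class `conic_encoding`.
#' @export
conic_encoding <- function(n, Aeq_p, beq_p, Aeq_q, beq_q,
                           lower_p, upper_p, lower_q, upper_q,
                           start_p = NULL, start_q = NULL) {
  stopifnot(ncol(Aeq_p) == n, ncol(Aeq_q) == n,
            length(lower_p) == n, length(upper_q) == n)
  structure(list(n = n,
                 Aeq_p = as.matrix(Aeq_p), beq_p = as.numeric(beq_p),
                 Aeq_q = as.matrix(Aeq_q), beq_q = as.numeric(beq_q),
                 lower_p = lower_p, upper_p = upper_p,
                 lower_q = lower_q, upper_q = upper_q,
                 start_p = start_p, start_q = start_q),
            class = "conic_encoding")
}

#' Solve the second-order-cone formulation
#'
#' Solved with sequential least-squares quadratic programming
#' (`nloptr`, algorithm `NLOPT_LD_SLSQP`) on the smooth epigraph form:
#' minimise `z` subject to the linear equalities, the bounds, and
#' `||p - q|| - z <= 0`. The cone constraint gradient is smooth wherever
#' `p != q`; the degenerate overlapping case is detected upstream by an exact
#' linear-programming test and never reaches this solver by default.
#'
#' @param encoding a [conic_encoding()].
#' @param tol relative convergence tolerance.
#' @param maxeval iteration cap.
#' @return a `solve_result`; `x` holds `c(p, q, z_dist)` and `objective` is
#'   the minimised `z_dist`.
#' @export
solve_socp <- function(encoding, tol = 1e-12, maxeval = 5000L) {
  stopifnot(inherits(encoding, "conic_encoding"))
  n <- encoding$n
  zmax <- sqrt(sum(pmax(abs(encoding$upper_p - encoding$lower_q),
                        abs(encoding$upper_q - encoding$lower_p))^2)) + 1
  p0 <- if (is.null(encoding$start_p)) (encoding$lower_p + encoding$upper_p) / 2 else encoding$start_p
  q0 <- if (is.null(encoding$start_q)) (encoding$lower_q + encoding$upper_q) / 2 else encoding$start_q
  z0 <- sqrt(sum((p0 - q0)^2)) + 1
  x0 <- c(p0, q0, z0)

  mp <- nrow(encoding$Aeq_p)
  mq <- nrow(encoding$Aeq_q)
  Aeq_full <- rbind(cbind(encoding$Aeq_p, matrix(0, mp, n), rep(0, mp)),
                    cbind(matrix(0, mq, n), encoding$Aeq_q, rep(0, mq)))
  beq_full <- c(encoding$beq_p, encoding$beq_q)

  eval_f <- function(v) list(objective = v[2 * n + 1],
                             gradient = c(rep(0, 2 * n), 1))
  eval_g_eq <- function(v) {
    list(constraints = as.numeric(Aeq_full %*% v - beq_full),
         jacobian = Aeq_full)
  }
  eval_g_ineq <- function(v) {
    d <- v[1:n] - v[(n + 1):(2 * n)]
    nd <- sqrt(sum(d^2))
    nd_safe <- max(nd, 1e-12)
    list(constraints = nd - v[2 * n + 1],
         jacobian = matrix(c(d / nd_safe, -d / nd_safe, -1), nrow = 1))
  }
  res <- tryCatch(
    nloptr::nloptr(x0 = x0, eval_f = eval_f,
                   eval_g_eq = eval_g_eq, eval_g_ineq = eval_g_ineq,
                   lb = c(encoding$lower_p, encoding$lower_q, 0),
                   ub = c(encoding$upper_p, encoding$upper_q, zmax),
                   opts = list(algorithm = "NLOPT_LD_SLSQP",
                               xtol_rel = tol, ftol_rel = tol,
                               maxeval = maxeval)),
    error = function(e) e)
  if (inherits(res, "error")) {
    return(solve_result("numeric_failure",
                        diagnostics = list(message = conditionMessage(res))))
  }
  v <- res$solution
  eqres <- if (nrow(Aeq_full)) max(abs(Aeq_full %*% v - beq_full)) else 0
  ok <- res$status > 0 && res$status != 5 && eqres < 1e-6
  if (!ok) {
    return(solve_result("numeric_failure",
                        diagnostics = list(status = res$status,
                                           message = res$message,
                                           equality_residual = eqres)))
  }
  solve_result("optimal", x = v, objective = v[2 * n + 1],
               diagnostics = list(iterations = res$iterations,
                                  equality_residual = eqres,
                                  nlopt_status = res$status))
}

solve_result <- function(status, x = NULL, objective = NA_real_,
                         diagnostics = list()) {
  structure(list(status = status, x = x, objective = objective,
                 diagnostics = diagnostics),
            class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat("<solve_result> status:", x$status)
  if (x$status == "optimal") cat("  objective:", format(x$objective, digits = 10))
  cat("\n")
  invisible(x)
}
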