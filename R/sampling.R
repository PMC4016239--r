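# ---------------------------------------------------------------------------
# Uniform sampling of the near-optimal flux polytope by artificially-centered
# hit-and-run (ACHR). Warmup points are LP optima of random directions (they
# sit on extreme vertices/faces); the chain starts at their centroid, picks
# directions as (random stored point - running center), and draws the next
# point uniformly from the feasible chord. Because every direction is a
# difference of mass-balanced points, every proposal stays in the null space
# of S by construction. Convergence is monitored with the mixed fraction:
# warmup points are split at the median of a designated flux, and the
# fraction of chains now on the opposite side of that median approaches 1/2
# at equilibrium.
# ---------------------------------------------------------------------------

region_polytope <- function(region) {
  if (inherits(region, "near_optimal_region")) {
    list(S = as.matrix(region$model$S), lower = region$lower,
         upper = region$upper, reactions = region$model$reactions)
  } else if (inherits(region, "metabolic_model")) {
    list(S = as.matrix(region$S), lower = region$lower,
         upper = region$upper, reactions = region$reactions)
  } else stop("region must be a near_optimal_region or metabolic_model")
}

nullspace_basis <- function(S) {
  n <- ncol(S)
  if (nrow(S) == 0) return(diag(n))
  sv <- svd(S, nu = 0, nv = n)
  tol <- max(dim(S)) * max(sv$d, 0) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (rank == n) return(matrix(0, n, 0))
  sv$v[, (rank + 1):n, drop = FALSE]
}

# Affine parameterisation of {S x = 0, x_pinned = bound}: an anchor point x0
# satisfying the equalities (least-squares projection of `pt`) plus an
# orthonormal basis N of directions keeping both S x and the pinned
# coordinates invariant. Chains moving as x0 + N y can never disturb a
# pinned flux, however the running center drifts numerically.
polytope_chart <- function(poly, pt, pin_tol = 1e-9) {
  n <- length(poly$lower)
  pinned <- which(poly$upper - poly$lower < pin_tol)
  A <- rbind(poly$S, diag(n)[pinned, , drop = FALSE])
  b <- c(rep(0, nrow(poly$S)), (poly$lower[pinned] + poly$upper[pinned]) / 2)
  # x0 = argmin ||x - pt|| s.t. A x = b
  sv <- svd(A)
  dtol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > dtol
  Apinv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  x0 <- pt - as.numeric(Apinv %*% (A %*% pt - b))
  list(x0 = x0, N = nullspace_basis(A), pinned = pinned)
}

#' Warmup points on the boundary of a flux polytope
#'
#' Each point maximises a random direction drawn uniformly on the unit
#' sphere, so the set samples the extreme vertices of the region. Failed
#' solves are retried with a fresh direction up to `retries` times.
#'
#' @param region a `near_optimal_region` (or a `metabolic_model`, sampled
#'   over its full polytope).
#' @param count number of points (>= 2).
#' @param seed integer seed; the point set is bit-reproducible.
#' @param retries per-point retry limit on LP failure.
#' @return matrix, `count` rows x one column per reaction.
#' @export
warmup_points <- function(region, count, seed = 1L, retries = 5L) {
  stopifnot(count >= 2)
  poly <- region_polytope(region)
  n <- length(poly$lower)
  set.seed(seed)
  pts <- matrix(NA_real_, count, n, dimnames = list(NULL, poly$reactions))
  for (k in seq_len(count)) {
    ok <- FALSE
    for (try in seq_len(retries)) {
      d <- rnorm(n)
      d <- d / sqrt(sum(d^2))
      lp <- linear_problem(objective = d, sense = "maximize",
                           Aeq = poly$S, beq = rep(0, nrow(poly$S)),
                           lower = poly$lower, upper = poly$upper)
      res <- solve_lp(lp)
      if (res$status == "optimal") {
        pts[k, ] <- res$x
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("warmup LP failed after ", retries, " retries (point ", k, ")")
  }
  pts
}

#' Mixed fraction of a hit-and-run chain
#'
#' The warmup points are partitioned into two sets at the median value of a
#' designated flux. As the chains move, the mixed fraction is the share of
#' points currently on the opposite side of that median from where they
#' started; it approaches 1/2 asymptotically, and a chain is conventionally
#' declared mixed slightly past the asymptote (0.53 by default in
#' [achr_sample()]).
#'
#' @param current numeric vector: current values of the designated flux, one
#'   per chain (length 0 returns 0 — nothing has crossed).
#' @param initial_side logical vector: each chain's starting side
#'   (`value > median`).
#' @param median_value the partition value.
#' @return crossing fraction in `[0, 1]`.
#' @export
mixed_fraction <- function(current, initial_side, median_value) {
  if (length(current) == 0) return(0)
  stopifnot(length(current) == length(initial_side))
  mean((current > median_value) != initial_side)
}

# choose a flux coordinate whose warmup values straddle their median with
# genuine spread (pinned fluxes carry ~1e-16 projection noise and must not
# be used to label chain sides)
pick_partition_flux <- function(W, min_spread = 1e-6) {
  spread <- apply(W, 2, function(v) diff(range(v)))
  for (j in order(spread, decreasing = TRUE)) {
    if (spread[j] <= min_spread * max(1, max(abs(W[, j])))) break
    med <- median(W[, j])
    # warmup points are vertices and often sit exactly on the median value;
    # points on the line would get noise-assigned sides, so split mid-range
    if (min(abs(W[, j] - med)) < 1e-9 * max(1, max(abs(W[, j])))) {
      med <- mean(range(W[, j]))
    }
    side <- W[, j] > med
    if (any(side) && any(!side)) return(list(j = j, median = med, side = side))
  }
  stop("no flux coordinate splits the warmup set; region may be a point")
}

# One hit-and-run move in chart coordinates y (flux x = x0 + N y, so mass
# balance and pinned fluxes hold identically for every proposal). The chord
# is computed on the flux-space bounds of the free coordinates through N.
achr_step <- function(y, center_y, pool_y, chart, lower, upper,
                      max_dir_tries = 20L) {
  N <- chart$N
  x <- chart$x0 + drop(N %*% y)
  free <- chart$free
  for (try in seq_len(max_dir_tries)) {
    r <- pool_y[sample.int(nrow(pool_y), 1L), ]
    dy <- r - center_y
    nd <- sqrt(sum(dy^2))
    if (nd < 1e-12) next
    dy <- dy / nd
    dx <- drop(N %*% dy)
    act <- free & abs(dx) > 1e-12
    if (!any(act)) next
    t_lo <- (lower[act] - x[act]) / dx[act]
    t_hi <- (upper[act] - x[act]) / dx[act]
    tmin <- max(pmin(t_lo, t_hi))
    tmax <- min(pmax(t_lo, t_hi))
    if (!is.finite(tmin) || !is.finite(tmax) || tmax - tmin < 1e-12) next
    t <- runif(1, tmin, tmax)
    return(y + t * dy)
  }
  y  # degenerate vertex: stay put this sweep
}

#' Artificially-centered hit-and-run sampling of a flux polytope
#'
#' Runs one chain per warmup point. Each sweep moves every chain one ACHR
#' step (direction = random stored point minus the running center of all
#' accepted points; step uniform on the feasible chord). Sweeps continue
#' until the mixed fraction reaches `target_mixed_fraction`, then chain
#' states are collected each sweep until `n_samples` points are gathered.
#' Warmup points are first projected onto the null space of `S`, so every
#' emitted sample is mass-balanced to machine precision; bounds are enforced
#' by the chord computation.
#'
#' @param region a `near_optimal_region` (or a whole-model polytope).
#' @param n_samples number of points to return (default 3000).
#' @param seed integer seed; all randomness flows from it.
#' @param target_mixed_fraction mixing target before collection starts
#'   (default 0.53).
#' @param n_warmup number of warmup points; default `2 *` the null-space
#'   dimension (at least 8).
#' @param step_cap maximum sweeps while waiting to mix.
#' @param thin collect chain states every `thin`-th sweep once mixed
#'   (larger values decorrelate consecutive samples).
#' @param cv_epsilon smallest `|mean|` for which a CV is reported.
#' @return a `sample_set`: `points` (matrix, one row per sample), `seed`,
#'   `steps` (sweeps run), `mixed_fraction` (the value at which the target
#'   was declared reached; `mixed_fraction_final` carries the last sweep's
#'   value, which keeps fluctuating around 1/2), and `summary` — a per-flux
#'   data.frame of mean, sd and coefficient of variation (CV = sd/mean,
#'   `NA` where `|mean|` is below `cv_epsilon`).
#' @export
achr_sample <- function(region, n_samples = 3000, seed = 1L,
                        target_mixed_fraction = 0.53, n_warmup = NULL,
                        step_cap = 2000L, thin = 1L, cv_epsilon = 1e-9) {
  poly <- region_polytope(region)
  n <- length(poly$lower)
  if (is.null(n_warmup)) {
    nullity <- ncol(nullspace_basis(poly$S))
    if (nullity == 0) stop("polytope has no degrees of freedom; nothing to sample")
    n_warmup <- max(50L, 2L * nullity)
  }
  W <- warmup_points(region, n_warmup, seed = seed)
  chart <- polytope_chart(poly, colMeans(W))
  if (ncol(chart$N) == 0) stop("polytope has no degrees of freedom; nothing to sample")
  chart$free <- !(seq_len(n) %in% chart$pinned)
  # chart coordinates: every reconstructed flux vector is mass-balanced and
  # keeps pinned fluxes exact, by construction
  Y <- sweep(W, 2, chart$x0) %*% chart$N
  W <- sweep(Y %*% t(chart$N), 2, chart$x0, "+")
  colnames(W) <- poly$reactions
  part <- pick_partition_flux(W)

  center_y <- colMeans(Y)
  n_acc <- nrow(Y)
  samples <- matrix(NA_real_, n_samples, n, dimnames = list(NULL, poly$reactions))
  got <- 0L
  mixed <- 0
  mixed_at_target <- NA_real_
  mixed_reached <- FALSE
  sweeps <- 0L
  since_collect <- 0L
  while (got < n_samples) {
    sweeps <- sweeps + 1L
    if (!mixed_reached && sweeps > step_cap) {
      stop("mixed fraction ", format(mixed, digits = 3),
           " did not reach ", target_mixed_fraction,
           " within ", step_cap, " sweeps")
    }
    for (i in seq_len(nrow(Y))) {
      Y[i, ] <- achr_step(Y[i, ], center_y, Y, chart, poly$lower, poly$upper)
      center_y <- (center_y * n_acc + Y[i, ]) / (n_acc + 1)
      n_acc <- n_acc + 1
    }
    X <- sweep(Y %*% t(chart$N), 2, chart$x0, "+")
    mixed <- mixed_fraction(X[, part$j], part$side, part$median)
    if (!mixed_reached && mixed >= target_mixed_fraction) {
      mixed_reached <- TRUE
      mixed_at_target <- mixed
    }
    if (mixed_reached) {
      since_collect <- since_collect + 1L
      if (since_collect >= thin) {
        since_collect <- 0L
        take <- min(nrow(X), n_samples - got)
        samples[(got + 1):(got + take), ] <- X[seq_len(take), , drop = FALSE]
        got <- got + take
      }
    }
  }
  samples <- pmin(pmax(samples, rep(poly$lower, each = n_samples)),
                  rep(poly$upper, each = n_samples))
  mu <- colMeans(samples)
  sdv <- apply(samples, 2, sd)
  summary <- data.frame(reaction_id = poly$reactions, mean = mu, sd = sdv,
                        cv = ifelse(abs(mu) > cv_epsilon, sdv / mu, NA_real_),
                        row.names = NULL)
  structure(list(points = samples, seed = seed, steps = sweeps,
                 mixed_fraction = mixed_at_target,
                 mixed_fraction_final = mixed, summary = summary,
                 n_warmup = n_warmup),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set> ", nrow(x$points), " points x ", ncol(x$points),
      " fluxes; sweeps: ", x$steps,
      "; mixed fraction at target: ", format(x$mixed_fraction, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Per-flux coefficient of variation of a sample set
#'
#' CV = sd/mean per flux across sampled points; fluxes whose `|mean|` falls
#' below `epsilon` are flagged undefined (`NA`) rather than divided.
#'
#' @param samples a `sample_set` (or a plain points matrix).
#' @param epsilon smallest `|mean|` for which a CV is reported.
#' @return data.frame with columns `reaction_id, mean, sd, cv`.
#' @export
flux_cv <- function(samples, epsilon = 1e-9) {
  pts <- if (inherits(samples, "sample_set")) samples$points else as.matrix(samples)
  if (nrow(pts) < 2) stop("need at least 2 points")
  mu <- colMeans(pts)
  sdv <- apply(pts, 2, sd)
  ids <- colnames(pts)
  if (is.null(ids)) ids <- paste0("v", seq_along(mu))
  data.frame(reaction_id = ids, mean = as.numeric(mu), sd = as.numeric(sdv),
             cv = ifelse(abs(mu) > epsilon, sdv / mu, NA_real_),
             row.names = NULL)
}
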