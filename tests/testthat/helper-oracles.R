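# Independent oracles. These deliberately share no code with the package's
# solver path: vertex enumeration and active-set enumeration are plain
# linear algebra on the constraint description, and the projection oracle
# for the two-polytope distance is alternating exact projections.

# orthonormal null-space basis (plain svd)
oracle_null <- function(S) {
  S <- as.matrix(S)
  n <- ncol(S)
  if (nrow(S) == 0) return(diag(n))
  sv <- svd(S, nu = 0, nv = n)
  tol <- max(dim(S)) * max(sv$d, 0) * .Machine$double.eps
  r <- sum(sv$d > tol)
  if (r == n) return(matrix(0, n, 0))
  sv$v[, (r + 1):n, drop = FALSE]
}

# Enumerate all vertices of {S x = 0, l <= x <= u}: in null-space
# coordinates y (x = N y) pick every subset of k = dim(y) bound rows,
# solve the square system, keep feasible solutions.
oracle_vertices <- function(model, lower = NULL, upper = NULL, tol = 1e-7) {
  S <- as.matrix(model$S)
  l <- if (is.null(lower)) model$lower else lower
  u <- if (is.null(upper)) model$upper else upper
  N <- oracle_null(S)
  k <- ncol(N)
  G <- rbind(N, -N)               # G y <= h  with rows (x_i <= u_i), (-x_i <= -l_i)
  h <- c(u, -l)
  if (k == 0) return(matrix(numeric(0), 0, ncol(S)))
  combs <- utils::combn(nrow(G), k)
  verts <- list()
  for (ci in seq_len(ncol(combs))) {
    A <- G[combs[, ci], , drop = FALSE]
    if (abs(det(A)) < 1e-10) next
    y <- solve(A, h[combs[, ci]])
    x <- as.numeric(N %*% y)
    if (all(x <= u + tol) && all(x >= l - tol)) {
      verts[[length(verts) + 1]] <- pmin(pmax(x, l), u)
    }
  }
  out <- unique(do.call(rbind, verts))
  colnames(out) <- model$reactions
  out
}

oracle_fba_growth <- function(model) {
  V <- oracle_vertices(model)
  if (nrow(V) == 0) return(NA_real_)
  max(V[, model$biomass])
}

# Exact Euclidean projection onto {S x = 0, l <= x <= u} by active-set
# enumeration in null-space coordinates. The factory precomputes the
# geometry; each call enumerates candidate active sets, accepting
# immediately on a full KKT certificate (primal feasible + multipliers
# non-negative), else falling back to the best feasible candidate.
make_oracle_projector <- function(S, l, u, tol = 1e-9) {
  N <- oracle_null(S)
  k <- ncol(N)
  G <- rbind(N, -N)
  h <- c(u, -l)
  combos <- lapply(seq_len(k), function(sz) utils::combn(nrow(G), sz))
  function(ref) {
    y0 <- as.numeric(t(N) %*% ref)  # unconstrained minimiser (N orthonormal)
    best <- NULL
    best_obj <- Inf
    feas <- function(x) all(x <= u + tol) && all(x >= l - tol)
    x_un <- as.numeric(N %*% y0)
    if (feas(x_un)) {
      return(list(x = pmin(pmax(x_un, l), u),
                  distance = sqrt(sum((x_un - ref)^2))))
    }
    for (sz in seq_len(k)) {
      combs <- combos[[sz]]
      for (ci in seq_len(ncol(combs))) {
        idx <- combs[, ci]
        A <- G[idx, , drop = FALSE]
        # minimise ||y - y0||^2 (isometry) s.t. A y = h_A via KKT
        KKT <- rbind(cbind(2 * diag(k), t(A)),
                     cbind(A, matrix(0, sz, sz)))
        sol <- tryCatch(solve(KKT, c(2 * y0, h[idx])), error = function(e) NULL)
        if (is.null(sol)) next
        y <- sol[seq_len(k)]
        x <- as.numeric(N %*% y)
        if (!feas(x)) next
        obj <- sum((x - ref)^2)
        lambda <- sol[-seq_len(k)]
        if (all(lambda >= -1e-9)) {
          return(list(x = pmin(pmax(x, l), u), distance = sqrt(obj)))
        }
        if (obj < best_obj) {
          best_obj <- obj
          best <- x
        }
      }
    }
    list(x = pmin(pmax(best, l), u), distance = sqrt(best_obj))
  }
}

oracle_project <- function(S, l, u, ref, tol = 1e-9) {
  make_oracle_projector(S, l, u, tol)(ref)
}

# Minimum distance between two polytopes by alternating exact projections
# (each projection from the enumeration oracle above).
oracle_pseudo_distance <- function(S1, l1, u1, S2, l2, u2,
                                   start = NULL, max_iter = 5000) {
  proj1 <- make_oracle_projector(S1, l1, u1)
  proj2 <- make_oracle_projector(S2, l2, u2)
  q <- if (is.null(start)) pmin(pmax(rep(0, length(l2)), l2), u2) else start
  q <- proj2(q)$x
  d_prev <- Inf
  stable <- 0L
  for (it in seq_len(max_iter)) {
    p <- proj1(q)$x
    q <- proj2(p)$x
    d <- sqrt(sum((p - q)^2))
    if (abs(d_prev - d) < 1e-12) stable <- stable + 1L else stable <- 0L
    if (stable >= 5L) break
    d_prev <- d
  }
  list(p = p, q = q, distance = d, iterations = it)
}

# Textbook transcription of the dependent-correlation Z test sharing one
# variable, kept deliberately scalar and literal.
oracle_meng_z <- function(r1, r2, rx, n) {
  z1 <- 0.5 * log((1 + r1) / (1 - r1))
  z2 <- 0.5 * log((1 + r2) / (1 - r2))
  r2bar <- (r1 * r1 + r2 * r2) / 2
  f <- (1 - rx) / (2 * (1 - r2bar))
  if (f > 1) f <- 1
  h <- (1 - f * r2bar) / (1 - r2bar)
  (z1 - z2) * sqrt((n - 3) / (2 * (1 - rx) * h))
}
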