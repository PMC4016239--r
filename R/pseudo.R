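# ---------------------------------------------------------------------------
# The polytope-to-polytope objective. The wild type is represented not by a
# single optimal vector but by its near-optimal region: all flux vectors
# supporting at least a threshold fraction of maximal growth. The mutant
# prediction q is the point of the mutant polytope closest (Euclidean) to
# that region; the paired point p in the region is returned for inspection.
# Distance 0 is diagnostic of overlap: the mutant can itself grow at or
# above the threshold.
# ---------------------------------------------------------------------------

#' Build the near-optimal growth region
#'
#' The constraint set `b_L <= p <= b_U, S p = 0,
#' p_GROWTH >= threshold * f_hat_GROWTH`, where `f_hat_GROWTH` is recomputed
#' from a fresh FBA solve of the wild-type model. Nonempty whenever the wild
#' type is feasible (the FBA optimum itself lies in it).
#'
#' @param model wild-type `metabolic_model` with media applied.
#' @param threshold growth fraction alpha in (0, 1]; default 0.90.
#' @return a `near_optimal_region`: the model, threshold, wild-type optimum,
#'   and the tightened bounds.
#' @export
build_near_optimal_region <- function(model, threshold = 0.90) {
  stopifnot(threshold > 0, threshold <= 1)
  wt <- fba(model)
  if (wt$status != "optimal") stop("wild-type FBA ", wt$status)
  if (wt$growth <= 1e-9) stop("wild-type growth is zero; near-optimal region undefined")
  lower <- model$lower
  # relative backoff keeps threshold = 1 (optimal face only) feasible in the
  # presence of the LP optimum's ~1e-12 constraint residual
  lower[model$biomass] <- max(lower[model$biomass],
                              threshold * wt$growth * (1 - 1e-9))
  structure(list(model = model, threshold = threshold,
                 wild_type_optimum = wt$growth,
                 wild_type_flux = wt$flux,
                 lower = lower, upper = model$upper),
            class = "near_optimal_region")
}

#' @export
print.near_optimal_region <- function(x, ...) {
  cat("<near_optimal_region> threshold:", x$threshold,
      " wild-type optimum:", format(x$wild_type_optimum, digits = 8),
      " growth floor:", format(x$threshold * x$wild_type_optimum, digits = 8), "\n")
  invisible(x)
}

#' Encode the polytope-distance objective as a quadratic program
#'
#' Stacked variable `(p, q)` of length `2n`; quadratic matrix
#' `[[I, -I], [-I, I]]` (eigenvalues only 0 and 2, hence convex);
#' block-diagonal equality `[[S, 0], [0, S]]` concatenating the two
#' conservation-of-mass constraints; region bounds on `p`, mutant bounds on
#' `q`. The objective value at a point is the squared distance `||p - q||^2`.
#'
#' @param region a [build_near_optimal_region()] result.
#' @param mutant_model the mutant `metabolic_model`.
#' @return a [quadratic_problem()].
#' @export
encode_pseudo_qp <- function(region, mutant_model) {
  n <- n_reactions(region$model)
  stopifnot(n_reactions(mutant_model) == n)
  I <- diag(n)
  Q <- rbind(cbind(I, -I), cbind(-I, I))
  S <- as.matrix(region$model$S)
  Sm <- as.matrix(mutant_model$S)
  m <- nrow(S)
  Aeq <- rbind(cbind(S, matrix(0, m, n)),
               cbind(matrix(0, m, n), Sm))
  quadratic_problem(Q = Q, c = rep(0, 2 * n),
                    Aeq = Aeq, beq = rep(0, 2 * m),
                    lower = c(region$lower, mutant_model$lower),
                    upper = c(region$upper, mutant_model$upper))
}

#' Encode the polytope-distance objective as a second-order-cone program
#'
#' Adds the difference vector `x = p - q` and a scalar `z_dist` constrained
#' to the quadratic cone `z_dist >= ||x||`; minimising `z_dist` returns the
#' distance directly, no square root needed. See [conic_encoding()] for how
#' the linkage is realised.
#'
#' @inheritParams encode_pseudo_qp
#' @param start_p,start_q optional starting points (feasible points of the
#'   two polytopes speed up and stabilise the nonlinear solve).
#' @return a [conic_encoding()].
#' @export
encode_pseudo_socp <- function(region, mutant_model,
                               start_p = NULL, start_q = NULL) {
  n <- n_reactions(region$model)
  m <- length(region$model$metabolites)
  conic_encoding(n = n,
                 Aeq_p = as.matrix(region$model$S), beq_p = rep(0, m),
                 Aeq_q = as.matrix(mutant_model$S), beq_q = rep(0, m),
                 lower_p = region$lower, upper_p = region$upper,
                 lower_q = mutant_model$lower, upper_q = mutant_model$upper,
                 start_p = start_p, start_q = start_q)
}

#' Predict a mutant flux distribution from the near-optimal region
#'
#' Solves `minimize ||p - q||` over `p` in the wild type's near-optimal
#' growth region and `q` in the mutant polytope. Both formulations — the
#' quadratic program on the stacked variable and the second-order-cone
#' epigraph — reach the same global optimum (convexity); `q` is the
#' prediction.
#'
#' When the mutant's own growth optimum reaches `threshold` times the
#' wild-type optimum the two polytopes intersect and the minimum distance is
#' exactly 0; this degenerate overlap is detected by an exact LP test before
#' any quadratic solve (`overlap_check = FALSE` forces the full solve, used
#' for cross-validation).
#'
#' @param model wild-type `metabolic_model` with media applied.
#' @param mut a [mutation()], or an already-mutated `metabolic_model`.
#' @param threshold near-optimal growth fraction, default 0.90.
#' @param formulation `"qp"` or `"socp"`.
#' @param overlap_check detect the distance-0 overlap case exactly via LP
#'   before solving.
#' @param overlap_epsilon distance below which the solution is flagged as
#'   overlapping.
#' @param normalize divide reported fluxes by the mutant's glucose (first
#'   listed uptake) rate — `NULL` (off) or the exchange reaction id to
#'   normalise by.
#' @param detect_degenerate re-solve from a second starting point and flag
#'   `distance_degenerate_possible` when a different optimal pair (same
#'   distance) is found.
#' @return a `pseudo_solution`: `p`, `q` (named flux vectors), `distance`
#'   (recomputed as `||p - q||` from the primal), `overlap`, `growth`
#'   (growth of `q`), `threshold`, `formulation_used`, `status`.
#' @export
pseudo <- function(model, mut, threshold = 0.90,
                   formulation = c("qp", "socp"), overlap_check = TRUE,
                   overlap_epsilon = 1e-6, normalize = NULL,
                   detect_degenerate = FALSE) {
  formulation <- match.arg(formulation)
  region <- build_near_optimal_region(model, threshold)
  mutant_model <- if (inherits(mut, "metabolic_model")) mut else
    apply_mutation(model, mut)
  mut_fba <- fba(mutant_model)
  if (mut_fba$status == "infeasible") {
    return(pseudo_solution(status = "infeasible", threshold = threshold,
                           formulation = formulation,
                           diagnostics = list(message = "mutant polytope infeasible")))
  }

  floor_growth <- threshold * region$wild_type_optimum
  if (overlap_check && mut_fba$status == "optimal" &&
      mut_fba$growth >= floor_growth - 1e-9 * max(1, abs(floor_growth))) {
    pt <- mut_fba$flux
    return(pseudo_solution(p = pt, q = pt, distance = 0, overlap = TRUE,
                           status = "optimal", threshold = threshold,
                           formulation = formulation, region = region,
                           normalize = normalize, model = mutant_model))
  }

  n <- n_reactions(model)
  if (formulation == "qp") {
    qp <- encode_pseudo_qp(region, mutant_model)
    start <- c(region$wild_type_flux, if (!is.null(mut_fba$flux)) mut_fba$flux
               else rep(0, n))
    res <- solve_qp(qp, start = start)
    if (res$status != "optimal") {
      return(pseudo_solution(status = res$status, threshold = threshold,
                             formulation = formulation,
                             diagnostics = res$diagnostics))
    }
    p <- res$x[1:n]
    q <- res$x[(n + 1):(2 * n)]
    degenerate <- NA
    if (detect_degenerate) {
      res2 <- solve_qp(qp, start = rep(0, 2 * n))
      if (res2$status == "optimal" &&
          abs(sqrt(max(res2$objective, 0)) - sqrt(max(res$objective, 0))) < 1e-6 &&
          sqrt(sum((res2$x - res$x)^2)) > 1e-6) {
        degenerate <- TRUE
      } else degenerate <- FALSE
    }
  } else {
    enc <- encode_pseudo_socp(region, mutant_model,
                              start_p = region$wild_type_flux,
                              start_q = mut_fba$flux)
    res <- solve_socp(enc)
    if (res$status != "optimal") {
      return(pseudo_solution(status = res$status, threshold = threshold,
                             formulation = formulation,
                             diagnostics = res$diagnostics))
    }
    p <- res$x[1:n]
    q <- res$x[(n + 1):(2 * n)]
    degenerate <- NA
  }
  dist <- sqrt(sum((p - q)^2))
  pseudo_solution(p = setNames(p, model$reactions),
                  q = setNames(q, model$reactions),
                  distance = dist, overlap = dist <= overlap_epsilon,
                  status = "optimal", threshold = threshold,
                  formulation = formulation, region = region,
                  degenerate = degenerate, normalize = normalize,
                  model = mutant_model, diagnostics = res$diagnostics)
}

pseudo_solution <- function(p = NULL, q = NULL, distance = NA_real_,
                            overlap = NA, status, threshold, formulation,
                            region = NULL, degenerate = NA, normalize = NULL,
                            model = NULL, diagnostics = list()) {
  growth <- if (!is.null(q) && !is.null(model)) unname(q[model$biomass]) else NA_real_
  q_report <- q
  p_report <- p
  if (!is.null(normalize) && !is.null(q)) {
    rate <- abs(q[[normalize]])
    if (rate > 1e-12) {
      q_report <- q / rate
      p_report <- p / rate
    }
  }
  structure(list(p = p_report, q = q_report, distance = distance,
                 overlap = overlap, growth = growth, threshold = threshold,
                 formulation_used = formulation,
                 wild_type_optimum = if (!is.null(region)) region$wild_type_optimum else NA_real_,
                 distance_degenerate_possible = degenerate,
                 status = status, diagnostics = diagnostics),
            class = "pseudo_solution")
}

#' @export
print.pseudo_solution <- function(x, ...) {
  cat("<pseudo_solution> status:", x$status)
  if (x$status == "optimal") {
    cat("  distance:", format(x$distance, digits = 8),
        " overlap:", x$overlap,
        " growth(q):", format(x$growth, digits = 8),
        " threshold:", x$threshold,
        " [", x$formulation_used, "]")
  }
  cat("\n")
  invisible(x)
}
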