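# ---------------------------------------------------------------------------
# Minimization of metabolic adjustment: project a wild-type flux vector onto
# the mutant's feasible polytope under the Euclidean norm. The objective
# ||m - f_hat||^2 is strictly convex, so the projection is unique.
# ---------------------------------------------------------------------------

#' Minimization of metabolic adjustment (MOMA)
#'
#' Finds the mutant flux vector `m` of minimum Euclidean distance to a
#' wild-type reference `f_hat`, subject to mass balance and the mutant
#' bounds: `minimize ||m - f_hat|| s.t. S m = 0, bounds`. When the reference
#' already satisfies the mutant constraints the projection is the reference
#' itself and the distance is 0.
#'
#' The conventional reference is the wild-type FBA solution after the
#' parsimonious 1-norm pass (see [fba()] with `parsimonious = TRUE`); a
#' measured flux vector may be supplied instead.
#'
#' @param mutant_model a `metabolic_model` with the mutation applied.
#' @param wild_type_flux named reference flux vector covering every reaction.
#' @return a `moma_solution`: `flux`, `growth`, `distance`, `reference`,
#'   `status`.
#' @export
moma <- function(mutant_model, wild_type_flux) {
  n <- n_reactions(mutant_model)
  ref <- wild_type_flux[mutant_model$reactions]
  if (anyNA(ref)) stop("wild_type_flux must cover every model reaction")
  ref <- as.numeric(ref)
  qp <- quadratic_problem(Q = diag(n), c = -2 * ref,
                          Aeq = as.matrix(mutant_model$S),
                          beq = rep(0, length(mutant_model$metabolites)),
                          lower = mutant_model$lower,
                          upper = mutant_model$upper)
  res <- solve_qp(qp)
  if (res$status != "optimal") {
    return(structure(list(flux = NULL, growth = NA_real_, distance = NA_real_,
                          reference = setNames(ref, mutant_model$reactions),
                          status = res$status, diagnostics = res$diagnostics),
                     class = "moma_solution"))
  }
  flux <- setNames(res$x, mutant_model$reactions)
  structure(list(flux = flux,
                 growth = unname(flux[mutant_model$biomass]),
                 distance = sqrt(sum((res$x - ref)^2)),
                 reference = setNames(ref, mutant_model$reactions),
                 status = "optimal", diagnostics = res$diagnostics),
            class = "moma_solution")
}

#' @export
print.moma_solution <- function(x, ...) {
  cat("<moma_solution> status:", x$status)
  if (x$status == "optimal") {
    cat("  growth:", format(x$growth, digits = 8),
        " distance:", format(x$distance, digits = 8))
  }
  cat("\n")
  invisible(x)
}
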