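# ---------------------------------------------------------------------------
# Flux balance analysis: maximise the biomass flux over the steady-state
# polytope {S f = 0, b_L <= f <= b_U}. The optimum is typically degenerate —
# many flux vectors share the maximal growth — so the returned vector is one
# optimal point, and the optional 1-norm secondary pass picks the
# parsimonious representative.
# ---------------------------------------------------------------------------

model_lp <- function(model, objective, sense = "maximize",
                     lower = NULL, upper = NULL) {
  linear_problem(objective = objective, sense = sense,
                 Aeq = as.matrix(model$S), beq = rep(0, length(model$metabolites)),
                 lower = if (is.null(lower)) model$lower else lower,
                 upper = if (is.null(upper)) model$upper else upper)
}

#' Flux balance analysis
#'
#' Solves `maximize f_GROWTH subject to S f = 0, b_L <= f <= b_U`. The growth
#' optimum is unique; the flux vector is one optimal vertex among possibly
#' many (the degenerate optimal face). Use `parsimonious = TRUE` to follow
#' with the 1-norm secondary objective.
#'
#' @param model a `metabolic_model` with media applied.
#' @param parsimonious apply the 1-norm secondary pass at the fixed optimum.
#' @return an `fba_solution`: `flux` (named vector), `growth`, `status`,
#'   `parsimonious`.
#' @export
fba <- function(model, parsimonious = FALSE) {
  obj <- as.numeric(model$reactions == model$biomass)
  res <- solve_lp(model_lp(model, obj))
  if (res$status != "optimal") {
    return(structure(list(flux = NULL, growth = NA_real_, status = res$status,
                          parsimonious = FALSE, diagnostics = res$diagnostics),
                     class = "fba_solution"))
  }
  flux <- setNames(res$x, model$reactions)
  growth <- unname(flux[model$biomass])
  if (parsimonious) {
    flux <- parsimonious_pass(model, growth)
    growth <- unname(flux[model$biomass])
  }
  structure(list(flux = flux, growth = growth, status = "optimal",
                 parsimonious = parsimonious, diagnostics = res$diagnostics),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("<fba_solution> status:", x$status)
  if (x$status == "optimal") {
    cat("  growth:", format(x$growth, digits = 8),
        if (x$parsimonious) " (parsimonious)" else "")
  }
  cat("\n")
  invisible(x)
}

#' Parsimonious (1-norm) secondary pass
#'
#' Among flux vectors attaining a fixed growth value, returns one minimising
#' the total flux `sum(|f_i|)`. Implemented exactly as a linear program by
#' splitting each flux into non-negative positive and negative parts; the
#' 1-norm objective drives null-space futile cycles to zero.
#'
#' @param model a `metabolic_model`.
#' @param fixed_growth growth value to hold (must be feasible).
#' @return named flux vector.
#' @export
parsimonious_pass <- function(model, fixed_growth) {
  n <- n_reactions(model)
  S <- as.matrix(model$S)
  # variables: (f_plus, f_minus), f = f_plus - f_minus
  up_plus <- pmax(model$upper, 0)
  up_minus <- pmax(-model$lower, 0)
  lo_plus <- pmax(model$lower, 0)   # if lower > 0 the positive part must carry it
  lo_minus <- pmax(-model$upper, 0)
  Aeq <- cbind(S, -S)
  beq <- rep(0, nrow(S))
  g <- as.numeric(model$reactions == model$biomass)
  Aeq <- rbind(Aeq, c(g, -g))
  beq <- c(beq, fixed_growth)
  # the requested growth may sit a solver-tolerance above the true optimum;
  # back off relatively before declaring the pin infeasible
  for (backoff in c(0, 1e-11, 1e-9, 1e-7)) {
    beq[length(beq)] <- fixed_growth * (1 - backoff)
    lp <- linear_problem(objective = rep(1, 2 * n), sense = "minimize",
                         Aeq = Aeq, beq = beq,
                         lower = c(lo_plus, lo_minus),
                         upper = c(up_plus, up_minus))
    res <- solve_lp(lp)
    if (res$status == "optimal") {
      return(setNames(res$x[1:n] - res$x[(n + 1):(2 * n)], model$reactions))
    }
  }
  stop("parsimonious pass ", res$status, " at growth ", fixed_growth)
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux attainable while growth
#' stays at or above `growth_fraction` of the wild-type optimum — the
#' degenerate range of that flux. `fold_degeneracy` is the range divided by
#' the magnitude of the point FBA flux (reported only where that magnitude is
#' nonzero; futile cycles make it unbounded in spirit, here capped by the
#' default bounds).
#'
#' @param model a `metabolic_model`.
#' @param growth_fraction fraction of the FBA optimum to retain, in (0, 1].
#' @param reactions subset of reaction ids (default all).
#' @return a `data.frame` with columns `reaction_id, min_flux, max_flux,
#'   degenerate_range, fba_flux, fold_degeneracy`; the fraction used is
#'   attached as attribute `growth_fraction`.
#' @export
flux_variability <- function(model, growth_fraction = 0.90, reactions = NULL) {
  stopifnot(growth_fraction > 0, growth_fraction <= 1)
  wt <- fba(model)
  if (wt$status != "optimal" || wt$growth <= 0) {
    stop("flux variability requires a feasible model with positive growth")
  }
  if (is.null(reactions)) reactions <- model$reactions
  lower <- model$lower
  gi <- model$biomass
  # relative backoff keeps the floor feasible when fraction = 1 pins the
  # optimal face (the LP optimum carries ~1e-12 constraint residual)
  lower[gi] <- max(lower[gi], growth_fraction * wt$growth * (1 - 1e-9))
  out <- lapply(reactions, function(r) {
    obj <- as.numeric(model$reactions == r)
    lo <- solve_lp(model_lp(model, obj, "minimize", lower = lower))
    hi <- solve_lp(model_lp(model, obj, "maximize", lower = lower))
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("variability solve failed for reaction ", r, " (", lo$status, "/",
           hi$status, ")")
    }
    c(min_flux = lo$objective, max_flux = hi$objective)
  })
  out <- do.call(rbind, out)
  fba_flux <- as.numeric(wt$flux[reactions])
  rng <- out[, "max_flux"] - out[, "min_flux"]
  df <- data.frame(reaction_id = reactions,
                   min_flux = out[, "min_flux"],
                   max_flux = out[, "max_flux"],
                   degenerate_range = rng,
                   fba_flux = fba_flux,
                   fold_degeneracy = ifelse(abs(fba_flux) > 1e-9,
                                            rng / abs(fba_flux), NA_real_),
                   row.names = NULL)
  attr(df, "growth_fraction") <- growth_fraction
  attr(df, "wild_type_growth") <- wt$growth
  df
}
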