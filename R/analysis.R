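# ---------------------------------------------------------------------------
# Downstream analyses: lethality calls, carbon-fate partitioning of a flux
# vector, sensitivity scans over pinned fluxes, growth-threshold sweeps of
# the polytope-distance objective, dependent-correlation comparisons, and
# batch mutant screens.
# ---------------------------------------------------------------------------

#' Lethality call from predicted growth
#'
#' A mutant is predicted lethal when its growth rate is less than a fraction
#' (default 5%) of the wild-type maximum.
#'
#' @param mutant_growth predicted mutant growth (vectorised).
#' @param wild_type_growth wild-type maximal growth (> 0).
#' @param cutoff lethality fraction, default 0.05.
#' @return character vector, `"lethal"` or `"viable"`.
#' @export
lethality_call <- function(mutant_growth, wild_type_growth, cutoff = 0.05) {
  stopifnot(wild_type_growth > 0)
  ifelse(mutant_growth / wild_type_growth < cutoff, "lethal", "viable")
}

#' Carbon-fate partition of a flux vector
#'
#' Consumed carbon enters through uptaking exchanges (negative flux) and
#' leaves as biomass, CO2, or secreted organic metabolites (positive
#' exchanges). Each boundary flux is weighted by the carbon count of its
#' metabolite; biomass carbon is the growth flux times the net carbon
#' consumed by the biomass equation. Fluxes are in mmol carbon/gDW/hr;
#' fractions are normalised by consumed carbon and sum to 1 on
#' carbon-balanced models.
#'
#' @param model a `metabolic_model` with metabolite formulas.
#' @param flux named flux vector (steady state).
#' @param co2_ids exchange reaction ids treated as CO2 output; by default
#'   detected as exchanges of metabolites with formula `CO2`.
#' @param secretion_floor smallest positive exchange flux counted in the
#'   secreted-metabolite profile.
#' @return a `carbon_fate`: molar fluxes `consumed`, `biomass`, `co2`,
#'   `secreted`; fractions `biomass_fraction`, `co2_fraction`,
#'   `secreted_fraction`; and `secreted_profile`, a per-metabolite data
#'   frame of carbon secretion fluxes.
#' @export
carbon_partition <- function(model, flux, co2_ids = NULL,
                             secretion_floor = 1e-6) {
  if (is.null(model$formulas)) stop("model has no metabolite formulas")
  flux <- flux[model$reactions]
  ex <- setdiff(model$exchanges, model$biomass)
  ex_met <- vapply(ex, function(r) {
    col <- model$S[, r]
    model$metabolites[which(col != 0)[1]]
  }, character(1))
  fml <- model$formulas[ex_met]
  if (anyNA(fml)) {
    relevant <- ex[is.na(fml)]
    stop("missing formula for boundary metabolite(s) of: ",
         paste(relevant, collapse = ", "))
  }
  cc <- carbon_count(fml)
  # exchange stoichiometry sign: flux>0 with S=-1 exports the metabolite
  ex_sign <- vapply(ex, function(r) {
    col <- model$S[, r]
    -sum(col[col != 0])
  }, numeric(1))
  outflow <- as.numeric(flux[ex]) * ex_sign   # >0: metabolite leaves the system
  if (is.null(co2_ids)) co2_ids <- ex[fml == "CO2"]

  consumed <- sum(pmax(-outflow, 0) * cc)
  co2 <- sum(pmax(outflow[ex %in% co2_ids], 0) * cc[ex %in% co2_ids])
  sec_mask <- !(ex %in% co2_ids) & outflow > 0 & cc > 0
  secreted <- sum(outflow[sec_mask] * cc[sec_mask])
  bio_net_c <- -sum(as.numeric(model$S[, model$biomass]) *
                      carbon_count(model$formulas[model$metabolites]))
  biomass_c <- unname(flux[model$biomass]) * bio_net_c

  profile_mask <- sec_mask & outflow * cc > secretion_floor
  profile <- data.frame(exchange = ex[profile_mask],
                        metabolite = ex_met[profile_mask],
                        carbon_flux = outflow[profile_mask] * cc[profile_mask],
                        row.names = NULL)
  frac <- function(x) if (consumed > 1e-12) x / consumed else NA_real_
  structure(list(consumed = consumed, biomass = biomass_c, co2 = co2,
                 secreted = secreted,
                 biomass_fraction = frac(biomass_c),
                 co2_fraction = frac(co2),
                 secreted_fraction = frac(secreted),
                 secreted_profile = profile),
            class = "carbon_fate")
}

#' @export
print.carbon_fate <- function(x, ...) {
  cat("<carbon_fate> consumed:", format(x$consumed, digits = 6),
      "mmol C/gDW/hr | biomass:", format(100 * x$biomass_fraction, digits = 3),
      "% co2:", format(100 * x$co2_fraction, digits = 3),
      "% secreted:", format(100 * x$secreted_fraction, digits = 3), "%\n")
  invisible(x)
}

#' Sensitivity scan over a pinned flux
#'
#' Fixes one flux to each of a series of exact values (both bounds) and
#' re-solves the chosen objective, recording growth and secreted carbon at
#' each pin. Infeasible pins are recorded with their status, never dropped.
#'
#' @param model wild-type model with media applied.
#' @param mut optional [mutation()] applied before scanning.
#' @param pinned_flux reaction id to pin.
#' @param values numeric vector of pin values.
#' @param method `"fba"`, `"moma"` or `"pseudo"`.
#' @param threshold near-optimal threshold (pseudo only).
#' @param reference wild-type reference flux for MOMA; default parsimonious
#'   FBA of `model`.
#' @param track extra reaction ids to report.
#' @return data.frame: one row per pin value with `growth`,
#'   `secreted_carbon` (when formulas exist), tracked fluxes, `status`.
#' @export
sensitivity_scan <- function(model, mut = NULL, pinned_flux, values,
                             method = c("fba", "moma", "pseudo"),
                             threshold = 0.90, reference = NULL,
                             track = character(0)) {
  method <- match.arg(method)
  if (!length(values)) stop("empty value list")
  rxn_index(model, pinned_flux)
  base <- if (is.null(mut)) model else apply_mutation(model, mut)
  if (method == "moma" && is.null(reference)) {
    reference <- fba(model, parsimonious = TRUE)$flux
  }
  rows <- lapply(values, function(v) {
    m <- base
    m$lower[pinned_flux] <- v
    m$upper[pinned_flux] <- v
    sol <- switch(method,
                  fba = fba(m),
                  moma = moma(m, reference),
                  pseudo = pseudo(model, m, threshold = threshold))
    row <- list(pinned_value = v, status = sol$status,
                growth = if (sol$status == "optimal") sol$growth else NA_real_)
    fl <- if (method == "pseudo") sol$q else sol$flux
    if (!is.null(model$formulas)) {
      row$secreted_carbon <- if (sol$status == "optimal") {
        carbon_partition(m, fl)$secreted
      } else NA_real_
    }
    for (tr in track) {
      row[[tr]] <- if (sol$status == "optimal") unname(fl[tr]) else NA_real_
    }
    as.data.frame(row, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "method") <- method
  attr(out, "pinned_flux") <- pinned_flux
  out
}

#' Growth-threshold sweep of the polytope-distance objective
#'
#' Re-solves the mutant prediction across a grid of near-optimal growth
#' thresholds (default the 80-99% range) and reports distance, growth and
#' overlap per threshold. Distances are checked to be non-increasing as the
#' threshold decreases (nested regions); thresholds at or above 0.999 draw a
#' warning, as the near-optimal region degenerates toward the optimal face
#' and interior-point style solves become ill-conditioned there.
#'
#' @param model wild-type model with media applied.
#' @param mut a [mutation()] or mutant model.
#' @param thresholds numeric vector in (0, 1).
#' @param ... passed to [pseudo()].
#' @return data.frame with one row per threshold: `threshold, distance,
#'   growth, overlap, status`.
#' @export
threshold_sweep <- function(model, mut, thresholds = seq(0.80, 0.99, by = 0.01),
                            ...) {
  stopifnot(all(thresholds > 0), all(thresholds < 1))
  if (any(thresholds >= 0.999)) {
    warning("thresholds at or above 0.999 approach the optimal face; ",
            "solutions may not be computable there")
  }
  mutant_model <- if (inherits(mut, "metabolic_model")) mut else
    apply_mutation(model, mut)
  rows <- lapply(thresholds, function(th) {
    sol <- pseudo(model, mutant_model, threshold = th, ...)
    data.frame(threshold = th, distance = sol$distance, growth = sol$growth,
               overlap = sol$overlap, status = sol$status)
  })
  out <- do.call(rbind, rows)
  ok <- out$status == "optimal"
  d <- out$distance[ok][order(out$threshold[ok])]
  if (any(diff(d) < -1e-6)) {
    warning("distance not monotone in threshold; check solver tolerances")
  }
  out
}

#' Batch mutant screen
#'
#' Applies each mutation in turn and records growth per method, the
#' lethality call, and the polytope distance. Failures are isolated per
#' mutant with a status column; the batch never aborts. Growth is also
#' reported normalised to the wild-type optimum so predicted yields have
#' maximum 1.
#'
#' @param model wild-type model with media applied.
#' @param mutations a (possibly named) list of [mutation()] objects.
#' @param methods subset of `c("fba", "moma", "pseudo")`.
#' @param threshold near-optimal threshold for the distance objective.
#' @param lethality_cutoff growth fraction below which a mutant is called
#'   lethal.
#' @return data.frame, one row per mutant.
#' @export
mutant_screen <- function(model, mutations,
                          methods = c("fba", "moma", "pseudo"),
                          threshold = 0.90, lethality_cutoff = 0.05) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!length(mutations)) {
    return(data.frame(mutant = character(0)))
  }
  wt <- fba(model, parsimonious = TRUE)
  if (wt$status != "optimal") stop("wild-type FBA ", wt$status)
  nm <- names(mutations)
  if (is.null(nm)) nm <- vapply(mutations, function(m) paste(m$targets, collapse = "+"),
                                character(1))
  rows <- lapply(seq_along(mutations), function(i) {
    row <- list(mutant = nm[i])
    res <- tryCatch({
      mm <- apply_mutation(model, mutations[[i]])
      for (meth in methods) {
        sol <- switch(meth,
                      fba = fba(mm),
                      moma = moma(mm, wt$flux),
                      pseudo = pseudo(model, mm, threshold = threshold))
        g <- if (sol$status == "optimal") sol$growth else
          if (sol$status == "infeasible") 0 else NA_real_
        row[[paste0("growth_", meth)]] <- g
        row[[paste0("yield_", meth)]] <- min(g / wt$growth, 1 + 1e-9)
        row[[paste0("lethal_", meth)]] <-
          lethality_call(g, wt$growth, lethality_cutoff)
        if (meth == "pseudo") row$distance <- sol$distance
      }
      row$status <- "ok"
      row
    }, error = function(e) {
      row$status <- paste("error:", conditionMessage(e))
      row
    })
    as.data.frame(res, check.names = FALSE)
  })
  nm_all <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (m in setdiff(nm_all, names(r))) r[[m]] <- NA
    r[nm_all]
  })
  do.call(rbind, rows)
}
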