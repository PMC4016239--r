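# ---------------------------------------------------------------------------
# Synthetic fixture generator: small carbon-balanced metabolic models with
# analytically known optima and controllable degeneracy, so every solver and
# the sampler can be tested without any external model.
#
# Topology: glucose (C6) enters through an exchange; k parallel pathways
# convert one glucose into y_i units of a one-carbon biomass precursor B
# plus (6 - y_i) CO2; the biomass reaction drains B, so growth equals the B
# supply rate and the FBA optimum is uptake_limit * max(yield). Optional
# extras: a secretion route from B to an exportable organic metabolite, and
# a futile two-cycle that the 1-norm pass must silence.
# ---------------------------------------------------------------------------

#' Specification for a toy metabolic network
#'
#' @param n_pathways number of parallel glucose-to-precursor pathways.
#' @param yields per-pathway biomass-precursor yield per glucose, each in
#'   (0, 6] (the precursor carries one carbon; the remaining
#'   `6 - yield` carbons leave as CO2, keeping the network carbon-balanced).
#' @param uptake_limit maximum glucose uptake (mmol/gDW/hr).
#' @param futile_cycle include a null-space two-cycle.
#' @param secretion include an exportable organic metabolite route.
#' @param secreted_carbon carbon count of the secreted species.
#' @param seed recorded for provenance (generation is deterministic).
#' @return a `toy_spec`.
#' @export
toy_spec <- function(n_pathways = 2, yields = rep(1, n_pathways),
                     uptake_limit = 10, futile_cycle = FALSE,
                     secretion = TRUE, secreted_carbon = 2, seed = 1L) {
  stopifnot(n_pathways >= 1, length(yields) == n_pathways,
            all(yields > 0), all(yields <= 6), uptake_limit > 0,
            secreted_carbon >= 1)
  structure(list(n_pathways = n_pathways, yields = yields,
                 uptake_limit = uptake_limit, futile_cycle = futile_cycle,
                 secretion = secretion, secreted_carbon = secreted_carbon,
                 seed = seed),
            class = "toy_spec")
}

#' Generate a toy metabolic model with its analytic answer sheet
#'
#' @param spec a [toy_spec()].
#' @return list of `model` (a validated, carbon-balanced `metabolic_model`)
#'   and `answers`: closed-form values — `wt_growth`
#'   (`uptake_limit * max(yields)`), `best_pathways` (which pathways attain
#'   the best yield), per-pathway flux-variability ranges at growth fraction
#'   1.0, and the glucose uptake at optimum.
#' @export
make_toy_model <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  k <- spec$n_pathways
  mets <- c("glc", "B", "co2")
  formulas <- c(glc = "C6H12O6", B = "CH2O", co2 = "CO2")
  rxns <- c("EX_glc", paste0("PWY", seq_len(k)), "EX_co2", "BIOMASS")
  if (spec$secretion) {
    mets <- c(mets, "org")
    formulas["org"] <- paste0("C", spec$secreted_carbon, "H",
                              2 * spec$secreted_carbon, "O", spec$secreted_carbon)
    rxns <- c(rxns, "SECRETE", "EX_org")
  }
  if (spec$futile_cycle) {
    mets <- c(mets, "Bx")
    formulas["Bx"] <- "CH2O"
    rxns <- c(rxns, "FC_fwd", "FC_rev")
  }
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["glc", "EX_glc"] <- -1
  for (i in seq_len(k)) {
    p <- paste0("PWY", i)
    S["glc", p] <- -1
    S["B", p] <- spec$yields[i]
    S["co2", p] <- 6 - spec$yields[i]
  }
  S["co2", "EX_co2"] <- -1
  S["B", "BIOMASS"] <- -1
  if (spec$secretion) {
    S["B", "SECRETE"] <- -spec$secreted_carbon
    S["org", "SECRETE"] <- 1
    S["org", "EX_org"] <- -1
  }
  if (spec$futile_cycle) {
    S["B", "FC_fwd"] <- -1
    S["Bx", "FC_fwd"] <- 1
    S["Bx", "FC_rev"] <- -1
    S["B", "FC_rev"] <- 1
  }
  big <- 1000
  lower <- setNames(rep(0, length(rxns)), rxns)
  upper <- setNames(rep(big, length(rxns)), rxns)
  lower["EX_glc"] <- -spec$uptake_limit
  upper["EX_glc"] <- 0
  model <- metabolic_model(reactions = rxns, metabolites = mets, S = S,
                           lower = lower, upper = upper,
                           biomass = "BIOMASS", formulas = formulas,
                           id = sprintf("toy_k%d_seed%d", k, spec$seed))

  best <- max(spec$yields)
  best_idx <- which(abs(spec$yields - best) < 1e-12)
  # FVA ranges at fraction 1.0: a best pathway can carry anything from 0 (if
  # another best pathway exists to take over) up to the full uptake; a
  # strictly worse pathway must stay at 0 at the optimum.
  fva_full <- lapply(seq_len(k), function(i) {
    if (i %in% best_idx) {
      if (length(best_idx) > 1) c(0, spec$uptake_limit) else
        c(spec$uptake_limit, spec$uptake_limit)
    } else c(0, 0)
  })
  names(fva_full) <- paste0("PWY", seq_len(k))
  answers <- list(wt_growth = spec$uptake_limit * best,
                  best_pathways = paste0("PWY", best_idx),
                  glucose_uptake_at_optimum = -spec$uptake_limit,
                  fva_full_fraction = fva_full)
  list(model = model, answers = answers, spec = spec)
}

#' Canned mutation suite for a toy model
#'
#' Produces at least: a neutral knockout (another equally good pathway
#' exists, so the mutant optimum equals the wild type's and the polytope
#' distance is 0), a yield-reducing knockout (positive distance when the
#' surviving yield ratio falls below the threshold), and a lethal knockout
#' (glucose uptake removed, growth 0).
#'
#' @param toy result of [make_toy_model()].
#' @param threshold near-optimal growth fraction the expectations refer to.
#' @return list of entries `list(mutation, expect)`, where `expect` is one
#'   of `"neutral"`, `"reduced"`, `"lethal"`, plus the expected mutant
#'   optimum.
#' @export
make_mutation_suite <- function(toy, threshold = 0.90) {
  spec <- toy$spec
  yields <- spec$yields
  best <- max(yields)
  best_idx <- which(abs(yields - best) < 1e-12)
  suite <- list()
  if (length(best_idx) > 1) {
    suite$neutral_ko <- list(
      mutation = mutation(paste0("PWY", best_idx[1])),
      expect = "neutral",
      mutant_optimum = spec$uptake_limit * best)
  } else if (spec$secretion) {
    # knocking out an unused route never moves the optimum
    suite$neutral_ko <- list(mutation = mutation("SECRETE"),
                             expect = "neutral",
                             mutant_optimum = spec$uptake_limit * best)
  } else {
    # bound override slack enough never to bind: the canonical no-op case
    suite$neutral_ko <- list(
      mutation = mutation("EX_co2", lower = 0, upper = 1000),
      expect = "neutral",
      mutant_optimum = spec$uptake_limit * best)
  }
  # knock out every best pathway; the survivor yield decides the outcome
  rest <- yields[-best_idx]
  if (length(rest)) {
    surv <- max(rest)
    suite$yield_ko <- list(
      mutation = mutation(paste0("PWY", best_idx)),
      expect = if (surv / best >= threshold) "neutral" else "reduced",
      mutant_optimum = spec$uptake_limit * surv)
  }
  suite$lethal_ko <- list(mutation = mutation("EX_glc"),
                          expect = "lethal", mutant_optimum = 0)
  suite
}

#' Write a toy fixture set to disk
#'
#' Emits the model as both COBRA JSON and SBML (so the two readers are
#' exercised by one suite) together with the answer sheet as JSON.
#'
#' @param toy result of [make_toy_model()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_toy_fixtures <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, toy$model$id)
  paths <- c(json = paste0(base, ".json"),
             sbml = paste0(base, ".xml"),
             answers = paste0(base, "_answers.json"))
  write_model(toy$model, paths["json"], "json")
  write_model(toy$model, paths["sbml"], "sbml")
  jsonlite::write_json(toy$answers, paths["answers"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' A deterministic family of toy fixtures
#'
#' Convenience generator used by the test-suite and the acceptance script:
#' a mix of single-pathway, redundant, unequal-yield, secreting and
#' futile-cycle networks, all with at most 8 reactions.
#'
#' @param n number of fixtures (cycled through the design grid).
#' @return list of [make_toy_model()] results.
#' @export
toy_fixture_family <- function(n = 20) {
  grid <- list(
    list(n_pathways = 1, yields = 1, uptake_limit = 10, secretion = FALSE),
    list(n_pathways = 1, yields = 0.5, uptake_limit = 8, secretion = FALSE),
    list(n_pathways = 2, yields = c(1, 1), uptake_limit = 10, secretion = FALSE),
    list(n_pathways = 2, yields = c(1, 0.4), uptake_limit = 10, secretion = FALSE),
    list(n_pathways = 2, yields = c(2, 1.5), uptake_limit = 5, secretion = TRUE),
    list(n_pathways = 3, yields = c(1, 1, 0.6), uptake_limit = 6, secretion = FALSE),
    list(n_pathways = 2, yields = c(1, 0.8), uptake_limit = 10, secretion = TRUE),
    list(n_pathways = 1, yields = 2, uptake_limit = 4, secretion = TRUE,
         futile_cycle = TRUE),
    list(n_pathways = 2, yields = c(3, 2.9), uptake_limit = 3, secretion = FALSE),
    list(n_pathways = 2, yields = c(1.2, 0.3), uptake_limit = 7, secretion = TRUE)
  )
  lapply(seq_len(n), function(i) {
    g <- grid[[(i - 1) %% length(grid) + 1]]
    g$seed <- i
    make_toy_model(do.call(toy_spec, g))
  })
}
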