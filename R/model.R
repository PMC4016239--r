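# ---------------------------------------------------------------------------
# The metabolic model container: stoichiometric matrix S (metabolites x
# reactions), per-reaction flux bounds b_L, b_U in mmol/gDW/hr, a designated
# biomass (growth) reaction, exchange reactions, metabolite formulas, and
# optional boolean gene-protein-reaction rules. Sign convention follows COBRA:
# exchange uptake is negative flux, secretion positive.
# ---------------------------------------------------------------------------

#' Construct a metabolic model
#'
#' @param reactions character vector of reaction identifiers (column order of
#'   `S`).
#' @param metabolites character vector of metabolite identifiers (row order).
#' @param S stoichiometric matrix, metabolites x reactions; coerced to a
#'   sparse `Matrix`.
#' @param lower,upper per-reaction flux bounds (mmol/gDW/hr). Irreversible
#'   reactions must have `lower >= 0`.
#' @param biomass identifier of the growth reaction.
#' @param exchanges identifiers of boundary (exchange) reactions. If `NULL`,
#'   detected as columns touching exactly one metabolite, excluding the
#'   biomass reaction.
#' @param formulas named character vector of elemental formulas per
#'   metabolite (optional, needed for carbon accounting).
#' @param gpr named character vector of boolean gene associations per
#'   reaction, e.g. `"(g1 and g2) or g3"` (optional).
#' @param id model identifier.
#' @param default_bound magnitude used for "unbounded" reactions; keeps every
#'   flux polytope bounded so vertex sampling is well defined.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(reactions, metabolites, S, lower, upper,
                            biomass, exchanges = NULL, formulas = NULL,
                            gpr = NULL, id = "model", default_bound = 1000) {
  S <- Matrix::Matrix(S, sparse = TRUE)
  dimnames(S) <- list(metabolites, reactions)
  lower <- setNames(as.numeric(lower), reactions)
  upper <- setNames(as.numeric(upper), reactions)
  if (is.null(exchanges)) {
    nz_per_col <- Matrix::colSums(S != 0)
    exchanges <- setdiff(reactions[nz_per_col == 1], biomass)
  }
  model <- structure(list(id = id, reactions = reactions,
                          metabolites = metabolites, S = S,
                          lower = lower, upper = upper,
                          biomass = biomass, exchanges = exchanges,
                          formulas = formulas, gpr = gpr,
                          genes = gpr_genes(gpr),
                          default_bound = default_bound),
                     class = "metabolic_model")
  validate_model(model)
}

#' Validate a metabolic model
#'
#' Checks structural invariants: bound ordering, biomass and exchange
#' membership, and stoichiometry dimensions. Returns the model invisibly on
#' success, errors otherwise.
#'
#' @param model a `metabolic_model`.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  n <- length(model$reactions)
  m <- length(model$metabolites)
  if (ncol(model$S) != n) stop("stoichiometry column count must equal number of reactions")
  if (nrow(model$S) != m) stop("stoichiometry row count must equal number of metabolites")
  if (anyDuplicated(model$reactions)) stop("duplicate reaction ids")
  if (anyDuplicated(model$metabolites)) stop("duplicate metabolite ids")
  if (any(model$lower > model$upper + 1e-12)) {
    bad <- model$reactions[model$lower > model$upper + 1e-12]
    stop("lower bound exceeds upper bound for: ", paste(bad, collapse = ", "))
  }
  if (!model$biomass %in% model$reactions) {
    stop("biomass reaction '", model$biomass, "' not in model")
  }
  missing_ex <- setdiff(model$exchanges, model$reactions)
  if (length(missing_ex)) {
    stop("exchange ids not in model: ", paste(missing_ex, collapse = ", "))
  }
  if (!is.null(model$formulas)) {
    unknown <- setdiff(names(model$formulas), model$metabolites)
    if (length(unknown)) stop("formulas for unknown metabolites: ",
                              paste(unknown, collapse = ", "))
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, ": ", length(x$metabolites), " metabolites x ",
      length(x$reactions), " reactions; biomass = ", x$biomass,
      "; ", length(x$exchanges), " exchanges\n", sep = "")
  invisible(x)
}

n_reactions <- function(model) length(model$reactions)

rxn_index <- function(model, ids) {
  idx <- match(ids, model$reactions)
  if (anyNA(idx)) stop("unknown reaction id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Media specification
#'
#' Uptake limits on exchange reactions plus the non-growth-associated ATP
#' maintenance requirement. The growth-associated ATP cost is recorded as
#' metadata; it enters the model through the biomass equation, not through a
#' bound. The minimal-glucose preset used throughout mirrors standard
#' aerobic glucose medium: glucose 8, oxygen 18.5, maintenance 8.39
#' (all mmol/gDW/hr), growth-associated ATP 59.81 mmol/gDW.
#'
#' @param uptake_limits named numeric vector, exchange reaction id -> maximum
#'   uptake rate (non-negative, mmol/gDW/hr).
#' @param maintenance_flux non-growth ATP maintenance (mmol/gDW/hr), imposed
#'   by fixing the maintenance reaction to this value.
#' @param maintenance_reaction id of the ATP maintenance reaction.
#' @param growth_associated_atp recorded metadata (mmol/gDW).
#' @return an object of class `media_spec`.
#' @export
media_spec <- function(uptake_limits = numeric(0), maintenance_flux = 0,
                       maintenance_reaction = "ATPM",
                       growth_associated_atp = NA_real_) {
  if (any(uptake_limits < 0) || maintenance_flux < 0) {
    stop("media rates must be non-negative")
  }
  structure(list(uptake_limits = uptake_limits,
                 maintenance_flux = maintenance_flux,
                 maintenance_reaction = maintenance_reaction,
                 growth_associated_atp = growth_associated_atp),
            class = "media_spec")
}

#' The minimal-glucose media preset
#'
#' Glucose 8 and oxygen 18.5 mmol/gDW/hr, non-growth ATP maintenance 8.39
#' mmol/gDW/hr, growth-associated ATP 59.81 mmol/gDW — the standard aerobic
#' glucose formulation for the iAF1260 E. coli reconstruction.
#'
#' @param glucose_exchange,oxygen_exchange,maintenance_reaction reaction ids
#'   in the target model.
#' @return a [media_spec()].
#' @export
media_iaf1260_glucose <- function(glucose_exchange = "EX_glc__D_e",
                                  oxygen_exchange = "EX_o2_e",
                                  maintenance_reaction = "ATPM") {
  media_spec(uptake_limits = setNames(c(8, 18.5),
                                      c(glucose_exchange, oxygen_exchange)),
             maintenance_flux = 8.39,
             maintenance_reaction = maintenance_reaction,
             growth_associated_atp = 59.81)
}

#' Apply a media specification to a model
#'
#' Sets each listed exchange's lower bound to `-limit` (uptake is negative
#' flux), leaves unlisted exchanges at their defaults ("available in excess"
#' nutrients keep effectively unlimited uptake), and fixes the maintenance
#' reaction to the maintenance flux (both bounds).
#'
#' @param model a `metabolic_model`.
#' @param media a [media_spec()].
#' @return the constrained model.
#' @export
apply_media <- function(model, media) {
  stopifnot(inherits(model, "metabolic_model"), inherits(media, "media_spec"))
  ids <- names(media$uptake_limits)
  not_ex <- setdiff(ids, model$exchanges)
  if (length(not_ex)) {
    stop("uptake limit on non-exchange reaction(s): ", paste(not_ex, collapse = ", "))
  }
  for (i in seq_along(ids)) {
    model$lower[ids[i]] <- -media$uptake_limits[[i]]
    if (model$upper[ids[i]] < model$lower[ids[i]]) {
      model$upper[ids[i]] <- model$lower[ids[i]]
    }
  }
  if (media$maintenance_flux > 0) {
    mr <- media$maintenance_reaction
    if (!mr %in% model$reactions) {
      stop("maintenance reaction '", mr, "' absent but maintenance_flux > 0")
    }
    model$lower[mr] <- media$maintenance_flux
    model$upper[mr] <- media$maintenance_flux
  }
  validate_model(model)
  model
}

#' Mutation (knockout or bound override)
#'
#' Targets are reaction ids or gene ids. The default override `[0, 0]`
#' encodes a knockout; other overrides tighten the targeted reactions to the
#' intersection of the base bounds and the override interval, matching the
#' mutant polytope definition `b_L <= q <= b_U` and `b'_L <= q_MUT <= b'_U`.
#'
#' @param targets character vector of reaction or gene ids.
#' @param lower,upper override bounds (recycled across targets).
#' @param type `"auto"` resolves each target as a reaction id first, then as
#'   a gene id; or force `"reaction"` / `"gene"`.
#' @return an object of class `mutation`.
#' @export
mutation <- function(targets, lower = 0, upper = 0,
                     type = c("auto", "reaction", "gene")) {
  type <- match.arg(type)
  lower <- rep_len(lower, length(targets))
  upper <- rep_len(upper, length(targets))
  if (any(lower > upper)) stop("mutation lower bound exceeds upper bound")
  structure(list(targets = as.character(targets), lower = lower,
                 upper = upper, type = type),
            class = "mutation")
}

#' Apply a mutation to a model
#'
#' Reaction targets get bounds intersected with the override interval
#' (knockouts become `[0, 0]`). Gene targets are translated through the
#' boolean gene-protein-reaction rules: a reaction is disabled exactly when
#' its rule evaluates false with the deleted genes absent (`and` = all
#' required, `or` = alternatives). Idempotent: applying the same mutation
#' twice changes nothing further.
#'
#' @param model a `metabolic_model`.
#' @param mut a [mutation()].
#' @return the mutant model.
#' @export
apply_mutation <- function(model, mut) {
  stopifnot(inherits(model, "metabolic_model"), inherits(mut, "mutation"))
  clamp <- function(model, i, lo, up) {
    model$lower[i] <- max(model$lower[i], lo)
    model$upper[i] <- min(model$upper[i], up)
    if (model$lower[i] > model$upper[i]) {
      # empty intersection collapses the reaction to zero flux
      model$lower[i] <- 0
      model$upper[i] <- 0
    }
    model
  }
  as_gene <- vapply(seq_along(mut$targets), function(k) {
    switch(mut$type, reaction = FALSE, gene = TRUE,
           auto = !(mut$targets[k] %in% model$reactions))
  }, logical(1))
  for (k in which(!as_gene)) {
    model <- clamp(model, rxn_index(model, mut$targets[k]),
                   mut$lower[k], mut$upper[k])
  }
  if (any(as_gene)) {
    genes <- mut$targets[as_gene]
    if (is.null(model$gpr)) {
      stop("gene target(s) ", paste0("'", genes, "'", collapse = ", "),
           " but model has no GPR rules; only reaction-level knockouts",
           " are possible")
    }
    unknown <- setdiff(genes, model$genes)
    if (length(unknown)) stop("unknown gene id: ", paste(unknown, collapse = ", "))
    # evaluate every rule with the full deletion set absent at once: two
    # deleted isozymes must jointly disable their reaction
    affected <- names(model$gpr)[vapply(model$gpr, function(rule) {
      any(genes %in% gpr_rule_genes(rule)) && !gpr_eval(rule, absent = genes)
    }, logical(1))]
    k1 <- which(as_gene)[1]
    for (r in affected) {
      model <- clamp(model, rxn_index(model, r), mut$lower[k1], mut$upper[k1])
    }
  }
  validate_model(model)
  model
}

# Evaluate a boolean GPR rule with the given genes deleted. Every other gene
# is assumed present. Rules use `and`/`or` (case-insensitive) and parentheses.
gpr_eval <- function(rule, absent) {
  genes <- gpr_rule_genes(rule)
  expr <- rule
  expr <- gsub("\\band\\b", "&&", expr, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "||", expr, ignore.case = TRUE)
  vals <- setNames(as.list(!(genes %in% absent)), genes)
  ok <- tryCatch(eval(parse(text = expr)[[1]], envir = vals),
                 error = function(e) stop("unparseable GPR rule: ", rule))
  isTRUE(ok)
}

gpr_rule_genes <- function(rule) {
  toks <- regmatches(rule, gregexpr("[A-Za-z_][A-Za-z0-9_.-]*", rule))[[1]]
  setdiff(unique(toks), c("and", "or", "AND", "OR", "And", "Or"))
}

gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(NULL)
  unique(unlist(lapply(gpr, gpr_rule_genes)))
}

#' Count carbon atoms in an elemental formula
#'
#' Parses Hill-style formula tokens (element symbol + optional count) and
#' returns the carbon stoichiometry. Two-letter symbols are respected, so
#' `Cl`, `Ca`, `Co` etc. do not count as carbon.
#'
#' @param formula elemental formula string, e.g. `"C6H12O6"`.
#' @return non-negative integer carbon count (vectorised).
#' @examples
#' carbon_count("C6H12O6")  # 6
#' carbon_count("H2O")      # 0
#' @export
carbon_count <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(f)) {
      stop("unparseable formula: '", f, "'")
    }
    cnt <- 0
    for (tok in toks) {
      el <- gsub("[0-9]", "", tok)
      num <- gsub("[^0-9]", "", tok)
      if (el == "C") cnt <- cnt + if (nzchar(num)) as.numeric(num) else 1
    }
    cnt
  }, numeric(1), USE.NAMES = FALSE)
}
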