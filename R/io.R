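# ---------------------------------------------------------------------------
# Model readers/writers. Two dialects: COBRA-style JSON (jsonlite) and SBML
# Level 3 Version 1 with the fbc package (xml2). Both round-trip the fields
# the solvers need: stoichiometry, bounds, biomass objective, formulas, GPR.
# ---------------------------------------------------------------------------

#' Load a metabolic model from file
#'
#' @param path file path.
#' @param format `"json"` (COBRA-style) or `"sbml"` (Level 3 with fbc
#'   annotations); guessed from the extension when omitted.
#' @param biomass optional explicit biomass reaction id. When absent the
#'   objective annotation is used; if that is missing, a single reaction id
#'   matching `biomass` (case-insensitive) is accepted. Ambiguity is an
#'   error, never a guess.
#' @param default_bound magnitude substituted for unbounded reactions.
#' @return a validated `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml"),
                       biomass = NULL, default_bound = 1000) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  switch(format,
         json = load_model_json(path, biomass, default_bound),
         sbml = load_model_sbml(path, biomass, default_bound))
}

resolve_biomass <- function(reactions, objective_id, explicit, path) {
  if (!is.null(explicit)) {
    if (!explicit %in% reactions) {
      stop("configured biomass reaction '", explicit, "' not found in ", path)
    }
    return(explicit)
  }
  if (!is.null(objective_id) && length(objective_id) == 1 &&
      objective_id %in% reactions) {
    return(objective_id)
  }
  hits <- reactions[grepl("biomass|growth", reactions, ignore.case = TRUE)]
  if (length(hits) == 1) return(hits)
  if (length(hits) == 0) stop("no biomass reaction identifiable in ", path)
  stop("ambiguous biomass reaction in ", path, ": ", paste(hits, collapse = ", "))
}

load_model_json <- function(path, biomass = NULL, default_bound = 1000) {
  doc <- jsonlite::read_json(path)
  mets <- vapply(doc$metabolites, function(m) m$id, character(1))
  formulas <- vapply(doc$metabolites, function(m) {
    if (is.null(m$formula)) NA_character_ else m$formula
  }, character(1))
  names(formulas) <- mets
  rxns <- vapply(doc$reactions, function(r) r$id, character(1))
  n <- length(rxns)
  S <- Matrix::Matrix(0, length(mets), n, sparse = TRUE)
  lower <- numeric(n)
  upper <- numeric(n)
  obj_id <- NULL
  gpr <- character(0)
  for (j in seq_len(n)) {
    r <- doc$reactions[[j]]
    coefs <- unlist(r$metabolites)
    if (length(coefs)) {
      idx <- match(names(coefs), mets)
      if (anyNA(idx)) {
        stop("reaction '", r$id, "' cites undeclared metabolite(s): ",
             paste(names(coefs)[is.na(idx)], collapse = ", "))
      }
      S[idx, j] <- as.numeric(coefs)
    }
    rev_flag <- isTRUE(r$reversible)
    lower[j] <- if (!is.null(r$lower_bound)) r$lower_bound else
      if (rev_flag) -default_bound else 0
    upper[j] <- if (!is.null(r$upper_bound)) r$upper_bound else default_bound
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0) {
      obj_id <- c(obj_id, r$id)
    }
    if (!is.null(r$gene_reaction_rule) && nzchar(r$gene_reaction_rule)) {
      gpr[r$id] <- r$gene_reaction_rule
    }
  }
  lower[!is.finite(lower)] <- -default_bound
  upper[!is.finite(upper)] <- default_bound
  bio <- resolve_biomass(rxns, obj_id, biomass, path)
  metabolic_model(rxns, mets, S, lower, upper, biomass = bio,
                  formulas = if (all(is.na(formulas))) NULL else formulas,
                  gpr = if (length(gpr)) gpr else NULL,
                  id = if (!is.null(doc$id)) doc$id else basename(path),
                  default_bound = default_bound)
}

#' Write a metabolic model
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @param format `"json"` or `"sbml"`.
#' @export
write_model <- function(model, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

write_model_json <- function(model, path) {
  Sd <- as.matrix(model$S)
  mets <- lapply(model$metabolites, function(m) {
    out <- list(id = m)
    if (!is.null(model$formulas) && !is.na(model$formulas[m])) {
      out$formula <- unname(model$formulas[m])
    }
    out
  })
  rxns <- lapply(seq_along(model$reactions), function(j) {
    r <- model$reactions[j]
    nz <- which(Sd[, j] != 0)
    out <- list(id = r,
                metabolites = as.list(setNames(Sd[nz, j], model$metabolites[nz])),
                lower_bound = unname(model$lower[j]),
                upper_bound = unname(model$upper[j]),
                reversible = unname(model$lower[j] < 0))
    if (r == model$biomass) out$objective_coefficient <- 1
    if (!is.null(model$gpr) && r %in% names(model$gpr)) {
      out$gene_reaction_rule <- unname(model$gpr[r])
    }
    out
  })
  genes <- lapply(model$genes, function(g) list(id = g))
  jsonlite::write_json(list(id = model$id, metabolites = mets,
                            reactions = rxns, genes = genes),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

write_model_sbml <- function(model, path) {
  Sd <- as.matrix(model$S)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)),
    '    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    "    <listOfSpecies>")
  for (m in model$metabolites) {
    formula <- if (!is.null(model$formulas) && !is.na(model$formulas[m])) {
      sprintf(' fbc:chemicalFormula="%s"', esc(model$formulas[m]))
    } else ""
    lines <- c(lines, sprintf(
      '      <species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"%s/>',
      esc(m), formula))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (j in seq_along(model$reactions)) {
    lines <- c(lines,
               sprintf('      <parameter id="lb_%d" value="%s" constant="true"/>', j, fmt(model$lower[j])),
               sprintf('      <parameter id="ub_%d" value="%s" constant="true"/>', j, fmt(model$upper[j])))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[j]
    rev_flag <- if (model$lower[j] < 0) "true" else "false"
    gpr_xml <- ""
    if (!is.null(model$gpr) && r %in% names(model$gpr)) {
      gpr_xml <- sprintf(
        "\n        <fbc:geneProductAssociation>%s</fbc:geneProductAssociation>",
        gpr_to_xml(model$gpr[[r]]))
    }
    reac <- which(Sd[, j] < 0)
    prod <- which(Sd[, j] > 0)
    body <- character(0)
    if (length(reac)) {
      body <- c(body, "        <listOfReactants>",
                sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                        esc(model$metabolites[reac]), fmt(-Sd[reac, j])),
                "        </listOfReactants>")
    }
    if (length(prod)) {
      body <- c(body, "        <listOfProducts>",
                sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                        esc(model$metabolites[prod]), fmt(Sd[prod, j])),
                "        </listOfProducts>")
    }
    lines <- c(lines, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_%d" fbc:upperFluxBound="ub_%d">%s',
      esc(r), rev_flag, j, j, gpr_xml), body, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>",
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             "        <fbc:listOfFluxObjectives>",
             sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                     esc(model$biomass)),
             "        </fbc:listOfFluxObjectives>",
             "      </fbc:objective>",
             "    </fbc:listOfObjectives>")
  if (!is.null(model$genes) && length(model$genes)) {
    lines <- c(lines, "    <fbc:listOfGeneProducts>",
               sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                       esc(model$genes), esc(model$genes)),
               "    </fbc:listOfGeneProducts>")
  }
  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path)
}

gpr_to_xml <- function(rule) {
  # parse a boolean rule into the fbc association tree
  node <- gpr_parse(rule)
  gpr_node_xml(node)
}

gpr_node_xml <- function(node) {
  if (node$type == "gene") {
    return(sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>', node$id))
  }
  tag <- if (node$type == "and") "fbc:and" else "fbc:or"
  inner <- paste(vapply(node$children, gpr_node_xml, character(1)), collapse = "")
  sprintf("<%s>%s</%s>", tag, inner, tag)
}

# Minimal recursive-descent parser for `a and (b or c)` style rules.
gpr_parse <- function(rule) {
  toks <- regmatches(rule, gregexpr("\\(|\\)|[A-Za-z_][A-Za-z0-9_.-]*", rule))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L; toks[pos - 1L] }
  parse_or <- function() {
    left <- parse_and()
    children <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      children <- c(children, list(parse_and()))
    }
    if (length(children) == 1) left else list(type = "or", children = children)
  }
  parse_and <- function() {
    left <- parse_atom()
    children <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      children <- c(children, list(parse_atom()))
    }
    if (length(children) == 1) left else list(type = "and", children = children)
  }
  parse_atom <- function() {
    tok <- advance()
    if (identical(tok, "(")) {
      node <- parse_or()
      if (!identical(advance(), ")")) stop("unbalanced parentheses in GPR: ", rule)
      return(node)
    }
    list(type = "gene", id = tok)
  }
  out <- parse_or()
  if (pos <= length(toks)) stop("trailing tokens in GPR: ", rule)
  out
}

gpr_xml_to_rule <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    return(xml2::xml_attr(node, "geneProduct"))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, gpr_xml_to_rule, character(1))
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

load_model_sbml <- function(path, biomass = NULL, default_bound = 1000) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- xml2::xml_attr(sp_nodes, "id")
  formulas <- vapply(sp_nodes, function(nd) {
    v <- xml2::xml_attr(nd, "fbc:chemicalFormula")
    if (is.na(v)) xml2::xml_attr(nd, "chemicalFormula") else v
  }, character(1))
  names(formulas) <- mets
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                    xml2::xml_attr(params, "id"))
  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- xml2::xml_attr(rxn_nodes, "id")
  n <- length(rxns)
  S <- Matrix::Matrix(0, length(mets), n, sparse = TRUE)
  lower <- numeric(n)
  upper <- numeric(n)
  gpr <- character(0)
  for (j in seq_len(n)) {
    nd <- rxn_nodes[[j]]
    for (sr in xml2::xml_find_all(nd, "./s:listOfReactants/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(sr, "species")
      i <- match(sp, mets)
      if (is.na(i)) stop("reaction '", rxns[j], "' cites undeclared metabolite: ", sp)
      S[i, j] <- S[i, j] - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(nd, "./s:listOfProducts/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(sr, "species")
      i <- match(sp, mets)
      if (is.na(i)) stop("reaction '", rxns[j], "' cites undeclared metabolite: ", sp)
      S[i, j] <- S[i, j] + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    lb_id <- xml2::xml_attr(nd, "lowerFluxBound")
    ub_id <- xml2::xml_attr(nd, "upperFluxBound")
    rev_flag <- identical(xml2::xml_attr(nd, "reversible"), "true")
    lower[j] <- if (!is.na(lb_id) && lb_id %in% names(pvals)) pvals[[lb_id]] else
      if (rev_flag) -default_bound else 0
    upper[j] <- if (!is.na(ub_id) && ub_id %in% names(pvals)) pvals[[ub_id]] else default_bound
    assoc <- xml2::xml_find_first(nd, "./fbc:geneProductAssociation/*", ns)
    if (!inherits(assoc, "xml_missing")) {
      gpr[rxns[j]] <- gpr_xml_to_rule(assoc)
    }
  }
  lower[!is.finite(lower)] <- -default_bound
  upper[!is.finite(upper)] <- default_bound
  obj_node <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  obj_id <- if (!inherits(obj_node, "xml_missing")) {
    xml2::xml_attr(obj_node, "reaction")
  } else NULL
  model_id <- xml2::xml_attr(xml2::xml_find_first(doc, ".//s:model", ns), "id")
  bio <- resolve_biomass(rxns, obj_id, biomass, path)
  metabolic_model(rxns, mets, S, lower, upper, biomass = bio,
                  formulas = if (all(is.na(formulas))) NULL else formulas,
                  gpr = if (length(gpr)) gpr else NULL,
                  id = if (is.na(model_id)) basename(path) else model_id,
                  default_bound = default_bound)
}

#' Write a flux vector as a CSV table
#'
#' Columns: `reaction_id, flux, lower_bound, upper_bound`.
#'
#' @param model the model supplying ids and bounds.
#' @param flux named flux vector.
#' @param path output path.
#' @export
write_flux_csv <- function(model, flux, path) {
  df <- data.frame(reaction_id = model$reactions,
                   flux = as.numeric(flux[model$reactions]),
                   lower_bound = as.numeric(model$lower),
                   upper_bound = as.numeric(model$upper))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a flux vector from a CSV table
#'
#' @param path CSV with columns `reaction_id` and `flux`.
#' @return named numeric vector.
#' @export
read_flux_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  setNames(df$flux, df$reaction_id)
}
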