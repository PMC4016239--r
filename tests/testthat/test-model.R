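test_that("model construction enforces structural invariants", {
  m <- segment_model()
  expect_s3_class(m, "metabolic_model")
  expect_equal(ncol(m$S), length(m$reactions))
  expect_true(all(m$lower <= m$upper))
  # exchange detection: single-metabolite columns except biomass
  expect_setequal(m$exchanges, c("SRC", "SINK_A"))

  expect_error(metabolic_model("R1", "M1", matrix(1), lower = 2, upper = 1,
                               biomass = "R1"), "exceeds")
  expect_error(metabolic_model("R1", "M1", matrix(1), lower = 0, upper = 1,
                               biomass = "nope"), "not in model")
  expect_error(metabolic_model(c("R1", "R1"), "M1", matrix(1, 1, 2),
                               lower = c(0, 0), upper = c(1, 1),
                               biomass = "R1"), "duplicate")
})

test_that("carbon counting parses Hill formulas and rejects garbage", {
  expect_equal(carbon_count("C6H12O6"), 6)
  expect_equal(carbon_count("H2O"), 0)
  expect_equal(carbon_count("CO2"), 1)
  # two-letter symbols must not count as carbon
  expect_equal(carbon_count("CaCl2"), 0)
  expect_equal(carbon_count(c("C10H12N5O13P3", "CH4")), c(10, 1))
  expect_error(carbon_count("C6H12-O6"), "unparseable")
  expect_true(is.na(carbon_count(NA_character_)))
})

test_that("media application sets uptake bounds and pins maintenance", {
  toy <- make_toy_model(toy_spec(uptake_limit = 20))
  m <- toy$model
  med <- media_spec(uptake_limits = c(EX_glc = 8))
  m2 <- apply_media(m, med)
  expect_equal(unname(m2$lower["EX_glc"]), -8)
  # starvation: zero uptake of the sole carbon source kills growth
  m0 <- apply_media(m, media_spec(uptake_limits = c(EX_glc = 0)))
  expect_equal(fba(m0)$growth, 0, tolerance = 1e-8)

  # maintenance pinned to both bounds; glucose/oxygen preset carries 8.39
  atpm <- m
  atpm$reactions <- c(atpm$reactions, "ATPM")
  atpm$S <- cbind(atpm$S, 0)
  colnames(atpm$S)[ncol(atpm$S)] <- "ATPM"
  atpm$lower <- c(atpm$lower, ATPM = 0)
  atpm$upper <- c(atpm$upper, ATPM = 1000)
  atpm <- validate_model(atpm)
  preset <- media_iaf1260_glucose(glucose_exchange = "EX_glc")
  expect_equal(preset$maintenance_flux, 8.39)
  expect_equal(unname(preset$uptake_limits), c(8, 18.5))
  expect_equal(preset$growth_associated_atp, 59.81)
  m3 <- apply_media(atpm, media_spec(maintenance_flux = 8.39,
                                     maintenance_reaction = "ATPM"))
  expect_equal(unname(m3$lower["ATPM"]), 8.39)
  expect_equal(unname(m3$upper["ATPM"]), 8.39)

  expect_error(apply_media(m, media_spec(uptake_limits = c(PWY1 = 5))),
               "non-exchange")
  expect_error(apply_media(m, media_spec(maintenance_flux = 1,
                                         maintenance_reaction = "ATPM")),
               "absent")
  expect_error(media_spec(uptake_limits = c(EX_glc = -1)), "non-negative")
})

test_that("reaction mutations intersect bounds and are idempotent", {
  m <- make_toy_model(toy_spec())$model
  ko <- mutation("PWY1")
  m1 <- apply_mutation(m, ko)
  expect_equal(unname(m1$lower["PWY1"]), 0)
  expect_equal(unname(m1$upper["PWY1"]), 0)
  expect_identical(apply_mutation(m1, ko)$lower, m1$lower)

  # override [0,3] touches only the targeted pair
  m2 <- apply_mutation(m, mutation("PWY2", lower = 0, upper = 3))
  expect_equal(unname(m2$upper["PWY2"]), 3)
  untouched <- setdiff(m$reactions, "PWY2")
  expect_identical(m2$lower[untouched], m$lower[untouched])
  expect_identical(m2$upper[untouched], m$upper[untouched])

  expect_error(apply_mutation(m, mutation("missing", type = "reaction")),
               "unknown reaction")
})

test_that("gene knockouts follow boolean GPR evaluation", {
  m <- gpr_toy_model()
  # isozyme redundancy: (g1 or g2) survives deletion of g1
  m1 <- apply_mutation(m, mutation("g1"))
  expect_gt(unname(m1$upper["PWY1"]), 0)
  # both isozymes gone: reaction disabled
  m2 <- apply_mutation(m, mutation(c("g1", "g2")))
  expect_equal(unname(m2$upper["PWY1"]), 0)
  # complex subunit: (g3 and g4) dies with g3 alone
  m3 <- apply_mutation(m, mutation("g3"))
  expect_equal(unname(m3$upper["PWY2"]), 0)
  expect_gt(unname(m3$upper["PWY1"]), 0)

  expect_error(apply_mutation(m, mutation("g99")), "unknown gene")
  no_gpr <- make_toy_model(toy_spec())$model
  expect_error(apply_mutation(no_gpr, mutation("g1", type = "gene")),
               "no GPR")
})

test_that("JSON and SBML round-trips preserve the model exactly", {
  toy <- make_toy_model(toy_spec(n_pathways = 2, yields = c(1, 0.4),
                                 uptake_limit = 10, futile_cycle = TRUE))
  m <- toy$model
  m$gpr <- c(PWY1 = "(g1 or g2)", PWY2 = "g3 and (g4 or g5)")
  m$genes <- c("g1", "g2", "g3", "g4", "g5")
  for (fmt in c("json", "sbml")) {
    path <- tempfile(fileext = if (fmt == "json") ".json" else ".xml")
    write_model(m, path, fmt)
    m2 <- load_model(path, fmt)
    expect_identical(m2$reactions, m$reactions)
    expect_identical(m2$metabolites, m$metabolites)
    expect_equal(as.matrix(m2$S), as.matrix(m$S), ignore_attr = TRUE)
    expect_equal(unname(m2$lower), unname(m$lower))
    expect_equal(unname(m2$upper), unname(m$upper))
    expect_equal(m2$biomass, m$biomass)
    expect_equal(unname(m2$formulas[m2$metabolites]),
                 unname(m$formulas[m$metabolites]))
    # GPR semantics preserved (string form may be re-parenthesised)
    for (g in c("g1", "g3", "g4")) {
      a <- apply_mutation(m, mutation(g))
      b <- apply_mutation(m2, mutation(g))
      expect_equal(unname(b$upper), unname(a$upper))
    }
  }
})

test_that("the loader rejects undeclared metabolites and ambiguous biomass", {
  bad <- list(id = "bad",
              metabolites = list(list(id = "A")),
              reactions = list(list(id = "R1",
                                    metabolites = list(A = -1, GHOST = 1),
                                    lower_bound = 0, upper_bound = 10,
                                    objective_coefficient = 1)))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(load_model(path), "undeclared metabolite")

  amb <- list(id = "amb",
              metabolites = list(list(id = "A")),
              reactions = list(
                list(id = "biomass_a", metabolites = list(A = -1),
                     lower_bound = 0, upper_bound = 10),
                list(id = "biomass_b", metabolites = list(A = 1),
                     lower_bound = 0, upper_bound = 10)))
  path2 <- tempfile(fileext = ".json")
  jsonlite::write_json(amb, path2, auto_unbox = TRUE)
  expect_error(load_model(path2), "ambiguous")
  m <- load_model(path2, biomass = "biomass_a")
  expect_equal(m$biomass, "biomass_a")
})

test_that("reversibility conventions give symmetric or one-sided defaults", {
  doc <- list(id = "conv",
              metabolites = list(list(id = "A")),
              reactions = list(
                list(id = "rev", metabolites = list(A = 1), reversible = TRUE),
                list(id = "irr", metabolites = list(A = -1), reversible = FALSE),
                list(id = "growth", metabolites = list(A = -1),
                     lower_bound = 0, upper_bound = 10,
                     objective_coefficient = 1)))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  m <- load_model(path)
  expect_equal(unname(m$lower["rev"]), -1000)
  expect_equal(unname(m$upper["rev"]), 1000)
  expect_equal(unname(m$lower["irr"]), 0)
})
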