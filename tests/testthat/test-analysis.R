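test_that("lethality is called at 5% of wild-type growth", {
  expect_equal(lethality_call(0, 10), "lethal")
  expect_equal(lethality_call(0.4, 10), "lethal")     # ratio 0.04
  expect_equal(lethality_call(10, 10), "viable")
  expect_equal(lethality_call(c(0.49, 0.51), 10), c("lethal", "viable"))
  expect_error(lethality_call(1, 0), "wild_type_growth > 0")
})

test_that("carbon partitioning balances a hand-built oxidation network", {
  # glucose either fully oxidised or burned for biomass
  m <- metabolic_model(
    reactions = c("EX_glc", "OX", "EX_co2", "BIOMASS"),
    metabolites = c("glc", "co2"),
    S = matrix(c(-1, 0, -1, 6, 0, -1, -1, 0), 2, 4,
               dimnames = list(c("glc", "co2"),
                               c("EX_glc", "OX", "EX_co2", "BIOMASS"))),
    lower = c(-10, 0, 0, 0), upper = c(0, 1000, 1000, 1000),
    biomass = "BIOMASS",
    formulas = c(glc = "C6H12O6", co2 = "CO2"))
  # all carbon to CO2
  flux <- c(EX_glc = -10, OX = 10, EX_co2 = 60, BIOMASS = 0)
  cf <- carbon_partition(m, flux)
  expect_equal(cf$consumed, 60)
  expect_equal(cf$co2_fraction, 1.0)
  expect_equal(cf$biomass_fraction, 0)
  # zero flux: all molar fluxes zero
  cf0 <- carbon_partition(m, flux * 0)
  expect_equal(cf0$consumed, 0)
  expect_equal(cf0$co2, 0)
})

test_that("consumed carbon equals biomass + CO2 + secreted on solved fixtures", {
  for (toy in toy_fixture_family(6)) {
    m <- toy$model
    wt <- fba(m, parsimonious = TRUE)
    cf <- carbon_partition(m, wt$flux)
    expect_lt(abs(cf$consumed - cf$biomass - cf$co2 - cf$secreted),
              1e-6 * max(1, cf$consumed))
    mm <- apply_mutation(m, mutation("PWY1"))
    ps <- pseudo(m, mm, 0.9)
    if (ps$status == "optimal") {
      cfq <- carbon_partition(m, ps$q)
      expect_lt(abs(cfq$consumed - cfq$biomass - cfq$co2 - cfq$secreted),
                1e-6 * max(1, cfq$consumed))
    }
  }
})

test_that("missing boundary formulas are an error, not a silent zero", {
  toy <- make_toy_model(toy_spec())
  m <- toy$model
  m$formulas["co2"] <- NA
  expect_error(carbon_partition(m, fba(m)$flux), "missing formula")
})

test_that("sensitivity scans pin fluxes and keep infeasible pins visible", {
  toy <- make_toy_model(toy_spec(n_pathways = 2, yields = c(1, 0.4),
                                 uptake_limit = 10))
  m <- toy$model
  wt <- fba(m)
  # pinning a flux at its unconstrained optimum leaves the objective alone
  opt_co2 <- unname(wt$flux["EX_co2"])
  # the low-yield pathway emits 5.6 C per glucose, capping CO2 output at 56;
  # 1.05 x the optimum (52.5) is reachable only by sacrificing growth
  tab <- sensitivity_scan(m, pinned_flux = "EX_co2",
                          values = c(opt_co2, opt_co2 * 1.05, 2000),
                          method = "fba")
  expect_equal(tab$growth[1], wt$growth, tolerance = 1e-6)
  expect_lt(tab$growth[2], wt$growth)
  expect_equal(tab$status[3], "infeasible")   # beyond reachable CO2 output

  # growth as a function of a pinned branch flux is concave piecewise-linear
  vals <- seq(0, 10, by = 1)
  g <- sensitivity_scan(m, pinned_flux = "PWY1", values = vals,
                        method = "fba")$growth
  d2 <- diff(diff(g))
  expect_true(all(d2 <= 1e-6))
  expect_error(sensitivity_scan(m, pinned_flux = "PWY1", values = numeric(0)),
               "empty value list")
})

test_that("the threshold sweep is monotone and flags the overlap onset", {
  toy <- make_toy_model(toy_spec(n_pathways = 2, yields = c(1, 0.85),
                                 uptake_limit = 10, secretion = FALSE))
  sw <- threshold_sweep(toy$model, mutation("PWY1"),
                        thresholds = seq(0.80, 0.99, by = 0.01))
  expect_equal(nrow(sw), 20)
  # mutant optimum ratio 0.85: distance 0 at and below, positive above
  expect_true(all(sw$distance[sw$threshold <= 0.85] < 1e-9))
  expect_true(all(sw$distance[sw$threshold >= 0.86] > 0))
  ord <- order(sw$threshold)
  expect_true(all(diff(sw$distance[ord]) >= -1e-6))
  expect_warning(threshold_sweep(toy$model, mutation("PWY1"),
                                 thresholds = 0.9995), "0.999")
})

test_that("dependent-correlation comparison matches the formula oracle", {
  set.seed(320)
  n <- 320
  y <- rnorm(n)
  x1 <- 0.8 * y + rnorm(n, 0, 0.5)
  x2 <- 0.5 * y + rnorm(n, 0, 0.9)
  r1 <- cor(x1, y); r2 <- cor(x2, y); rx <- cor(x1, x2)
  mz <- meng_z_test(r1, r2, rx, n)
  expect_equal(mz$z, oracle_meng_z(r1, r2, rx, n), tolerance = 1e-10)
  expect_equal(fisher_z_se(n), 1 / sqrt(n - 3), tolerance = 1e-12)
  # equal correlations give Z = 0, p = 0.5
  mz0 <- meng_z_test(0.7, 0.7, 0.4, 50)
  expect_equal(mz0$z, 0)
  expect_equal(mz0$p_one_sided, 0.5)
})

test_that("prediction tables are compared with correlations, Z and bootstrap", {
  measured <- data.frame(flux_id = paste0("f", 1:5),
                         value = c(1, 3, 2, 5, 4),
                         pathway = c("gly", "gly", "tca", "tca", "tca"))
  pred <- list(
    pseudo = data.frame(flux_id = paste0("f", 1:5), value = c(1.1, 2.9, 2.2, 4.8, 4.1)),
    fba = data.frame(flux_id = paste0("f", 1:5), value = c(2, 2, 2, 6, 3)))
  st <- compare_predictions(pred, measured, n_boot = 500, seed = 4)
  # exact agreement with the direct correlation computations on this table
  expect_equal(st$correlations$pearson[1],
               cor(pred$pseudo$value, measured$value))
  expect_equal(st$correlations$spearman[2],
               cor(pred$fba$value, measured$value, method = "spearman"))
  expect_equal(st$meng$r_between, cor(pred$pseudo$value, pred$fba$value))
  expect_true(all(st$errors$error_lower <= st$errors$mean_error &
                    st$errors$mean_error <= st$errors$error_upper))
  expect_equal(sort(unique(st$by_pathway$pathway)), c("gly", "tca"))

  # monotone nonlinear prediction separates the rank from the linear measure
  measured2 <- data.frame(flux_id = paste0("f", 1:6), value = 1:6)
  pred2 <- list(m = data.frame(flux_id = paste0("f", 1:6), value = (1:6)^3))
  st2 <- compare_predictions(pred2, measured2, focal = "m", n_boot = 100)
  expect_equal(st2$correlations$spearman, 1)
  expect_lt(st2$correlations$pearson, 1)

  expect_error(compare_predictions(list(a = pred$pseudo), measured[1:3, ]),
               "at least 4")
  const <- data.frame(flux_id = paste0("f", 1:5), value = rep(1, 5))
  expect_error(compare_predictions(list(a = const), measured), "constant")
})

test_that("bootstrap intervals are seeded and bracket the estimate", {
  set.seed(10)
  x <- rnorm(30, mean = 2)
  ci1 <- bootstrap_mean_ci(x, n_boot = 2000, seed = 99)
  ci2 <- bootstrap_mean_ci(x, n_boot = 2000, seed = 99)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lower, ci1$estimate)
  expect_gte(ci1$upper, ci1$estimate)
})

test_that("the mutant screen matches element-wise solves and isolates failures", {
  toy <- make_toy_model(toy_spec(n_pathways = 2, yields = c(1, 0.4),
                                 uptake_limit = 10))
  m <- toy$model
  expect_equal(nrow(mutant_screen(m, list())), 0)

  muts <- list(pwy1 = mutation("PWY1"), pwy2 = mutation("PWY2"),
               glc = mutation("EX_glc"), sec = mutation("SECRETE"),
               both = mutation(c("PWY1", "PWY2")))
  tab <- mutant_screen(m, muts, threshold = 0.9)
  expect_equal(nrow(tab), 5)
  wt <- fba(m, parsimonious = TRUE)
  for (i in seq_along(muts)) {
    mm <- apply_mutation(m, muts[[i]])
    expect_equal(tab$growth_fba[i], fba(mm)$growth, tolerance = 1e-6)
    expect_equal(tab$growth_moma[i], moma(mm, wt$flux)$growth, tolerance = 1e-5)
    expect_equal(tab$distance[i], pseudo(m, mm, 0.9)$distance, tolerance = 1e-6)
  }
  expect_true(all(tab$yield_fba >= -1e-9 & tab$yield_fba <= 1 + 1e-6))
  expect_equal(tab$lethal_fba[tab$mutant == "glc"], "lethal")
  expect_equal(tab$lethal_fba[tab$mutant == "sec"], "viable")

  # a bad mutation is isolated with a status, the batch survives
  tab2 <- mutant_screen(m, list(ok = mutation("PWY1"),
                                bad = mutation("NOPE", type = "reaction")))
  expect_equal(tab2$status[1], "ok")
  expect_match(tab2$status[2], "error")
})
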