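test_that("tree simulation is reproducible, sized and ultrametric", {
  t1 <- simulate_tree(50, seed = 1)
  t2 <- simulate_tree(50, seed = 1)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(ape::Ntip(t1), 50L)
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_error(simulate_tree(50, birth = 0.5, death = 1), "death rate")
})

test_that("direct development lands in monophyletic clades near target", {
  tr <- simulate_tree(100, seed = 2)
  dev <- assign_direct_development(tr, dd_fraction = 0.1,
                                   dd_clade_count = 1L, seed = 3)
  frac <- attr(dev, "realized_fraction")
  expect_lte(abs(frac - 0.1), 0.05)
  clades <- attr(dev, "clades")
  expect_length(clades, 1L)
  # each marked clade is monophyletic: its tips equal the descendants of
  # their most recent common ancestor
  for (cl in clades) {
    mrca <- ape::getMRCA(tr, cl)
    expect_setequal(tr$tip.label[unlist(ape::prop.part(tr)[[
      mrca - ape::Ntip(tr)]])], cl)
  }
  expect_setequal(names(dev)[dev == "direct"], unlist(clades))
})

test_that("environmental gradients carry the requested autocorrelation", {
  e1 <- simulate_env(120, rho_env = 8, seed = 4)
  e2 <- simulate_env(120, rho_env = 0.01, seed = 4)
  # large range: strong positive Moran's I; vanishing range: none
  m1 <- morans_i(e1$env$BIO4, e1$coords, n_perm = 499, seed = 5,
                 alternative = "greater")
  m2 <- morans_i(e2$env$BIO4, e2$coords, n_perm = 499, seed = 5,
                 alternative = "greater")
  expect_lt(m1$p_value, 0.01)
  expect_gt(m1$observed, 0.1)
  expect_lt(m2$observed, 0.1)
  # columns are standardized
  expect_equal(colMeans(as.matrix(e1$env)), rep(0, 4),
               ignore_attr = TRUE, tolerance = 1e-10)
  # reproducible under the same seed
  e3 <- simulate_env(120, rho_env = 8, seed = 4)
  expect_identical(e1, e3)
})

test_that("assembled communities respect the richness filter and scale", {
  sc <- simulate_scenario(scenario_config(n_species = 60, n_sites = 80,
                                          dd_fraction = 0.15,
                                          dd_clade_count = 2L,
                                          richness_target = 10,
                                          seed = 6))
  rich <- site_richness(sc$cm)
  expect_true(all(rich >= 2L))
  expect_lt(abs(mean(rich) - 10), 2.5)
  expect_equal(dim(sc$cm$incidence), c(80L, 60L))
  # same config, same seed: bit-identical output
  sc2 <- simulate_scenario(scenario_config(n_species = 60, n_sites = 80,
                                           dd_fraction = 0.15,
                                           dd_clade_count = 2L,
                                           richness_target = 10,
                                           seed = 6))
  expect_identical(sc$cm$incidence, sc2$cm$incidence)
  expect_identical(sc$site_table, sc2$site_table)
})

test_that("null path structure decouples the DD proportion from climate", {
  # all structural coefficients zero, short spatial ranges so the sample
  # correlation noise at 500 sites stays well under the 0.1 bound
  zero <- list(
    PCPS1 = c(BIO4 = 0, BIO12 = 0, ET0 = 0, slope = 0),
    SES.FD = c(BIO4 = 0, BIO12 = 0, ET0 = 0, slope = 0),
    prop_dd = c(BIO4 = 0, BIO12 = 0, ET0 = 0,
                slope = 0, PCPS1 = 0, SES.FD = 0))
  cfg <- scenario_config(n_species = 50, n_sites = 500,
                         dd_fraction = 0.15, dd_clade_count = 2L,
                         rho_env = 0.5, rho_err = 0.2,
                         paths = zero, seed = 7)
  sc <- simulate_scenario(cfg)
  s <- ses_dd_proportion(sc$cm, sc$dev, n_null = 199, seed = 8)
  ok <- s$defined
  for (v in c("BIO4", "BIO12", "ET0", "slope")) {
    expect_lt(abs(cor(s$ses[ok], sc$env[[v]][ok])), 0.1)
  }
})

test_that("a strong negative humidity path is recovered through assembly", {
  # communities are assembled from the latent propensity; the SEM fit on
  # pipeline-measured variables must recover the negative ET0 effect
  sc <- simulate_scenario(scenario_config(n_species = 60, n_sites = 300,
                                          dd_fraction = 0.15,
                                          dd_clade_count = 2L,
                                          dd_site_effect = 1.5,
                                          seed = 9))
  s <- ses_dd_proportion(sc$cm, sc$dev, n_null = 199, seed = 10)
  fit <- gls_exponential(ses ~ BIO4 + BIO12 + ET0 + slope,
                         data = cbind(ses = s$ses, sc$env),
                         coords = sc$coords)
  ct <- fit$coef_table
  expect_lt(ct["ET0", "Estimate"], 0)
  expect_lt(ct["ET0", "Pr(>|t|)"], 0.05)
})

test_that("scenario configs validate their inputs", {
  expect_error(scenario_config(n_species = 2), "n_species")
  expect_error(scenario_config(dd_fraction = 1.2), "dd_fraction")
  expect_error(scenario_config(birth = -1), "rates")
})
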