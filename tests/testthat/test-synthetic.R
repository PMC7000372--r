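test_that("campaign generation is deterministic in the seed", {
  tr <- truth_parameters(seed = 99)
  c1 <- generate_campaign(tr)
  c2 <- generate_campaign(tr)
  expect_identical(c1$rates, c2$rates)
  expect_identical(c1$nmr, c2$nmr)
  expect_identical(c1$offgas, c2$offgas)
  c3 <- generate_campaign(truth_parameters(seed = 100))
  expect_false(identical(c1$nmr, c3$nmr))
})

test_that("campaign generation leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_campaign(truth_parameters(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("a noise-free campaign reproduces the model predictions exactly
           and round-trips through inference", {
  tr <- truth_parameters("FORMATE_METHYL", f_wlp = 0.2, sigma_rate = 0,
                         sigma_nmr = 0, sigma_gas = 0, seed = 3)
  camp <- generate_campaign(tr)
  s <- simulate_labeling(ref_cfg, ref_rates, tr$scenario,
                         times = c(0, 4, 8))
  for (i in seq_len(nrow(camp$nmr))) {
    pred <- pool_position_enrichment(s, camp$nmr$time_h[i])
    expect_equal(camp$nmr$pct_methyl[i], pred[["methyl"]], tolerance = 1e-9)
    expect_equal(camp$nmr$pct_carbonyl[i], pred[["carbonyl"]],
                 tolerance = 1e-9)
  }
  # replicate rates equal the truth, and scenario fitting recovers both
  # the scenario and the WLP fraction
  expect_equal(campaign_mean_rates(camp)$q, ref_rates$q, tolerance = 1e-12)
  fits <- fit_scenario(camp$nmr, ref_cfg, ref_rates)
  expect_equal(fits$scenario[1], "FORMATE_METHYL")
  expect_equal(fits$f_wlp[1], 0.2, tolerance = 1e-3)
})

test_that("noiseless synthetic yields return the truth fluxes", {
  net <- build_network("FORMATE_METHYL")
  sol <- theoretical_stoichiometry(net)
  reg <- default_registry()
  y <- yield_set(c(acetate = unname(sol$yields[["acetate"]]) * 2 / 6,
                   co2 = unname(sol$yields[["co2"]]) / 6), registry = reg)
  fv <- infer_fluxes(y, net, reg)
  expect_equal(unname(fv$fluxes), unname(sol$fluxes), tolerance = 1e-6)
})

test_that("campaign noise levels behave as declared", {
  tr <- truth_parameters(sigma_rate = 0.05, sigma_nmr = 0.3, seed = 17)
  camp <- generate_campaign(tr, n_rate_replicates = 200)
  # multiplicative rate noise: relative spread ~ sigma_rate, sign kept
  ac <- camp$rates$q[camp$rates$compound == "acetate"]
  expect_true(all(ac > 0))
  expect_equal(sd(log(ac)), 0.05, tolerance = 0.25)
  gal <- camp$rates$q[camp$rates$compound == "galacturonate"]
  expect_true(all(gal < 0))
  # NMR noise stays inside [0, 100]
  expect_true(all(camp$nmr$pct_methyl >= 0 & camp$nmr$pct_methyl <= 100))
})

test_that("raising the NMR noise raises the error of the recovered WLP
           fraction", {
  sigmas <- c(0.1, 0.6, 2.0)
  med_err <- vapply(seq_along(sigmas), function(k) {
    errs <- vapply(1:100, function(rep) {
      tr <- truth_parameters("FORMATE_METHYL", f_wlp = 0.2,
                             sigma_nmr = sigmas[k], seed = 1000 * k + rep)
      camp <- generate_campaign(tr)
      fit <- fit_scenario(camp$nmr, ref_cfg, ref_rates,
                          scenarios = "FORMATE_METHYL")
      abs(fit$f_wlp[1] - 0.2)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) > 0))
})

test_that("a campaign written to disk round-trips through the readers", {
  dir <- withr::local_tempdir()
  tr <- truth_parameters(seed = 8)
  camp <- generate_campaign(tr, dir = dir)
  expect_setequal(dir(dir), c("rates.tsv", "nmr.tsv", "offgas.tsv",
                              "truth.json"))
  nmr <- read_nmr_tsv(file.path(dir, "nmr.tsv"))
  expect_equal(nmr$pct_carbonyl, camp$nmr$pct_carbonyl, tolerance = 1e-5)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 8L)
  expect_equal(truth$scenario, "FORMATE_METHYL")
})
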