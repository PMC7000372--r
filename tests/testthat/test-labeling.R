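test_that("bicarbonate speciation follows Henderson-Hasselbalch", {
  expect_equal(dic_speciation(7.8), 1 / (1 + 10^(6.35 - 7.8)),
               tolerance = 1e-12)
  expect_equal(dic_speciation(7.8), 0.9657, tolerance = 1e-4)
  expect_equal(dic_speciation(6.35), 0.5, tolerance = 1e-12)
  expect_gte(dic_speciation(9.0), 0.99)
})

test_that("titrant base demand counts acids fully and CO2 via speciation", {
  expect_equal(titrant_dic_input(ref_rates, ref_cfg),
               6.9 + 0.4 + 4.3 * dic_speciation(7.8), tolerance = 1e-12)
  zero <- rate_set(c(galacturonate = -1, acetate = 0, formate = 0, co2 = 0))
  expect_equal(titrant_dic_input(zero, ref_cfg), 0)
  # at pH far below pKa1 the retained CO2 stays dissolved CO2: acids only
  lo <- chemostat_config(ph = 6.0)
  expect_equal(titrant_dic_input(ref_rates, lo),
               6.9 + 0.4 + 4.3 * dic_speciation(6.0), tolerance = 1e-12)
})

test_that("all pools start at natural abundance and NO_WLP stays there", {
  s <- simulate_labeling(ref_cfg, ref_rates, scenario("NO_WLP"))
  expect_equal(unname(pool_position_enrichment(s, 0)),
               c(1.0, 1.0), tolerance = 1e-9)
  expect_lt(max(abs(s$e_me - 0.01)), 1e-9)
  expect_lt(max(abs(s$e_co - 0.01)), 1e-9)
  # ... while the DIC pool itself still labels up from the titrant
  expect_gt(tail(s$e_dic, 1), 0.5)
})

test_that("long-time DIC enrichment reaches the flux-ratio steady state
           independently of the starting pool size", {
  e_ss <- function(s) tail(s$e_dic, 1)
  tin <- titrant_dic_input(ref_rates, ref_cfg)
  r_co2 <- 4.3
  expected <- (tin + r_co2 * 0.01) / (tin + r_co2)
  s1 <- simulate_labeling(ref_cfg, ref_rates, scenario("NO_WLP"),
                          t_end = 300, t_step = 1)
  cfg_big <- chemostat_config(dic0 = 300)
  s2 <- simulate_labeling(cfg_big, ref_rates, scenario("NO_WLP"),
                          t_end = 300, t_step = 1)
  expect_equal(e_ss(s1), expected, tolerance = 1e-4)
  expect_equal(e_ss(s2), expected, tolerance = 1e-4)
})

test_that("DIC enrichment approaches steady state exponentially at the
           pool turnover rate", {
  s <- simulate_labeling(ref_cfg, ref_rates, scenario("NO_WLP"),
                         t_end = 120, t_step = 0.5)
  tin <- titrant_dic_input(ref_rates, ref_cfg)
  e_ss <- (tin + 4.3 * 0.01) / (tin + 4.3)
  win <- s$time >= 60 & s$time <= 90
  fit <- lm(log(e_ss - s$e_dic[win]) ~ s$time[win])
  k_obs <- -coef(fit)[[2]]
  # late-time turnover/pool = D for a pool at its post-switch steady state
  expect_equal(k_obs, ref_cfg$dilution_rate, tolerance = 0.05)
})

test_that("enrichments rise monotonically when there is no stripping", {
  for (scn in list(scenario("CANONICAL_WLP", 0.2),
                   scenario("FORMATE_METHYL", 0.3))) {
    s <- simulate_labeling(ref_cfg, ref_rates, scn)
    expect_true(all(diff(s$e_dic) > -1e-10))
    expect_true(all(diff(s$e_me) > -1e-10))
    expect_true(all(diff(s$e_co) > -1e-10))
  }
})

test_that("13C above natural abundance is conserved between titrant input,
           pools and effluent", {
  for (scn in list(scenario("CANONICAL_WLP", 0.2),
                   scenario("FORMATE_METHYL", 0.7, k_exchange = 0.1))) {
    s <- simulate_labeling(ref_cfg, ref_rates, scn, t_end = 8)
    p <- attr(s, "params")
    added <- p$t_in * (1 - p$a0) * s$time
    in_pools <- (s$e_dic - p$a0) * s$dic +
      s$acetate * ((s$e_me - p$a0) + (s$e_co - p$a0))
    balance <- in_pools + s$cum_excess_out
    rel <- abs(balance[-1] - added[-1]) / added[-1]
    expect_lt(max(rel), 1e-6)
  }
})

test_that("position enrichment pools are the washout-weighted average of
           newly made acetate (quadrature oracle)", {
  s <- simulate_labeling(ref_cfg, ref_rates, scenario("CANONICAL_WLP", 0.2),
                         t_end = 8, t_step = 0.005)
  D <- ref_cfg$dilution_rate
  f <- 0.2; a0 <- 0.01
  e_new <- f * s$e_dic + (1 - f) * a0
  # e_pos(t) = a0 exp(-D t) + int_0^t D exp(-D (t - u)) e_new(u) du
  t8 <- max(s$time)
  kern <- D * exp(-D * (t8 - s$time)) * e_new
  pred <- a0 * exp(-D * t8) + trapz(s$time, kern)
  expect_equal(tail(s$e_co, 1), pred, tolerance = 1e-6)
  # the pre-switch pool weight itself: exp(-0.8) = 0.449 at 8 h
  expect_equal(exp(-D * 8), 0.4493, tolerance = 1e-4)
})

test_that("halving the output step leaves the 8 h carbonyl enrichment
           unchanged to 1e-4 (integrator convergence)", {
  scn <- scenario("FORMATE_METHYL", 0.5)
  s1 <- simulate_labeling(ref_cfg, ref_rates, scn, t_step = 0.05)
  s2 <- simulate_labeling(ref_cfg, ref_rates, scn, t_step = 0.025)
  expect_lt(abs(tail(s1$e_co, 1) - tail(s2$e_co, 1)), 1e-4)
})

test_that("the formate-fed methyl branch keeps the methyl position within
           0.1 percentage point of natural abundance", {
  s <- simulate_labeling(ref_cfg, ref_rates, scenario("FORMATE_METHYL", 0.9))
  expect_lt(max(abs(100 * s$e_me - 1.0)), 0.1)
  expect_gt(tail(s$e_co, 1), 0.05)  # carbonyl labels strongly meanwhile
})

test_that("produced-label bookkeeping has the right limits", {
  s0 <- simulate_labeling(ref_cfg, ref_rates, scenario("CANONICAL_WLP", 0))
  expect_equal(produced_label_fraction(s0, 8), 0)
  s1 <- simulate_labeling(ref_cfg, ref_rates, scenario("NO_WLP"))
  expect_equal(produced_label_fraction(s1, 8), 0)
  expect_error(produced_label_fraction(s1, -1), "switch")
  expect_error(produced_label_fraction(s1, 99), "range")
})

test_that("the labeled fraction of produced acetate equals the quadrature
           of f_wlp x capped position-excess enrichment", {
  f <- 0.2
  s <- simulate_labeling(ref_cfg, ref_rates, scenario("CANONICAL_WLP", f),
                         t_end = 8, t_step = 0.005)
  p_label <- f * pmin(2 * pmax(s$e_dic - 0.01, 0), 1)
  expected <- 100 * trapz(s$time, p_label) / max(s$time)
  expect_equal(produced_label_fraction(s, 8), expected, tolerance = 1e-4)
})
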