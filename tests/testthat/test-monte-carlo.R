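as_point_spec <- function(n_trials = 500, seed = 1) {
  simulation_spec(point_dist(188), "As",
                  ir_dist = point_dist(20), bw_dist = point_dist(80.8),
                  n_trials = n_trials, seed = seed)
}

test_that("a point-mass spec collapses onto the deterministic equations", {
  sim <- simulate_risk(as_point_spec(), "ctr")
  adult <- exposure_scenario("adult_combined", ir = 20, bw = 80.8)
  hq_det <- hazard_quotient(average_daily_dose(188, adult), 3e-4)
  expect_equal(sim$summary$mean, hq_det, tolerance = 1e-12)
  expect_equal(sim$summary$cv, 0)
  expect_equal(sim$summary$p95, sim$summary$mean)
  expect_equal(upper_bound(sim)$p95, hq_det, tolerance = 1e-12)

  sim_cr <- simulate_risk(as_point_spec(), "cr")
  cr_det <- carcinogenic_risk(lifetime_average_daily_dose(188, adult), 1.5)
  expect_equal(sim_cr$summary$mean, cr_det, tolerance = 1e-12)
})

test_that("simulation is reproducible and summary invariants always hold", {
  spec <- simulation_spec(
    fitted_dist("lognormal", c(meanlog = log(188), sdlog = 1.1)), "As",
    n_trials = 2000, seed = 99)
  s1 <- simulate_risk(spec, "ctr")
  s2 <- simulate_risk(spec, "ctr")
  expect_identical(s1$trials, s2$trials)
  for (seed in c(1, 7, 23)) {
    sp <- spec; sp$seed <- seed
    s <- simulate_risk(sp, "ctr")$summary
    expect_true(all(simulate_risk(sp, "ctr")$trials >= 0))
    expect_true(s$p25 <= s$median && s$median <= s$p75 &&
                  s$p75 <= s$p95 && s$p95 <= s$maximum)
    expect_gte(s$cv, 0)
  }
})

test_that("simulated mean agrees with the independence moment oracle", {
  spec <- simulation_spec(
    fitted_dist("lognormal", c(meanlog = log(50), sdlog = 0.9)), "As",
    n_trials = 10000, seed = 17)
  sim <- simulate_risk(spec, "ctr")
  # E[HQ] = E[C] E[IR] E[1/BW] * EF ED CF / (AT_days * RfD), independence
  k <- spec$ef * spec$ed * spec$cf / (spec$at_days * 3e-4)
  oracle <- dist_mean(spec$conc_dist) * dist_mean(spec$ir_dist) *
    inv_bw_moment(spec$bw_dist) * k
  mc_se <- sd(sim$trials) / sqrt(length(sim$trials))
  expect_lt(abs(sim$summary$mean - oracle), 3 * mc_se)
})

test_that("rescaling the concentration distribution rescales every summary", {
  base <- fitted_dist("lognormal", c(meanlog = log(30), sdlog = 0.8))
  scaled <- fitted_dist("lognormal", c(meanlog = log(30) + log(3), sdlog = 0.8))
  s1 <- simulate_risk(simulation_spec(base, "As", n_trials = 3000, seed = 5),
                      "ctr")$summary
  s3 <- simulate_risk(simulation_spec(scaled, "As", n_trials = 3000, seed = 5),
                      "ctr")$summary
  for (col in c("mean", "median", "p25", "p75", "p95", "maximum")) {
    expect_equal(s3[[col]], 3 * s1[[col]], tolerance = 1e-12)
  }
  expect_equal(s3$cv, s1$cv, tolerance = 1e-12)
})

test_that("CTR and CR trials obey the shared-draw algebraic identity", {
  spec <- simulation_spec(
    fitted_dist("lognormal", c(meanlog = 2, sdlog = 0.7)), "As",
    n_trials = 1000, seed = 8)
  ctr <- simulate_risk(spec, "ctr")$trials
  cr <- simulate_risk(spec, "cr")$trials
  # same seed, ED = LT: CR = CTR * RfD * SF trial by trial
  expect_equal(cr, ctr * 3e-4 * 1.5, tolerance = 1e-12)
})

test_that("risk kinds require the matching toxicity constant", {
  expect_error(
    simulate_risk(simulation_spec(point_dist(10), "Pb", n_trials = 10), "ctr"),
    "RFD")
  expect_error(
    simulate_risk(simulation_spec(point_dist(10), "Cd", n_trials = 10), "cr"),
    "SF")
})

test_that("bootstrap of a point-mass spec has zero spread", {
  bs <- bootstrap_uncertainty(as_point_spec(), "ctr", repetitions = 10,
                              trials_per_repetition = 50)
  expect_equal(bs$se, c(0, 0))
  expect_equal(bs$iqr, c(0, 0))
})

test_that("bootstrap SE tracks the CLT and shrinks like 1/sqrt(trials)", {
  spec <- simulation_spec(
    fitted_dist("lognormal", c(meanlog = log(50), sdlog = 0.8)), "As",
    n_trials = 1000, seed = 31)
  bs_small <- bootstrap_uncertainty(spec, "ctr", repetitions = 200,
                                    trials_per_repetition = 250, seed = 31)
  bs_large <- bootstrap_uncertainty(spec, "ctr", repetitions = 200,
                                    trials_per_repetition = 1000, seed = 31)
  se_ratio <- bs_small$se[bs_small$statistic == "mean"] /
    bs_large$se[bs_large$statistic == "mean"]
  expect_gt(se_ratio, 1.5)
  expect_lt(se_ratio, 2.7)
  # SE of the mean ~ sd(trials)/sqrt(trials) within a factor of 1.5
  sim <- simulate_risk(spec, "ctr")
  clt_se <- sd(sim$trials) / sqrt(1000)
  se_mean <- bs_large$se[bs_large$statistic == "mean"]
  expect_gt(se_mean / clt_se, 1 / 1.5)
  expect_lt(se_mean / clt_se, 1.5)
  # every repetition mean lies inside the pooled trial range
  reps <- attr(bs_large, "replicates")
  expect_true(all(reps$mean >= 0))
  # reproducible under the same master seed
  bs_again <- bootstrap_uncertainty(spec, "ctr", repetitions = 200,
                                    trials_per_repetition = 1000, seed = 31)
  expect_equal(bs_again$se, bs_large$se)
})

test_that("upper_bound labels printed population risks by the zone taxonomy", {
  mk <- function(p95) tibble::tibble(p95 = p95)
  expect_equal(as.character(upper_bound(mk(5.14e-4), "cr")$zone),
               "cr_high_priority")
  expect_equal(as.character(upper_bound(mk(6.23e-5), "cr")$zone),
               "cr_low_priority")
  expect_equal(as.character(upper_bound(mk(2.34e-6), "cr")$zone),
               "cr_acceptable")
  expect_equal(as.character(upper_bound(mk(6.28e-7), "cr")$zone),
               "cr_safe")
})

test_that("tidy, glance and autoplot work on simulation objects", {
  sim <- simulate_risk(as_point_spec(n_trials = 200), "ctr")
  td <- generics::tidy(sim)
  expect_true(all(c("mean", "median", "p95", "cv") %in% td$statistic))
  gl <- generics::glance(sim)
  expect_equal(gl$element_form, "As")
  expect_equal(gl$n_trials, 200)
  spec <- simulation_spec(
    fitted_dist("lognormal", c(meanlog = 2, sdlog = 0.5)), "As",
    n_trials = 300, seed = 2)
  p <- ggplot2::autoplot(simulate_risk(spec, "ctr"))
  expect_s3_class(p, "ggplot")
  bs <- bootstrap_uncertainty(spec, "ctr", repetitions = 5,
                              trials_per_repetition = 50)
  expect_s3_class(ggplot2::autoplot(bs), "ggplot")
})
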