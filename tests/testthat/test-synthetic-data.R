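test_that("generator spec validation catches bad parameters", {
  g <- tibble::tibble(element = "As", site_category = "urban",
                      median_mg_kg = 7, gsd = 3, n_records = 10)
  expect_s3_class(generator_spec(g), "generator_spec")
  expect_error(generator_spec(dplyr::mutate(g, median_mg_kg = -1)), "positive")
  expect_error(generator_spec(dplyr::mutate(g, gsd = 1)), "exceed 1")
  expect_error(generator_spec(dplyr::mutate(g, n_records = 0)), ">= 1")
  expect_error(generator_spec(dplyr::mutate(g, element = "Hg")),
               "unsupported element")
  expect_error(generator_spec(g, hotspot_fraction = 1.5), "\\[0, 1\\]")
})

test_that("generation is reproducible and respects per-group counts", {
  spec <- default_turkey_like_spec(n_per_group = 3, seed = 42)
  d1 <- generate_concentrations(spec)
  d2 <- generate_concentrations(spec)
  expect_identical(d1, d2)
  counts <- dplyr::count(d1, element, site_category)
  expect_true(all(counts$n == 3))
  expect_equal(nrow(d1), 11 * 5 * 3)
  # single-record groups give exactly one record each
  spec1 <- default_turkey_like_spec(n_per_group = 1, seed = 1)
  expect_equal(nrow(generate_concentrations(spec1)), 55)
})

test_that("generated group medians track the spec medians", {
  groups <- tibble::tibble(
    element = "As",
    site_category = c("rural", "urban", "industrial"),
    median_mg_kg = c(2.5, 6.98, 500),
    gsd = 3, n_records = 200)
  spec <- generator_spec(groups, seed = 11)
  recs <- generate_concentrations(spec)
  med <- recs |>
    dplyr::group_by(site_category) |>
    dplyr::summarise(m = median(concentration_mg_kg))
  target <- setNames(groups$median_mg_kg, groups$site_category)
  for (cat in names(target)) {
    expect_lt(abs(med$m[med$site_category == cat] - target[[cat]]) /
                target[[cat]], 0.15)
  }
})

test_that("without hotspots the sample CV matches the lognormal closed form", {
  groups <- tibble::tibble(element = "Zn", site_category = "urban",
                           median_mg_kg = 128, gsd = 3, n_records = 1e4)
  spec <- generator_spec(groups, hotspot_fraction = 0, seed = 21)
  recs <- generate_concentrations(spec)
  sigma <- log(3)
  cv_analytic <- sqrt(exp(sigma^2) - 1)
  s <- summarize_concentrations(recs, "element")
  expect_lt(abs(s$cv - cv_analytic) / cv_analytic, 0.10)
})

test_that("the default spec covers the grid with plausible structure", {
  spec <- default_turkey_like_spec()
  g <- spec$groups
  expect_equal(nrow(g), 55)
  expect_setequal(unique(g$element), pte_elements())
  # anthropogenic markers ordered industrial >= urban >= rural
  for (el in c("As", "Ni", "Pb", "Cr")) {
    m <- setNames(g$median_mg_kg[g$element == el],
                  g$site_category[g$element == el])
    expect_gte(m[["industrial"]], m[["urban"]])
    expect_gte(m[["urban"]], m[["rural"]])
  }
  # lognormal CVs inside the reported 0.83-3.85 envelope
  cv <- sqrt(exp(log(g$gsd)^2) - 1)
  expect_true(all(cv >= 0.83 & cv <= 3.85))
  # generated data pass validation and As exceeds its regulation limit
  recs <- generate_concentrations(default_turkey_like_spec(n_per_group = 40,
                                                           seed = 2))
  expect_silent(validate_concentration_records(recs))
  as_mean <- mean(recs$concentration_mg_kg[recs$element == "As"])
  expect_gt(exceedance_ratio(as_mean, "As"), 1)
})

test_that("industrial vs agricultural As separation is detected across seeds", {
  spec0 <- default_turkey_like_spec(n_per_group = 50)
  rejections <- vapply(1:40, function(s) {
    spec <- spec0
    spec$seed <- s
    recs <- generate_concentrations(spec)
    cmp <- compare_site_categories(recs, "As")
    row <- cmp[cmp$group_a == "industrial" & cmp$group_b == "agricultural", ]
    isTRUE(row$reject)
  }, logical(1))
  expect_gte(mean(rejections), 0.9)
})

test_that("generate -> summarize -> fit -> simulate -> bootstrap holds end to end", {
  for (s in c(1, 2, 3)) {
    spec <- default_turkey_like_spec(n_per_group = 30, seed = s)
    recs <- generate_concentrations(spec)
    summ <- summarize_concentrations(recs, c("element", "site_category"))
    expect_true(all(summ$p25 <= summ$median & summ$median <= summ$p75 &
                      summ$p75 <= summ$p95))
    as_vals <- recs$concentration_mg_kg[recs$element == "As"]
    fit <- fit_best(as_vals)
    expect_true(fit$family %in% c("lognormal", "gamma", "weibull"))
    sim <- simulate_risk(simulation_spec(fit, "As", n_trials = 500, seed = s),
                         "ctr")
    expect_true(all(sim$trials >= 0))
    ss <- sim$summary
    expect_true(ss$p25 <= ss$median && ss$p95 <= ss$maximum)
    bs <- bootstrap_uncertainty(simulation_spec(fit, "As", seed = s), "ctr",
                                repetitions = 5, trials_per_repetition = 100)
    expect_true(all(bs$se >= 0) && all(bs$iqr >= 0))
  }
})

test_that("fit_best recovers the generating lognormal from synthetic data", {
  groups <- tibble::tibble(element = "Cu", site_category = "suburban",
                           median_mg_kg = 66, gsd = 2.5, n_records = 5000)
  spec <- generator_spec(groups, hotspot_fraction = 0, seed = 99)
  recs <- generate_concentrations(spec)
  fit <- fit_best(recs$concentration_mg_kg)
  expect_equal(fit$family, "lognormal")
  expect_equal(unname(fit$params[["meanlog"]]), log(66), tolerance = 0.05)
  expect_equal(unname(fit$params[["sdlog"]]), log(2.5), tolerance = 0.05)
})
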