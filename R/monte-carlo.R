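#' Specify a Monte Carlo population-risk simulation
#'
#' Bundles the three sampled inputs (concentration, ingestion rate, body
#' weight), the fixed exposure factors and the toxicity constants of one
#' element form. Defaults follow the probabilistic design: 10,000 trials,
#' EF 350 day/yr, ED 75 yr, averaging time 27,375 days (75 x 365), lifetime
#' 75 yr, the lognormal population ingestion-rate distribution and the
#' Turkish scaled-beta body-weight distribution.
#'
#' @param conc_dist [fitted_dist()] for the soil concentration, mg/kg.
#' @param element_form Element (or speciated form) label matching `tox`.
#' @param tox Toxicity table, default [default_toxicity()].
#' @param ir_dist [fitted_dist()] for the ingestion rate, mg/day.
#' @param bw_dist [fitted_dist()] for body weight, kg.
#' @param n_trials Number of Monte Carlo trials.
#' @param seed Integer seed; identical specs give identical output.
#' @param ef,ed,lt Exposure frequency (day/yr), duration (yr), lifetime (yr).
#' @param at_days Averaging time in days (default 27,375 = 75 yr).
#' @param cf Mass conversion factor kg/mg.
#' @return A `simulation_spec` object.
#' @export
#' @examples
#' spec <- simulation_spec(fitted_dist("lognormal",
#'                                     c(meanlog = log(10), sdlog = 1)),
#'                         element_form = "As", n_trials = 1000, seed = 7)
simulation_spec <- function(conc_dist, element_form,
                            tox = default_toxicity(),
                            ir_dist = ingestion_rate_distribution(),
                            bw_dist = body_weight_distribution(),
                            n_trials = 10000, seed = 1,
                            ef = 350, ed = 75, lt = 75,
                            at_days = 27375, cf = 1e-6) {
  stopifnot(inherits(conc_dist, "fitted_dist"),
            inherits(ir_dist, "fitted_dist"),
            inherits(bw_dist, "fitted_dist"))
  validate_toxicity(tox)
  if (!element_form %in% tox$element_form) {
    abort(paste0("no toxicity entry for '", element_form, "'"))
  }
  if (!(is.numeric(n_trials) && n_trials >= 1)) abort("n_trials must be >= 1")
  if (any(c(ef, ed, lt, at_days, cf) <= 0)) {
    abort("fixed exposure factors must be positive")
  }
  if (ef > 366) abort("exposure frequency cannot exceed 366 day/yr")
  structure(list(conc_dist = conc_dist, ir_dist = ir_dist, bw_dist = bw_dist,
                 element_form = element_form, tox = tox,
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 ef = ef, ed = ed, lt = lt, at_days = at_days, cf = cf),
            class = "simulation_spec")
}

# draw n values inside the distribution's support, re-drawing any non-finite
# or out-of-support values up to a bounded number of rounds
draw_checked <- function(dist, n, max_rounds = 50) {
  x <- dist_sample(dist, n)
  lo <- dist$support[1]; hi <- dist$support[2]
  bad <- !is.finite(x) | x < lo | x > hi
  rounds <- 0
  while (any(bad)) {
    rounds <- rounds + 1
    if (rounds > max_rounds) {
      abort("too many invalid draws; check the distribution specification")
    }
    x[bad] <- dist_sample(dist, sum(bad))
    bad <- !is.finite(x) | x < dist$support[1] | x > dist$support[2]
  }
  x
}

summarize_trials <- function(trials) {
  q <- quantile(trials, c(0.25, 0.5, 0.75, 0.95), type = 7, names = FALSE)
  m <- mean(trials)
  tibble::tibble(
    mean = m, median = q[2], p25 = q[1], p75 = q[3], p95 = q[4],
    maximum = max(trials),
    cv = if (m == 0) 0 else sd(trials) / m,
    n_trials = length(trials)
  )
}

#' Monte Carlo simulation of population risk
#'
#' Each trial draws concentration, ingestion rate and body weight
#' independently, computes the (lifetime) average daily dose and converts it
#' to a hazard quotient (`risk_kind = "ctr"`, chronic toxic risk) or a
#' carcinogenic risk (`risk_kind = "cr"`). The full trial vector is retained
#' and summarised (mean, median, quartiles, 95th-percentile upper bound,
#' maximum, CV).
#'
#' @param spec A [simulation_spec()].
#' @param risk_kind `"ctr"` (needs an RfD) or `"cr"` (needs an SF).
#' @return A `risk_simulation` object: list with `trials` (numeric vector),
#'   `summary` (one-row tibble), `risk_kind`, `element_form`, `spec`.
#'   Use [tidy()], [glance()], [autoplot()] and [upper_bound()] on it.
#' @export
#' @examples
#' spec <- simulation_spec(fitted_dist("point", c(value = 188)),
#'                         element_form = "As",
#'                         ir_dist = fitted_dist("point", c(value = 20)),
#'                         bw_dist = fitted_dist("point", c(value = 80.8)),
#'                         n_trials = 100, seed = 1)
#' simulate_risk(spec, "ctr")$summary
simulate_risk <- function(spec, risk_kind = c("ctr", "cr")) {
  stopifnot(inherits(spec, "simulation_spec"))
  risk_kind <- match.arg(risk_kind)
  const <- tox_lookup(spec$tox, spec$element_form,
                      if (risk_kind == "ctr") "rfd" else "sf")

  withr::local_seed(spec$seed)
  n <- spec$n_trials
  conc <- draw_checked(spec$conc_dist, n)
  ir <- draw_checked(spec$ir_dist, n)
  bw <- draw_checked(spec$bw_dist, n)
  if (any(bw <= 0)) abort("body-weight draws must be positive")

  denom_days <- if (risk_kind == "ctr") spec$at_days else spec$lt * 365
  dose <- conc * ir * spec$ef * spec$ed * spec$cf / (bw * denom_days)
  trials <- if (risk_kind == "ctr") dose / const else dose * const

  structure(list(trials = trials, summary = summarize_trials(trials),
                 risk_kind = risk_kind, element_form = spec$element_form,
                 spec = spec),
            class = "risk_simulation")
}

#' @export
print.risk_simulation <- function(x, ...) {
  cat("<risk_simulation> ", x$element_form, " ",
      toupper(x$risk_kind), ", ", x$summary$n_trials, " trials\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.risk_simulation <- function(x, ...) {
  x$summary |>
    tidyr::pivot_longer(-"n_trials", names_to = "statistic",
                        values_to = "value") |>
    dplyr::select("statistic", "value")
}

#' @export
glance.risk_simulation <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(element_form = x$element_form, risk_kind = x$risk_kind),
    x$summary
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.risk_simulation <- function(object, bins = 60, ...) {
  df <- tibble::tibble(risk = object$trials[object$trials > 0])
  bounds <- if (object$risk_kind == "cr") c(1e-6, 1e-5, 1e-4) else c(0.1, 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$risk)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60", colour = "grey30") +
    ggplot2::geom_vline(xintercept = bounds, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      title = paste0(object$element_form, " simulated ",
                     toupper(object$risk_kind)),
      x = if (object$risk_kind == "cr") "carcinogenic risk"
          else "hazard quotient",
      y = "trials") +
    ggplot2::theme_minimal()
}

#' Upper-bound (95th percentile) risk with zone label
#'
#' @param x A `risk_simulation` or its one-row summary tibble, together with
#'   the risk kind when a bare summary is given.
#' @param risk_kind `"ctr"` or `"cr"`; taken from the simulation when
#'   available.
#' @return One-row tibble with `p95` and its risk `zone`.
#' @export
upper_bound <- function(x, risk_kind = NULL) {
  if (inherits(x, "risk_simulation")) {
    risk_kind <- x$risk_kind
    x <- x$summary
  }
  stopifnot(is.data.frame(x), "p95" %in% names(x))
  risk_kind <- match.arg(risk_kind, c("ctr", "cr"))
  zone <- if (risk_kind == "cr") classify_cr(x$p95) else classify_hq(x$p95)
  tibble::tibble(p95 = x$p95, zone = zone)
}

#' Bootstrap uncertainty of Monte Carlo summaries
#'
#' Repeats the whole Monte Carlo simulation `repetitions` times with
#' independent seed substreams (default: 200 repetitions of 1,000 trials)
#' and reports, for the mean and the median of the trial vector, the
#' standard error and the interquartile range of the statistic across
#' repetitions — the uncertainty contributed by the random-sampling process
#' itself.
#'
#' @param spec A [simulation_spec()]; its `n_trials` is overridden by
#'   `trials_per_repetition`.
#' @param risk_kind `"ctr"` or `"cr"`.
#' @param repetitions Number of independent simulation repetitions (>= 2).
#' @param trials_per_repetition Trials per repetition.
#' @param seed Master seed spawning one substream per repetition; defaults
#'   to the spec's seed.
#' @return A `risk_bootstrap` object: tibble with one row per statistic
#'   (`mean`, `median`) and columns `estimate`, `se`, `iqr`, `repetitions`,
#'   `trials_per_repetition`, plus the per-repetition statistics in
#'   `attr(, "replicates")`.
#' @export
bootstrap_uncertainty <- function(spec, risk_kind = c("ctr", "cr"),
                                  repetitions = 200,
                                  trials_per_repetition = 1000,
                                  seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  risk_kind <- match.arg(risk_kind)
  if (repetitions < 2) abort("bootstrap needs at least 2 repetitions")

  withr::local_seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, repetitions)
  reps <- purrr::map_dfr(sub_seeds, function(s) {
    sp <- spec
    sp$seed <- s
    sp$n_trials <- as.integer(trials_per_repetition)
    sim <- simulate_risk(sp, risk_kind)
    tibble::tibble(mean = sim$summary$mean, median = sim$summary$median)
  })

  out <- tibble::tibble(
    statistic = c("mean", "median"),
    estimate = c(mean(reps$mean), median(reps$median)),
    se = c(sd(reps$mean), sd(reps$median)),
    iqr = c(IQR(reps$mean, type = 7), IQR(reps$median, type = 7)),
    repetitions = repetitions,
    trials_per_repetition = trials_per_repetition
  )
  attr(out, "replicates") <- reps
  class(out) <- c("risk_bootstrap", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.risk_bootstrap <- function(object, ...) {
  reps <- attr(object, "replicates")
  df <- tidyr::pivot_longer(reps, dplyr::everything(),
                            names_to = "statistic", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60", colour = "grey30") +
    ggplot2::facet_wrap(~statistic, scales = "free_x") +
    ggplot2::labs(title = "Bootstrap distribution of simulation summaries",
                  x = "statistic value per repetition", y = "repetitions") +
    ggplot2::theme_minimal()
}
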