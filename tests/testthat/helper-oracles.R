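# Independent oracles used across test files.

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n_a + n_b, n_a) rank assignments (tie-free data assumed).
mwu_enumeration_p <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  assignments <- utils::combn(n_a + n_b, n_a)
  u_all <- apply(assignments, 2, function(idx) {
    sum(seq_len(n_a + n_b)[idx]) - n_a * (n_a + 1) / 2
  })
  mid <- n_a * n_b / 2
  p1 <- if (u_obs > mid) mean(u_all >= u_obs) else mean(u_all <= u_obs)
  min(2 * p1, 1)
}

# E[1/BW] for a scaled-beta body weight, by numerical integration.
inv_bw_moment <- function(bw_dist) {
  p <- as.list(bw_dist$params)
  stopifnot(bw_dist$family == "beta_scaled", p$min == 0)
  integrate(function(u) dbeta(u, p$alpha, p$beta) / (p$max * u),
            0, 1, rel.tol = 1e-10)$value
}

# convenience record builder
make_records <- function(element, conc, site_category = "urban",
                         province = "Izmir", source_id = "test") {
  tibble::tibble(element = element, concentration_mg_kg = conc,
                 province = province, site_category = site_category,
                 source_id = source_id)
}

point_dist <- function(value) fitted_dist("point", c(value = value))
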