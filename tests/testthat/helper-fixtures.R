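# Shared fixtures: all synthetic, generated in code at test time.

# standard single-chemical study: 7-level 2.5x series from 50 uM, 3 tech x
# 3 bio treated, 27 controls, QCs and blanks over 2 batches
std_design <- function(n_qc = 12, n_batches = 2, time_points = 24) {
  build_design(50, 2.5, 7, chemical = "chemA", n_qc = n_qc,
               n_blank = 4, n_batches = n_batches, time_points = time_points)
}

# fixture with planted drift, dropout and internal standard; memoised since
# several tests share it
.std_cache <- new.env()
std_table <- function(seed = 11, sdlog = 0.1, with_artifacts = TRUE) {
  key <- paste(seed, sdlog, with_artifacts)
  if (!is.null(.std_cache[[key]])) return(.std_cache[[key]])
  d <- std_design()
  tr <- make_truths(d, n_responsive = 8, n_null = 60, n_blank_only = 3,
                    sdlog = sdlog, seed = seed)
  tab <- simulate_intensities(d, tr, noise = list(sdlog = sdlog), seed = seed)
  if (with_artifacts)
    tab <- apply_artifacts(tab,
                           drift = list(ppm_start = 2, ppm_end = -2,
                                        fold_end = 1.3),
                           missing = list(threshold = 2e5), seed = seed)
  .std_cache[[key]] <- tab
  tab
}

# independent BMC oracle: dense grid scan for the first crossing of
# |m(d) - m(0)| = delta, refined by bisection
oracle_bmc <- function(model, params, delta, s = 1, top = 50,
                       n_grid = 4000, tol = 1e-12) {
  f <- function(d) abs(bmc_mean(model, params, d, s) -
                         bmc_mean(model, params, 0, s)) - delta
  grid <- seq(0, 10 * top, length.out = n_grid)
  vals <- f(grid)  # mean functions are vectorised in dose
  i <- which(vals[-1] > 0 & vals[-length(vals)] <= 0)
  if (!length(i)) return(Inf)
  stats::uniroot(f, c(grid[i[1]], grid[i[1] + 1]), tol = tol)$root
}

# random parameter draw for each model, kept in a regime where the BMC is
# finite and inside the searchable range
random_params <- function(model, rng) {
  g <- rng(5, 15); sd <- rng(0.05, 0.3)
  switch(model,
    linear = list(params = c(g = g, b = rng(-0.5, 0.5)), s = 1),
    power  = list(params = c(g = g, b = rng(0.05, 0.5) * sample(c(-1, 1), 1),
                             delta = rng(1, 3)), s = 1),
    hill   = list(params = c(g = g, v = rng(0.5, 2) * sample(c(-1, 1), 1),
                             k = rng(0.3, 20), n = rng(1, 4)), s = 1),
    exp2   = list(params = c(a = g, b = rng(0.005, 0.05)),
                  s = sample(c(-1, 1), 1)),
    exp3   = list(params = c(a = g, b = rng(0.005, 0.05), c = rng(1, 3)),
                  s = sample(c(-1, 1), 1)),
    exp4   = list(params = c(a = g, b = rng(0.05, 0.5), c = rng(1.05, 2)),
                  s = 1),
    exp5   = list(params = c(a = g, b = rng(0.05, 0.5), c = rng(1.05, 2),
                             gg = rng(1, 3)), s = 1))
}

# simulated Hill feature responses on the standard design's dose layout
hill_responses <- function(conc = c(50 / 2.5^(0:6), 0), n_per_group = 9,
                           g = 10, v = 1, k = 1.28, n = 2, sd = 0.1) {
  d <- rep(conc, each = n_per_group)
  mu <- g + v * ifelse(d > 0, d^n / (k^n + d^n), 0)
  list(doses = d, mu = mu, responses = mu + stats::rnorm(length(d), 0, sd),
       true_bmc_1sd = k * ((sd / abs(v)) / (1 - sd / abs(v)))^(1 / n))
}
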