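# Model fitting, BMC inversion, confidence bounds, lack-of-fit testing,
# model selection and the dual-BMR screen.

test_that("exact linear data are interpolated exactly", {
  d <- rep(c(0, 1, 2, 4), each = 3)
  f <- fit_model("linear", d, 1 + 2 * d)
  expect_lt(f$sse, 1e-12)
  expect_equal(unname(f$params), c(1, 2), tolerance = 1e-9)
  expect_true(f$converged)
  expect_equal(f$AIC, 2 * 3 - 2 * f$loglik)
})

test_that("closed-form BMC inversions match the worked cases", {
  # hill: 50 d / (9 + d) = 5  =>  d = 1
  f1 <- bmc_fit("hill", c(g = 100, v = 50, k = 9, n = 1), sigma = 5)
  expect_equal(compute_bmc(f1, 1), 1, tolerance = 1e-12)
  # power: 2 d = 12  =>  d = 6
  f2 <- bmc_fit("power", c(g = 0, b = 2, delta = 1), sigma = 4)
  expect_equal(compute_bmc(f2, 3), 6, tolerance = 1e-12)
  # decreasing linear: |change| used
  f3 <- bmc_fit("linear", c(g = 10, b = -1), sigma = 1)
  expect_equal(compute_bmc(f3, 1), 1, tolerance = 1e-12)
  # saturating hill that never reaches the benchmark response
  f4 <- bmc_fit("hill", c(g = 0, v = 1, k = 1, n = 2), sigma = 2)
  expect_equal(compute_bmc(f4, 1), Inf)
})

test_that("analytic inversion agrees with grid+bisection on all models", {
  set.seed(101)
  rng <- function(a, b) stats::runif(1, a, b)
  for (model in c("linear", "power", "hill", "exp2", "exp3", "exp4",
                  "exp5")) {
    for (rep in 1:6) {
      pr <- random_params(model, rng)
      delta <- rng(0.05, 0.5)
      ana <- invert_bmc(model, pr$params, delta, pr$s)
      ora <- oracle_bmc(model, pr$params, delta, pr$s)
      if (is.finite(ana) && ana <= 500) {
        expect_equal(ana, ora, tolerance = 1e-6,
                     label = paste(model, "analytic"),
                     expected.label = paste(model, "oracle"))
      } else {
        expect_gt(ora, 500 * 0.999)
      }
    }
  }
})

test_that("planted Hill parameters and BMC are recovered", {
  set.seed(42)
  hx <- hill_responses(sd = 0.05)
  f <- fit_model("hill", hx$doses, hx$responses)
  expect_true(f$converged)
  expect_lt(abs(f$params[["k"]] - 1.28) / 1.28, 0.25)
  bmc <- compute_bmc(f, 1)
  true1 <- 1.28 * sqrt((0.05 / 1) / (1 - 0.05 / 1))
  expect_lt(abs(bmc - true1) / true1, 0.25)
})

test_that("constant responses yield a flat fit and an uninformative BMC", {
  d <- rep(c(0, 1, 2, 4, 8), each = 3)
  y <- rep(5, length(d))
  fl <- fit_model("linear", d, y)
  expect_lt(abs(fl$params[["b"]]), 1e-8)
  # AIC favours the fewest parameters among equally perfect flat fits
  fp <- fit_model("power", d, y)
  fh <- fit_model("hill", d, y)
  expect_lt(fl$AIC, fp$AIC)
  expect_lt(fl$AIC, fh$AIC)
  # with measurement noise, a null feature's BMC lands beyond the range
  set.seed(14)
  fn <- fit_model("linear", d, y + stats::rnorm(length(d), 0, 0.01))
  expect_gt(compute_bmc(fn, 1), max(d))
})

test_that("BMC at 3 SD is never below BMC at 1 SD", {
  set.seed(7)
  hx <- hill_responses(sd = 0.1)
  for (model in c("linear", "power", "hill", "exp4")) {
    f <- fit_model(model, hx$doses, exp(hx$responses / 5))
    if (!f$converged) next
    b1 <- compute_bmc(f, 1); b3 <- compute_bmc(f, 3)
    if (is.finite(b1) && is.finite(b3)) expect_gte(b3, b1)
  }
})

test_that("profile bounds bracket the BMC and tighten as noise vanishes", {
  set.seed(31)
  widths <- sapply(c(0.2, 0.02), function(sd) {
    hx <- hill_responses(sd = sd)
    f <- fit_model("hill", hx$doses, hx$responses)
    b <- compute_bmc(f, 1)
    bb <- compute_bmc_bounds(f, 1)
    expect_lte(bb[["bmcl"]], b)
    expect_gte(bb[["bmcu"]], b)
    (b - bb[["bmcl"]]) / b
  })
  expect_lt(widths[2], widths[1])
})

test_that("profile bounds are consistent with a bootstrap cross-check", {
  set.seed(55)
  hx <- hill_responses(sd = 0.1)
  f <- fit_model("hill", hx$doses, hx$responses)
  prof <- compute_bmc_bounds(f, 1)
  boot <- bootstrap_bmc_bounds(f, 1, n_boot = 60, seed = 56)
  # same order of magnitude, overlapping intervals
  expect_lt(prof[["bmcl"]], boot[["bmcu"]])
  expect_gt(prof[["bmcu"]], boot[["bmcl"]])
  expect_lt(abs(log10(prof[["bmcl"]] / boot[["bmcl"]])), 0.5)
})

test_that("lack-of-fit p-value behaves at both extremes", {
  d <- rep(c(0, 1, 2, 4, 8, 16, 32, 50), each = 3)
  # model passing exactly through the group means: deviance 0, p = 1
  set.seed(3)
  noise <- stats::rnorm(length(d), 0, 0.2)
  noise <- noise - stats::ave(noise, d)  # group means exactly on the line
  y <- 1 + 2 * d + noise
  flin <- fit_model("linear", d, y)
  expect_equal(fit_pvalue(flin), 1, tolerance = 1e-6)
  # gross misfit: straight line on a step function
  ystep <- ifelse(d >= 8, 10, 0) + stats::rnorm(length(d), 0, 0.1)
  fbad <- fit_model("linear", d, ystep)
  expect_lt(fit_pvalue(fbad), 0.05)
  # df arithmetic: 8 groups - 4 hill mean parameters = 4
  fh <- fit_model("hill", d, y)
  expect_equal(length(unique(d)) - (fh$n_params - 1L), 4L)
})

test_that("model selection follows AIC with the Hill-k exclusion", {
  set.seed(12)
  hx <- hill_responses(sd = 0.05)
  fits <- lapply(c("linear", "power", "hill", "exp2", "exp3", "exp4",
                   "exp5"),
                 function(m) fit_model(m, hx$doses, hx$responses))
  best <- select_best(fits, lowest_positive_dose = 0.2048)
  expect_equal(best$model, "hill")
  aics <- sapply(fits, function(f) {
    p <- fit_pvalue(f)
    if (f$converged && (is.na(p) || p > 0.05)) f$AIC else NA_real_
  })
  expect_equal(best$AIC, min(aics, na.rm = TRUE))
  # a Hill fit with k below a third of the lowest dose is excluded
  cheat <- fits
  kpos <- which(sapply(fits, function(f) f$model == "hill"))
  cheat[[kpos]]$params[["k"]] <- 0.05  # 0.05 < 0.2048 / 3 = 0.0683
  best2 <- select_best(cheat, lowest_positive_dose = 0.2048)
  expect_false(is.null(best2))
  expect_false(best2$model == "hill")
  # all non-converged: nothing to select
  none <- lapply(fits, function(f) { f$converged <- FALSE; f })
  expect_null(select_best(none, 0.2048))
})

test_that("dual-BMR screen applies the three criteria at both passes", {
  set.seed(77)
  conc <- c(50 / 2.5^(0:6), 0)
  d <- rep(conc, each = 9)
  mk <- function(y) matrix(y, ncol = 1)
  fm <- data.frame(feature_id = "f1", mz = 300.1)
  # strong planted response inside the range passes both BMRs
  hx <- hill_responses(sd = 0.1, v = 1.2, k = 1.28, n = 2)
  scr <- screen_features(hx$doses, mk(hx$responses), fm)
  expect_true(scr$passed_dual)
  expect_lt(abs(scr$bmc_1sd - hx$true_bmc_1sd) / hx$true_bmc_1sd, 0.5)
  expect_lte(scr$bmcl_1sd, scr$bmc_1sd)
  expect_lte(scr$bmc_1sd, scr$bmcu_1sd)
  expect_gte(scr$bmc_3sd, scr$bmc_1sd)
  # weak response whose 3 SD BMC exceeds the top concentration fails the
  # dual rule even though the 1 SD pass succeeds
  weak <- hill_responses(sd = 0.1, v = 0.32, k = 30, n = 4)
  scr2 <- screen_features(weak$doses, mk(weak$responses), fm)
  if (!is.na(scr2$bmc_3sd) && scr2$pass_1sd) {
    expect_false(scr2$pass_3sd && scr2$bmc_3sd < max(conc))
    expect_false(scr2$passed_dual)
  } else {
    expect_false(scr2$passed_dual)
  }
  # null feature fails
  ynull <- stats::rnorm(length(d), 10, 0.1)
  scr3 <- screen_features(d, mk(ynull), fm)
  expect_false(scr3$passed_dual)
})

test_that("screen re-evaluation confirms every retained record", {
  set.seed(88)
  conc <- c(50 / 2.5^(0:6), 0)
  resp <- sapply(1:8, function(i) {
    if (i <= 4) hill_responses(sd = 0.1, v = stats::runif(1, 0.8, 1.4),
                               k = stats::runif(1, 0.5, 5),
                               n = sample(1:3, 1))$responses
    else stats::rnorm(72, 10, 0.1)
  })
  fm <- data.frame(feature_id = paste0("f", 1:8), mz = 100 + 1:8)
  scr <- screen_features(rep(conc, each = 9), resp, fm)
  top <- max(conc)
  for (i in which(scr$passed_dual)) {
    expect_lt(scr$bmc_3sd[i], top)
    expect_lt(scr$bmc_1sd[i], top)
    expect_true(is.na(scr$p[i]) || scr$p[i] > 1e-4)
    expect_lt(scr$bmc_3sd[i] / scr$bmcl_3sd[i], 20)
    expect_lt(scr$bmc_1sd[i] / scr$bmcl_1sd[i], 20)
  }
  # at least the strong planted features are retained
  expect_gte(sum(scr$passed_dual[1:4]), 3)
  expect_false(any(scr$passed_dual[5:8]))
})

test_that("fewer than four dose groups are rejected", {
  expect_error(fit_model("linear", rep(c(0, 1, 2), each = 3), rnorm(9)),
               ">= 4 dose groups")
})
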