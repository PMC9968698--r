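# Continuous benchmark-concentration (BMC) modelling. Seven mean functions
# (linear, power, Hill, exponential 2-5) are fitted per feature by maximum
# likelihood under Normal errors with constant variance; the BMC at a
# benchmark response of k standard deviations solves
# |m(d) - m(0)| = k * sigma-hat. BMCL/BMCU are one-sided profile-likelihood
# bounds; model selection is lowest-AIC among converged fits passing a
# saturated-model lack-of-fit test, with the Hill-k exclusion rule.

.bmc_model_names <- c("linear", "power", "hill", "exp2", "exp3", "exp4", "exp5")

# number of mean-function parameters per model (variance adds one more)
.bmc_npar <- c(linear = 2L, power = 3L, hill = 4L,
               exp2 = 2L, exp3 = 3L, exp4 = 3L, exp5 = 4L)

#' Mean function of a dose-response model
#'
#' @param model One of `linear`, `power`, `hill`, `exp2`, `exp3`, `exp4`,
#'   `exp5`.
#' @param params Named parameter vector: `g` (intercept/control mean), `b`
#'   (slope/scale), `delta` (power exponent), `v`/`k`/`n` (Hill asymptote,
#'   half-max, exponent), `a` (exponential control mean), `c` (asymptote
#'   ratio), `gg` (exp5 asymmetry exponent).
#' @param d Dose vector (uM), 0 allowed.
#' @param s Trend sign (+1/-1) used by `exp2`/`exp3`.
#' @return Model mean at each dose.
#' @export
bmc_mean <- function(model, params, d, s = 1) {
  p <- params
  switch(model,
    linear = p[["g"]] + p[["b"]] * d,
    power  = p[["g"]] + p[["b"]] * d^p[["delta"]],
    hill   = p[["g"]] + p[["v"]] *
      ifelse(d > 0, d^p[["n"]] / (p[["k"]]^p[["n"]] + d^p[["n"]]), 0),
    exp2   = p[["a"]] * exp(s * p[["b"]] * d),
    exp3   = p[["a"]] * exp(s * (p[["b"]] * d)^p[["c"]]),
    exp4   = p[["a"]] * (p[["c"]] - (p[["c"]] - 1) * exp(-p[["b"]] * d)),
    exp5   = p[["a"]] * (p[["c"]] - (p[["c"]] - 1) *
                           exp(-(p[["b"]] * d)^p[["gg"]])),
    stop("unknown model: ", model)
  )
}

#' Analytic BMC inversion
#'
#' Smallest positive dose at which the model mean departs from the control
#' mean `m(0)` by `delta` in absolute value. All seven mean functions are
#' monotone in dose, so the solution is closed-form; `Inf` is returned when
#' the response never reaches `delta` (e.g. a saturating curve with asymptote
#' below the benchmark response).
#'
#' @inheritParams bmc_mean
#' @param delta Absolute response change defining the benchmark response.
#' @return Dose in uM, possibly `Inf`.
#' @export
invert_bmc <- function(model, params, delta, s = 1) {
  p <- params
  if (delta == 0) return(0)
  out <- switch(model,
    linear = delta / abs(p[["b"]]),
    power  = (delta / abs(p[["b"]]))^(1 / p[["delta"]]),
    hill   = {
      r <- delta / abs(p[["v"]])
      if (r >= 1) Inf else p[["k"]] * (r / (1 - r))^(1 / p[["n"]])
    },
    exp2   = {
      if (s > 0) log1p(delta / p[["a"]]) / p[["b"]]
      else if (delta >= p[["a"]]) Inf else -log(1 - delta / p[["a"]]) / p[["b"]]
    },
    exp3   = {
      u <- if (s > 0) log1p(delta / p[["a"]])
           else if (delta >= p[["a"]]) Inf else -log(1 - delta / p[["a"]])
      u^(1 / p[["c"]]) / p[["b"]]
    },
    exp4   = {
      u <- 1 - delta / (p[["a"]] * abs(p[["c"]] - 1))
      if (u <= 0) Inf else -log(u) / p[["b"]]
    },
    exp5   = {
      u <- 1 - delta / (p[["a"]] * abs(p[["c"]] - 1))
      if (u <= 0) Inf else (-log(u))^(1 / p[["gg"]]) / p[["b"]]
    },
    stop("unknown model: ", model)
  )
  if (!is.finite(out) || out < 0) Inf else out
}

# log-likelihood of a Normal constant-variance fit with sigma profiled out
.bmc_loglik <- function(sse, n) {
  if (sse <= 0) sse <- 1e-300
  -n / 2 * (log(2 * pi * sse / n) + 1)
}

.bmc_fit_obj <- function(model, params, s, doses, responses, sse,
                         converged, iterations = NA_integer_) {
  n <- length(responses)
  sigma <- sqrt(sse / n)
  ll <- .bmc_loglik(sse, n)
  np <- .bmc_npar[[model]] + 1L  # variance counted as a parameter
  structure(list(model = model, params = params, s = s, sigma = sigma,
                 sse = sse, loglik = ll, AIC = 2 * np - 2 * ll,
                 n_params = np, converged = converged,
                 direction = if (s > 0) "increase" else "decrease",
                 doses = doses, responses = responses,
                 iterations = iterations),
            class = "bmc_fit")
}

#' Construct a dose-response fit object from known parameters
#'
#' Mainly for computing BMCs from externally specified model parameters
#' (e.g. planted ground truth); [fit_model()] produces the same structure
#' from data.
#'
#' @inheritParams bmc_mean
#' @param sigma Residual standard deviation.
#' @param doses Optional dose vector (used for the extrapolation cap).
#' @return A `bmc_fit` object.
#' @export
bmc_fit <- function(model, params, sigma, s = 1, doses = NULL) {
  f <- .bmc_fit_obj(model, params, s, doses %||% numeric(0), numeric(0),
                    sse = 0, converged = TRUE)
  f$sigma <- sigma
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bmc_fit <- function(x, ...) {
  cat("bmc_fit:", x$model, if (!x$converged) "(NOT converged)", "\n")
  cat("  params:", paste(names(x$params), signif(x$params, 5),
                         sep = "=", collapse = ", "), "\n")
  cat("  sigma:", signif(x$sigma, 5), " AIC:", signif(x$AIC, 6), "\n")
  invisible(x)
}

# optimiser-space transforms: log for positive scale parameters, identity
# with box bounds for restricted exponents
.bmc_opt_spec <- function(model, s, exponent_max = 18) {
  emax <- exponent_max
  switch(model,
    hill = list(
      # outer parameters (log k, n); (g, v) profiled by least squares
      lower = c(-25, 1), upper = c(25, emax)),
    exp2 = list(names = c("a", "b"),
      to = function(p) log(c(p[["a"]], p[["b"]])),
      from = function(t) c(a = exp(t[1]), b = exp(t[2])),
      lower = c(-300, -300), upper = c(300, 300)),
    exp3 = list(names = c("a", "b", "c"),
      to = function(p) c(log(p[["a"]]), log(p[["b"]]), p[["c"]]),
      from = function(t) c(a = exp(t[1]), b = exp(t[2]), c = t[3]),
      lower = c(-300, -300, 1), upper = c(300, 300, emax)),
    exp4 = list(names = c("a", "b", "c"),
      to = function(p) c(log(p[["a"]]), log(p[["b"]]), p[["c"]]),
      from = function(t) c(a = exp(t[1]), b = exp(t[2]), c = t[3]),
      lower = if (s > 0) c(-300, -300, 1 + 1e-8) else c(-300, -300, 1e-8),
      upper = if (s > 0) c(300, 300, 1e4) else c(300, 300, 1 - 1e-8)),
    exp5 = list(names = c("a", "b", "c", "gg"),
      to = function(p) c(log(p[["a"]]), log(p[["b"]]), p[["c"]], p[["gg"]]),
      from = function(t) c(a = exp(t[1]), b = exp(t[2]), c = t[3], gg = t[4]),
      lower = if (s > 0) c(-300, -300, 1 + 1e-8, 1) else c(-300, -300, 1e-8, 1),
      upper = if (s > 0) c(300, 300, 1e4, emax) else c(300, 300, 1 - 1e-8, emax))
  )
}

.sse <- function(model, params, s, d, y) {
  mu <- bmc_mean(model, params, d, s)
  if (any(!is.finite(mu))) return(Inf)
  sum((y - mu)^2)
}

# trend sign from the data (slope of a straight-line fit)
.trend_sign <- function(d, y) {
  sl <- stats::cov(d, y)
  if (!is.finite(sl) || sl == 0) 1 else sign(sl)
}

# Hill profile: for fixed (k, n), (g, v) solve by least squares
.hill_profile <- function(logk_n, d, y) {
  k <- unname(exp(logk_n[1])); n <- unname(logk_n[2])
  x <- ifelse(d > 0, d^n / (k^n + d^n), 0)
  if (any(!is.finite(x)) || stats::var(x) < 1e-300) return(list(sse = Inf))
  fit <- stats::lm.fit(cbind(1, x), y)
  list(sse = sum(fit$residuals^2),
       params = c(g = unname(fit$coefficients[1]),
                  v = unname(fit$coefficients[2]), k = k, n = n))
}

#' Fit one dose-response model by maximum likelihood
#'
#' Normal errors, constant variance, multi-start optimisation with the power
#' and Hill exponents restricted to be >= 1 by default. The optimiser
#' iteration cap applies per start; a fit that never reaches an optimum is
#' returned with `converged = FALSE` and is excluded from model selection.
#'
#' @param model_name One of the seven model names.
#' @param doses Dose vector including 0 (uM), one entry per observation.
#' @param responses Response vector (transformed intensities), complete.
#' @param restrict_exponent Lower-bound power/Hill/exp exponents at 1.
#' @param max_iter Optimiser iteration cap (default 250).
#' @return A `bmc_fit`.
#' @export
fit_model <- function(model_name, doses, responses,
                      restrict_exponent = TRUE, max_iter = 250) {
  model_name <- match.arg(model_name, .bmc_model_names)
  d <- as.numeric(doses); y <- as.numeric(responses)
  stopifnot(length(d) == length(y), !anyNA(d), !anyNA(y))
  if (length(unique(d)) < 4) stop("need >= 4 dose groups")
  s <- .trend_sign(d, y)
  emin <- if (restrict_exponent) 1 else 1e-2

  if (model_name == "linear") {
    fit <- stats::lm.fit(cbind(1, d), y)
    params <- c(g = unname(fit$coefficients[1]), b = unname(fit$coefficients[2]))
    if (anyNA(params)) params[is.na(params)] <- 0
    return(.bmc_fit_obj("linear", params, s, d, y, sum(fit$residuals^2), TRUE))
  }
  if (model_name == "power") {
    prof <- function(delta) {
      x <- d^delta
      f <- stats::lm.fit(cbind(1, x), y)
      sum(f$residuals^2)
    }
    op <- stats::optimize(prof, c(emin, 18))
    delta <- op$minimum
    # boundary check: compare against delta = emin exactly
    if (prof(emin) <= op$objective) delta <- emin
    f <- stats::lm.fit(cbind(1, d^delta), y)
    params <- c(g = unname(f$coefficients[1]), b = unname(f$coefficients[2]),
                delta = delta)
    if (anyNA(params)) params[is.na(params)] <- 0
    return(.bmc_fit_obj("power", params, s, d, y, sum(f$residuals^2), TRUE))
  }
  if (model_name == "hill") {
    dpos <- sort(unique(d[d > 0]))
    ks <- log(c(min(dpos), exp(mean(log(range(dpos)))), max(dpos)))
    starts <- rbind(cbind(ks, 1), cbind(ks[2], 3), cbind(ks[3], 2))
    best <- NULL; conv <- FALSE
    for (i in seq_len(nrow(starts))) {
      op <- tryCatch(stats::nlminb(starts[i, ],
        function(t) .hill_profile(t, d, y)$sse,
        lower = c(log(min(dpos)) - 12, emin), upper = c(log(max(dpos)) + 12, 18),
        control = list(iter.max = max_iter)), error = function(e) NULL)
      if (is.null(op) || !is.finite(op$objective)) next
      if (is.null(best) || op$objective < best$objective) {
        best <- op; conv <- op$convergence == 0
      } else if (op$objective <= best$objective + 1e-10 && op$convergence == 0)
        conv <- TRUE
    }
    if (is.null(best)) {
      return(.bmc_fit_obj("hill", c(g = mean(y), v = 0, k = 1, n = 1), s,
                          d, y, sum((y - mean(y))^2), FALSE))
    }
    pr <- .hill_profile(best$par, d, y)
    return(.bmc_fit_obj("hill", pr$params, s, d, y, pr$sse, conv,
                        best$iterations))
  }

  # exponential family: nlminb in transformed space, several starts
  spec <- .bmc_opt_spec(model_name, s)
  if (!restrict_exponent && model_name %in% c("exp3", "exp5")) {
    spec$lower[spec$names %in% c("c", "gg")] <-
      pmin(spec$lower[spec$names %in% c("c", "gg")], emin)
  }
  a0 <- mean(y[d == min(d)])
  if (!is.finite(a0) || a0 <= 0) {
    # exponential mean functions require a positive control mean
    params <- spec$from((spec$lower + pmin(spec$upper, 10)) / 2)
    return(.bmc_fit_obj(model_name, params, s, d, y,
                        sum((y - mean(y))^2), FALSE))
  }
  dtop <- max(d)
  rel <- abs(mean(y[d == dtop]) / a0 - 1)
  b0 <- max(rel, 0.05) / dtop
  starts <- switch(model_name,
    exp2 = list(c(log(a0), log(b0)), c(log(a0), log(b0 / 10)),
                c(log(a0), log(b0 * 10))),
    exp3 = list(c(log(a0), log(b0), 1), c(log(a0), log(b0), 2),
                c(log(a0), log(b0 * 10), 1)),
    exp4 = {
      ctar <- mean(y[d == dtop]) / a0
      c0 <- if (s > 0) max(ctar, 1.01) else min(max(ctar, 0.01), 0.99)
      list(c(log(a0), log(1 / stats::median(d[d > 0])), c0),
           c(log(a0), log(1 / dtop), c0),
           c(log(a0), log(10 / dtop), c0))
    },
    exp5 = {
      ctar <- mean(y[d == dtop]) / a0
      c0 <- if (s > 0) max(ctar, 1.01) else min(max(ctar, 0.01), 0.99)
      list(c(log(a0), log(1 / stats::median(d[d > 0])), c0, 1),
           c(log(a0), log(1 / dtop), c0, 2),
           c(log(a0), log(10 / dtop), c0, 1))
    })
  obj <- function(t) .sse(model_name, spec$from(t), s, d, y)
  best <- NULL; conv <- FALSE
  for (st in starts) {
    op <- tryCatch(stats::nlminb(st, obj, lower = spec$lower,
                                 upper = spec$upper,
                                 control = list(iter.max = max_iter)),
                   error = function(e) NULL)
    if (is.null(op) || !is.finite(op$objective)) next
    if (is.null(best) || op$objective < best$objective) {
      best <- op; conv <- op$convergence == 0
    } else if (op$objective <= best$objective + 1e-10 && op$convergence == 0)
      conv <- TRUE
  }
  if (is.null(best)) {
    params <- spec$from(vapply(starts[[1]], identity, numeric(1)))
    return(.bmc_fit_obj(model_name, params, s, d, y,
                        sum((y - mean(y))^2), FALSE))
  }
  .bmc_fit_obj(model_name, spec$from(best$par), s, d, y, best$objective,
               conv, best$iterations)
}

#' Benchmark concentration of a fitted model
#'
#' Solves `|m(d) - m(0)| = bmr_sd * sigma` for the smallest positive dose,
#' using the closed-form inversion of the fitted mean function. Doses beyond
#' ten times the top tested concentration are treated as "no solution" and
#' reported as `Inf`, which fails the retention criteria downstream.
#'
#' @param fit A `bmc_fit`.
#' @param bmr_sd Benchmark response in multiples of the residual SD.
#' @return BMC in uM (`Inf` when unreachable).
#' @export
compute_bmc <- function(fit, bmr_sd) {
  stopifnot(inherits(fit, "bmc_fit"))
  if (!fit$converged) stop("fit did not converge")
  delta <- bmr_sd * fit$sigma
  bmc <- invert_bmc(fit$model, fit$params, delta, fit$s)
  if (length(fit$doses) && is.finite(bmc) && bmc > 10 * max(fit$doses))
    return(Inf)
  bmc
}

#' Profile-likelihood confidence bounds on the BMC
#'
#' One-sided lower and upper bounds at the stated confidence level: the
#' extreme BMC over mean-parameter vectors whose profile log-likelihood
#' (variance profiled out) lies within `qchisq(2*conf - 1, 1) / 2` of the
#' maximum. The search is a penalised multi-start optimisation; individual
#' optimiser failures are ignored and the bound taken over the successful
#' profile points.
#'
#' @param fit A converged `bmc_fit` with data attached.
#' @param bmr_sd Benchmark response in SD multiples.
#' @param confidence Two-sided-equivalent confidence level (default 0.95).
#' @return Named vector `c(bmcl =, bmcu =)`; `(0, Inf)` with attribute
#'   `flat = TRUE` when the likelihood carries no information on the BMC.
#' @export
compute_bmc_bounds <- function(fit, bmr_sd, confidence = 0.95) {
  stopifnot(inherits(fit, "bmc_fit"))
  d <- fit$doses; y <- fit$responses; n <- length(y)
  bmc <- compute_bmc(fit, bmr_sd)
  if (!is.finite(bmc)) return(c(bmcl = 0, bmcu = Inf))
  crit <- stats::qchisq(2 * confidence - 1, 1) / 2
  llmax <- fit$loglik
  top <- max(d)

  model <- fit$model; s <- fit$s
  if (model %in% c("linear", "power", "hill")) {
    to <- function(p) switch(model,
      linear = unname(p),
      power  = c(p[["g"]], p[["b"]], log(p[["delta"]])),
      hill   = c(p[["g"]], p[["v"]], log(p[["k"]]), log(p[["n"]])))
    from <- function(t) switch(model,
      linear = c(g = t[1], b = t[2]),
      power  = c(g = t[1], b = t[2], delta = exp(t[3])),
      hill   = c(g = t[1], v = t[2], k = exp(t[3]), n = exp(t[4])))
  } else {
    spec <- .bmc_opt_spec(model, s)
    to <- spec$to; from <- spec$from
  }
  prof <- function(t) {
    p <- from(t)
    sse <- .sse(model, p, s, d, y)
    if (!is.finite(sse)) return(NULL)
    sig <- sqrt(sse / n)
    b <- invert_bmc(model, p, bmr_sd * sig, s)
    list(ll = .bmc_loglik(sse, n), bmc = b)
  }
  pen_obj <- function(t, sign_) {
    pr <- prof(t)
    if (is.null(pr)) return(1e10)
    viol <- max(0, (llmax - crit) - pr$ll)
    lb <- if (is.finite(pr$bmc) && pr$bmc > 0) log(pr$bmc) else log(100 * top)
    sign_ * lb + 5000 * viol^2
  }
  t0 <- to(fit$params)
  jit <- function(k) t0 + stats::rnorm(length(t0), 0, 0.05 * k)
  # randomized pre-search: feasible profile points with extreme BMC make
  # good extra starting points for the penalised optimiser
  presearch <- function(sign_) {
    best_st <- NULL; best_val <- Inf
    for (i in seq_len(60)) {
      tt <- t0 + stats::rnorm(length(t0), 0, 0.15)
      pr <- prof(tt)
      if (is.null(pr) || pr$ll < llmax - crit) next
      lb <- if (is.finite(pr$bmc) && pr$bmc > 0) log(pr$bmc) else log(100 * top)
      if (sign_ * lb < best_val) { best_val <- sign_ * lb; best_st <- tt }
    }
    best_st
  }
  run_side <- function(sign_) {
    vals <- c()
    starts <- list(t0, jit(1), jit(2), jit(4), jit(8))
    ps <- presearch(sign_)
    if (!is.null(ps)) starts <- c(starts, list(ps))
    for (st in starts) {
      op <- tryCatch(stats::nlminb(st, pen_obj, sign_ = sign_,
                                   control = list(iter.max = 500)),
                     error = function(e) NULL)
      if (is.null(op)) next
      pr <- prof(op$par)
      if (is.null(pr)) next
      if (pr$ll >= llmax - crit - 0.05)  # accept near-binding solutions
        vals <- c(vals, pr$bmc)
    }
    vals
  }
  lo <- run_side(+1); hi <- run_side(-1)
  bmcl <- if (length(lo)) min(lo, bmc) else bmc
  bmcu <- if (length(hi)) max(hi, bmc) else bmc
  if (!length(lo) && !length(hi)) {
    out <- c(bmcl = 0, bmcu = Inf); attr(out, "flat") <- TRUE
    return(out)
  }
  if (is.finite(bmcu) && bmcu > 10 * top) bmcu <- Inf
  c(bmcl = max(bmcl, 0), bmcu = bmcu)
}

#' Bootstrap percentile bounds on the BMC (cross-check)
#'
#' Nonparametric residual bootstrap alternative to the profile-likelihood
#' bounds, intended for cross-checking rather than routine use.
#'
#' @inheritParams compute_bmc_bounds
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @export
bootstrap_bmc_bounds <- function(fit, bmr_sd, confidence = 0.95,
                                 n_boot = 200, seed = 1) {
  stopifnot(inherits(fit, "bmc_fit"))
  set.seed(seed)
  d <- fit$doses; y <- fit$responses
  mu <- bmc_mean(fit$model, fit$params, d, fit$s)
  res <- y - mu
  bmcs <- rep(NA_real_, n_boot)
  for (i in seq_len(n_boot)) {
    yb <- mu + sample(res, length(res), replace = TRUE)
    fb <- tryCatch(fit_model(fit$model, d, yb), error = function(e) NULL)
    if (is.null(fb) || !fb$converged) next
    bmcs[i] <- compute_bmc(fb, bmr_sd)
  }
  bmcs <- bmcs[is.finite(bmcs)]
  alpha <- 1 - confidence
  c(bmcl = unname(stats::quantile(bmcs, alpha)),
    bmcu = unname(stats::quantile(bmcs, 1 - alpha)))
}

#' Lack-of-fit p-value against the saturated group-means model
#'
#' Likelihood-ratio test of the fitted mean function against the model with a
#' free mean per dose group (shared constant variance), on
#' `n_groups - n_mean_params` degrees of freedom. A p-value near 1 indicates
#' the model tracks the group means well.
#'
#' @param fit A `bmc_fit` with data attached.
#' @return p-value; `NA` with attribute `df_flag = TRUE` when df <= 0 (the
#'   model then passes the p-value gates by convention, flagged).
#' @export
fit_pvalue <- function(fit) {
  stopifnot(inherits(fit, "bmc_fit"))
  d <- fit$doses; y <- fit$responses; n <- length(y)
  gm <- stats::ave(y, d)
  sse_sat <- sum((y - gm)^2)
  df <- length(unique(d)) - (fit$n_params - 1L)
  if (df <= 0) {
    out <- NA_real_; attr(out, "df_flag") <- TRUE
    return(out)
  }
  if (sse_sat <= 0) return(if (fit$sse <= 1e-12) 1 else 0)
  dev <- n * log(fit$sse / sse_sat)
  if (dev < 0) dev <- 0
  stats::pchisq(dev, df, lower.tail = FALSE)
}

#' Select the best model by AIC with exclusion rules
#'
#' Non-converged fits are dropped; Hill fits with half-max `k` below one
#' third of the lowest positive dose are flagged and excluded; among the
#' remaining fits whose lack-of-fit p-value exceeds `p_threshold` the lowest
#' AIC wins, ties broken by fewer parameters then by the fixed model order.
#'
#' @param fits List of `bmc_fit` objects on the same data.
#' @param lowest_positive_dose Lowest nonzero tested concentration (uM).
#' @param p_threshold Lack-of-fit gate for eligibility (default 0.05).
#' @return The selected `bmc_fit` (with `$p_lack_of_fit` and `$hill_k_flag`
#'   set), or `NULL` when no fit survives.
#' @export
select_best <- function(fits, lowest_positive_dose, p_threshold = 0.05) {
  if (!length(fits)) return(NULL)
  keep <- list()
  for (f in fits) {
    if (!inherits(f, "bmc_fit") || !f$converged) next
    f$hill_k_flag <- FALSE
    if (f$model == "hill" &&
        f$params[["k"]] < lowest_positive_dose / 3) {
      f$hill_k_flag <- TRUE
      next
    }
    p <- fit_pvalue(f)
    f$p_lack_of_fit <- p
    f$p_df_flag <- isTRUE(attr(p, "df_flag"))
    if (!is.na(p) && p <= p_threshold) next
    keep[[length(keep) + 1L]] <- f
  }
  if (!length(keep)) return(NULL)
  aic <- vapply(keep, function(f) f$AIC, numeric(1))
  np <- vapply(keep, function(f) f$n_params, numeric(1))
  ord <- match(vapply(keep, function(f) f$model, character(1)),
               .bmc_model_names)
  keep[[order(aic, np, ord)[1]]]
}

#' Screen features by dual-pass BMC criteria
#'
#' For each feature, all seven models are fitted once (the fits do not depend
#' on the BMR) and the best is selected; BMC, BMCL and BMCU are then computed
#' at each benchmark response in `bmr`. A feature passes at a given BMR when
#' BMC < top tested concentration, the best model's lack-of-fit p-value
#' exceeds `p_min`, and BMC/BMCL < `bmc_bmcl_max`; it is retained
#' (`passed_dual`) only when it passes at every BMR. Confidence bounds are
#' only computed when the cheaper criteria can still be met.
#'
#' @param doses Dose per sample (uM, including 0), aligned with the rows of
#'   `responses`.
#' @param responses Samples x features matrix of transformed intensities,
#'   complete (imputed upstream).
#' @param feature_meta Data frame with `feature_id` and `mz` per column of
#'   `responses`.
#' @param bmr Benchmark responses in SD multiples (default `c(3, 1)`: a
#'   3 SD filter pass and a 1 SD analysis pass).
#' @param confidence Confidence level for BMCL/BMCU.
#' @param max_iter Optimiser iteration cap.
#' @param p_min Final retention gate on the lack-of-fit p-value.
#' @param bmc_bmcl_max Upper limit on the BMC/BMCL ratio.
#' @param p_select Eligibility gate used during model selection.
#' @return Data frame, one row per feature: selected model, AIC, p-value,
#'   direction, per-BMR BMC/BMCL/BMCU, per-BMR pass flags and `passed_dual`.
#' @export
screen_features <- function(doses, responses, feature_meta,
                            bmr = c(3, 1), confidence = 0.95, max_iter = 250,
                            p_min = 1e-4, bmc_bmcl_max = 20,
                            p_select = 0.05) {
  responses <- as.matrix(responses)
  stopifnot(nrow(responses) == length(doses),
            ncol(responses) == nrow(feature_meta))
  top <- max(doses)
  lowest <- min(doses[doses > 0])
  bmr_lab <- function(b) gsub("\\.", "p", paste0(b, "sd"))
  rows <- vector("list", ncol(responses))
  for (j in seq_len(ncol(responses))) {
    y <- responses[, j]
    fits <- lapply(.bmc_model_names, function(mn)
      tryCatch(fit_model(mn, doses, y, max_iter = max_iter),
               error = function(e) NULL))
    fits <- fits[!vapply(fits, is.null, logical(1))]
    best <- select_best(fits, lowest, p_threshold = p_select)
    rec <- data.frame(feature_id = feature_meta$feature_id[j],
                      mz = feature_meta$mz[j],
                      model = NA_character_, aic = NA_real_, p = NA_real_,
                      direction = NA_character_, sigma = NA_real_,
                      hill_k_flag = FALSE,
                      n_nonconverged = sum(!vapply(fits, function(f)
                        f$converged, logical(1))),
                      stringsAsFactors = FALSE)
    pass_all <- !is.null(best)
    if (!is.null(best)) {
      rec$model <- best$model
      rec$aic <- best$AIC
      rec$p <- if (is.na(best$p_lack_of_fit)) NA_real_ else best$p_lack_of_fit
      rec$direction <- best$direction
      rec$sigma <- best$sigma
      rec$hill_k_flag <- any(vapply(fits, function(f)
        f$model == "hill" && f$converged &&
          f$params[["k"]] < lowest / 3, logical(1)))
    }
    for (b in bmr) {
      lab <- bmr_lab(b)
      bmc <- bmcl <- bmcu <- NA_real_
      pass <- FALSE
      if (!is.null(best)) {
        bmc <- compute_bmc(best, b)
        p_ok <- is.na(rec$p) || rec$p > p_min
        if (is.finite(bmc) && bmc < top && p_ok) {
          bb <- compute_bmc_bounds(best, b, confidence)
          bmcl <- bb[["bmcl"]]; bmcu <- bb[["bmcu"]]
          pass <- bmcl > 0 && is.finite(bmcl) && (bmc / bmcl) < bmc_bmcl_max
        }
      }
      rec[[paste0("bmc_", lab)]] <- bmc
      rec[[paste0("bmcl_", lab)]] <- bmcl
      rec[[paste0("bmcu_", lab)]] <- bmcu
      rec[[paste0("pass_", lab)]] <- pass
      pass_all <- pass_all && pass
    }
    rec$passed_dual <- pass_all
    rows[[j]] <- rec
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
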