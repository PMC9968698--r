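# The preprocessing cascade: from an aligned DIMS feature table to
# BMC-ready, normalised data. Steps are pure functions feature_table ->
# feature_table so the cascade driver can log exact before/after counts.

#' Cascade configuration
#'
#' Bundles the thresholds of the preprocessing cascade. Defaults follow
#' common DIMS practice for a polar positive assay: features kept when
#' present in >= 50% of samples and >= 70% of QCs, samples dropped at >= 40%
#' missing, 3 x MAD internal-standard outlier rule, 30% QC RSD ceiling,
#' kNN imputation with k = 5, 95% confidence PCA outlier ellipse.
#'
#' @param presence_fraction Minimum fraction of non-blank samples a feature
#'   must be detected in.
#' @param qc_presence_fraction Minimum fraction of QCs.
#' @param max_sample_missing Missing-value fraction at or above which a
#'   sample is removed (0.40 polar positive; 0.50 polar negative / lipid
#'   positive).
#' @param mad_multiplier Internal-standard outlier threshold in unscaled
#'   MADs.
#' @param qc_rsd_max Maximum QC relative standard deviation, percent.
#' @param knn_k Neighbours for imputation.
#' @param pca_conf Confidence level of the Hotelling T-squared ellipse.
#' @param blank_ratio_threshold Feature removed when its mean study intensity
#'   is below this multiple of its mean blank intensity. `Inf` reduces the
#'   rule to presence-in-blanks.
#' @param glog_lambda Fixed glog lambda; `NULL` = estimate from QC replicates.
#' @param group_min Starting per-concentration-group presence rule for BMC
#'   sub-tables (tightened to `group_min + 1` when residual missingness
#'   exceeds 50%).
#' @param rerun_on_outliers Re-run the cascade without PCA outliers.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(presence_fraction = 0.5,
                           qc_presence_fraction = 0.7,
                           max_sample_missing = 0.40,
                           mad_multiplier = 3,
                           qc_rsd_max = 30,
                           knn_k = 5,
                           pca_conf = 0.95,
                           blank_ratio_threshold = 20,
                           glog_lambda = NULL,
                           group_min = 4,
                           rerun_on_outliers = TRUE) {
  fr <- c(presence_fraction, qc_presence_fraction)
  if (any(fr <= 0 | fr > 1)) stop("presence fractions must be in (0, 1]")
  if (mad_multiplier <= 0 || qc_rsd_max <= 0) stop("multipliers must be positive")
  structure(as.list(environment()), class = "cascade_config")
}

# locate the internal-standard feature: median observed m/z within
# ppm_window of the theoretical value, detected in >= min_present of samples
.find_is <- function(table, is_mz, ppm_window = 10, min_present = 0.8) {
  med_mz <- apply(table$mz_observed, 2, stats::median, na.rm = TRUE)
  cand <- which(abs(ppm_error(med_mz, is_mz)) <= ppm_window)
  if (!length(cand)) return(NA_integer_)
  pres <- colMeans(!is.na(table$intensities[, cand, drop = FALSE]))
  cand <- cand[pres >= min_present]
  if (!length(cand)) return(NA_integer_)
  cand[which.min(abs(ppm_error(med_mz[cand], is_mz)))]
}

#' Correct mass-accuracy drift using the internal standard
#'
#' The per-sample ppm error of the internal standard's observed m/z against
#' its theoretical value is modelled as a function of acquisition order with
#' a 1-D smoothing spline whose smoothing parameter minimises leave-one-out
#' cross-validated error; every sample's observed m/z values are then divided
#' by the modelled relative error.
#'
#' @param table A [feature_table()].
#' @param is_mz Theoretical internal-standard m/z
#'   (default [is_theoretical_mz()]).
#' @return Corrected table with attribute `is_residual_ppm` (per-sample
#'   residual ppm error of the IS after correction).
#' @export
correct_mass_drift <- function(table, is_mz = is_theoretical_mz()) {
  j <- .find_is(table, is_mz)
  if (is.na(j)) stop("internal standard not found within 10 ppm of ",
                     format(is_mz, digits = 9))
  ord <- table$samples$acq_order
  obs <- table$mz_observed[, j]
  ok <- !is.na(table$intensities[, j]) & !is.na(obs)
  err <- ppm_error(obs, is_mz)
  if (sum(ok) < 5) {
    warning("fewer than 5 usable internal-standard points; ",
            "applying constant (median) mass correction")
    fitted <- rep(stats::median(err[ok]), nrow(table$samples))
  } else {
    sp <- stats::smooth.spline(ord[ok], err[ok], cv = TRUE)
    fitted <- stats::predict(sp, ord)$y
  }
  mz_corr <- table$mz_observed / (1 + fitted * 1e-6)
  out <- feature_table(table$intensities, table$samples, table$features,
                       mz_corr)
  attr(out, "truth") <- attr(table, "truth")
  attr(out, "is_residual_ppm") <- ppm_error(mz_corr[, j], is_mz)
  out
}

#' Remove internal-standard outlier samples
#'
#' Samples whose internal-standard intensity deviates from the median by more
#' than `mad_multiplier` times the (unscaled) median absolute deviation are
#' removed, re-scoring the survivors until the rule is stable (mirroring the
#' re-run of processing without outliers; this also makes the step
#' idempotent). The rule is applied independently within the study-sample
#' stratum (treated + vehicle controls) and the QC stratum; blanks are never
#' scored.
#'
#' @inheritParams correct_mass_drift
#' @param mad_multiplier Threshold in MAD units (default 3).
#' @export
remove_is_outliers <- function(table, is_mz = is_theoretical_mz(),
                               mad_multiplier = 3) {
  j <- .find_is(table, is_mz)
  if (is.na(j)) stop("internal standard not found")
  repeat {
    x <- table$intensities[, j]
    cls <- table$samples$class
    drop <- rep(FALSE, length(x))
    for (stratum in list(c("study", "control"), "QC")) {
      i <- which(cls %in% stratum & !is.na(x))
      if (length(i) < 3) next
      med <- stats::median(x[i])
      mad_u <- stats::median(abs(x[i] - med))
      if (mad_u == 0) {
        warning("zero MAD in IS intensities; removing only exact deviants")
        drop[i] <- x[i] != med
      } else {
        drop[i] <- abs(x[i] - med) > mad_multiplier * mad_u
      }
    }
    if (!any(drop)) return(table)
    table <- ft_subset(table, samples = which(!drop))
  }
}

#' Subtract extraction-blank features
#'
#' A feature detected in the extraction blanks is removed unless its mean
#' study intensity exceeds `ratio_threshold` times its mean blank intensity.
#'
#' @inheritParams correct_mass_drift
#' @param ratio_threshold Study/blank mean-intensity ratio a feature must
#'   reach to survive despite blank detection; `Inf` removes every feature
#'   detected in any blank.
#' @param drop_blanks Also remove the blank samples afterwards.
#' @export
blank_filter <- function(table, ratio_threshold = 20, drop_blanks = FALSE) {
  bi <- .ft_class_idx(table, "blank")
  if (!length(bi)) {
    warning("no blank samples present; blank filter skipped")
    return(table)
  }
  si <- .ft_class_idx(table, c("study", "control"))
  bm <- colMeans(table$intensities[bi, , drop = FALSE], na.rm = TRUE)
  sm <- colMeans(table$intensities[si, , drop = FALSE], na.rm = TRUE)
  sm[is.nan(sm)] <- 0
  in_blank <- colSums(!is.na(table$intensities[bi, , drop = FALSE])) > 0
  remove <- in_blank & if (is.infinite(ratio_threshold)) TRUE else
    sm < ratio_threshold * bm
  out <- ft_subset(table, features = which(!remove))
  if (drop_blanks)
    out <- ft_subset(out, samples = which(out$samples$class != "blank"))
  out
}

#' Presence filter across the dataset
#'
#' Keeps features detected in at least `fraction` of the non-blank samples
#' (boundary inclusive).
#'
#' @inheritParams correct_mass_drift
#' @param fraction Minimum detected fraction (default 0.5).
#' @export
presence_filter <- function(table, fraction = 0.5) {
  si <- .ft_class_idx(table, c("study", "control", "QC"))
  pres <- colMeans(!is.na(table$intensities[si, , drop = FALSE]))
  ft_subset(table, features = which(pres >= fraction))
}

#' Remove samples with excessive missingness
#'
#' Non-blank samples whose missing-value fraction is at or above
#' `max_missing` are removed (0.40 for a polar positive assay, 0.50 for
#' polar negative and lipid positive).
#'
#' @inheritParams correct_mass_drift
#' @param max_missing Removal threshold on the per-sample missing fraction.
#' @export
sparse_sample_filter <- function(table, max_missing = 0.40) {
  fr <- rowMeans(is.na(table$intensities))
  drop <- fr >= max_missing & table$samples$class != "blank"
  ft_subset(table, samples = which(!drop))
}

#' QC presence filter
#'
#' Keeps features detected in at least `fraction` of the intrastudy QC
#' samples (boundary inclusive).
#'
#' @inheritParams correct_mass_drift
#' @param fraction Minimum detected fraction among QCs (default 0.7).
#' @export
qc_presence_filter <- function(table, fraction = 0.7) {
  qi <- .ft_class_idx(table, "QC")
  if (!length(qi)) stop("no QC samples present")
  pres <- colMeans(!is.na(table$intensities[qi, , drop = FALSE]))
  ft_subset(table, features = which(pres >= fraction))
}

#' QC-anchored signal drift and batch effect correction
#'
#' Per feature and batch, the QC intensity trend over acquisition order is
#' fitted by a cross-validated smoothing spline (capped in equivalent df so
#' it cannot interpolate QC noise; a straight line below 5 QC points),
#' interpolated to all samples in the batch and divided out; batch levels are
#' then aligned on their QC medians. Batches in which a feature is absent
#' from all QCs are left uncorrected for that feature and flagged.
#'
#' @inheritParams correct_mass_drift
#' @return Corrected table; attribute `uncorrected` lists feature/batch pairs
#'   skipped for lack of QC coverage.
#' @export
drift_batch_correct <- function(table) {
  man <- table$samples
  qi <- .ft_class_idx(table, "QC")
  if (length(qi) < 2) stop("need >= 2 QC samples for drift correction")
  m <- table$intensities
  batches <- unique(man$batch)
  skipped <- list()
  for (j in seq_len(ncol(m))) {
    bmed <- rep(NA_real_, length(batches))
    for (bi in seq_along(batches)) {
      b <- batches[bi]
      rows <- which(man$batch == b)
      qrows <- intersect(rows, qi)
      qx <- man$acq_order[qrows]; qy <- m[qrows, j]
      usable <- !is.na(qy)
      if (sum(usable) < 2) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(feature = table$features$feature_id[j], batch = b)
        next
      }
      qx <- qx[usable]; qy <- qy[usable]
      med <- stats::median(qy)
      nq <- length(qx)
      pred <- NULL
      if (nq >= 5) {
        # GCV smoothing spline; cap the equivalent df so the trend cannot
        # interpolate the QC noise (which would deflate the apparent
        # technical variance to zero)
        sp <- tryCatch(suppressWarnings(stats::smooth.spline(qx, qy,
                                                             cv = FALSE)),
                       error = function(e) NULL)
        if (!is.null(sp) && sp$df > nq - 2)
          sp <- tryCatch(suppressWarnings(
            stats::smooth.spline(qx, qy, df = max(2, nq - 2))),
            error = function(e) NULL)
        if (!is.null(sp)) {
          pr <- stats::predict(sp, man$acq_order[rows])$y
          # clamp extrapolation beyond the QC range to the edge values
          lo <- min(qx); hi <- max(qx)
          pr[man$acq_order[rows] < lo] <- stats::predict(sp, lo)$y
          pr[man$acq_order[rows] > hi] <- stats::predict(sp, hi)$y
          pred <- pr
        }
      }
      if (is.null(pred)) {
        cf <- stats::lm.fit(cbind(1, qx), qy)$coefficients
        pred <- cf[1] + cf[2] * man$acq_order[rows]
      }
      fac <- pred / med
      if (any(!is.finite(fac)) || any(fac <= 0)) fac <- rep(1, length(rows))
      m[rows, j] <- m[rows, j] / fac
      bmed[bi] <- stats::median(m[intersect(rows, qi), j], na.rm = TRUE)
    }
    # align batch levels on their QC medians
    if (sum(!is.na(bmed)) >= 2) {
      grand <- stats::median(m[qi, j], na.rm = TRUE)
      for (bi in seq_along(batches)) {
        if (is.na(bmed[bi]) || bmed[bi] <= 0) next
        rows <- which(man$batch == batches[bi])
        m[rows, j] <- m[rows, j] * (grand / bmed[bi])
      }
    }
  }
  out <- feature_table(m, man, table$features, table$mz_observed)
  attr(out, "truth") <- attr(table, "truth")
  attr(out, "uncorrected") <- if (length(skipped)) do.call(rbind, skipped)
  out
}

#' Probabilistic quotient normalisation
#'
#' Each non-blank sample is divided by the median of its feature-wise
#' quotients against a reference spectrum (the median spectrum of the QC
#' samples; of the study samples when no QCs are present), using only
#' features observed in both. After normalisation every sample's median
#' quotient against the reference equals 1 by construction.
#'
#' @inheritParams correct_mass_drift
#' @param min_shared Minimum shared features for a quotient to be computed;
#'   samples below it are left unnormalised and flagged.
#' @return Normalised table with attributes `pqn_reference` and
#'   `pqn_flagged`.
#' @export
pqn_normalise <- function(table, min_shared = 10) {
  qi <- .ft_class_idx(table, "QC")
  ref_rows <- if (length(qi)) qi else .ft_class_idx(table, c("study", "control"))
  ref <- apply(table$intensities[ref_rows, , drop = FALSE], 2,
               stats::median, na.rm = TRUE)
  m <- table$intensities
  flagged <- character(0)
  for (i in seq_len(nrow(m))) {
    if (table$samples$class[i] == "blank") next
    shared <- which(!is.na(m[i, ]) & !is.na(ref) & ref > 0)
    if (length(shared) < min_shared) {
      flagged <- c(flagged, table$samples$sample_id[i])
      next
    }
    coef <- stats::median(m[i, shared] / ref[shared])
    if (is.finite(coef) && coef > 0) m[i, ] <- m[i, ] / coef
  }
  out <- feature_table(m, table$samples, table$features, table$mz_observed)
  attr(out, "truth") <- attr(table, "truth")
  attr(out, "pqn_reference") <- ref
  attr(out, "pqn_flagged") <- flagged
  if (length(flagged))
    warning("PQN skipped for ", length(flagged), " sample(s) with < ",
            min_shared, " shared features")
  out
}

#' QC relative standard deviation filter
#'
#' Removes features whose RSD (sample SD / mean x 100, on un-transformed
#' post-normalisation intensities) across the QC samples exceeds `max_rsd`.
#' Features with fewer than two QC observations are kept (RSD undefined).
#'
#' @inheritParams correct_mass_drift
#' @param max_rsd Maximum RSD in percent (default 30).
#' @export
qc_rsd_filter <- function(table, max_rsd = 30) {
  qi <- .ft_class_idx(table, "QC")
  if (!length(qi)) stop("no QC samples present")
  rsd <- apply(table$intensities[qi, , drop = FALSE], 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2 || mean(x) == 0) return(NA_real_)
    stats::sd(x) / mean(x) * 100
  })
  ft_subset(table, features = which(is.na(rsd) | rsd <= max_rsd))
}

#' QC median RSD
#'
#' Dataset-level precision summary: the median across features of the QC
#' relative standard deviation.
#'
#' @inheritParams correct_mass_drift
#' @return mRSD in percent.
#' @export
qc_mrsd <- function(table) {
  qi <- .ft_class_idx(table, "QC")
  rsd <- apply(table$intensities[qi, , drop = FALSE], 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2 || mean(x) == 0) return(NA_real_)
    stats::sd(x) / mean(x) * 100
  })
  stats::median(rsd, na.rm = TRUE)
}

#' k-nearest-neighbour imputation
#'
#' Missing values are imputed from the k features nearest to the target
#' feature (root-mean-square Euclidean distance over samples where both are
#' observed), averaging the neighbours' values in the target sample. Features
#' with no usable neighbour fall back to the feature median, with a warning.
#'
#' @inheritParams correct_mass_drift
#' @param k Number of neighbours (default 5; clamped to the number of
#'   available neighbours).
#' @param min_shared Minimum shared samples for a distance to be defined.
#' @export
impute_knn <- function(table, k = 5, min_shared = 3) {
  m <- table$intensities
  if (!anyNA(m)) return(table)
  miss_feats <- which(colSums(is.na(m)) > 0)
  fell_back <- 0L
  for (j in miss_feats) {
    xj <- m[, j]
    obs_j <- !is.na(xj)
    dist <- rep(NA_real_, ncol(m))
    for (l in seq_len(ncol(m))) {
      if (l == j) next
      shared <- obs_j & !is.na(m[, l])
      if (sum(shared) < min_shared) next
      dist[l] <- sqrt(mean((xj[shared] - m[shared, l])^2))
    }
    for (i in which(is.na(xj))) {
      cand <- which(!is.na(dist) & !is.na(m[i, ]))
      if (!length(cand)) {
        m[i, j] <- stats::median(xj, na.rm = TRUE)
        fell_back <- fell_back + 1L
        next
      }
      nb <- cand[order(dist[cand])][seq_len(min(k, length(cand)))]
      m[i, j] <- mean(m[i, nb])
    }
  }
  if (fell_back)
    warning(fell_back, " value(s) imputed by feature median ",
            "(no complete neighbours)")
  out <- feature_table(m, table$samples, table$features, table$mz_observed)
  attr(out, "truth") <- attr(table, "truth")
  out
}

#' Generalised log transform
#'
#' `glog(x) = ln(x + sqrt(x^2 + lambda))`: logarithmic at high intensity,
#' linear near zero, variance-stabilising in between.
#'
#' @param x Non-negative numeric values.
#' @param lambda Transform parameter, >= 0.
#' @export
glog <- function(x, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  log(x + sqrt(x^2 + lambda))
}

#' Estimate the glog lambda from QC replicates
#'
#' Maximum-likelihood choice of lambda on the QC samples: the transformed QC
#' replicates of each feature are modelled as Normal around a feature mean
#' with a shared variance, and the Jacobian-corrected likelihood is maximised
#' over lambda on a log scale.
#'
#' @inheritParams correct_mass_drift
#' @return Estimated lambda.
#' @export
glog_lambda_qc <- function(table) {
  qi <- .ft_class_idx(table, "QC")
  if (length(qi) < 3) stop("need >= 3 QC samples to estimate lambda")
  x <- table$intensities[qi, , drop = FALSE]
  keep <- colSums(!is.na(x)) >= 3
  x <- x[, keep, drop = FALSE]
  nll <- function(loglam) {
    lam <- exp(loglam)
    z <- glog(x, lam)
    zc <- sweep(z, 2, colMeans(z, na.rm = TRUE))
    n <- sum(!is.na(zc))
    sse <- sum(zc^2, na.rm = TRUE)
    # Jacobian of the transform: dz/dx = 1 / sqrt(x^2 + lambda)
    jac <- -0.5 * sum(log(x^2 + lam), na.rm = TRUE)
    n / 2 * log(sse / n) - jac
  }
  mx <- max(x, na.rm = TRUE)
  op <- stats::optimize(nll, c(log(mx^2) - 30, log(mx^2)))
  exp(op$minimum)
}

#' glog transform and per-feature mean centring
#'
#' @inheritParams correct_mass_drift
#' @param lambda Transform parameter; `NULL` estimates it from QC replicates
#'   via [glog_lambda_qc()] (falling back to 1 without QCs).
#' @param centre Subtract the per-feature mean afterwards (default TRUE).
#' @return Transformed table with attribute `glog_lambda`.
#' @export
glog_mean_centre <- function(table, lambda = NULL, centre = TRUE) {
  if (is.null(lambda)) {
    lambda <- tryCatch(glog_lambda_qc(table), error = function(e) 1)
  }
  if (lambda < 0) stop("lambda must be >= 0")
  m <- glog(table$intensities, lambda)
  if (centre) m <- sweep(m, 2, colMeans(m, na.rm = TRUE))
  out <- feature_table(m, table$samples, table$features, table$mz_observed)
  attr(out, "truth") <- attr(table, "truth")
  attr(out, "glog_lambda") <- lambda
  out
}

#' PCA outlier removal (Hotelling T-squared)
#'
#' Scores the non-blank samples on the first two principal components and
#' removes those outside the Hotelling T-squared ellipse at the stated
#' confidence level. Requires imputed, transformed data.
#'
#' @inheritParams correct_mass_drift
#' @param conf Confidence level (default 0.95; `conf = 1` removes nothing).
#' @param iterate Repeat until no sample falls outside the ellipse.
#' @return Table without the outlying samples; attribute `pca_outliers`
#'   lists the removed sample ids.
#' @export
pca_outlier_removal <- function(table, conf = 0.95, iterate = FALSE) {
  removed <- character(0)
  repeat {
    si <- .ft_class_idx(table, c("study", "control", "QC"))
    n <- length(si)
    if (n < 4) {
      warning("fewer than 4 samples; PCA outlier removal skipped")
      break
    }
    x <- table$intensities[si, , drop = FALSE]
    if (anyNA(x)) stop("PCA outlier removal requires imputed data")
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    npc <- min(2L, ncol(pc$x))
    sc <- pc$x[, seq_len(npc), drop = FALSE]
    v <- pc$sdev[seq_len(npc)]^2
    t2 <- rowSums(sweep(sc^2, 2, v, "/"))
    thr <- npc * (n - 1) / (n - npc) * stats::qf(conf, npc, n - npc)
    out_i <- which(t2 > thr)
    if (!length(out_i)) break
    removed <- c(removed, table$samples$sample_id[si[out_i]])
    table <- ft_subset(table, samples = setdiff(seq_len(nrow(table$samples)),
                                                si[out_i]))
    if (!iterate) break
  }
  attr(table, "pca_outliers") <- removed
  table
}

#' Build a BMC-ready sub-table for one chemical and time point
#'
#' Restricts the table to the study samples of one chemical plus the vehicle
#' controls at one time point, then keeps only features detected in at least
#' `group_min` samples of every concentration group. If the per-feature or
#' per-sample missing percentage still exceeds 50% the rule is tightened to
#' `group_min + 1` and the filter re-applied.
#'
#' @inheritParams correct_mass_drift
#' @param chemical Chemical label.
#' @param time Time point (h).
#' @param group_min Starting presence rule (default 4).
#' @return List: `table` (the sub-table), `rule` (4 or 5),
#'   `max_missing_pct`.
#' @export
prepare_bmc_groups <- function(table, chemical, time, group_min = 4) {
  man <- table$samples
  keep <- (man$class == "study" & man$chemical == chemical &
             man$time == time) |
          (man$class == "control" & man$time == time)
  keep[is.na(keep)] <- FALSE
  sub <- ft_subset(table, samples = which(keep))
  doses <- sub$samples$conc
  groups <- sort(unique(doses))
  cnt <- table(doses)
  if (any(cnt < 4))
    stop("concentration group(s) with fewer than 4 samples: ",
         paste(names(cnt)[cnt < 4], collapse = ", "))
  apply_rule <- function(rule) {
    ok <- rep(TRUE, ncol(sub$intensities))
    for (g in groups) {
      rows <- which(doses == g)
      ok <- ok & colSums(!is.na(sub$intensities[rows, , drop = FALSE])) >= rule
    }
    ft_subset(sub, features = which(ok))
  }
  rule <- group_min
  res <- apply_rule(rule)
  mm <- function(tb) {
    if (!ncol(tb$intensities)) return(0)
    100 * max(colMeans(is.na(tb$intensities)), rowMeans(is.na(tb$intensities)))
  }
  if (mm(res) > 50) {
    rule <- group_min + 1
    res <- apply_rule(rule)
  }
  list(table = res, rule = rule, max_missing_pct = mm(res))
}

.log_step <- function(log, step, before, after) {
  rbind(log, data.frame(
    step = step,
    samples_before = nrow(before$samples), samples_after = nrow(after$samples),
    features_before = nrow(before$features),
    features_after = nrow(after$features),
    stringsAsFactors = FALSE))
}

#' Run the full preprocessing cascade
#'
#' Applies, in order: mass-drift correction, internal-standard outlier
#' removal, blank subtraction (blank samples dropped afterwards), dataset
#' presence filter, sparse-sample removal, QC presence filter, QC-anchored
#' signal/batch drift correction, probabilistic quotient normalisation and
#' the QC RSD filter; then, on an imputed glog-transformed copy, PCA outlier
#' removal. When PCA outliers are found and `config$rerun_on_outliers` is
#' set, the cascade is re-run from scratch without those samples.
#'
#' The returned table is the normalised, un-imputed table (missingness is
#' still meaningful for the per-group presence rules of
#' [prepare_bmc_groups()]); the imputed/transformed PCA branch is returned
#' alongside.
#'
#' @inheritParams correct_mass_drift
#' @param config A [cascade_config()].
#' @return List of class `cascade_result`: `table`, `pca_table`,
#'   `log` (the filter log), `is_residual_ppm`, `glog_lambda`,
#'   `pca_outliers`.
#' @export
run_cascade <- function(table, config = cascade_config(),
                        is_mz = is_theoretical_mz()) {
  log <- NULL
  step <- function(name, f, tab) {
    out <- f(tab)
    log <<- .log_step(log, name, tab, out)
    out
  }
  t0 <- table
  t1 <- step("mass_drift_correction",
             function(x) correct_mass_drift(x, is_mz), t0)
  is_res <- attr(t1, "is_residual_ppm")
  t2 <- step("is_outlier_removal",
             function(x) remove_is_outliers(x, is_mz, config$mad_multiplier),
             t1)
  t3 <- step("blank_filter",
             function(x) blank_filter(x, config$blank_ratio_threshold,
                                      drop_blanks = TRUE), t2)
  t4 <- step("presence_filter",
             function(x) presence_filter(x, config$presence_fraction), t3)
  t5 <- step("sparse_sample_filter",
             function(x) sparse_sample_filter(x, config$max_sample_missing),
             t4)
  t6 <- step("qc_presence_filter",
             function(x) qc_presence_filter(x, config$qc_presence_fraction),
             t5)
  t7 <- step("drift_batch_correction", drift_batch_correct, t6)
  t8 <- step("pqn_normalisation", pqn_normalise, t7)
  t9 <- step("qc_rsd_filter",
             function(x) qc_rsd_filter(x, config$qc_rsd_max), t8)
  imp <- step("knn_imputation", function(x) impute_knn(x, config$knn_k), t9)
  trf <- step("glog_mean_centre",
              function(x) glog_mean_centre(x, config$glog_lambda), imp)
  pca <- step("pca_outlier_removal",
              function(x) pca_outlier_removal(x, config$pca_conf), trf)
  outliers <- attr(pca, "pca_outliers")
  if (length(outliers) && isTRUE(config$rerun_on_outliers)) {
    keep <- which(!(table$samples$sample_id %in% outliers))
    cfg2 <- config
    cfg2$rerun_on_outliers <- FALSE  # single re-pass
    res2 <- run_cascade(ft_subset(table, samples = keep), cfg2, is_mz)
    res2$log <- rbind(log, res2$log)
    res2$pca_outliers <- c(outliers, res2$pca_outliers)
    return(res2)
  }
  # drop the PCA outliers from the normalised table as well
  t_final <- ft_subset(t9, samples = which(!(t9$samples$sample_id %in%
                                               outliers)))
  structure(list(table = t_final, pca_table = pca, log = log,
                 is_residual_ppm = is_res,
                 glog_lambda = attr(trf, "glog_lambda"),
                 pca_outliers = outliers),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("cascade_result:\n")
  print(x$log, row.names = FALSE)
  invisible(x)
}
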