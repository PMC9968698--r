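# The preprocessing cascade: each step's contract plus cascade-level
# invariants (idempotent filters, monotone counts, reconciling log).

# minimal hand-built table: values chosen per test
mini_table <- function(m, classes, conc = NULL, batch = 1, mz = NULL) {
  n <- nrow(m); p <- ncol(m)
  if (is.null(mz)) mz <- 100 + seq_len(p)
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    chemical = ifelse(classes %in% c("study", "control"), "chemA", NA),
    conc = if (is.null(conc)) ifelse(classes == "study", 10,
                                     ifelse(classes == "control", 0, NA))
           else conc,
    time = 24, bio_rep = 1, tech_rep = seq_len(n), class = classes,
    batch = batch, acq_order = seq_len(n), stringsAsFactors = FALSE)
  features <- data.frame(feature_id = sprintf("f%02d", seq_len(p)), mz = mz,
                         stringsAsFactors = FALSE)
  feature_table(m, samples, features)
}

test_that("internal-standard outliers are removed by the 3xMAD rule", {
  # worked example: median 10.5, MAD 1.5, threshold 4.5 -> only 40 removed
  is_int <- c(8, 9, 10, 11, 12, 40)
  m <- cbind(is_int, matrix(100, 6, 2))
  tab <- mini_table(m, rep("study", 6), mz = c(is_theoretical_mz(), 201, 202))
  out <- remove_is_outliers(tab)
  expect_equal(nrow(out$samples), 5)
  expect_false("s06" %in% out$samples$sample_id)
  # all equal: no removals
  m2 <- cbind(rep(10, 6), matrix(100, 6, 2))
  tab2 <- mini_table(m2, rep("study", 6),
                     mz = c(is_theoretical_mz(), 201, 202))
  expect_warning(out2 <- remove_is_outliers(tab2), "zero MAD")
  expect_equal(nrow(out2$samples), 6)
})

test_that("IS outlier strata are independent and blanks never scored", {
  # an extreme QC must not shift the study-sample threshold
  is_int <- c(8, 9, 10, 11, 12, 13,      # study
              10, 10, 10, 10, 1000,      # QC (one extreme)
              1e9)                       # blank (never scored)
  m <- cbind(is_int, matrix(100, 12, 1))
  tab <- mini_table(m, c(rep("study", 6), rep("QC", 5), "blank"),
                    mz = c(is_theoretical_mz(), 201))
  out <- suppressWarnings(remove_is_outliers(tab))  # zero MAD in the QCs
  expect_true(all(sprintf("s%02d", 1:6) %in% out$samples$sample_id))
  expect_false("s11" %in% out$samples$sample_id)
  expect_true("s12" %in% out$samples$sample_id)
})

test_that("mass-drift correction undoes a linear ppm drift", {
  d <- std_design()
  tr <- make_truths(d, 2, 10, 0, seed = 6)
  tab <- simulate_intensities(d, tr, seed = 6)
  drifted <- apply_artifacts(tab, drift = list(ppm_start = 2, ppm_end = -2),
                             seed = 6)
  corr <- correct_mass_drift(drifted)
  expect_lt(max(abs(attr(corr, "is_residual_ppm"))), 0.1)
  # strict RMS improvement
  is_col <- which(abs(ppm_error(drifted$features$mz, is_theoretical_mz()))
                  < 1)
  rms <- function(x) sqrt(mean(x^2))
  before <- ppm_error(drifted$mz_observed[, is_col], is_theoretical_mz())
  expect_lt(rms(attr(corr, "is_residual_ppm")), rms(before))
  # zero drift: near-identity
  clean <- apply_artifacts(tab, seed = 6)
  corr0 <- correct_mass_drift(clean)
  rel <- abs(corr0$mz_observed - clean$mz_observed) / clean$mz_observed
  expect_lt(max(rel) * 1e6, 0.05)
  # IS absent: error
  expect_error(correct_mass_drift(tab), "internal standard")
})

test_that("blank subtraction uses the study/blank intensity ratio", {
  m <- rbind(c(1500, 100, 25000),
             c(1500, 100, 25000),
             c(1000,  NA,  1000),
             c(1000,  NA,  1000))
  tab <- mini_table(m, c("study", "study", "blank", "blank"))
  out <- blank_filter(tab, ratio_threshold = 20)
  # f1: 1500 < 20*1000 -> removed; f2 absent from blanks -> kept;
  # f3: 25000 >= 20*1000 -> kept
  expect_equal(out$features$feature_id, c("f02", "f03"))
  # no blanks: warning, no-op
  tab2 <- mini_table(m[1:2, ], c("study", "study"))
  expect_warning(out2 <- blank_filter(tab2, 20), "no blank")
  expect_equal(dim(out2$intensities), dim(tab2$intensities))
})

test_that("presence filters use inclusive boundaries", {
  m <- matrix(NA_real_, 10, 3)
  m[1:4, 1] <- 1   # 4/10 -> removed at 0.5
  m[1:5, 2] <- 1   # 5/10 -> kept (boundary)
  m[, 3] <- 1
  tab <- mini_table(m, rep("study", 10))
  out <- presence_filter(tab, 0.5)
  expect_equal(out$features$feature_id, c("f02", "f03"))
  expect_equal(ncol(presence_filter(tab, 1e-9)$intensities), 3)
  # QC presence: 6/10 removed, 7/10 kept
  mq <- matrix(NA_real_, 10, 2)
  mq[1:6, 1] <- 1; mq[1:7, 2] <- 1
  tabq <- mini_table(mq, rep("QC", 10))
  outq <- qc_presence_filter(tabq, 0.7)
  expect_equal(outq$features$feature_id, "f02")
  expect_error(qc_presence_filter(mini_table(mq, rep("study", 10)), 0.7),
               "no QC")
})

test_that("sparse samples are removed at the assay threshold", {
  m <- matrix(1, 3, 100)
  m[1, 1:45] <- NA  # 45% missing -> removed at 0.40
  m[2, 1:39] <- NA  # 39% -> kept
  tab <- mini_table(m, rep("study", 3))
  out <- sparse_sample_filter(tab, 0.40)
  expect_equal(out$samples$sample_id, c("s02", "s03"))
  expect_equal(nrow(sparse_sample_filter(tab, 1.0)$samples), 3)
})

test_that("QC-anchored drift correction flattens QC trends and aligns batches", {
  # two batches, x2 offset, linear in-batch drift
  n <- 40
  cls <- rep(c("QC", "study", "study", "study"), 10)
  batch <- rep(1:2, each = 20)
  base <- 1000
  drift <- seq(1, 2, length.out = 20)
  lev <- ifelse(batch == 1, 1, 2)
  x <- base * lev * c(drift, drift)
  m <- cbind(x, x * 2)
  tab <- mini_table(m, cls, batch = batch)
  out <- drift_batch_correct(tab)
  qc <- out$samples$class == "QC"
  for (j in 1:2) {
    # QC trend slope ~ 0 after correction
    sl <- stats::coef(stats::lm(out$intensities[qc, j] ~
                                  out$samples$acq_order[qc]))[2]
    expect_lt(abs(sl) * 20 / mean(out$intensities[qc, j]), 0.02)
    # batch means agree within 5%
    b1 <- mean(out$intensities[batch == 1, j])
    b2 <- mean(out$intensities[batch == 2, j])
    expect_lt(abs(b1 / b2 - 1), 0.05)
  }
  # drift-free data: correction within 1% of identity
  m0 <- cbind(rep(1000, n), rep(2000, n))
  tab0 <- mini_table(m0, cls, batch = batch)
  out0 <- drift_batch_correct(tab0)
  expect_lt(max(abs(out0$intensities / m0 - 1)), 0.01)
})

test_that("PQN normalises by the median quotient against the reference", {
  # sample [20, 40] vs reference [10, 20]: quotient 2 -> [10, 20]
  ref_rows <- matrix(rep(c(10, 20), each = 12), 12)
  samp <- c(20, 40)
  m <- rbind(ref_rows, samp)
  tab <- mini_table(m, c(rep("QC", 12), "study"))
  out <- pqn_normalise(tab, min_shared = 2)
  expect_equal(unname(out$intensities[13, ]), c(10, 20))
  # a sample equal to the reference is unchanged
  tab2 <- mini_table(rbind(ref_rows, c(10, 20)),
                     c(rep("QC", 12), "study"))
  out2 <- pqn_normalise(tab2, min_shared = 2)
  expect_equal(unname(out2$intensities[13, ]), c(10, 20))
  # post-condition on real-ish data: every sample's median quotient is 1
  tab3 <- std_table(with_artifacts = FALSE)
  out3 <- pqn_normalise(tab3)
  ref <- attr(out3, "pqn_reference")
  for (i in which(out3$samples$class != "blank")) {
    sh <- which(!is.na(out3$intensities[i, ]) & !is.na(ref) & ref > 0)
    if (length(sh) < 10) next
    expect_equal(stats::median(out3$intensities[i, sh] / ref[sh]), 1,
                 tolerance = 1e-9)
  }
})

test_that("QC RSD filter computes percent RSD on QC samples", {
  m <- cbind(c(90, 100, 110), c(100, 200, 300), c(100, 100, 100))
  tab <- mini_table(m, rep("QC", 3))
  out <- qc_rsd_filter(tab, 30)
  # RSDs: 10% kept, 50% removed, 0% kept
  expect_equal(out$features$feature_id, c("f01", "f03"))
})

test_that("kNN imputation averages the nearest features", {
  # two identical features, one missing a value -> imputed to the twin
  f1 <- c(5, 6, 7, 8, 9, 10)
  m <- cbind(f1, f1, f1 * 100)
  m[3, 1] <- NA
  tab <- mini_table(m, rep("study", 6))
  out <- impute_knn(tab, k = 1, min_shared = 3)
  expect_equal(out$intensities[3, 1], 7)
  expect_false(anyNA(out$intensities))
  # no missing values: identity
  tab2 <- mini_table(cbind(f1, f1), rep("study", 6))
  expect_identical(impute_knn(tab2, 5)$intensities, tab2$intensities)
  # k larger than the feature count: clamped to available neighbours
  out3 <- impute_knn(tab, k = 50, min_shared = 3)
  expect_equal(out3$intensities[3, 1], mean(c(7, 700)))
})

test_that("glog transform and centring behave at the closed-form points", {
  expect_equal(glog(0, 1), 0)
  x <- c(1, 10, 100)
  expect_equal(glog(x, 0), log(2 * x))
  expect_error(glog(1, -1), "lambda")
  tab <- std_table(with_artifacts = FALSE)
  out <- glog_mean_centre(tab, lambda = 1)
  cm <- colMeans(out$intensities, na.rm = TRUE)
  expect_lt(max(abs(cm)), 1e-10)
})

test_that("PCA outlier removal follows the Hotelling ellipse", {
  set.seed(20)
  n <- 100
  m <- matrix(exp(stats::rnorm(n * 20, 10, 0.3)), n, 20)
  tabg <- mini_table(m, rep("study", n))
  tabg <- glog_mean_centre(tabg, lambda = 1)
  out <- pca_outlier_removal(tabg, 0.95)
  removed <- n - nrow(out$samples)
  # homogeneous cloud: ~5 of 100 outside the 95% ellipse
  expect_lte(abs(removed - 5), 5)
  # conf = 1: removes none
  expect_equal(nrow(pca_outlier_removal(tabg, 1)$samples), n)
  # a sample displaced by 10 SDs is removed
  m2 <- m
  m2[1, ] <- m2[1, ] * exp(3)   # ~10 x sdlog displacement
  tab2 <- glog_mean_centre(mini_table(m2, rep("study", n)), lambda = 1)
  out2 <- pca_outlier_removal(tab2, 0.95)
  expect_false("s01" %in% out2$samples$sample_id)
  # tiny tables are left alone
  expect_warning(pca_outlier_removal(
    glog_mean_centre(mini_table(m[1:3, ], rep("study", 3)), lambda = 1),
    0.95), "fewer than 4")
})

test_that("BMC group preparation applies the 4-to-5 presence rule", {
  d <- std_design()
  tr <- make_truths(d, 2, 20, 0, seed = 9)
  tab <- simulate_intensities(d, tr, seed = 9)
  # feature present in only 3 samples of the top concentration group: drop
  man <- tab$samples
  top_rows <- which(man$class == "study" & man$conc == 50)
  m <- tab$intensities
  m[top_rows[4:9], 1] <- NA
  tab2 <- feature_table(m, man, tab$features)
  prep <- prepare_bmc_groups(tab2, "chemA", 24)
  expect_false("f01" %in% prep$table$features$feature_id ||
                 tab$features$feature_id[1] %in%
                   prep$table$features$feature_id)
  expect_equal(prep$rule, 4)
  expect_lte(prep$max_missing_pct, 50)
  # a group with fewer than 4 samples in total is an error
  few <- ft_subset(tab, samples = which(!(man$conc %in% 50) |
                                          man$tech_rep == 1 |
                                          man$class != "study"))
  few2 <- ft_subset(few, samples = which(few$samples$class %in%
                                           c("study", "control")))
  expect_error(prepare_bmc_groups(few2, "chemA", 24), "fewer than 4")
})

test_that("the missingness rule tightens from 4 to 5 when needed", {
  # 8 samples per group, feature detected in exactly 4 of each group but
  # with >50% total missingness triggers the n=5 rule
  conc <- c(10, 4, 0)
  n_per <- 8
  cls <- rep(c("study", "study", "control"), each = n_per)
  cc <- rep(conc, each = n_per)
  p <- 10
  m <- matrix(1000, 3 * n_per, p)
  # feature 1: present in exactly 4 samples of each group (50% missing)
  m[, 1] <- NA
  for (g in conc) m[which(cc == g)[1:4], 1] <- 1000
  # several more such features to push the table's max missingness over 50%
  for (j in 2:6) { m[, j] <- NA; for (g in conc) m[which(cc == g)[1:4], j] <- 1000 }
  # and one sample missing almost everything except those
  tab <- mini_table(m, cls, conc = cc)
  prep <- prepare_bmc_groups(tab, "chemA", 24)
  expect_equal(prep$rule, 5)
  # under the n=5 rule the 4-of-each-group features are gone
  expect_false(any(sprintf("f%02d", 1:6) %in%
                     prep$table$features$feature_id))
})

test_that("removal filters are idempotent", {
  tab <- std_table()
  corr <- correct_mass_drift(tab)
  filters <- list(
    function(x) remove_is_outliers(x),
    function(x) blank_filter(x, 20),
    function(x) presence_filter(x, 0.5),
    function(x) sparse_sample_filter(x, 0.4),
    function(x) qc_presence_filter(x, 0.7),
    function(x) qc_rsd_filter(x, 30))
  for (f in filters) {
    once <- f(corr)
    twice <- f(once)
    expect_identical(twice$intensities, once$intensities)
    expect_identical(twice$samples$sample_id, once$samples$sample_id)
  }
})

test_that("the full cascade reconciles its filter log and removes plants", {
  tab <- std_table()
  res <- run_cascade(tab)
  log <- res$log
  # counts never increase and consecutive steps reconcile exactly
  expect_true(all(log$samples_after <= log$samples_before))
  expect_true(all(log$features_after <= log$features_before))
  brk <- which(log$step == "mass_drift_correction")[-1]  # re-pass boundary
  for (i in seq_len(nrow(log) - 1)) {
    if ((i + 1) %in% brk) next
    expect_equal(log$samples_before[i + 1], log$samples_after[i])
    expect_equal(log$features_before[i + 1], log$features_after[i])
  }
  # planted blank-only contaminants are gone
  truth <- attr(tab, "truth")
  blank_ids <- sprintf("mz_%.5f", truth$feature_mz[truth$category ==
                                                     "blank_only"])
  expect_false(any(blank_ids %in% res$table$features$feature_id))
  # QC precision of the processed table sits inside the quality envelope
  expect_lt(qc_mrsd(res$table), 30)
  # residual IS mass error is small on the corrected table
  expect_lt(sqrt(mean(res$is_residual_ppm^2)), 0.5)
})

test_that("a clean table passes the cascade nearly untouched", {
  d <- std_design()
  tr <- make_truths(d, 3, 30, 2, seed = 17)
  tab <- simulate_intensities(d, tr, noise = list(sdlog = 0.05), seed = 17)
  tab <- apply_artifacts(tab, seed = 17)  # IS only, no artifacts
  res <- run_cascade(tab, cascade_config(rerun_on_outliers = FALSE))
  truth <- attr(tab, "truth")
  wanted <- sprintf("mz_%.5f", truth$feature_mz[truth$category != "blank_only"])
  kept <- res$table$features$feature_id
  expect_true(all(setdiff(wanted, kept) %in% character(0)) ||
                length(setdiff(wanted, kept)) <= 2)
  blank_ids <- sprintf("mz_%.5f", truth$feature_mz[truth$category ==
                                                     "blank_only"])
  expect_false(any(blank_ids %in% kept))
})
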