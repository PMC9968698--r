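# Synthetic DIMS study generator. Emulates the design of a high-throughput
# in vitro toxicometabolomics screen: a geometric dilution series plus
# vehicle control, technical x biological replication, pooled-cell QCs,
# extraction blanks, a spiked internal standard, planted sigmoidal
# concentration-response features, intensity-dependent (MNAR) dropout, and
# batch/signal/mass-accuracy drift over the acquisition sequence. Ground
# truth is recorded so downstream stages can be tested for recovery.

#' Build a dilution-series study design
#'
#' Constructs the concentration series `top_conc / dilution_factor^(0:(n_levels-1))`
#' plus a vehicle control at dose 0, and expands the replicate structure into
#' a per-sample manifest (treated, control, QC and blank samples with batch
#' and acquisition order).
#'
#' @param top_conc Highest concentration (uM), > 0.
#' @param dilution_factor Serial dilution factor, > 1.
#' @param n_levels Number of positive concentration levels, >= 1.
#' @param chemical Chemical label carried into the manifest.
#' @param n_tech_treated,n_bio Technical and biological replicates per
#'   treated concentration group (defaults 3 x 3 = 9 samples per group).
#' @param n_tech_control Technical replicates per biological replicate for
#'   vehicle controls (default 9, giving 27 controls per time point).
#' @param time_points Sampling time points in hours.
#' @param n_qc,n_blank Pooled QC and extraction-blank samples per time point.
#' @param n_batches Number of analytical batches the acquisition sequence is
#'   split into (contiguous blocks).
#' @return Object of class `study_design`: the series, replicate counts and
#'   the sample `manifest` data frame.
#' @export
build_design <- function(top_conc, dilution_factor = 2.5, n_levels = 7,
                         chemical = "chemical",
                         n_tech_treated = 3, n_bio = 3, n_tech_control = 9,
                         time_points = 24, n_qc = 8, n_blank = 4,
                         n_batches = 1) {
  for (v in list(top_conc, dilution_factor, n_levels))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("top_conc, dilution_factor and n_levels must be finite and positive")
  if (dilution_factor <= 1) stop("dilution_factor must exceed 1")
  if (n_levels < 1) stop("n_levels must be >= 1")
  conc <- top_conc / dilution_factor^(0:(n_levels - 1L))

  manifest <- list()
  for (tp in time_points) {
    rows <- list()
    for (ci in seq_along(conc)) for (b in seq_len(n_bio))
      for (te in seq_len(n_tech_treated))
        rows[[length(rows) + 1L]] <- data.frame(
          chemical = chemical, conc = conc[ci], time = tp, bio_rep = b,
          tech_rep = te, class = "study", stringsAsFactors = FALSE)
    for (b in seq_len(n_bio)) for (te in seq_len(n_tech_control))
      rows[[length(rows) + 1L]] <- data.frame(
        chemical = chemical, conc = 0, time = tp, bio_rep = b,
        tech_rep = te, class = "control", stringsAsFactors = FALSE)
    study <- do.call(rbind, rows)
    qc <- blank <- NULL
    if (n_qc > 0)
      qc <- data.frame(chemical = NA, conc = NA, time = tp, bio_rep = NA,
                       tech_rep = seq_len(n_qc), class = "QC",
                       stringsAsFactors = FALSE)
    if (n_blank > 0)
      blank <- data.frame(chemical = NA, conc = NA, time = tp, bio_rep = NA,
                          tech_rep = seq_len(n_blank), class = "blank",
                          stringsAsFactors = FALSE)
    # deterministic run order: leading/trailing blanks, QCs spread evenly
    # through the study block
    ns <- nrow(study)
    seqs <- study
    block <- seqs
    if (!is.null(qc)) {
      pos <- round(seq(1, ns, length.out = n_qc))
      out <- vector("list", ns + n_qc); si <- 1L; qi <- 1L; k <- 1L
      for (i in seq_len(ns)) {
        while (qi <= n_qc && pos[qi] == i) {
          out[[k]] <- qc[qi, , drop = FALSE]; k <- k + 1L; qi <- qi + 1L
        }
        out[[k]] <- seqs[i, , drop = FALSE]; k <- k + 1L
      }
      while (qi <= n_qc) { out[[k]] <- qc[qi, , drop = FALSE]; k <- k + 1L; qi <- qi + 1L }
      block <- do.call(rbind, out)
    }
    if (!is.null(blank)) {
      h <- ceiling(n_blank / 2)
      block <- rbind(blank[seq_len(h), , drop = FALSE], block,
                     blank[seq(h + 1, length.out = n_blank - h), , drop = FALSE])
    }
    manifest[[length(manifest) + 1L]] <- block
  }
  manifest <- do.call(rbind, manifest)
  n <- nrow(manifest)
  manifest$acq_order <- seq_len(n)
  manifest$batch <- if (n_batches <= 1) 1L else
    as.integer(cut(manifest$acq_order, breaks = n_batches, labels = FALSE))
  manifest$sample_id <- sprintf("S%03d_%s_t%g", manifest$acq_order,
                                manifest$class, manifest$time)
  rownames(manifest) <- NULL
  structure(list(chemical_label = chemical, top_conc = top_conc,
                 dilution_factor = dilution_factor, n_levels = n_levels,
                 concentrations = conc,
                 n_tech_treated = n_tech_treated, n_bio = n_bio,
                 n_tech_control = n_tech_control, time_points = time_points,
                 n_qc = n_qc, n_blank = n_blank, n_batches = n_batches,
                 manifest = manifest),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("study_design:", x$chemical_label, "\n")
  cat("  series (uM):", paste(signif(x$concentrations, 6), collapse = ", "),
      "+ control 0\n")
  cat("  samples:", nrow(x$manifest), "over", length(x$time_points),
      "time point(s),", x$n_batches, "batch(es)\n")
  invisible(x)
}

# Analytic 1 SD benchmark concentration of a planted log-scale curve:
# smallest d > 0 with |m(d) - m(0)| = sd.
.truth_bmc <- function(shape, params, sd) {
  if (shape == "hill") {
    r <- sd / abs(params$v)
    if (r >= 1) return(Inf)
    params$k * (r / (1 - r))^(1 / params$n)
  } else if (shape == "exponential") {
    r <- sd / abs(params$v)
    if (r >= 1) return(Inf)
    -params$k * log(1 - r)
  } else Inf
}

#' Generate planted feature ground truth
#'
#' Responsive features follow a Hill or saturating-exponential curve on the
#' log-intensity scale; null features are flat; blank-only features model
#' extraction contaminants. Each responsive truth records its analytic 1 SD
#' benchmark concentration given the generator's noise SD.
#'
#' @param design A [build_design()] object.
#' @param n_responsive,n_null,n_blank_only Feature counts per category.
#' @param sdlog Log-scale noise SD the true BMC is computed against
#'   (lognormal multiplicative noise; `sdlog` 0.1 is ~10% RSD).
#' @param effect_range Range of absolute log-scale asymptotic effect sizes.
#' @param shapes Shapes sampled for responsive features.
#' @param seed Integer seed; the truth set is a pure function of it.
#' @return Data frame of feature truths (one row per feature).
#' @export
make_truths <- function(design, n_responsive = 20, n_null = 80,
                        n_blank_only = 0, sdlog = 0.1,
                        effect_range = c(0.6, 1.5),
                        shapes = c("hill", "exponential"), seed = 1) {
  set.seed(seed)
  n <- n_responsive + n_null + n_blank_only
  mz <- round(sort(stats::runif(n, 80, 1200)), 5)
  if (anyDuplicated(mz)) stop("feature m/z collision in generated truths")
  span <- range(design$concentrations)
  cat_ <- rep(c("responsive", "null", "blank_only"),
              c(n_responsive, n_null, n_blank_only))
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    b0 <- stats::runif(1, log(1e5), log(1e7))
    if (cat_[i] == "responsive") {
      shape <- sample(shapes, 1)
      dirn <- sample(c(1, -1), 1)
      v <- dirn * stats::runif(1, effect_range[1], effect_range[2])
      k <- 10^stats::runif(1, log10(span[1]), log10(span[2] / 2))
      nn <- sample(1:3, 1)
      params <- list(b0 = b0, v = v, k = k,
                     n = if (shape == "hill") nn else NA_real_)
      bmc <- .truth_bmc(shape, params, sdlog)
      truths[[i]] <- data.frame(
        feature_mz = mz[i], category = "responsive", model_shape = shape,
        b0 = b0, v = v, k = k, hill_n = params$n,
        direction = if (dirn > 0) "increase" else "decrease",
        true_bmc_1sd = bmc, stringsAsFactors = FALSE)
    } else {
      truths[[i]] <- data.frame(
        feature_mz = mz[i], category = cat_[i], model_shape = "none",
        b0 = b0, v = 0, k = NA_real_, hill_n = NA_real_,
        direction = NA_character_, true_bmc_1sd = Inf,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, truths)
}

# log-scale mean curve of a truth row at dose d
.truth_mean <- function(tr, d) {
  if (tr$model_shape == "hill") {
    tr$b0 + tr$v * ifelse(d > 0, d^tr$hill_n / (tr$k^tr$hill_n + d^tr$hill_n), 0)
  } else if (tr$model_shape == "exponential") {
    tr$b0 + tr$v * (1 - exp(-d / tr$k))
  } else rep(tr$b0, length(d))
}

#' Simulate a feature table from a design and truth set
#'
#' Study and control samples draw lognormal intensities around each truth's
#' concentration-response curve; QCs draw around the pooled study mean;
#' blanks contain only the designated contaminant (blank-only) features,
#' which also appear at low level in study samples. Identical seeds give
#' bit-identical tables.
#'
#' @param design A [build_design()] object.
#' @param truths Truth data frame from [make_truths()].
#' @param noise List: `sdlog` (log-scale noise SD for study samples),
#'   `qc_sdlog` (QCs; defaults to `sdlog`), `blank_level` (log intensity of
#'   contaminants in blanks), `blank_study_ratio` (contaminant study/blank
#'   intensity ratio, < 1 so the blank filter removes them).
#' @param seed Integer seed.
#' @return A [feature_table()] with the truth attached as attribute `truth`.
#' @export
simulate_intensities <- function(design, truths,
                                 noise = list(sdlog = 0.1), seed = 1) {
  if (is.null(noise$sdlog)) noise$sdlog <- 0.1
  if (is.null(noise$qc_sdlog)) noise$qc_sdlog <- noise$sdlog
  if (is.null(noise$blank_level)) noise$blank_level <- log(5e4)
  if (is.null(noise$blank_study_ratio)) noise$blank_study_ratio <- 0.5
  if (anyDuplicated(truths$feature_mz))
    stop("feature m/z collision in truths")
  set.seed(seed)
  man <- design$manifest
  ns <- nrow(man); nf <- nrow(truths)
  m <- matrix(NA_real_, ns, nf)
  study_idx <- which(man$class %in% c("study", "control"))
  for (j in seq_len(nf)) {
    tr <- truths[j, ]
    if (tr$category == "blank_only") {
      mu <- rep(NA_real_, ns)
      mu[man$class == "blank"] <- noise$blank_level
      mu[study_idx] <- noise$blank_level + log(noise$blank_study_ratio)
      mu[man$class == "QC"] <- noise$blank_level + log(noise$blank_study_ratio)
    } else {
      mu <- rep(NA_real_, ns)
      mu[study_idx] <- .truth_mean(tr, man$conc[study_idx])
      # pooled QC: log of the mean intensity across study samples
      pooled <- log(mean(exp(mu[study_idx])))
      mu[man$class == "QC"] <- pooled
      # ordinary features absent from extraction blanks
    }
    sd_s <- ifelse(man$class == "QC", noise$qc_sdlog, noise$sdlog)
    val <- exp(mu + if (all(sd_s == 0)) 0 else stats::rnorm(ns, 0, sd_s))
    m[, j] <- val
  }
  features <- data.frame(feature_id = ft_feature_id(truths$feature_mz),
                         mz = truths$feature_mz, stringsAsFactors = FALSE)
  tab <- feature_table(m, man, features)
  attr(tab, "truth") <- truths
  tab
}

#' Theoretical internal-standard m/z
#'
#' The default internal standard is tryptophan-d5 observed as its protonated
#' ion; the m/z is derived from the formula via the annotation module, never
#' hard-coded.
#'
#' @param formula Molecular formula of the internal standard.
#' @param adduct Observed adduct.
#' @return m/z in Th.
#' @export
is_theoretical_mz <- function(formula = "C11H7D5N2O2", adduct = "[M+H]+") {
  adduct_mz(monoisotopic_mass(parse_formula(formula)), adduct)
}

#' Overlay acquisition artifacts on a simulated table
#'
#' Adds the spiked internal-standard feature, perturbs per-sample observed
#' m/z by a ppm mass-error curve over acquisition order, multiplies
#' intensities by a per-batch signal-drift curve, and censors values below an
#' intensity threshold (missing-not-at-random dropout, the DIMS detection
#' mechanism). With all artifact magnitudes zero the table is returned
#' unchanged apart from the added internal standard.
#'
#' @param table A [feature_table()] from [simulate_intensities()].
#' @param drift List: `ppm_start`,`ppm_end` (linear mass-error curve in ppm
#'   over the acquisition sequence) or `ppm_fun(order_frac)`; `fold_end`
#'   (multiplicative intensity drift reached at the end of each batch,
#'   linear within batch; 1 = none).
#' @param missing List: `threshold` (intensities below it become `NA`),
#'   `mcar_frac` (additional completely-at-random dropout fraction).
#' @param is_spec List: `formula`, `adduct`, `level` (log intensity),
#'   `sdlog`. Set `is_spec = NULL` to skip the internal standard.
#' @param seed Integer seed (used for IS noise and MCAR dropout).
#' @return The perturbed [feature_table()] (truth attribute preserved).
#' @export
apply_artifacts <- function(table,
                            drift = list(ppm_start = 0, ppm_end = 0, fold_end = 1),
                            missing = list(threshold = 0, mcar_frac = 0),
                            is_spec = list(formula = "C11H7D5N2O2",
                                           adduct = "[M+H]+",
                                           level = log(2e6), sdlog = 0.05),
                            seed = 1) {
  set.seed(seed)
  if (is.null(drift$ppm_start)) drift$ppm_start <- 0
  if (is.null(drift$ppm_end)) drift$ppm_end <- 0
  if (is.null(drift$fold_end)) drift$fold_end <- 1
  if (is.null(missing$threshold)) missing$threshold <- 0
  if (is.null(missing$mcar_frac)) missing$mcar_frac <- 0
  truth <- attr(table, "truth")
  man <- table$samples
  m <- table$intensities
  mzobs <- table$mz_observed
  features <- table$features

  if (!is.null(is_spec)) {
    is_mz <- is_theoretical_mz(is_spec$formula, is_spec$adduct)
    lv <- if (is.null(is_spec$level)) log(2e6) else is_spec$level
    sdl <- if (is.null(is_spec$sdlog)) 0.05 else is_spec$sdlog
    # the IS is carried by the extraction solvent, so blanks contain it too
    is_int <- exp(lv + stats::rnorm(nrow(m), 0, sdl))
    m <- cbind(m, is_int)
    features <- rbind(features,
                      data.frame(feature_id = ft_feature_id(is_mz), mz = is_mz,
                                 stringsAsFactors = FALSE))
    mzobs <- cbind(mzobs, rep(is_mz, nrow(m)))
  }

  # mass-accuracy drift over the whole acquisition sequence
  frac <- (man$acq_order - 1) / max(1, (nrow(man) - 1))
  ppm <- if (!is.null(drift$ppm_fun)) drift$ppm_fun(frac) else
    drift$ppm_start + (drift$ppm_end - drift$ppm_start) * frac
  mzobs <- mzobs * (1 + ppm * 1e-6)

  # within-batch linear signal drift
  if (drift$fold_end != 1) {
    fac <- rep(1, nrow(man))
    for (b in unique(man$batch)) {
      i <- which(man$batch == b)
      bf <- (rank(man$acq_order[i]) - 1) / max(1, length(i) - 1)
      fac[i] <- 1 + (drift$fold_end - 1) * bf
    }
    m <- m * fac
  }

  if (missing$threshold > 0) m[!is.na(m) & m < missing$threshold] <- NA
  if (missing$mcar_frac > 0) {
    drop <- stats::runif(length(m)) < missing$mcar_frac
    m[drop & !is.na(m)] <- NA
  }
  # blanks are structurally near-empty (only contaminants), so the
  # usability guard applies to the biological and QC classes
  for (cl in setdiff(unique(man$class), "blank")) {
    fr <- mean(is.na(m[man$class == cl, , drop = FALSE]))
    if (fr > 0.9)
      stop("missing fraction ", round(100 * fr), "% in class '", cl,
           "': unusable fixture")
  }
  out <- feature_table(m, man, features, mzobs)
  attr(out, "truth") <- truth
  out
}
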