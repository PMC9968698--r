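# The feature_table container: a samples x features intensity matrix with
# per-sample metadata, per-feature m/z, and per-sample observed m/z (DIMS
# instruments drift in mass accuracy over the acquisition sequence, so the
# observed m/z of a feature is a property of the sample, not only of the
# feature). Missing values are NA, distinct from zero.

#' Construct a feature table
#'
#' @param intensities Numeric matrix, samples in rows, features in columns.
#'   `NA` marks a missing (undetected) value.
#' @param samples Data frame of per-sample metadata. Required columns:
#'   `sample_id`, `class` (one of `study`, `control`, `QC`, `blank`),
#'   `batch`, `acq_order`. Study/control rows additionally carry `chemical`,
#'   `conc` (uM), `time` (h), `tech_rep`, `bio_rep`.
#' @param features Data frame of per-feature metadata with columns
#'   `feature_id` and `mz` (Th).
#' @param mz_observed Optional samples x features matrix of per-sample
#'   observed m/z; defaults to the nominal feature m/z replicated per sample.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(intensities, samples, features, mz_observed = NULL) {
  intensities <- as.matrix(intensities)
  stopifnot(is.data.frame(samples), is.data.frame(features))
  if (nrow(intensities) != nrow(samples))
    stop("intensities rows must match samples")
  if (ncol(intensities) != nrow(features))
    stop("intensities columns must match features")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (anyDuplicated(features$feature_id)) stop("duplicate feature ids")
  for (b in unique(samples$batch)) {
    ao <- samples$acq_order[samples$batch == b]
    if (anyDuplicated(ao)) stop("duplicate acquisition order within batch ", b)
  }
  rownames(intensities) <- samples$sample_id
  colnames(intensities) <- features$feature_id
  if (is.null(mz_observed)) {
    mz_observed <- matrix(rep(features$mz, each = nrow(samples)),
                          nrow = nrow(samples))
  }
  mz_observed <- as.matrix(mz_observed)
  dimnames(mz_observed) <- dimnames(intensities)
  structure(list(intensities = intensities, samples = samples,
                 features = features, mz_observed = mz_observed),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cls <- table(x$samples$class)
  cat("feature_table: ", nrow(x$intensities), " samples x ",
      ncol(x$intensities), " features\n", sep = "")
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  cat("  missing: ",
      round(100 * mean(is.na(x$intensities)), 1), "%\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Subset a feature table by sample or feature
#'
#' @param table A [feature_table()].
#' @param samples Logical/integer/character index over samples (optional).
#' @param features Logical/integer/character index over features (optional).
#' @return The subsetted `feature_table`.
#' @export
ft_subset <- function(table, samples = NULL, features = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(table$intensities)) else samples
  if (is.character(si)) si <- match(si, table$samples$sample_id)
  fi <- if (is.null(features)) seq_len(ncol(table$intensities)) else features
  if (is.character(fi)) fi <- match(fi, table$features$feature_id)
  out <- feature_table(table$intensities[si, fi, drop = FALSE],
                       table$samples[si, , drop = FALSE],
                       table$features[fi, , drop = FALSE],
                       table$mz_observed[si, fi, drop = FALSE])
  attr(out, "truth") <- attr(table, "truth")
  out
}

.ft_class_idx <- function(table, classes) which(table$samples$class %in% classes)

# Feature ids are formatted from m/z at 5 decimal places, matching the
# precision DIMS features are commonly reported at.
ft_feature_id <- function(mz) sprintf("mz_%.5f", mz)

#' Write a feature table as delimited text
#'
#' Produces `<prefix>_intensities.tsv` (samples x features, feature ids
#' `mz_<value to 5 dp>` as the header), `<prefix>_samples.tsv` (sample
#' metadata) and, when per-sample observed m/z differ from nominal,
#' `<prefix>_mz.tsv`.
#'
#' @param table A [feature_table()].
#' @param prefix Path prefix for the output files.
#' @return Invisibly, the paths written.
#' @export
write_feature_table <- function(table, prefix) {
  pi <- paste0(prefix, "_intensities.tsv")
  ps <- paste0(prefix, "_samples.tsv")
  ints <- as.data.frame(table$intensities, check.names = FALSE)
  ints <- cbind(sample_id = table$samples$sample_id, ints)
  utils::write.table(ints, pi, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$samples, ps, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(pi, ps)
  nominal <- matrix(rep(table$features$mz, each = nrow(table$intensities)),
                    nrow = nrow(table$intensities))
  if (any(abs(table$mz_observed - nominal) > 0, na.rm = TRUE)) {
    pm <- paste0(prefix, "_mz.tsv")
    mzd <- as.data.frame(table$mz_observed, check.names = FALSE)
    mzd <- cbind(sample_id = table$samples$sample_id, mzd)
    utils::write.table(mzd, pm, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, pm)
  }
  invisible(paths)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param prefix Path prefix used at write time.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(prefix) {
  pi <- paste0(prefix, "_intensities.tsv")
  ps <- paste0(prefix, "_samples.tsv")
  if (!file.exists(pi)) stop("intensity sheet not found: ", pi)
  if (!file.exists(ps)) stop("sample metadata sheet not found: ", ps)
  ints <- utils::read.table(pi, header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
  samples <- utils::read.table(ps, header = TRUE, sep = "\t",
                               check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(ints$sample_id)) stop("duplicate sample ids in ", pi)
  ids <- setdiff(names(ints), "sample_id")
  mz <- suppressWarnings(as.numeric(sub("^mz_", "", ids)))
  if (anyNA(mz) || !all(grepl("^mz_", ids)))
    stop("unparseable feature headers (expected mz_<float>): ",
         paste(utils::head(ids[!grepl("^mz_", ids) | is.na(mz)], 3),
               collapse = ", "))
  m <- as.matrix(ints[ids])
  features <- data.frame(feature_id = ids, mz = mz, stringsAsFactors = FALSE)
  pm <- paste0(prefix, "_mz.tsv")
  mzobs <- NULL
  if (file.exists(pm)) {
    mzd <- utils::read.table(pm, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    mzobs <- as.matrix(mzd[ids])
  }
  feature_table(m, samples, features, mzobs)
}
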