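# Point-of-departure derivation from screened BMC records: canonical
# ranking, the three POD methods (1st ranked feature, 1st annotated feature,
# n-th ranked feature), accumulation curves, the extrapolation floor and
# time-course fold changes.

#' Rank screened BMC records
#'
#' Ascending by the analysis-pass (1 SD) BMC; ties broken by ascending m/z
#' then feature id so the ranking is deterministic. Only records that passed
#' the dual-BMR criteria are ranked.
#'
#' @param records Data frame from [screen_features()].
#' @param bmc_col Column holding the BMC used for ranking
#'   (default `"bmc_1sd"`).
#' @return The passing records, ranked, with a `rank` column.
#' @export
rank_records <- function(records, bmc_col = "bmc_1sd") {
  if (is.null(records) || !nrow(records)) {
    out <- data.frame(feature_id = character(0), mz = numeric(0),
                      passed_dual = logical(0), rank = integer(0))
    out[[bmc_col]] <- numeric(0)
    return(out)
  }
  r <- records[records$passed_dual, , drop = FALSE]
  r <- r[order(r[[bmc_col]], r$mz, r$feature_id), , drop = FALSE]
  r$rank <- seq_len(nrow(r))
  rownames(r) <- NULL
  r
}

#' Derive a POD from ranked records
#'
#' Method `first_unannotated` takes the first-ranked feature (the lowest BMC,
#' whether or not it happens to carry an annotation); `first_annotated` the
#' first-ranked feature with at least one putative annotation;
#' `nth_feature` the n-th ranked feature (default n = 25, carried over from
#' transcriptomics practice). When the request cannot be satisfied (no
#' annotated feature, fewer than n features) the result carries an explicit
#' `undefined` status rather than an error.
#'
#' @param ranked Output of [rank_records()].
#' @param method One of `first_unannotated`, `first_annotated`,
#'   `nth_feature`.
#' @param annotations Annotation data frame from [match_library()] (needed
#'   for `first_annotated`; matched on `feature_id`).
#' @param n Rank for `nth_feature`.
#' @param floor Extrapolation floor in uM (optional; sets the
#'   `below_extrapolation_floor` flag).
#' @param bmc_col Column holding the BMC (default `"bmc_1sd"`).
#' @return One-row data frame: method, status (`ok`/`undefined`), pod (uM),
#'   feature id, m/z, annotation (first match, or NA), flag.
#' @export
derive_pod <- function(ranked, method = c("first_unannotated",
                                          "first_annotated", "nth_feature"),
                       annotations = NULL, n = 25, floor = NA_real_,
                       bmc_col = "bmc_1sd") {
  method <- match.arg(method)
  undefined <- data.frame(method = method, status = "undefined",
                          pod = NA_real_, feature_id = NA_character_,
                          mz = NA_real_, annotation = NA_character_,
                          below_extrapolation_floor = NA,
                          stringsAsFactors = FALSE)
  if (is.null(ranked) || !nrow(ranked)) return(undefined)
  annotated_ids <- unique(annotations$feature_id)
  ann_for <- function(id) {
    if (is.null(annotations)) return(NA_character_)
    hits <- annotations$name[annotations$feature_id == id]
    if (!length(hits)) NA_character_ else paste(unique(hits), collapse = "; ")
  }
  rec <- switch(method,
    first_unannotated = ranked[1, ],
    first_annotated = {
      if (is.null(annotations)) return(undefined)
      i <- which(ranked$feature_id %in% annotated_ids)
      if (!length(i)) return(undefined)
      ranked[i[1], ]
    },
    nth_feature = {
      if (nrow(ranked) < n) return(undefined)
      ranked[n, ]
    })
  pod <- rec[[bmc_col]]
  data.frame(method = method, status = "ok", pod = pod,
             feature_id = rec$feature_id, mz = rec$mz,
             annotation = ann_for(rec$feature_id),
             below_extrapolation_floor =
               if (is.na(floor)) NA else pod < floor,
             stringsAsFactors = FALSE)
}

#' Accumulation curve of concentration-responsive features
#'
#' Sorted BMC values paired with the cumulative feature count (ranks 1..N):
#' the sensitivity distribution of the screen.
#'
#' @inheritParams rank_records
#' @return Data frame with columns `bmc` and `count`.
#' @export
accumulation_curve <- function(records, bmc_col = "bmc_1sd") {
  ranked <- rank_records(records, bmc_col)
  if (!nrow(ranked))
    return(data.frame(bmc = numeric(0), count = integer(0)))
  data.frame(bmc = ranked[[bmc_col]], count = ranked$rank)
}

#' Extrapolation floor of a study design
#'
#' One third of the lowest tested (nonzero) concentration: BMC estimates
#' below it are extrapolations beyond the tested range and are flagged, not
#' censored.
#'
#' @param design A [build_design()] object, or a numeric vector of
#'   concentrations.
#' @return Floor in uM.
#' @export
extrapolation_floor <- function(design) {
  conc <- if (inherits(design, "study_design")) design$concentrations
          else as.numeric(design)
  conc <- conc[conc > 0]
  if (!length(conc)) stop("no positive concentrations in design")
  min(conc) / 3
}

#' POD time-course summary
#'
#' Per assay, the POD-versus-time series and the fold change between the
#' earliest and latest sampling points with a defined POD
#' (`fold = POD(earliest) / POD(latest)`). Time points with an undefined POD
#' are reported as gaps.
#'
#' @param pods Data frame with columns `assay`, `time`, `pod` (NA = gap).
#' @return List: `series` (the input, ordered), `fold` (per-assay fold
#'   changes; NA when either endpoint is undefined).
#' @export
time_course <- function(pods) {
  stopifnot(all(c("assay", "time", "pod") %in% names(pods)))
  pods <- pods[order(pods$assay, pods$time), , drop = FALSE]
  folds <- lapply(split(pods, pods$assay), function(g) {
    def <- g[!is.na(g$pod), , drop = FALSE]
    fold <- if (nrow(def) >= 2 &&
                min(g$time) %in% def$time && max(g$time) %in% def$time) {
      def$pod[def$time == min(g$time)][1] / def$pod[def$time == max(g$time)][1]
    } else NA_real_
    data.frame(assay = g$assay[1], earliest = min(g$time),
               latest = max(g$time), fold = fold, n_gaps = sum(is.na(g$pod)),
               stringsAsFactors = FALSE)
  })
  fold <- do.call(rbind, folds)
  rownames(fold) <- NULL
  list(series = pods, fold = fold)
}

#' Plot an accumulation curve
#'
#' Cumulative count of concentration-responsive features against their BMC,
#' with the extrapolation floor as a dashed red line.
#'
#' @param curve Data frame from [accumulation_curve()] (optionally with a
#'   `group` column for facetting by time point or assay).
#' @param floor Extrapolation floor (uM) to draw; NA omits the line.
#' @return A ggplot object.
#' @export
plot_accumulation <- function(curve, floor = NA_real_) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$bmc, y = .data$count)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "BMC (µM)", y = "Cumulative feature count") +
    ggplot2::theme_bw()
  if (!is.na(floor))
    p <- p + ggplot2::geom_vline(xintercept = floor, linetype = "dashed",
                                 colour = "red")
  if ("group" %in% names(curve))
    p <- p + ggplot2::facet_wrap(~group)
  p
}

#' Plot POD versus sampling time
#'
#' @param pods Data frame with `assay`, `time`, `pod`.
#' @param floor Extrapolation floor (uM); NA omits the line.
#' @return A ggplot object.
#' @export
plot_pod_time <- function(pods, floor = NA_real_) {
  p <- ggplot2::ggplot(pods[!is.na(pods$pod), ],
                       ggplot2::aes(x = .data$time, y = .data$pod,
                                    colour = .data$assay)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Exposure time (h)", y = "POD (µM)") +
    ggplot2::theme_bw()
  if (!is.na(floor))
    p <- p + ggplot2::geom_hline(yintercept = floor, linetype = "dashed",
                                 colour = "red")
  p
}
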