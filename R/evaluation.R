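#' Average precision of a segment ranking
#'
#' Segments are labelled positive when they overlap any true
#' functional-sequence interval by at least one base; the precision-recall
#' curve of the score-ranked segments is then summarised by average
#' precision with step-wise interpolation, `AP = sum (R_t - R_{t-1}) P_t`
#' over descending score thresholds. Tied scores enter as one group.
#'
#' @param segments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `score`, one row per scored genome segment.
#' @param truth true functional-sequence intervals in any form accepted by
#'   [parse_regions()] (e.g. `truth$fs` from [simulate_screen()]).
#' @return Average precision in \[0, 1\].
#' @export
average_precision <- function(segments, truth) {
  if (any(!is.finite(segments$score)))
    stop_tilefs("scores must be finite", class = "tilefs_domain_error")
  seg_gr <- GRanges(segments$chrom,
                    IRanges(start = segments$start + 1L,
                            end = segments$end))
  positive <- overlapsAny(seg_gr, parse_regions(truth))
  if (all(positive) || !any(positive))
    stop_tilefs("average precision is undefined without both positive and ",
                "negative segments", class = "tilefs_domain_error")
  ap_from_ranking(segments$score, positive)
}

# AP over descending unique score thresholds, ties grouped.
ap_from_ranking <- function(score, positive) {
  thr <- sort(unique(score), decreasing = TRUE)
  grp <- match(score, thr)
  tp_by_grp <- tabulate(grp[positive], nbins = length(thr))
  n_by_grp <- tabulate(grp, nbins = length(thr))
  tp <- cumsum(tp_by_grp)
  n_called <- cumsum(n_by_grp)
  precision <- tp / n_called
  recall <- tp / sum(positive)
  sum(diff(c(0, recall)) * precision)
}

#' Precision and recall of significant regions
#'
#' Precision is the fraction of significant regions overlapping at least
#' one true functional sequence; recall is the number of distinct true
#' functional sequences overlapped by at least one significant region.
#' Overlap means sharing at least one base pair.
#'
#' @param significant significant genomic intervals ([parse_regions()]
#'   forms; may be empty).
#' @param truth true functional-sequence intervals.
#' @return List with `precision` (NA when no region is significant) and
#'   `recall_count`.
#' @export
precision_recall <- function(significant, truth) {
  truth_gr <- parse_regions(truth)
  sig_gr <- if (is.data.frame(significant) && nrow(significant) == 0)
    GRanges() else parse_regions(significant)
  if (length(sig_gr) == 0)
    return(list(precision = NA_real_, recall_count = 0L))
  list(precision = mean(overlapsAny(sig_gr, truth_gr)),
       recall_count = sum(overlapsAny(truth_gr, sig_gr)))
}

#' Base-pair accuracy of significant regions
#'
#' The fraction of all significant base pairs that lie within true
#' functional sequences; overlapping significant regions are unioned
#' before counting, so the metric is invariant to how a called region is
#' split into adjacent pieces.
#'
#' @inheritParams precision_recall
#' @return Fraction in \[0, 1\], or NA when nothing is significant.
#' @export
bp_accuracy <- function(significant, truth) {
  sig_gr <- if (is.data.frame(significant) && nrow(significant) == 0)
    GRanges() else parse_regions(significant)
  if (length(sig_gr) == 0) return(NA_real_)
  sig_gr <- reduce(sig_gr)
  hit <- intersect(sig_gr, reduce(parse_regions(truth)))
  sum(width(hit)) / sum(width(sig_gr))
}

#' Score a fitted screen against simulated truth
#'
#' Convenience wrapper computing all evaluation metrics for a fit on
#' simulated data: average precision of the combined per-segment
#' functional probability, precision and recall of the credible regions,
#' and their base-pair accuracy.
#'
#' @param fit an [ibss_fit] (or the `fit` element of [select_k()] output).
#' @param truth a `sim_truth` from [simulate_screen()].
#' @param coverage credible-region coverage (default 0.95).
#' @return One-row data.frame with `average_precision`, `precision`,
#'   `recall_count`, `bp_accuracy`, `n_fs_true`.
#' @export
evaluate_fit <- function(fit, truth, coverage = 0.95) {
  stopifnot(inherits(fit, "ibss_fit"), inherits(truth, "sim_truth"))
  segs <- fit$segmap$segments
  segs$score <- pmin(1, pmax(0, colSums(fit$pi)))
  regions <- credible_regions(fit, coverage)
  pr <- precision_recall(regions, truth$fs)
  data.frame(average_precision = average_precision(segs, truth$fs),
             precision = pr$precision,
             recall_count = pr$recall_count,
             bp_accuracy = bp_accuracy(regions, truth$fs),
             n_fs_true = nrow(truth$fs))
}
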