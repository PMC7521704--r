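#' Write per-sequence probability tracks
#'
#' Writes one bedGraph per functional-sequence row of the probability
#' matrix (records only for segments with nonzero probability) plus a
#' combined track of the per-segment probability that any functional
#' sequence is present, `p_m = min(1, sum_k pi[k, m])`. Coordinates are
#' 0-based half-open.
#'
#' @param pi (K+1) x M probability matrix (row 1 = positive controls).
#' @param segmap the matching [build_segment_map] result.
#' @param out_dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_probability_tracks <- function(pi, segmap, out_dir) {
  pi <- rbind(pi)
  stopifnot(inherits(segmap, "segment_map"), ncol(pi) == segmap$M)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seg_gr <- segment_ranges(segmap)
  files <- character(0)
  write_track <- function(score, name, file) {
    keep <- score > 0
    gr <- seg_gr[keep]
    mcols(gr)$score <- score[keep]
    ucsc <- methods::new("UCSCData", gr,
                         trackLine = methods::new("GraphTrackLine",
                                                  name = name,
                                                  type = "bedGraph"))
    rtracklayer::export.ucsc(ucsc, file, subformat = "bedGraph")
    file
  }
  for (k in seq_len(nrow(pi))) {
    name <- paste0("FS", k - 1L)
    files <- c(files, write_track(pi[k, ], name,
                                  file.path(out_dir,
                                            paste0(name, ".bedGraph"))))
  }
  files <- c(files, write_track(pmin(1, pmax(0, colSums(pi))), "p_combined",
                                file.path(out_dir, "p_combined.bedGraph")))
  invisible(files)
}

#' Write credible regions as BED6
#'
#' One record per credible-region interval, named `FS<k>`, scored by
#' 1000 x the cumulative posterior mass of the region, sorted by
#' coordinate.
#'
#' @param regions a [credible_regions] data.frame.
#' @param out output BED path.
#' @return `out`, invisibly.
#' @export
write_fs_regions <- function(regions, out) {
  if (nrow(regions) == 0) {
    file.create(out)
    return(invisible(out))
  }
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  gr <- GRanges(regions$chrom,
                IRanges(start = regions$start + 1L, end = regions$end))
  mcols(gr)$name <- paste0("FS", regions$fs)
  mcols(gr)$score <- round(1000 * regions$posterior)
  rtracklayer::export(gr, out, format = "BED")
  invisible(out)
}

#' Write the full probability matrix as CSV
#'
#' One row per genome segment with its coordinates and the probability it
#' is covered by each functional sequence.
#'
#' @inheritParams write_probability_tracks
#' @param out output CSV path.
#' @return `out`, invisibly.
#' @export
write_pi_csv <- function(pi, segmap, out) {
  pi <- rbind(pi)
  stopifnot(inherits(segmap, "segment_map"), ncol(pi) == segmap$M)
  df <- cbind(segmap$segments,
              as.data.frame(t(pi), check.names = FALSE),
              p_combined = pmin(1, pmax(0, colSums(pi))))
  write.csv(df, out, row.names = FALSE, quote = FALSE)
  invisible(out)
}
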