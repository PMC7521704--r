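#' Tile the screened region into genome segments
#'
#' Divides the screened span into M non-overlapping segments of uniform
#' width and records, for every sgRNA, the set g(n) of segment indices that
#' intersect the guide's area of effect (its target site extended by
#' `effect_range` on each side). Segments are anchored at the minimum
#' effect-extended coordinate per chromosome (floored at 0), so segment
#' content is invariant to translating all coordinates. Multi-chromosome
#' input is tiled per chromosome and the segments concatenated into one
#' index space; functional-sequence placements never cross a chromosome
#' boundary.
#'
#' @param data a [screen_data] object.
#' @param segment_size segment width in bp (default 100).
#' @param effect_range bp added on each side of the target site (default
#'   200, i.e. a 400 bp area of effect typical of CRISPRi/CRISPRa; use ~10
#'   for Cas9 indel screens).
#'
#' @return An object of class `"segment_map"` with elements `segments`
#'   (data.frame `chrom`,`start`,`end`, 0-based half-open), `M`, `g` (list of
#'   sorted segment-index vectors per guide), `run` (integer chromosome-run
#'   id per segment), `segment_size`, `effect_range`.
#' @export
build_segment_map <- function(data, segment_size = 100, effect_range = 200) {
  stopifnot(inherits(data, "screen_data"))
  if (segment_size < 1) stop_tilefs("segment_size must be >= 1",
                                    class = "tilefs_config_error")
  if (effect_range < 0) stop_tilefs("effect_range must be >= 0",
                                    class = "tilefs_config_error")
  g <- data$guides
  lo_all <- pmax(0L, g$start - as.integer(effect_range))
  hi_all <- g$end + as.integer(effect_range)
  chroms <- unique(g$chrom)
  seg_list <- list()
  run <- integer(0)
  for (i in seq_along(chroms)) {
    on_c <- g$chrom == chroms[i]
    lo <- min(lo_all[on_c])
    hi <- max(hi_all[on_c])
    m_c <- ceiling((hi - lo) / segment_size)
    starts <- lo + (seq_len(m_c) - 1L) * as.integer(segment_size)
    seg_list[[i]] <- data.frame(chrom = chroms[i], start = starts,
                                end = starts + as.integer(segment_size),
                                stringsAsFactors = FALSE)
    run <- c(run, rep(i, m_c))
  }
  segments <- do.call(rbind, seg_list)
  segmap <- list(segments = segments, M = nrow(segments), run = run,
                 segment_size = as.integer(segment_size),
                 effect_range = as.integer(effect_range))
  seg_gr <- GRanges(segments$chrom,
                    IRanges(start = segments$start + 1L, end = segments$end))
  eff_gr <- GRanges(g$chrom, IRanges(start = lo_all + 1L, end = hi_all))
  ov <- findOverlaps(eff_gr, seg_gr)
  gsets <- unname(split(subjectHits(ov), factor(queryHits(ov),
                                                levels = seq_len(nrow(g)))))
  segmap$g <- lapply(gsets, function(s) sort(unique(s)))
  if (any(lengths(segmap$g) == 0))
    stop_tilefs("internal error: a guide overlaps no segment",
                class = "tilefs_internal_error")
  structure(segmap, class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat("Segment map:", x$M, "segments of", x$segment_size, "bp on",
      length(unique(x$segments$chrom)), "chromosome(s)\n")
  cat("  area of effect: +/-", x$effect_range, "bp;",
      "median |g(n)| =", stats::median(lengths(x$g)), "\n")
  invisible(x)
}

#' Mark positive-control segments
#'
#' Builds the fixed row of the functional-sequence probability matrix for
#' known functional sequences (the positive controls, e.g. the target-gene
#' promoter): probability 1 for every segment overlapping a control interval
#' by at least one base, 0 elsewhere.
#'
#' @param segmap a [build_segment_map] result.
#' @param controls control regions in any form accepted by [parse_regions()].
#' @return Numeric vector of length M with entries 0 or 1.
#' @export
mark_fs0 <- function(segmap, controls) {
  stopifnot(inherits(segmap, "segment_map"))
  gr <- parse_regions(controls)
  if (length(gr) == 0)
    stop_tilefs("empty control region set", class = "tilefs_config_error")
  # control regions on a chromosome absent from the map give zero hits;
  # the disjoint-seqlevels warning is redundant with the error below
  hits <- suppressWarnings(
    unique(subjectHits(findOverlaps(gr, segment_ranges(segmap)))))
  if (length(hits) == 0)
    stop_tilefs("no control interval overlaps any genome segment; ",
                "cannot anchor the known functional sequence row",
                class = "tilefs_config_error")
  pi0 <- numeric(segmap$M)
  pi0[hits] <- 1.0
  pi0
}
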