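#' Screen count data
#'
#' Container for a pooled CRISPR screen: per-sgRNA metadata (target-site
#' coordinates and label) together with the N x J matrix of observed counts
#' across the J sequenced pools. All coordinates are 0-based half-open.
#'
#' @param guides data.frame with columns `guide_id`, `chrom`, `start`, `end`,
#'   `label` (one of `"targeting"`, `"positive_control"`, `"non_targeting"`,
#'   `"other"`).
#' @param counts integer matrix with one row per guide and one column per pool.
#' @param pool_names character vector of J pool names.
#' @param replicate_of named character vector mapping pool name to replicate
#'   id; defaults to a single replicate.
#'
#' @return An object of class `"screen_data"`.
#' @export
screen_data <- function(guides, counts, pool_names = colnames(counts),
                        replicate_of = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  required <- c("guide_id", "chrom", "start", "end", "label")
  if (!all(required %in% names(guides)))
    stop_tilefs("guides must have columns ", paste(required, collapse = ", "),
                class = "tilefs_parse_error")
  if (nrow(guides) != nrow(counts))
    stop_tilefs("guides and counts disagree on the number of sgRNAs",
                class = "tilefs_parse_error")
  if (nrow(guides) < 1)
    stop_tilefs("no sgRNAs", class = "tilefs_empty_input")
  if (ncol(counts) < 2)
    stop_tilefs("at least two pools are required (J >= 2)",
                class = "tilefs_config_error")
  if (any(guides$start >= guides$end))
    stop_tilefs("target_start must be < target_end for every guide",
                class = "tilefs_parse_error")
  if (!is_count_vector(as.vector(counts)))
    stop_tilefs("counts must be non-negative integers",
                class = "tilefs_parse_error")
  bad <- !guides$label %in% c("targeting", "positive_control",
                              "non_targeting", "other")
  if (any(bad))
    stop_tilefs("unknown guide label(s): ",
                paste(unique(guides$label[bad]), collapse = ", "),
                class = "tilefs_parse_error")
  guides$start <- as.integer(guides$start)
  guides$end <- as.integer(guides$end)
  if (is.null(pool_names)) pool_names <- paste0("pool", seq_len(ncol(counts)))
  if (is.null(replicate_of))
    replicate_of <- setNames(rep("rep1", length(pool_names)), pool_names)
  colnames(counts) <- pool_names
  rownames(counts) <- guides$guide_id
  structure(list(guides = as.data.frame(guides, stringsAsFactors = FALSE),
                 counts = counts,
                 pool_names = pool_names,
                 replicate_of = replicate_of),
            class = "screen_data")
}

#' @export
print.screen_data <- function(x, ...) {
  cat("Screen count data:", nrow(x$counts), "sgRNAs x",
      ncol(x$counts), "pools\n")
  cat("  pools:", paste(x$pool_names, collapse = ", "), "\n")
  cat("  chromosomes:", paste(unique(x$guides$chrom), collapse = ", "), "\n")
  lab <- table(x$guides$label)
  cat("  labels:", paste(names(lab), lab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a screen count table
#'
#' Reads the text CSV input format: columns `guide_id,chrom,start,end,label`
#' followed by one integer count column per pool. Non-targeting sgRNAs are
#' dropped (the model does not use them); remaining rows keep their input
#' order. Coordinates are interpreted as 0-based half-open unless
#' `one_based = TRUE` (1-based inclusive, converted on read).
#'
#' @param path path to the CSV file.
#' @param pool_names optional character vector naming which columns (in
#'   order) hold counts; default: every column after `label`.
#' @param replicate_of optional named character vector (pool -> replicate) or
#'   path to a YAML file with a `replicates:` mapping.
#' @param one_based logical; input coordinates are 1-based inclusive.
#'
#' @return A [screen_data] object.
#' @export
read_screen_counts <- function(path, pool_names = NULL, replicate_of = NULL,
                               one_based = FALSE) {
  if (!file.exists(path))
    stop_tilefs("file not found: ", path, class = "tilefs_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("guide_id", "chrom", "start", "end", "label")
  if (!all(required %in% names(df)))
    stop_tilefs("missing required column(s): ",
                paste(setdiff(required, names(df)), collapse = ", "),
                class = "tilefs_parse_error")
  count_cols <- pool_names %||% setdiff(names(df), required)
  if (length(count_cols) < 2)
    stop_tilefs("input declares ", length(count_cols),
                " count column(s); at least 2 pools are required",
                class = "tilefs_config_error")
  for (col in c("start", "end", count_cols)) {
    v <- df[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(v) | v != round(v))
    if (length(bad) > 0)
      stop_tilefs("column '", col, "' is not integer at line ", bad[1] + 1,
                  " of ", path, class = "tilefs_parse_error")
    df[[col]] <- as.integer(round(v))
  }
  if (one_based) df$start <- df$start - 1L
  nt <- df$label == "non_targeting"
  if (any(nt)) {
    message("dropping ", sum(nt), " non-targeting sgRNA(s)")
    df <- df[!nt, , drop = FALSE]
  }
  if (nrow(df) == 0)
    stop_tilefs("no targeting sgRNAs remain after filtering",
                class = "tilefs_empty_input")
  if (is.character(replicate_of) && length(replicate_of) == 1 &&
      file.exists(replicate_of)) {
    spec <- yaml::read_yaml(replicate_of)
    replicate_of <- unlist(spec$replicates)
  }
  screen_data(df[required], as.matrix(df[count_cols]),
              pool_names = count_cols, replicate_of = replicate_of)
}

#' Write a screen count table
#'
#' Inverse of [read_screen_counts()]; a write/read round trip reproduces the
#' object exactly.
#'
#' @param data a [screen_data] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_counts <- function(data, path) {
  stopifnot(inherits(data, "screen_data"))
  df <- cbind(data$guides, as.data.frame(data$counts, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse control (known functional sequence) regions
#'
#' Accepts a `GRanges`, a data.frame with `chrom`/`start`/`end`, a BED file
#' path, or `"chrom:start-end"` strings (0-based half-open, like BED).
#'
#' @param x the regions in any supported representation.
#' @return A `GRanges` of the control intervals.
#' @export
parse_regions <- function(x) {
  if (is(x, "GRanges")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) == 0)
      stop_tilefs("empty control region set", class = "tilefs_config_error")
    return(GRanges(x$chrom, IRanges(start = x$start + 1L, end = x$end)))
  }
  if (is.character(x) && length(x) == 1 && file.exists(x))
    return(rtracklayer::import(x, format = "BED"))
  if (is.character(x)) {
    if (length(x) == 0)
      stop_tilefs("empty control region set", class = "tilefs_config_error")
    m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))
    bad <- vapply(m, length, 1L) != 4L
    if (any(bad))
      stop_tilefs("cannot parse region string: ", x[bad][1],
                  class = "tilefs_parse_error")
    chrom <- vapply(m, `[`, "", 2L)
    s <- as.integer(vapply(m, `[`, "", 3L))
    e <- as.integer(vapply(m, `[`, "", 4L))
    return(GRanges(chrom, IRanges(start = s + 1L, end = e)))
  }
  stop_tilefs("unsupported control region representation",
              class = "tilefs_parse_error")
}

# GRanges (1-based closed) of the guides' effect-extended windows.
guide_effect_ranges <- function(data, effect_range) {
  g <- data$guides
  GRanges(g$chrom,
          IRanges(start = pmax(0L, g$start - effect_range) + 1L,
                  end = g$end + effect_range))
}

# GRanges of the tiled segments of a segment map.
segment_ranges <- function(segmap) {
  GRanges(segmap$segments$chrom,
          IRanges(start = segmap$segments$start + 1L,
                  end = segmap$segments$end))
}
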