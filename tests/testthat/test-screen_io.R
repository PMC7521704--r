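test_that("reading a count CSV drops non-targeting guides and keeps order", {
  csv <- write_toy_csv(tempfile(fileext = ".csv"), c(
    "guide_id,chrom,start,end,label,poolA,poolB",
    "g1,chr1,100,120,targeting,5,9",
    "g2,chr1,150,170,non_targeting,3,3",
    "g3,chr1,200,220,positive_control,8,1"))
  d <- suppressMessages(read_screen_counts(csv))
  expect_s3_class(d, "screen_data")
  expect_equal(nrow(d$counts), 2)
  expect_equal(ncol(d$counts), 2)
  expect_equal(d$guides$guide_id, c("g1", "g3"))
  expect_equal(d$pool_names, c("poolA", "poolB"))
  expect_equal(unname(d$counts[2, ]), c(8L, 1L))
})

test_that("malformed or underspecified inputs are rejected with context", {
  bad <- write_toy_csv(tempfile(fileext = ".csv"), c(
    "guide_id,chrom,start,end,label,poolA,poolB",
    "g1,chr1,100,120,targeting,5,9",
    "g2,chr1,150,170,targeting,3.5,3"))
  expect_error(read_screen_counts(bad), "line 3", class = "tilefs_parse_error")

  one_pool <- write_toy_csv(tempfile(fileext = ".csv"), c(
    "guide_id,chrom,start,end,label,poolA",
    "g1,chr1,100,120,targeting,5"))
  expect_error(read_screen_counts(one_pool), class = "tilefs_config_error")

  only_nt <- write_toy_csv(tempfile(fileext = ".csv"), c(
    "guide_id,chrom,start,end,label,poolA,poolB",
    "g1,chr1,100,120,non_targeting,5,9",
    "g2,chr1,150,170,non_targeting,3,3"))
  expect_error(suppressMessages(read_screen_counts(only_nt)),
               class = "tilefs_empty_input")
})

test_that("multi-pool FACS headers pass through in order", {
  csv <- write_toy_csv(tempfile(fileext = ".csv"), c(
    "guide_id,chrom,start,end,label,input,negative,low,high",
    "g1,chr1,100,120,targeting,5,9,2,0",
    "g2,chr1,150,170,targeting,1,2,3,4"))
  d <- read_screen_counts(csv)
  expect_equal(d$pool_names, c("input", "negative", "low", "high"))
  expect_equal(ncol(d$counts), 4)
})

test_that("write/read round trip reproduces the screen exactly", {
  set.seed(42)
  d <- toy_screen(starts = c(0, 500, 1200, 5000),
                  counts = matrix(rpois(12, 40), 4, 3,
                                  dimnames = list(NULL, c("a", "b", "c"))))
  csv <- tempfile(fileext = ".csv")
  write_screen_counts(d, csv)
  d2 <- read_screen_counts(csv)
  expect_identical(d2$counts, d$counts)
  expect_identical(d2$guides, d$guides)
  expect_identical(d2$pool_names, d$pool_names)
})

test_that("segment map matches a brute-force interval-intersection oracle", {
  set.seed(7)
  for (cfg in list(list(seg = 100, er = 200), list(seg = 50, er = 0),
                   list(seg = 120, er = 350))) {
    starts <- sort(sample(0:20000, 60))
    chrom <- rep(c("chr1", "chr2"), each = 30)
    d <- toy_screen(starts, matrix(1L, 60, 2), chrom = chrom, width = 20)
    sm <- build_segment_map(d, cfg$seg, cfg$er)
    expect_true(all(sm$segments$end - sm$segments$start == cfg$seg))
    # per chromosome: segments tile contiguously
    for (ch in unique(sm$segments$chrom)) {
      s <- sm$segments[sm$segments$chrom == ch, ]
      expect_equal(s$start[-1], s$end[-nrow(s)])
    }
    # brute-force all-pairs oracle over guides x segments
    for (n in seq_len(nrow(d$guides))) {
      lo <- max(0, d$guides$start[n] - cfg$er)
      hi <- d$guides$end[n] + cfg$er
      hits <- which(sm$segments$chrom == d$guides$chrom[n] &
                      sm$segments$start < hi & sm$segments$end > lo)
      expect_identical(sm$g[[n]], hits)
      expect_gte(length(hits), 1)
    }
  }
})

test_that("the effect-extended window maps to the expected segments", {
  # anchor guide puts the tiling origin at coordinate 0
  d <- toy_screen(starts = c(200, 1000), counts = matrix(1L, 2, 2),
                  width = 20)
  sm <- build_segment_map(d, segment_size = 100, effect_range = 200)
  expect_equal(sm$segments$start[1], 0)
  # guide [1000,1020) +/- 200 -> [800,1220) -> segments 9..13 (1-based)
  expect_equal(sm$g[[2]], 9:13)

  d2 <- toy_screen(starts = c(0, 1005), counts = matrix(1L, 2, 2),
                   width = 20)
  sm2 <- build_segment_map(d2, segment_size = 100, effect_range = 0)
  expect_length(sm2$g[[2]], 1)

  d3 <- toy_screen(starts = c(0, 10000), counts = matrix(1L, 2, 2))
  sm3 <- build_segment_map(d3, segment_size = 100, effect_range = 200)
  expect_length(intersect(sm3$g[[1]], sm3$g[[2]]), 0)
})

test_that("positive-control marking follows any-overlap semantics", {
  d <- toy_screen(starts = seq(0, 10000, by = 100),
                  counts = matrix(1L, 101, 2), width = 20)
  sm <- build_segment_map(d, segment_size = 100, effect_range = 0)
  pi0 <- mark_fs0(sm, data.frame(chrom = "chrT", start = 5000, end = 7100))
  expect_equal(which(pi0 == 1), 51:71)
  expect_true(all(pi0[-(51:71)] == 0))

  # half-overlap of a segment still marks it
  pi0b <- mark_fs0(sm, data.frame(chrom = "chrT", start = 4950, end = 5000))
  expect_equal(which(pi0b == 1), 50)

  expect_error(mark_fs0(sm, data.frame(chrom = character(0),
                                       start = integer(0),
                                       end = integer(0))),
               class = "tilefs_config_error")
  expect_error(mark_fs0(sm, data.frame(chrom = "chrZ", start = 0,
                                       end = 100)),
               class = "tilefs_config_error")
})

test_that("probability tracks are sparse bedGraphs with a combined track", {
  d <- toy_screen(starts = seq(0, 2000, by = 100),
                  counts = matrix(1L, 21, 2), width = 20)
  sm <- build_segment_map(d, segment_size = 100, effect_range = 0)
  pi <- matrix(0, 2, sm$M)
  pi[1, 3] <- 1
  pi[2, 13] <- 0.9
  pi[2, 14] <- 0.1
  out <- tempfile()
  files <- write_probability_tracks(pi, sm, out)
  fs1 <- readLines(file.path(out, "FS1.bedGraph"))
  expect_length(fs1, 3) # track line + 2 records
  expect_match(fs1[1], "^track")
  # all-zero row: header only
  pi0row <- rbind(pi[1, ], 0)
  files2 <- write_probability_tracks(pi0row, sm, tempfile())
  expect_length(readLines(files2[2]), 1)
  # combined track equals the clipped row sum
  comb <- read.table(file.path(out, "p_combined.bedGraph"), skip = 1)
  expect_equal(comb$V4[comb$V2 == 1200], 0.9)
  expect_equal(comb$V4[comb$V2 == 200], 1)
})

test_that("credible-region BED output merges and scores regions", {
  regions <- data.frame(fs = c(1, 2, 2), chrom = "chrT",
                        start = c(1000, 2000, 3000),
                        end = c(1300, 2100, 3200),
                        posterior = c(0.96, 0.5, 0.45))
  bed <- tempfile(fileext = ".bed")
  write_fs_regions(regions, bed)
  lines <- readLines(bed)
  expect_length(lines, 3)
  fields <- strsplit(lines[1], "\t")[[1]]
  expect_equal(fields[4], "FS1")
  expect_equal(fields[5], "960")
  # empty region set -> empty file
  empty <- regions[0, ]
  bed2 <- tempfile(fileext = ".bed")
  write_fs_regions(empty, bed2)
  expect_equal(file.size(bed2), 0)
})
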