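test_that("read_bed maps fields, skips headers, keeps file order", {
  path <- write_lines_tmp(c(
    "track name=dhs description=\"peaks\"",
    "# a comment",
    "chr14 1000 1600 peak1",
    "chr14\t2000\t2400",
    "chr2 5 10 x"))
  bed <- read_bed(path)
  expect_equal(nrow(bed), 3L)
  expect_equal(bed$chrom, c("chr14", "chr14", "chr2"))
  expect_equal(bed$start, c(1000L, 2000L, 5L))
  expect_equal(bed$end, c(1600L, 2400L, 10L))
  expect_equal(bed$label, c("peak1", NA, "x"))
})

test_that("read_bed returns an empty frame for an empty file", {
  expect_equal(nrow(read_bed(write_lines_tmp(character()))), 0L)
})

test_that("read_bed rejects malformed lines, naming the line number", {
  expect_error(read_bed(write_lines_tmp(c("chr1 0 100", "chr14 1600 1000"))),
               "line 2")
  expect_error(read_bed(write_lines_tmp("chr1 abc 100")), "non-integer")
  expect_error(read_bed(write_lines_tmp("chr1 100")), "at least 3")
})

test_that("classification follows the genic > non-genic > other precedence", {
  # exhaustive enumeration of which HMM states a peak overlaps
  states <- c(1L, 4L, 5L, 7L)
  for (mask in 1:15) {
    present <- states[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0]
    hmm <- data.frame(chrom = "chrT",
                      start = seq(0, by = 200, length.out = length(present)),
                      end = seq(200, by = 200, length.out = length(present)),
                      label = paste0(present, "_State"))
    dhs <- data.frame(chrom = "chrT", start = 0L,
                      end = max(hmm$end), label = "peak")
    got <- classify_promoters(dhs, hmm)$state
    want <- if (1L %in% present) "genic"
            else if (any(c(4L, 5L) %in% present)) "non_genic"
            else "other"
    expect_equal(as.character(got), want,
                 info = paste("states:", paste(present, collapse = ",")))
  }
})

test_that("peaks with no overlapping segment are classified other", {
  dhs <- data.frame(chrom = "chrT", start = 10000L, end = 10500L,
                    label = "lonely")
  hmm <- data.frame(chrom = "chrT", start = 0L, end = 100L, label = "1_A")
  expect_equal(as.character(classify_promoters(dhs, hmm)$state), "other")
})

test_that("classification is total, order-independent, midpoint-positioned", {
  set.seed(11)
  n <- 50
  start <- sort(sample.int(1e6, n)) * 3L
  dhs <- data.frame(chrom = "chrT", start = start, end = start + 400L,
                    label = sprintf("p%02d", seq_len(n)))
  hmm <- data.frame(chrom = "chrT", start = start - 50L, end = start + 50L,
                    label = sample(c("1_A", "4_E", "5_E", "9_Q"), n, TRUE))
  pr <- classify_promoters(dhs, hmm)
  expect_equal(nrow(pr), n)
  expect_equal(pr$pos, (dhs$start + dhs$end) %/% 2L)
  shuf <- sample.int(n)
  pr2 <- classify_promoters(dhs[shuf, ], hmm[rev(seq_len(n)), ])
  expect_equal(pr2, pr)
})

test_that("disjoint chromosomes cannot be classified", {
  dhs <- data.frame(chrom = "chr1", start = 0L, end = 100L, label = "a")
  hmm <- data.frame(chrom = "chr2", start = 0L, end = 100L, label = "1_A")
  expect_error(classify_promoters(dhs, hmm), "chromosome")
})

test_that("read_signal bins records with length proration and additivity", {
  one <- read_signal(write_lines_tmp("chr1 0 3000 5.0", ".bedGraph"))
  expect_equal(one$values, 5.0)
  split <- read_signal(write_lines_tmp("chr1 1500 4500 2.0", ".bedGraph"))
  expect_equal(split$values, c(1.0, 1.0))
  summed <- read_signal(write_lines_tmp(
    c("chr1 0 3000 1.0", "chr1 0 3000 2.0"), ".bedGraph"))
  expect_equal(summed$values, 3.0)
})

test_that("read_signal conserves total signal mass", {
  set.seed(3)
  n <- 40
  start <- sample.int(50000, n)
  len <- sample.int(8000, n)
  val <- round(runif(n, 0, 10), 3)
  lines <- sprintf("chr1 %d %d %g", start, start + len, val)
  track <- read_signal(write_lines_tmp(lines, ".bedGraph"))
  expect_equal(sum(track$values), sum(val), tolerance = 1e-9)
})

test_that("read_signal rejects negative values", {
  expect_error(read_signal(write_lines_tmp("chr1 0 3000 -1", ".bedGraph")),
               "negative")
})

test_that("signal_at indexes the containing bin and checks the extent", {
  track <- bin_signal(data.frame(start = 0L, end = 6000L, value = 4),
                      bin_size = 3000L)
  expect_equal(signal_at(track, c(0, 2999, 3000)), c(2, 2, 2))
  expect_error(signal_at(track, 6000), "extent")
})

test_that("promoter and signal writers round-trip through the readers", {
  pr <- make_promoters(c(100, 5000, 9000),
                       c("genic", "other", "non_genic"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_promoters(pr, tsv)
  expect_equal(read_promoters(tsv), pr)

  track <- bin_signal(data.frame(start = c(0L, 9000L), end = c(3000L, 12000L),
                                 value = c(2.5, 1.25)),
                      bin_size = 3000L, chrom = "chrT")
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  write_signal(track, bg)
  back <- read_signal(bg, bin_size = 3000L)
  expect_equal(back$values, track$values)
})
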