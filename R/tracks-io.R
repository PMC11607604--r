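#' Read a BED3+ interval file
#'
#' Parses a whitespace-delimited BED file into a data frame of genomic
#' intervals. Browser/track/comment header lines are skipped. Coordinates
#' follow the BED convention: 0-based, half-open `[start, end)`.
#'
#' @param path Path to a BED3 or BED4 file (whitespace-delimited).
#' @return A data frame with columns `chrom` (character), `start` (integer,
#'   0-based), `end` (integer, exclusive) and `label` (character; `NA` when
#'   the file has only three columns), one row per interval, in file order.
#' @details Malformed lines (fewer than three fields, non-integer
#'   coordinates, `end <= start`, negative `start`) raise an error naming the
#'   offending line number.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr14 1000 1600 peak1", bed)
#' read_bed(bed)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("line ", lineno[which(nf < 3L)[1L]],
         ": expected at least 3 whitespace-delimited fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    stop("line ", lineno[which(bad)[1L]], ": non-integer coordinates")
  }
  bad <- end <= start | start < 0L
  if (any(bad)) {
    stop("line ", lineno[which(bad)[1L]],
         ": invalid interval (need 0 <= start < end)")
  }
  label <- vapply(seq_along(fields), function(i) {
    if (nf[i] >= 4L) fields[[i]][4L] else NA_character_
  }, "")
  data.frame(chrom = chrom, start = start, end = end, label = label,
             stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' @param intervals Data frame with `chrom`, `start`, `end` and optionally
#'   `label` columns (0-based half-open coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  cols <- intervals[, c("chrom", "start", "end")]
  if (!is.null(intervals$label) && !all(is.na(intervals$label))) {
    cols$label <- intervals$label
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Classify DHS peaks into promoter firing states
#'
#' Assigns each DNase-hypersensitive site (DHS) peak a firing state from a
#' ChromHMM-style segmentation: peaks overlapping a state-1 segment are
#' active genic promoters (`"genic"`), peaks overlapping state 4 or 5 are
#' active non-genic promoters (`"non_genic"`), and all remaining peaks form
#' the `"other"` class. Precedence when a peak spans several segments is
#' genic > non-genic > other. The representative promoter coordinate is the
#' peak midpoint; peaks whose midpoints fall on the same base are merged
#' (first peak kept) so downstream looping distances are strictly positive.
#'
#' @param dhs Data frame of DHS peak intervals, as from [read_bed()].
#' @param hmm Data frame of segmentation intervals whose `label` starts with
#'   the numeric state (e.g. `"1_Active_Promoter"`, `"4"`).
#' @return A data frame of promoters sorted by position: `chrom`, `pos`
#'   (midpoint, bp), `state` (factor with levels genic, non_genic, other)
#'   and `id` (peak label, or `peak<i>` for unlabelled peaks).
#' @export
classify_promoters <- function(dhs, hmm) {
  if (nrow(dhs) == 0L) stop("no DHS peaks to classify")
  if (length(intersect(unique(dhs$chrom), unique(hmm$chrom))) == 0L) {
    stop("DHS and HMM tracks share no chromosome; cannot classify")
  }
  state_num <- suppressWarnings(
    as.integer(sub("^([0-9]+).*$", "\\1", hmm$label)))
  if (any(is.na(state_num))) {
    stop("HMM labels must start with the numeric state; offending label: ",
         hmm$label[which(is.na(state_num))[1L]])
  }
  peaks <- GenomicRanges::GRanges(
    dhs$chrom, IRanges::IRanges(dhs$start + 1L, dhs$end))
  segs <- GenomicRanges::GRanges(
    hmm$chrom, IRanges::IRanges(hmm$start + 1L, hmm$end))
  hits <- GenomicRanges::findOverlaps(peaks, segs)
  qh <- S4Vectors::queryHits(hits)
  st <- state_num[S4Vectors::subjectHits(hits)]
  state <- rep("other", nrow(dhs))
  ng <- unique(qh[st %in% c(4L, 5L)])
  state[ng] <- "non_genic"
  g <- unique(qh[st == 1L])
  state[g] <- "genic"
  id <- ifelse(is.na(dhs$label), paste0("peak", seq_len(nrow(dhs))),
               dhs$label)
  pos <- (dhs$start + dhs$end) %/% 2L
  out <- data.frame(chrom = dhs$chrom, pos = pos,
                    state = factor(state, levels = promoter_states()),
                    id = id, stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("chrom", "pos")]), , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Promoter firing state levels
#'
#' @return Character vector of the three firing states, in precedence order.
#' @export
promoter_states <- function() c("genic", "non_genic", "other")

#' Read a bedGraph signal track into fixed-width bins
#'
#' Sums a 4-column bedGraph into consecutive bins of `bin_size` bp. Each
#' record's value is treated as a total that is spread uniformly over the
#' record's extent, so a record overlapping several bins contributes to each
#' in proportion to the overlapped length; total signal is conserved.
#'
#' @param path Path to a bedGraph file (chrom, start, end, value).
#' @param bin_size Bin width in bp (default 3000, the coarse-graining used
#'   for comparison against nascent-transcription data).
#' @param chrom Optional chromosome to restrict to (default: the single
#'   chromosome present; an error if several and none specified).
#' @return A `signal_track`: list with `chrom`, `bin_size` and `values`
#'   (numeric, bin k is `[k*bin_size, (k+1)*bin_size)` for k = 0, 1, ...).
#' @export
read_signal <- function(path, bin_size = 3000L, chrom = NULL) {
  stopifnot(bin_size > 0)
  rec <- read_bed(path)
  names(rec)[4L] <- "value"
  rec$value <- as.numeric(rec$value)
  if (any(is.na(rec$value))) stop("bedGraph requires a numeric 4th column")
  if (any(rec$value < 0)) stop("negative signal value in ", path)
  if (is.null(chrom)) {
    chrom <- unique(rec$chrom)
    if (length(chrom) > 1L) {
      stop("multiple chromosomes in track; pass `chrom`")
    }
    if (length(chrom) == 0L) chrom <- "chr"
  } else {
    rec <- rec[rec$chrom == chrom, , drop = FALSE]
  }
  bin_signal(rec, bin_size = bin_size, chrom = chrom)
}

#' Bin interval signal records into a signal track
#'
#' @param rec Data frame with `start`, `end`, `value` (0-based half-open).
#' @param bin_size Bin width, bp.
#' @param chrom Chromosome name stored on the track.
#' @param n_bins Optional minimum number of bins (track padded with zeros).
#' @return A `signal_track` list (`chrom`, `bin_size`, `values`).
#' @export
bin_signal <- function(rec, bin_size = 3000L, chrom = "chr", n_bins = NULL) {
  n <- if (nrow(rec) == 0L) 0L else ceiling(max(rec$end) / bin_size)
  if (!is.null(n_bins)) n <- max(n, n_bins)
  values <- numeric(n)
  for (i in seq_len(nrow(rec))) {
    s <- rec$start[i]; e <- rec$end[i]; v <- rec$value[i]
    k0 <- s %/% bin_size; k1 <- (e - 1L) %/% bin_size
    for (k in k0:k1) {
      ov <- min(e, (k + 1) * bin_size) - max(s, k * bin_size)
      values[k + 1L] <- values[k + 1L] + v * ov / (e - s)
    }
  }
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 values = values),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", x$chrom, "|", length(x$values), "bins of",
      x$bin_size, "bp | total signal", format(sum(x$values)), "\n")
  invisible(x)
}

#' Signal value at the bin containing a position
#'
#' @param track A `signal_track`.
#' @param pos Base-pair positions (vector).
#' @return Numeric vector of bin values; error if a position lies beyond the
#'   track extent.
#' @export
signal_at <- function(track, pos) {
  bin <- pos %/% track$bin_size + 1L
  if (any(pos < 0) || any(bin > length(track$values))) {
    stop("position outside the signal track extent")
  }
  track$values[bin]
}

#' Write a signal track as bedGraph
#'
#' Zero bins are omitted, as is usual for sparse bedGraph.
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(track, path) {
  k <- which(track$values > 0) - 1L
  rec <- data.frame(chrom = track$chrom,
                    start = k * track$bin_size,
                    end = (k + 1L) * track$bin_size,
                    value = track$values[k + 1L])
  utils::write.table(rec, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a promoter table as TSV
#'
#' @param promoters Promoter data frame (`chrom`, `pos`, `state`, `id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  utils::write.table(promoters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a promoter table written by [write_promoters()]
#'
#' @param path TSV path.
#' @return Promoter data frame with `state` as a factor.
#' @export
read_promoters <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out$state <- factor(out$state, levels = promoter_states())
  out
}
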