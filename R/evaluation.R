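#' Spearman rank correlation with t-approximation p-value
#'
#' Correlation between two paired sets of values on tie-averaged ranks,
#' with the p-value from the large-sample t approximation (or, optionally,
#' a seeded permutation test for small n). Predicted firing ranks are
#' compared against nascent-transcription rankings with a significance
#' threshold of 1e-6.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param p_threshold Significance threshold reported as `significant`
#'   (default 1e-6).
#' @param n_perm If > 0, compute the p-value by permutation with this many
#'   resamples instead of the t approximation (two-sided).
#' @return List: `n`, `rho`, `p_value`, `significant`.
#' @export
spearman_cor <- function(x, y, p_threshold = 1e-6, n_perm = 0L) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input vector: Spearman rho is undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  if (n_perm > 0L) {
    obs <- abs(rho)
    hits <- sum(vapply(seq_len(n_perm), function(k) {
      abs(stats::cor(x, sample(y), method = "spearman")) >= obs - 1e-12
    }, logical(1)))
    p <- (hits + 1) / (n_perm + 1)
  } else {
    p <- ct$p.value
  }
  list(n = length(x), rho = rho, p_value = p,
       significant = p < p_threshold)
}

# Decile index (1..10) for each item given its rank vector; remainder items
# go to the earlier deciles so the split is deterministic.
decile_of <- function(rank_vec) {
  n <- length(rank_vec)
  sizes <- rep(n %/% 10L, 10L)
  if (n %% 10L > 0L) sizes[seq_len(n %% 10L)] <- sizes[seq_len(n %% 10L)] + 1L
  dec <- rep(seq_len(10L), sizes)
  dec[order(order(rank_vec))]
}

#' Decile confusion matrix between two rankings
#'
#' Items are binned into deciles by rank position in each ranking; entry
#' (i, j) is the fraction of all items in decile i of the first ranking and
#' decile j of the second. Identical rankings give 0.1 on each diagonal
#' cell; independent rankings give ~0.01 everywhere.
#'
#' @param rank_a,rank_b Rank vectors over the same items (1 = top).
#' @return A 10 x 10 matrix of fractions summing to 1.
#' @export
decile_confusion <- function(rank_a, rank_b) {
  n <- length(rank_a)
  stopifnot(length(rank_b) == n)
  if (n < 10L) stop("decile confusion requires at least 10 items")
  da <- decile_of(rank_a)
  db <- decile_of(rank_b)
  counts <- table(factor(da, levels = 1:10), factor(db, levels = 1:10))
  m <- unclass(counts) / n
  dimnames(m) <- NULL
  m
}

#' Decile agreement ratio
#'
#' The number of items falling in the same decile of both rankings, divided
#' by the number expected by chance (n/10). 10 means a perfect match, 1 is
#' chance level.
#'
#' @inheritParams decile_confusion
#' @return Dimensionless ratio in \[0, 10\].
#' @export
agreement_ratio <- function(rank_a, rank_b) {
  n <- length(rank_a)
  if (n < 10L) stop("agreement ratio requires at least 10 items")
  sum(decile_of(rank_a) == decile_of(rank_b)) / (n / 10)
}

#' Reference ranks of promoters from a signal track
#'
#' Scores each promoter by the signal of the bin containing its position
#' and returns tie-averaged descending ranks (1 = strongest signal).
#'
#' @param signal A `signal_track`.
#' @param promoters Promoter data frame on the same chromosome.
#' @return Numeric rank vector aligned with `promoters` rows.
#' @export
reference_ranks <- function(signal, promoters) {
  rank(-signal_at(signal, promoters$pos), ties.method = "average")
}

#' Compare a firing prediction with a reference ranking
#'
#' Full rank-based evaluation of a [predict_firing()] table against either
#' a nascent-transcription `signal_track` or a precomputed reference rank
#' vector: Spearman rho and p-value, the 10 x 10 decile confusion matrix,
#' and the decile agreement ratio.
#'
#' @param prediction Output of [predict_firing()].
#' @param reference A `signal_track`, or a numeric rank vector aligned with
#'   `prediction` rows.
#' @param promoters Promoter table matching `prediction` (only needed when
#'   `reference` is a signal track; defaults to the prediction's own
#'   columns).
#' @param p_threshold Significance threshold for the Spearman p-value.
#' @return A `rank_comparison` list: `n`, `spearman_rho`, `p_value`,
#'   `significant`, `decile_matrix`, `agreement_ratio`.
#' @export
evaluate_prediction <- function(prediction, reference, promoters = NULL,
                                p_threshold = 1e-6) {
  if (inherits(reference, "signal_track")) {
    if (is.null(promoters)) {
      promoters <- prediction[, c("chrom", "pos", "state", "id")]
    }
    ref_rank <- reference_ranks(reference, promoters)
  } else {
    ref_rank <- reference
    stopifnot(length(ref_rank) == nrow(prediction))
  }
  sp <- spearman_cor(-prediction$rank, -ref_rank, p_threshold = p_threshold)
  structure(list(n = nrow(prediction),
                 spearman_rho = sp$rho,
                 p_value = sp$p_value,
                 significant = sp$significant,
                 decile_matrix = decile_confusion(prediction$rank, ref_rank),
                 agreement_ratio = agreement_ratio(prediction$rank, ref_rank)),
            class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat("rank_comparison over", x$n, "promoters\n")
  cat("  Spearman rho :", format(x$spearman_rho, digits = 4),
      sprintf("(p = %.3g%s)", x$p_value,
              if (x$significant) ", significant at 1e-6" else ""), "\n")
  cat("  decile agreement ratio:", format(x$agreement_ratio, digits = 4),
      "(10 = perfect, 1 = chance)\n")
  invisible(x)
}
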