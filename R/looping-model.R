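#' Looping-formula parameters
#'
#' Bundle of the looping constant and state weights used by
#' [predict_firing()]. The relative firing probability of promoter i is
#' `ptrans(i) ~ b_i * (1 + c / l(i))`, where `l(i)` is the genomic distance
#' to the tethering promoter: the nearest active promoter of any state in
#' the 1-state variant, the nearest *genic* promoter in the 3-state variant.
#'
#' @param c Looping constant in bp. The default, 86,000 bp, is the average
#'   chromatin loop length measured in HeLa cells; at `l = c` the looped and
#'   unlooped configurations carry equal weight.
#' @param b_g,b_ng,b_o Dimensionless weights for genic, non-genic and other
#'   promoters (defaults 13.1, 3.3 and 1, the GRO-seq-derived ratios for
#'   human chromosome 14 in HUVECs). Ignored in the 1-state mode, where all
#'   promoters share one weight.
#' @param mode `"three_state"` or `"one_state"`.
#' @return A `looping_params` list.
#' @examples
#' looping_params()                       # 3-state defaults
#' looping_params(mode = "one_state")
#' @export
looping_params <- function(c = 86000, b_g = 13.1, b_ng = 3.3, b_o = 1,
                           mode = c("three_state", "one_state")) {
  mode <- match.arg(mode)
  stopifnot(c > 0, b_g > 0, b_ng > 0, b_o > 0)
  structure(list(c = c, b_g = b_g, b_ng = b_ng, b_o = b_o, mode = mode),
            class = "looping_params")
}

#' @export
print.looping_params <- function(x, ...) {
  cat("looping_params:", x$mode, "| c =", x$c, "bp")
  if (x$mode == "three_state") {
    cat(" | (b_g, b_ng, b_o) = (", x$b_g, ",", x$b_ng, ",", x$b_o, ")")
  }
  cat("\n")
  invisible(x)
}

#' Distance to the nearest active promoter
#'
#' For each promoter, the genomic distance in bp to the nearest other
#' promoter on the chromosome, any firing state eligible as neighbour.
#'
#' @param promoters Promoter data frame sorted by `pos` (one chromosome).
#' @param i Optional index (or vector of indices); default all promoters.
#' @return Numeric distances in bp; `NA` when the promoter has no neighbour
#'   (single-promoter chromosome).
#' @export
nearest_active_distance <- function(promoters, i = NULL) {
  pos <- promoters$pos
  n <- length(pos)
  if (is.unsorted(pos)) stop("promoters must be sorted by pos")
  if (n < 2L) {
    d <- rep(NA_real_, n)
  } else {
    gap_left <- c(Inf, diff(pos))
    gap_right <- c(diff(pos), Inf)
    d <- pmin(gap_left, gap_right)
  }
  if (is.null(i)) d else d[i]
}

#' Distance to the nearest genic promoter
#'
#' For each promoter, the genomic distance in bp to the nearest *other*
#' promoter of genic state; the 3-state looping formula only ever tethers
#' through a genic promoter. `NA` marks promoters with no available genic
#' partner (for which the looped term is dropped).
#'
#' @inheritParams nearest_active_distance
#' @return Numeric distances in bp, `NA` where no other genic promoter
#'   exists on the chromosome.
#' @export
nearest_genic_distance <- function(promoters, i = NULL) {
  pos <- promoters$pos
  if (is.unsorted(pos)) stop("promoters must be sorted by pos")
  gidx <- which(promoters$state == "genic")
  d <- vapply(seq_along(pos), function(j) {
    cand <- setdiff(gidx, j)
    if (length(cand) == 0L) return(NA_real_)
    min(abs(pos[cand] - pos[j]))
  }, numeric(1))
  if (is.null(i)) d else d[i]
}

#' Evaluate the looping formula
#'
#' Relative firing probability `b * (1 + c/l)`. When `l` is `NA` (no
#' tethering promoter available) only the unlooped configuration
#' contributes and the value is `b`.
#'
#' @param l Distance(s) to the tethering promoter, bp; `NA` allowed.
#' @param b State weight(s), dimensionless, > 0.
#' @param c Looping constant, bp, > 0.
#' @return Relative ptrans (arbitrary units; only ratios and ranks are
#'   meaningful).
#' @examples
#' ptrans_formula(24000, b = 1, c = 86000)  # 4.583...
#' @export
ptrans_formula <- function(l, b, c) {
  stopifnot(all(b > 0), c > 0)
  if (any(!is.na(l) & l <= 0)) {
    stop("l must be > 0 (coincident promoters must be merged upstream)")
  }
  ifelse(is.na(l), b, b * (1 + c / l))
}

#' Looped:unlooped configuration weight ratio
#'
#' The ratio of the looped configuration's Boltzmann weight to the unlooped
#' one's is `c/l`: 10:1 for an 8.6 kbp loop, 1:1 at 86 kbp, 1:10 at 860 kbp
#' (with the default looping constant).
#'
#' @param l Loop length, bp, > 0.
#' @param c Looping constant, bp, > 0.
#' @return Dimensionless ratio `c/l`.
#' @export
loop_weight_ratio <- function(l, c = 86000) {
  stopifnot(all(l > 0), c > 0)
  c / l
}

#' Boltzmann-weight derivation of the looping formula
#'
#' Computes the relative firing probability from first principles: the
#' unlooped configuration (one TF:pol--promoter contact) has weight
#' `n * exp(beta_eps) * (1 - p(l))` and the looped configuration (the
#' promoter additionally tethered to its neighbour at the factory, two
#' contacts) has weight `n * exp(2*beta_eps) * p(l)`, with the
#' fractal-globule contact probability `p(l) = a/l`. Their sum over the
#' partition function `Z` reduces algebraically to `b * (1 + c/l)` with
#' `b = n * exp(beta_eps) / Z` and `c = (exp(beta_eps) - 1) * a`.
#'
#' @param beta_eps TF:pol--promoter affinity in units of kT (dimensionless).
#' @param n Number of TF:pol complexes, > 0.
#' @param a Fractal-globule looping prefactor, bp, > 0.
#' @param Z Partition-function normaliser (arbitrary positive scale).
#' @param l Genomic distance to the nearest promoter, bp, > 0; requires
#'   `a/l < 1` so the looping probability is a probability.
#' @return List with `ptrans`, plus the `unlooped` and `looped` weights.
#' @export
boltzmann_ptrans <- function(beta_eps, n, a, Z, l) {
  stopifnot(n > 0, a > 0, Z > 0, all(l > 0))
  p_loop <- a / l
  if (any(p_loop >= 1)) {
    stop("a/l >= 1: looping probability must be < 1 (a too large for l)")
  }
  unlooped <- n * exp(beta_eps) * (1 - p_loop)
  looped <- n * exp(2 * beta_eps) * p_loop
  list(ptrans = (unlooped + looped) / Z,
       unlooped = unlooped, looped = looped)
}

#' Predict relative promoter firing probabilities
#'
#' Applies the 1-state or 3-state looping formula to a classified promoter
#' table and ranks promoters from the most to the least likely to fire.
#'
#' In the 1-state mode every promoter shares one weight (b = 1) and loops
#' to its nearest active promoter of any state; in the 3-state mode the
#' weight is `b_g`, `b_ng` or `b_o` by state and the loop always tethers
#' through the nearest genic promoter (dropped when none exists).
#'
#' @param promoters Classified promoter data frame (one chromosome, sorted
#'   by `pos`), as from [classify_promoters()].
#' @param params A [looping_params()] object.
#' @return Data frame: `id`, `chrom`, `pos`, `state`, `l_used` (bp, `NA`
#'   when the loop term is absent), `ptrans` and `rank` (1 = highest
#'   ptrans; ties averaged).
#' @examples
#' pr <- worked_example_promoters()
#' predict_firing(pr, looping_params())
#' @export
predict_firing <- function(promoters, params = looping_params()) {
  if (nrow(promoters) == 0L) stop("no promoters to predict")
  stopifnot(inherits(params, "looping_params"))
  if (length(unique(promoters$chrom)) > 1L) {
    stop("predict_firing works per chromosome; split the input")
  }
  if (params$mode == "one_state") {
    l <- nearest_active_distance(promoters)
    b <- rep(1, nrow(promoters))
  } else {
    l <- nearest_genic_distance(promoters)
    b <- c(genic = params$b_g, non_genic = params$b_ng,
           other = params$b_o)[as.character(promoters$state)]
  }
  pt <- ptrans_formula(l, b, params$c)
  out <- data.frame(id = promoters$id, chrom = promoters$chrom,
                    pos = promoters$pos, state = promoters$state,
                    l_used = l, ptrans = pt,
                    rank = rank(-pt, ties.method = "average"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Estimate state weights from a nascent-transcription track
#'
#' Estimates the relative weights (b_g, b_ng, b_o) as the mean signal over
#' promoters of each state, normalised so that the `other` class has weight
#' 1. Each promoter is scored by the signal of the bin containing its
#' position. Because the observed signal also carries the looping factor
#' `(1 + c/l)`, passing `params` divides that factor out per promoter
#' before averaging, which decouples the weight estimate from the distance
#' structure.
#'
#' @param promoters Classified promoter data frame.
#' @param signal A `signal_track` covering the promoter positions.
#' @param params Optional [looping_params()]; when supplied, each
#'   promoter's signal is divided by `(1 + c/l_genic)` before averaging.
#' @return Named numeric vector `c(b_g=, b_ng=, b_o=)`; `NA` for a state
#'   with no promoters.
#' @export
estimate_state_weights <- function(promoters, signal, params = NULL) {
  s <- signal_at(signal, promoters$pos)
  if (!is.null(params)) {
    l <- nearest_genic_distance(promoters)
    s <- s / ifelse(is.na(l), 1, 1 + params$c / l)
  }
  m <- vapply(promoter_states(), function(st) {
    v <- s[promoters$state == st]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  w <- m / m[["other"]]
  stats::setNames(w, c("b_g", "b_ng", "b_o"))
}
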