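#' The five-promoter worked-example chromosome segment
#'
#' A small fixture of five promoters p, q, r, s, t at 0, 10, 40, 64 and
#' 84 kbp (gaps 10, 30, 24 and 20 kbp) with states other, genic and three
#' non-genic. With the default looping constant of 86 kbp the 1-state
#' formula gives relative values (9.6, 9.6, 4.58, 5.3, 5.3) b and rank
#' order p = q > s = t > r, while the 3-state formula gives
#' (9.6 b_o, b_g, 3.87 b_ng, 2.59 b_ng, 2.16 b_ng) and, with weights
#' (13.1, 3.3, 1), rank order q, r, p, s, t.
#'
#' @return Classified promoter data frame (chrom, pos, state, id).
#' @examples
#' predict_firing(worked_example_promoters(), looping_params())
#' @export
worked_example_promoters <- function() {
  data.frame(chrom = "chrS",
             pos = c(0L, 10000L, 40000L, 64000L, 84000L),
             state = factor(
               c("other", "genic", "non_genic", "non_genic", "non_genic"),
               levels = promoter_states()),
             id = c("p", "q", "r", "s", "t"),
             stringsAsFactors = FALSE)
}

#' Write the worked example as BED tracks
#'
#' Emits a DHS peak file and a matching ChromHMM-style segmentation whose
#' classification through [read_bed()] + [classify_promoters()] reproduces
#' [worked_example_promoters()] up to a uniform 300 bp shift: peaks are
#' 600 bp wide starting at the promoter positions, so midpoints preserve
#' every inter-promoter gap (which is all the looping formula sees).
#'
#' @param dir Output directory (created if needed).
#' @return Named character vector with the `dhs` and `hmm` file paths.
#' @export
worked_example_files <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pr <- worked_example_promoters()
  dhs <- data.frame(chrom = pr$chrom,
                    start = pr$pos,
                    end = pr$pos + 600L,
                    label = pr$id)
  state_label <- c(genic = "1_Active_Promoter", non_genic = "4_Strong_Enhancer",
                   other = "7_Insulator")[as.character(pr$state)]
  hmm <- data.frame(chrom = pr$chrom,
                    start = dhs$start, end = dhs$end, label = state_label)
  dhs_path <- file.path(dir, "worked_example_dhs.bed")
  hmm_path <- file.path(dir, "worked_example_hmm.bed")
  write_bed(dhs, dhs_path)
  write_bed(hmm, hmm_path)
  c(dhs = dhs_path, hmm = hmm_path)
}

#' Configuration for a synthetic chromosome
#'
#' Defaults emulate human chromosome 14 in HUVECs: ~107 Mbp carrying 2,226
#' active promoters (mean spacing ~48 kbp) split into genic, non-genic and
#' other classes in proportions 344:938:944, with true 3-state weights
#' (13.1, 3.3, 1) and looping constant 86 kbp.
#'
#' @param chrom_length Chromosome length, bp.
#' @param n_promoters Number of promoters to place.
#' @param state_proportions Probabilities of (genic, non_genic, other).
#' @param true_params [looping_params()] used by the signal generator.
#' @param noise_sigma Lognormal sigma of multiplicative signal noise.
#' @param bin_size Signal bin width, bp.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(chrom_length = 107e6, n_promoters = 2226L,
                             state_proportions = c(344, 938, 944) / 2226,
                             true_params = looping_params(),
                             noise_sigma = 0, bin_size = 3000L) {
  stopifnot(abs(sum(state_proportions) - 1) < 1e-9, noise_sigma >= 0,
            chrom_length > 0, n_promoters >= 2L)
  structure(list(chrom_length = chrom_length,
                 n_promoters = as.integer(n_promoters),
                 state_proportions = state_proportions,
                 true_params = true_params,
                 noise_sigma = noise_sigma,
                 bin_size = as.integer(bin_size)),
            class = "synthetic_config")
}

#' Generate a synthetic chromosome of classified promoters
#'
#' Promoter positions are a homogeneous Poisson process (uniform order
#' statistics at fixed count) over the chromosome; positions falling in an
#' already occupied signal bin are re-drawn so every promoter is resolvable
#' at the track resolution. States are i.i.d. from the configured
#' proportions. Deterministic for a given seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return List: `promoters` (classified, sorted), `dhs` and `hmm` interval
#'   data frames that classify back to the same promoters, and `config`.
#' @export
synth_chromosome <- function(config = synthetic_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n_promoters
  bs <- config$bin_size
  if (config$chrom_length < 2 * bs) {
    stop("chromosome too short for two resolvable promoters")
  }
  pos <- integer(0)
  bins <- integer(0)
  while (length(pos) < n) {
    cand <- as.integer(floor(stats::runif(n - length(pos), bs,
                                          config$chrom_length - bs)))
    cb <- cand %/% bs
    keep <- !(cb %in% bins) & !duplicated(cb)
    pos <- c(pos, cand[keep])
    bins <- c(bins, cb[keep])
  }
  pos <- sort(pos)
  state <- sample(promoter_states(), n, replace = TRUE,
                  prob = config$state_proportions)
  promoters <- data.frame(chrom = "chrSyn", pos = pos,
                          state = factor(state, levels = promoter_states()),
                          id = sprintf("syn%04d", seq_len(n)),
                          stringsAsFactors = FALSE)
  half <- 150L
  dhs <- data.frame(chrom = "chrSyn", start = pos - half, end = pos + half,
                    label = promoters$id, stringsAsFactors = FALSE)
  state_label <- c(genic = "1_Active_Promoter",
                   non_genic = "4_Strong_Enhancer",
                   other = "8_Heterochrom")[state]
  hmm <- data.frame(chrom = "chrSyn", start = pos - half, end = pos + half,
                    label = state_label, stringsAsFactors = FALSE)
  list(promoters = promoters, dhs = dhs, hmm = hmm, config = config)
}

#' Generate a synthetic nascent-transcription signal track
#'
#' Each promoter's containing bin receives
#' `b_state * (1 + c / l_genic) * exp(eps)` with `eps ~ N(0, noise_sigma^2)`
#' (multiplicative lognormal noise, read-count-like); promoters without a
#' genic partner contribute `b_state` only; all other bins are zero. With
#' `noise_sigma = 0` the track's reference ranking equals the 3-state
#' prediction ranking exactly.
#'
#' @param promoters Classified promoter data frame.
#' @param true_params [looping_params()] supplying `c` and the weights.
#' @param noise_sigma Lognormal sigma (0 = noiseless).
#' @param seed Integer seed.
#' @param bin_size Bin width, bp.
#' @param chrom_length Optional chromosome length (track padded to cover it).
#' @return A `signal_track`.
#' @export
synth_signal <- function(promoters, true_params = looping_params(),
                         noise_sigma = 0, seed = 1L, bin_size = 3000L,
                         chrom_length = NULL) {
  set.seed(seed)
  l <- nearest_genic_distance(promoters)
  b <- c(genic = true_params$b_g, non_genic = true_params$b_ng,
         other = true_params$b_o)[as.character(promoters$state)]
  mu <- b * ifelse(is.na(l), 1, 1 + true_params$c / l)
  eps <- if (noise_sigma > 0) stats::rnorm(length(mu), 0, noise_sigma) else 0
  val <- mu * exp(eps)
  n_bins <- if (is.null(chrom_length)) NULL else ceiling(chrom_length / bin_size)
  k <- promoters$pos %/% bin_size
  rec <- data.frame(start = k * bin_size, end = (k + 1L) * bin_size,
                    value = val)
  bin_signal(rec, bin_size = bin_size, chrom = promoters$chrom[1],
             n_bins = n_bins)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits DHS and HMM BED files, the bedGraph signal track and a JSON
#' manifest recording the seed and true parameters, so a run can be
#' reproduced exactly from the directory alone.
#'
#' @param dir Output directory.
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_synthetic_dataset <- function(dir, config = synthetic_config(),
                                    seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chr <- synth_chromosome(config, seed = seed)
  sig <- synth_signal(chr$promoters, config$true_params,
                      noise_sigma = config$noise_sigma, seed = seed + 1L,
                      bin_size = config$bin_size,
                      chrom_length = config$chrom_length)
  paths <- c(dhs = file.path(dir, "dhs.bed"),
             hmm = file.path(dir, "hmm.bed"),
             signal = file.path(dir, "signal.bedGraph"),
             manifest = file.path(dir, "manifest.json"))
  write_bed(chr$dhs, paths[["dhs"]])
  write_bed(chr$hmm, paths[["hmm"]])
  write_signal(sig, paths[["signal"]])
  manifest <- list(seed = seed,
                   chrom_length = config$chrom_length,
                   n_promoters = config$n_promoters,
                   state_proportions = config$state_proportions,
                   noise_sigma = config$noise_sigma,
                   bin_size = config$bin_size,
                   true_params = unclass(config$true_params))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
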