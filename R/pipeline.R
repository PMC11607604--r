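#' @useDynLib loopfire, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

write_manifest <- function(path, ...) {
  jsonlite::write_json(list(...), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

check_outputs <- function(paths, overwrite) {
  exists <- file.exists(paths)
  if (any(exists) && !overwrite) {
    stop("output exists (use overwrite = TRUE): ",
         paste(paths[exists], collapse = ", "))
  }
}

#' Pipeline command: generate a synthetic dataset
#'
#' @param out_dir Output directory.
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param overwrite Overwrite existing outputs.
#' @return Paths of the written files, invisibly.
#' @export
run_synth <- function(out_dir, config = synthetic_config(), seed = 1L,
                      overwrite = FALSE) {
  if (dir.exists(out_dir) && !overwrite &&
      file.exists(file.path(out_dir, "manifest.json"))) {
    stop("dataset already present in ", out_dir, " (use overwrite = TRUE)")
  }
  write_synthetic_dataset(out_dir, config, seed = seed)
}

#' Pipeline command: classify DHS peaks into firing states
#'
#' Reads DHS peaks and a ChromHMM-style segmentation, classifies promoters
#' and writes the promoter table plus a manifest with per-state counts.
#'
#' @param dhs_bed,hmm_bed Input BED paths.
#' @param out_dir Output directory.
#' @param overwrite Overwrite existing outputs.
#' @return The promoter data frame, invisibly.
#' @export
run_classify <- function(dhs_bed, hmm_bed, out_dir, overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(out_dir, c("promoters.tsv", "classify_manifest.json"))
  check_outputs(out, overwrite)
  promoters <- classify_promoters(read_bed(dhs_bed), read_bed(hmm_bed))
  write_promoters(promoters, out[1])
  write_manifest(out[2], command = "classify", dhs = dhs_bed, hmm = hmm_bed,
                 n_promoters = nrow(promoters),
                 counts = as.list(table(promoters$state)))
  invisible(promoters)
}

#' Pipeline command: predict relative firing probabilities
#'
#' Classifies promoters from DHS + HMM tracks and applies the looping
#' formula, writing a ranked prediction table and a manifest.
#'
#' @param dhs_bed,hmm_bed Input BED paths.
#' @param out_dir Output directory.
#' @param params A [looping_params()].
#' @param overwrite Overwrite existing outputs.
#' @return The prediction data frame, invisibly.
#' @export
run_predict <- function(dhs_bed, hmm_bed, out_dir,
                        params = looping_params(), overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(out_dir, c("predictions.tsv", "predict_manifest.json"))
  check_outputs(out, overwrite)
  promoters <- classify_promoters(read_bed(dhs_bed), read_bed(hmm_bed))
  pred <- predict_firing(promoters, params)
  utils::write.table(pred, out[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(out[2], command = "predict", dhs = dhs_bed, hmm = hmm_bed,
                 params = unclass(params), n_promoters = nrow(pred),
                 counts = as.list(table(promoters$state)))
  invisible(pred)
}

#' Pipeline command: evaluate predictions against a signal track
#'
#' Scores a prediction table against a nascent-transcription bedGraph:
#' Spearman rho with its p-value (flagged at the 1e-6 threshold), the
#' decile agreement ratio, and the decile confusion matrix (CSV).
#'
#' @param predictions_tsv Prediction table from [run_predict()].
#' @param signal_bedgraph bedGraph signal path.
#' @param out_dir Output directory.
#' @param bin_size Signal bin width, bp.
#' @param overwrite Overwrite existing outputs.
#' @return The `rank_comparison`, invisibly.
#' @export
run_evaluate <- function(predictions_tsv, signal_bedgraph, out_dir,
                         bin_size = 3000L, overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(out_dir, c("evaluation.json", "decile_matrix.csv"))
  check_outputs(out, overwrite)
  pred <- utils::read.table(predictions_tsv, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (nrow(pred) == 0L) stop("empty prediction table: ", predictions_tsv)
  signal <- read_signal(signal_bedgraph, bin_size = bin_size,
                        chrom = pred$chrom[1])
  cmp <- evaluate_prediction(pred, signal)
  write_manifest(out[1], command = "evaluate",
                 predictions = predictions_tsv, signal = signal_bedgraph,
                 n = cmp$n, spearman_rho = cmp$spearman_rho,
                 p_value = cmp$p_value, significant = cmp$significant,
                 agreement_ratio = cmp$agreement_ratio)
  utils::write.table(cmp$decile_matrix, out[2], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(cmp)
}

#' Pipeline command: Brownian-dynamics simulation of a promoter set
#'
#' Coarse-grains the promoters into beads, runs equilibration plus sampled
#' production, and writes the residence-time firing estimates, a cluster
#' report, the peripheral cluster fraction, an XYZ trajectory and a
#' manifest. Bit-identical outputs for a given seed.
#'
#' @param promoters Classified promoter data frame (or path to a TSV from
#'   [write_promoters()]).
#' @param chrom_length Chromosome length, bp.
#' @param out_dir Output directory.
#' @param n_tfpol TF:pol count (default: one per 20 TU beads, at least 1).
#' @param ff A [forcefield()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param overwrite Overwrite existing outputs.
#' @return List with `state`, `residence`, `clusters_per_frame`,
#'   `peripheral_fraction`, invisibly.
#' @export
run_simulate <- function(promoters, chrom_length, out_dir, n_tfpol = NULL,
                         ff = forcefield(), cfg = sim_config(), seed = 1L,
                         overwrite = FALSE) {
  if (is.character(promoters)) promoters <- read_promoters(promoters)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(out_dir, c("residence.tsv", "clusters.tsv",
                              "trajectory.xyz", "simulate_manifest.json",
                              "beads.bed"))
  check_outputs(out, overwrite)
  beads <- build_beads(promoters, chrom_length)
  n_tu <- sum(grepl("_tu$", beads$type))
  if (is.null(n_tfpol)) n_tfpol <- max(1L, round(n_tu / 20))
  state <- run_sim(beads, n_tfpol, ff, cfg, seed = seed)
  res <- residence_ptrans(state, ff)
  utils::write.table(res, out[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  traj <- state$trajectory
  cl_rows <- list()
  peri <- numeric(0)
  for (f in seq_len(traj$n_frames)) {
    act <- traj$active[, f]
    cl <- detect_clusters(frame_coords(traj$tf, f)[act, , drop = FALSE],
                          d_cl = ff$rc)
    if (length(cl$clusters) > 0L) {
      cl_rows[[length(cl_rows) + 1L]] <- data.frame(
        frame = f, cluster = seq_along(cl$clusters),
        size = lengths(cl$clusters),
        x = cl$centroids[, 1], y = cl$centroids[, 2], z = cl$centroids[, 3])
      peri <- c(peri, peripheral_fraction(cl$centroids, state$semiaxes))
    }
  }
  clusters <- if (length(cl_rows)) do.call(rbind, cl_rows) else
    data.frame(frame = integer(), cluster = integer(), size = integer(),
               x = numeric(), y = numeric(), z = numeric())
  utils::write.table(clusters, out[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_xyz(state, out[3])
  write_bed(data.frame(chrom = promoters$chrom[1], start = beads$start,
                       end = beads$end, label = beads$type), out[5])
  pf <- if (length(peri)) mean(peri) else NaN
  write_manifest(out[4], command = "simulate", seed = seed,
                 chrom_length = chrom_length, n_beads = nrow(beads),
                 n_tu = n_tu, n_tfpol = n_tfpol,
                 forcefield = unclass(ff), config = unclass(cfg),
                 peripheral_fraction = pf)
  invisible(list(state = state, residence = res,
                 clusters_per_frame = clusters, peripheral_fraction = pf))
}

# XYZ trajectory: bead frames then TF:pol particles, one block per frame
write_xyz <- function(state, path) {
  traj <- state$trajectory
  con <- file(path, "w")
  on.exit(close(con))
  nb <- dim(traj$bead)[1]
  nt <- if (length(dim(traj$tf)) == 3L) dim(traj$tf)[1] else 0L
  for (f in seq_len(traj$n_frames)) {
    writeLines(c(as.character(nb + nt), paste("frame", f)), con)
    b <- frame_coords(traj$bead, f)
    writeLines(sprintf("C %.4f %.4f %.4f", b[, 1], b[, 2], b[, 3]), con)
    if (nt > 0L) {
      tfp <- frame_coords(traj$tf, f)
      writeLines(sprintf("O %.4f %.4f %.4f",
                         tfp[, 1], tfp[, 2], tfp[, 3]), con)
    }
  }
  invisible(path)
}

#' Pipeline command: cross-validate formula against simulation
#'
#' Runs the desk-scale version of the simulation/formula comparison: a
#' 3-state simulation of the given promoters, residence-time firing
#' estimates per TU bead, 3-state formula predictions aggregated to the
#' same beads, and their Spearman comparison.
#'
#' @param promoters Classified promoter data frame.
#' @param chrom_length Chromosome length, bp.
#' @param out_dir Output directory.
#' @param params [looping_params()] for the formula side.
#' @param n_tfpol TF:pol count.
#' @param ff,cfg Force field and schedule for the simulation side.
#' @param seed Integer seed.
#' @param overwrite Overwrite existing outputs.
#' @return List with `rho`, `p_value`, `residence`, `formula`, invisibly.
#' @export
run_compare_sim <- function(promoters, chrom_length, out_dir,
                            params = looping_params(), n_tfpol = NULL,
                            ff = forcefield(), cfg = sim_config(),
                            seed = 1L, overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- run_simulate(promoters, chrom_length, out_dir, n_tfpol = n_tfpol,
                      ff = ff, cfg = cfg, seed = seed, overwrite = overwrite)
  pred <- predict_firing(promoters, params)
  ptr <- formula_ptrans_per_bead(pred, sim$residence$bead)
  sp <- spearman_cor(sim$residence$residence, ptr)
  write_manifest(file.path(out_dir, "compare_manifest.json"),
                 command = "compare-sim", seed = seed, n_tu = length(ptr),
                 spearman_rho = sp$rho, p_value = sp$p_value)
  invisible(list(rho = sp$rho, p_value = sp$p_value,
                 residence = sim$residence, formula = ptr))
}

# formula ptrans aggregated per TU bead (max over contained promoters)
formula_ptrans_per_bead <- function(pred, beads, bead_bp = 3000L) {
  bead_of <- pred$pos %/% bead_bp + 1L
  vapply(beads, function(b) {
    v <- pred$ptrans[bead_of == b]
    if (length(v) == 0L) NA_real_ else max(v)
  }, numeric(1))
}
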