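# shared fixtures built in code at test time

write_lines_tmp <- function(lines, ext = ".bed") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# promoter table from positions (bp) and states, sorted, on one chromosome
make_promoters <- function(pos, state, chrom = "chrT") {
  ord <- order(pos)
  data.frame(chrom = chrom, pos = as.integer(pos[ord]),
             state = factor(state[ord], levels = promoter_states()),
             id = paste0("pr", seq_along(pos)),
             stringsAsFactors = FALSE)
}

# tiny toy chromosome + beads for simulation tests
toy_sim_system <- function(seed = 7, n_promoters = 10,
                           chrom_length = 600e3) {
  cfg <- synthetic_config(chrom_length = chrom_length,
                          n_promoters = n_promoters, noise_sigma = 0)
  chr <- synth_chromosome(cfg, seed = seed)
  list(chr = chr, beads = build_beads(chr$promoters, chrom_length))
}

# short simulation schedule for unit tests
fast_cfg <- function(...) {
  sim_config(equil_steps = 2000L, prod_steps = 6000L, sample_every = 200L,
             ...)
}
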