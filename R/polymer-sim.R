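#' Normalisation factor of the truncated-shifted Lennard-Jones potential
#'
#' Factor `N = 1 / (1 + 4[(sigma/rc)^12 - (sigma/rc)^6])` that rescales the
#' truncated, shifted LJ so its minimum depth equals `-eps` exactly. For
#' the model's cutoff `rc = 1.8 sigma`, `N` is about 1.1288.
#'
#' @param rc Cutoff distance; must exceed `sigma`.
#' @param sigma Particle diameter (the simulation length unit, 30 nm = 3 kbp).
#' @return The dimensionless normalisation factor.
#' @export
lj_norm_factor <- function(rc, sigma = 1) {
  if (rc <= sigma) stop("rc must exceed sigma")
  sr6 <- (sigma / rc)^6
  1 / (1 + 4 * (sr6^2 - sr6))
}

#' Truncated, shifted Lennard-Jones potential
#'
#' The attraction between an active TF:pol and a binding bead:
#' `U(d) = 4 eps N [(sigma/d)^12 - (sigma/d)^6 - (sigma/rc)^12 +
#' (sigma/rc)^6]` for `d < rc` and 0 beyond, with `N` chosen so the minimum
#' (at `d = 2^(1/6) sigma`) is exactly `-eps`. The potential is continuous
#' at the cutoff, where it vanishes.
#'
#' @param d Distance(s) between particle centres, > 0.
#' @param eps Well depth in kT (7.1, 4.4 and 3.5 for genic, non-genic and
#'   other transcription units; 2.7 for acetylated beads).
#' @param rc Cutoff distance (default 1.8 sigma).
#' @param sigma Particle diameter.
#' @return Potential energy in kT, vectorised over `d`.
#' @export
lj_shifted <- function(d, eps, rc = 1.8, sigma = 1) {
  stopifnot(all(d > 0), eps >= 0)
  N <- lj_norm_factor(rc, sigma)
  sr6 <- (sigma / d)^6
  src6 <- (sigma / rc)^6
  u <- 4 * eps * N * (sr6^2 - sr6 - src6^2 + src6)
  ifelse(d < rc, u, 0)
}

#' Force-field parameters of the chromatin polymer model
#'
#' Interaction strengths and mechanical parameters of the bead-and-spring
#' model, in reduced units (lengths in sigma = 30 nm, energies in kT).
#' Attractions: genic 7.1, non-genic 4.4, other 3.5 kT between active
#' TF:pols and transcription-unit beads, and a weak 2.7 kT attraction to
#' acetylated (open-chromatin) beads; all with range `rc = 1.8 sigma`.
#' Chain mechanics follow the standard Kremer-Grest choices (FENE K = 30
#' kT/sigma^2, R0 = 1.6 sigma) with a Kratky-Porod bending stiffness
#' giving a persistence length of about 3 sigma (~90 nm).
#'
#' @param eps_genic,eps_non_genic,eps_other,eps_acetyl Well depths, kT.
#' @param rc Attraction cutoff, sigma units.
#' @param wca_eps Repulsive (excluded-volume) energy scale, kT.
#' @param fene_K,fene_R0 FENE spring constant and maximum extension.
#' @param kappa Bending modulus, kT.
#' @param conf_k Harmonic confinement stiffness outside the ellipsoid.
#' @return A `forcefield` list.
#' @export
forcefield <- function(eps_genic = 7.1, eps_non_genic = 4.4,
                       eps_other = 3.5, eps_acetyl = 2.7,
                       rc = 1.8, wca_eps = 1, fene_K = 30, fene_R0 = 1.6,
                       kappa = 3, conf_k = 10) {
  stopifnot(rc > 1, eps_genic >= 0, eps_non_genic >= 0, eps_other >= 0,
            eps_acetyl >= 0)
  structure(list(eps_genic = eps_genic, eps_non_genic = eps_non_genic,
                 eps_other = eps_other, eps_acetyl = eps_acetyl,
                 rc = rc, wca_eps = wca_eps, fene_K = fene_K,
                 fene_R0 = fene_R0, kappa = kappa, conf_k = conf_k),
            class = "forcefield")
}

#' Coarse-grain a chromosome into typed beads
#'
#' Maps a chromosome to a string of beads of `bead_bp` (3 kbp = one 30 nm
#' bead). A bead containing a promoter becomes a transcription-unit (TU)
#' bead typed by the strongest contained state (genic > non-genic >
#' other); remaining beads overlapping an acetylation interval become
#' `acetylated`; all others are `inert`.
#'
#' @param promoters Classified promoter data frame.
#' @param chrom_length Chromosome length, bp.
#' @param acetyl_intervals Optional data frame of H3K27ac-like intervals
#'   (`start`, `end`).
#' @param bead_bp Base pairs per bead (default 3000).
#' @return Data frame: `bead` (1-based index), `start`, `end` (bp),
#'   `type` (genic_tu / non_genic_tu / other_tu / acetylated / inert).
#' @export
build_beads <- function(promoters, chrom_length, acetyl_intervals = NULL,
                        bead_bp = 3000L) {
  stopifnot(chrom_length > 0)
  n <- ceiling(chrom_length / bead_bp)
  type <- rep("inert", n)
  if (!is.null(acetyl_intervals) && nrow(acetyl_intervals) > 0L) {
    for (i in seq_len(nrow(acetyl_intervals))) {
      k0 <- acetyl_intervals$start[i] %/% bead_bp
      k1 <- min((acetyl_intervals$end[i] - 1L) %/% bead_bp, n - 1L)
      type[(k0:k1) + 1L] <- "acetylated"
    }
  }
  bead_of <- promoters$pos %/% bead_bp + 1L
  for (st in c("other", "non_genic", "genic")) {  # ascending precedence
    b <- bead_of[promoters$state == st]
    type[b[b <= n]] <- paste0(st, "_tu")
  }
  data.frame(bead = seq_len(n),
             start = (seq_len(n) - 1L) * bead_bp,
             end = pmin(seq_len(n) * bead_bp, chrom_length),
             type = type, stringsAsFactors = FALSE)
}

# one frame of an (n x 3 x F) trajectory array as an n x 3 matrix
frame_coords <- function(arr, f) {
  matrix(arr[, , f], ncol = 3)
}

# attraction depth per bead, from its type
bead_eps_from_types <- function(type, ff) {
  unname(c(genic_tu = ff$eps_genic, non_genic_tu = ff$eps_non_genic,
           other_tu = ff$eps_other, acetylated = ff$eps_acetyl,
           inert = 0)[type])
}

#' Ellipsoid semiaxes for a toy system at the model's volume fraction
#'
#' The full-chromosome model confines 35,784 beads in an ellipsoid of
#' semiaxes 22.24:34.24:41.80 sigma (particle volume fraction ~0.14).
#' For a toy system the same aspect ratio is kept and the volume scaled so
#' the volume fraction is preserved.
#'
#' @param n_particles Total particle count (beads + TF:pols).
#' @return Numeric vector of three semiaxes in sigma units.
#' @export
scaled_semiaxes <- function(n_particles) {
  full <- c(22.24, 34.24, 41.80)
  scale <- (n_particles / 35784)^(1 / 3)
  full * scale
}

#' Simulation schedule and integrator settings
#'
#' @param dt Time step in LJ time units (default 0.001 tau; the explicit
#'   Euler-Maruyama update of the overdamped dynamics needs a step this
#'   small to keep FENE bonds stable at temperature 1).
#' @param temperature Reduced temperature (kT; default 1).
#' @param pushoff_steps Zero-temperature, tightly displacement-capped steps
#'   run first to resolve overlaps in the initial conformation.
#' @param equil_steps Equilibration (burn-in) steps, not sampled.
#' @param prod_steps Production steps.
#' @param sample_every Sampling stride during production.
#' @param rate_on,rate_off TF:pol switching rates per time unit such that
#'   the per-step flip probability is `rate * dt`; the defaults give a mean
#'   dwell of 10 time units in each state and a stationary active fraction of
#'   one half.
#' @param max_disp Cap on the deterministic displacement per step (sigma);
#'   keeps transient overlap forces from overstretching bonds.
#' @param min_d Distance floor used when evaluating pair forces (softens
#'   initial overlaps).
#' @return A `sim_config` list.
#' @export
sim_config <- function(dt = 0.001, temperature = 1,
                       pushoff_steps = 1500L,
                       equil_steps = 10000L, prod_steps = 60000L,
                       sample_every = 300L,
                       rate_on = 0.1, rate_off = 0.1,
                       max_disp = 0.1, min_d = 0.6) {
  stopifnot(dt > 0, equil_steps >= 0, prod_steps > 0, sample_every > 0)
  structure(list(dt = dt, temperature = temperature,
                 pushoff_steps = as.integer(pushoff_steps),
                 equil_steps = as.integer(equil_steps),
                 prod_steps = as.integer(prod_steps),
                 sample_every = as.integer(sample_every),
                 rate_on = rate_on, rate_off = rate_off,
                 max_disp = max_disp, min_d = min_d),
            class = "sim_config")
}

# engine parameter list from forcefield + config + geometry
engine_params <- function(ff, cfg, semiaxes) {
  list(dt = cfg$dt, temperature = cfg$temperature, fene_K = ff$fene_K,
       fene_R0 = ff$fene_R0, kappa = ff$kappa, wca_eps = ff$wca_eps,
       sigma = 1, rc = ff$rc, conf_k = ff$conf_k, semiaxes = semiaxes,
       max_disp = cfg$max_disp, min_d = cfg$min_d)
}

#' Initialise a simulation state
#'
#' Places the chain on a serpentine path through a cubic lattice inscribed
#' in the ellipsoid (unit bonds, no self-overlaps by construction) and
#' TF:pols uniformly in the ellipsoid away from the chain; half the
#' TF:pols start active. Uses the current R RNG state (for TF placement).
#'
#' @param beads Bead table from [build_beads()].
#' @param n_tfpol Number of TF:pol particles.
#' @param semiaxes Ellipsoid semiaxes in sigma (default: scaled to the
#'   model's volume fraction for this particle count).
#' @return A `sim_state` list: `bead_xyz`, `tf_xyz`, `tf_active`,
#'   `semiaxes`, `beads`.
#' @export
init_sim <- function(beads, n_tfpol, semiaxes = NULL) {
  nb <- nrow(beads)
  if (is.null(semiaxes)) semiaxes <- scaled_semiaxes(nb + n_tfpol)
  xyz <- serpentine_chain(nb, semiaxes)
  inside <- function(p) sum((p / semiaxes)^2) < 1
  tf <- matrix(0, n_tfpol, 3)
  for (i in seq_len(n_tfpol)) {
    for (try in 1:2000) {
      q <- stats::runif(3, -1, 1) * semiaxes
      if (!inside(q)) next
      clear <- nrow(xyz) == 0L ||
        min(sqrt(colSums((t(xyz) - q)^2))) > 0.95
      if (clear || try > 1000) break
    }
    tf[i, ] <- q
  }
  active <- rep(c(TRUE, FALSE), length.out = n_tfpol)
  structure(list(bead_xyz = xyz, tf_xyz = tf, tf_active = active,
                 semiaxes = semiaxes, beads = beads),
            class = "sim_state")
}

# serpentine (boustrophedon) walk over a unit-spaced lattice box inscribed
# in the ellipsoid: consecutive sites are lattice neighbours, so bonds have
# length h and non-bonded beads are never closer than h
serpentine_chain <- function(nb, semiaxes, h = 1) {
  corner_ok <- function(n, h) {
    sum((((n - 1) / 2 * h) / semiaxes)^2) <= 0.95
  }
  repeat {
    n <- pmax(floor(2 * semiaxes / (sqrt(3) * h)), 1)
    guard <- 0L
    while (prod(n) < nb && guard < 200L) {
      guard <- guard + 1L
      best <- 0L
      best_frac <- Inf
      for (i in 1:3) {
        trial <- n; trial[i] <- trial[i] + 1L
        fr <- sum((((trial - 1) / 2 * h) / semiaxes)^2)
        if (fr <= 0.95 && fr < best_frac) { best <- i; best_frac <- fr }
      }
      if (best == 0L) break
      n[best] <- n[best] + 1L
    }
    if (prod(n) >= nb) break
    h <- h * 0.95
    if (h < 0.5) stop("cannot inscribe ", nb, " beads in the ellipsoid")
  }
  xs <- (seq_len(n[1]) - (n[1] + 1) / 2) * h
  ys <- (seq_len(n[2]) - (n[2] + 1) / 2) * h
  zs <- (seq_len(n[3]) - (n[3] + 1) / 2) * h
  xyz <- matrix(0, nb, 3)
  k <- 0L
  for (iz in seq_len(n[3])) {
    yr <- if (iz %% 2L == 1L) seq_len(n[2]) else rev(seq_len(n[2]))
    for (iy in yr) {
      fwd <- (k %/% n[1]) %% 2L == 0L
      xr <- if (fwd) seq_len(n[1]) else rev(seq_len(n[1]))
      for (ix in xr) {
        k <- k + 1L
        if (k > nb) return(xyz)
        xyz[k, ] <- c(xs[ix], ys[iy], zs[iz])
      }
    }
  }
  xyz
}

#' Advance a simulation state
#'
#' Runs `nsteps` overdamped-Langevin steps (optionally sampling frames)
#' and returns the updated state, with any sampled trajectory attached.
#' With temperature zero and no net forces, coordinates are unchanged.
#'
#' @param state A `sim_state` from [init_sim()] or a previous call.
#' @param ff A [forcefield()].
#' @param cfg A [sim_config()].
#' @param nsteps Number of steps to run.
#' @param sample_every Sampling stride (0 = no sampling).
#' @param switching Apply TF:pol activity switching (default TRUE).
#' @return The updated `sim_state`; if sampled, with a `trajectory` element
#'   (list: `bead` nb x 3 x F array, `tf`, `active` nt x F, `energy`).
#' @export
sim_step <- function(state, ff = forcefield(), cfg = sim_config(),
                     nsteps = 1L, sample_every = 0L, switching = TRUE) {
  eps <- bead_eps_from_types(state$beads$type, ff)
  res <- bd_run_cpp(state$bead_xyz, eps, state$tf_xyz, state$tf_active,
                    engine_params(ff, cfg, state$semiaxes),
                    as.integer(nsteps), as.integer(sample_every),
                    if (switching) cfg$rate_on else 0,
                    if (switching) cfg$rate_off else 0)
  state$bead_xyz <- res$bead_final
  if (nrow(state$tf_xyz) > 0L) state$tf_xyz <- res$tf_final
  state$tf_active <- res$active_final
  if (sample_every > 0L) {
    state$trajectory <- list(bead = res$bead_traj, tf = res$tf_traj,
                             active = res$active_traj, energy = res$energy,
                             n_frames = res$n_frames)
  }
  state
}

#' Flip TF:pol activity flags at constant rates
#'
#' One switching sweep: each TF:pol flips state independently with
#' probability `rate * dt` (on-rate for inactive particles, off-rate for
#' active ones). The stationary active fraction is
#' `rate_on / (rate_on + rate_off)`.
#'
#' @param active Logical vector of current activity flags.
#' @param rate_on,rate_off Switching rates (per time unit), >= 0.
#' @param dt Time step; requires `rate * dt <= 1`.
#' @return Updated logical vector.
#' @export
switch_tfpols <- function(active, rate_on, rate_off, dt) {
  stopifnot(rate_on >= 0, rate_off >= 0)
  if (rate_on * dt > 1 || rate_off * dt > 1) {
    stop("rate * dt exceeds 1: flip probability is not a probability")
  }
  u <- stats::runif(length(active))
  ifelse(active, u >= rate_off * dt, u < rate_on * dt)
}

#' Run a full simulation: equilibration then sampled production
#'
#' Convenience driver around [init_sim()] and [sim_step()]: equilibrates
#' without sampling, then runs production sampling every
#' `cfg$sample_every` steps. Fully deterministic given `seed`.
#'
#' @param beads Bead table from [build_beads()].
#' @param n_tfpol Number of TF:pol particles.
#' @param ff A [forcefield()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return The final `sim_state` with the production `trajectory`.
#' @export
run_sim <- function(beads, n_tfpol, ff = forcefield(), cfg = sim_config(),
                    seed = 1L) {
  set.seed(seed)
  state <- init_sim(beads, n_tfpol)
  if (cfg$pushoff_steps > 0L) {
    soft <- cfg
    soft$temperature <- 0
    soft$max_disp <- 0.02
    state <- sim_step(state, ff, soft, nsteps = cfg$pushoff_steps,
                      sample_every = 0L, switching = FALSE)
  }
  state <- sim_step(state, ff, cfg, nsteps = cfg$equil_steps,
                    sample_every = 0L)
  sim_step(state, ff, cfg, nsteps = cfg$prod_steps,
           sample_every = cfg$sample_every)
}

#' Residence-time estimate of firing probability per transcription unit
#'
#' For each TU bead, the fraction of sampled frames in which at least one
#' *active* TF:pol lies within the interaction range `rc` of the bead --
#' the simulation analogue of the promoter firing probability.
#'
#' @param state A `sim_state` carrying a `trajectory`.
#' @param ff The [forcefield()] used (its `rc` defines "bound").
#' @return Data frame: `bead`, `type`, `residence` in \[0, 1\], one row per
#'   TU bead.
#' @export
residence_ptrans <- function(state, ff = forcefield()) {
  traj <- state$trajectory
  if (is.null(traj) || traj$n_frames == 0L) {
    stop("no sampled frames: run production with sampling first")
  }
  tu <- which(grepl("_tu$", state$beads$type))
  nf <- traj$n_frames
  nt <- if (length(dim(traj$tf)) == 3L) dim(traj$tf)[1] else 0L
  bound <- matrix(0, length(tu), nf)
  for (f in seq_len(nf)) {
    if (nt == 0L) break
    act <- traj$active[, f]
    if (!any(act)) next
    tfp <- frame_coords(traj$tf, f)[act, , drop = FALSE]
    bp <- frame_coords(traj$bead, f)[tu, , drop = FALSE]
    d2 <- outer(rowSums(bp^2), rowSums(tfp^2), "+") -
      2 * bp %*% t(tfp)
    bound[, f] <- as.numeric(apply(d2 < ff$rc^2, 1L, any))
  }
  data.frame(bead = tu, type = state$beads$type[tu],
             residence = rowMeans(bound))
}

#' Single-linkage clusters of active TF:pols
#'
#' Groups active TF:pol positions into single-linkage components under a
#' distance threshold and reports clusters of two or more particles with
#' their centroids.
#'
#' @param positions n x 3 matrix of TF:pol coordinates.
#' @param d_cl Linkage threshold (default 1.8 sigma, the binding range).
#' @return List with `membership` (component id per particle), `clusters`
#'   (list of member index vectors, size >= 2), `centroids` (matrix, one
#'   row per reported cluster) and `largest_size` (including singletons).
#' @export
detect_clusters <- function(positions, d_cl = 1.8) {
  n <- nrow(positions)
  if (n == 0L) {
    return(list(membership = integer(), clusters = list(),
                centroids = matrix(numeric(), 0, 3), largest_size = 0L))
  }
  if (n == 1L) {
    return(list(membership = 1L, clusters = list(),
                centroids = matrix(numeric(), 0, 3), largest_size = 1L))
  }
  hc <- stats::hclust(stats::dist(positions), method = "single")
  memb <- stats::cutree(hc, h = d_cl)
  sizes <- table(memb)
  big <- as.integer(names(sizes)[sizes >= 2L])
  clusters <- lapply(big, function(k) which(memb == k))
  centroids <- do.call(rbind, lapply(clusters, function(id) {
    colMeans(positions[id, , drop = FALSE])
  }))
  if (is.null(centroids)) centroids <- matrix(numeric(), 0, 3)
  list(membership = memb, clusters = clusters, centroids = centroids,
       largest_size = as.integer(max(sizes)))
}

#' Fraction of points in the outer half of the ellipsoidal volume
#'
#' A point is peripheral when it lies outside the similar inner ellipsoid
#' of half the volume (semiaxes scaled by `2^(-1/3)`). Uniform random
#' points in the ellipsoid are peripheral with probability one half by
#' construction.
#'
#' @param points n x 3 matrix of coordinates (e.g. cluster centroids).
#' @param semiaxes Ellipsoid semiaxes.
#' @return Fraction in \[0, 1\]; `NaN` for an empty point set.
#' @export
peripheral_fraction <- function(points, semiaxes) {
  if (nrow(points) == 0L) return(NaN)
  s <- sweep(points, 2L, semiaxes * 2^(-1 / 3), "/")
  mean(rowSums(s^2) > 1)
}
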