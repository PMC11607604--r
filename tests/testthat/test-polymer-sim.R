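test_that("shifted LJ vanishes at the cutoff and has depth -eps", {
  expect_equal(lj_shifted(1.8, eps = 7.1), 0)
  expect_equal(lj_shifted(1.8000001, eps = 7.1), 0)
  # normalisation: N = 1 / (1 + 4[(s/rc)^12 - (s/rc)^6]) ~ 1.1288 at rc=1.8
  expect_equal(lj_norm_factor(1.8), 1.1288, tolerance = 1e-4)
  for (eps in c(2.7, 3.5, 4.4, 7.1)) {
    opt <- optimize(lj_shifted, c(0.8, 1.8), eps = eps, tol = 1e-12)
    expect_equal(opt$objective, -eps, tolerance = 1e-9)
    expect_equal(opt$minimum, 2^(1 / 6), tolerance = 1e-6)
  }
  expect_error(lj_norm_factor(0.9), "rc must exceed")
})

test_that("build_beads types beads by contained promoters with precedence", {
  pr <- make_promoters(4500, "genic")
  beads <- build_beads(pr, 30e3)
  expect_equal(nrow(beads), 10L)
  expect_equal(beads$type[2], "genic_tu")
  expect_equal(sum(beads$type == "inert"), 9L)

  # one bead holding every state multiset -> strongest state wins
  combos <- list(c("other"), c("non_genic"), c("genic"),
                 c("other", "non_genic"), c("other", "genic"),
                 c("non_genic", "genic"), c("other", "non_genic", "genic"))
  for (states in combos) {
    pr <- make_promoters(seq(100, by = 200, length.out = length(states)),
                         states)
    got <- build_beads(pr, 3000)$type[1]
    want <- if ("genic" %in% states) "genic_tu"
            else if ("non_genic" %in% states) "non_genic_tu" else "other_tu"
    expect_equal(got, want)
  }

  # acetylation marks non-TU beads only
  beads <- build_beads(make_promoters(4500, "genic"), 30e3,
                       acetyl_intervals = data.frame(start = 0L,
                                                     end = 9000L))
  expect_equal(beads$type[1:3], c("acetylated", "genic_tu", "acetylated"))
})

test_that("integration is deterministic and still at zero temperature", {
  no_beads <- data.frame(bead = integer(), start = integer(),
                         end = integer(), type = character(),
                         stringsAsFactors = FALSE)
  cold <- sim_config(temperature = 0, pushoff_steps = 0L)
  # isolated TF:pols at T=0: zero force, coordinates bit-identical
  set.seed(1)
  frozen <- init_sim(no_beads, 4, semiaxes = c(500, 500, 500))
  frozen$tf_xyz <- cbind(seq(1, 4) * 5, 10, 0)
  out <- sim_step(frozen, forcefield(), cold, nsteps = 10L,
                  switching = FALSE)
  expect_identical(out$tf_xyz, frozen$tf_xyz)

  # bonded beads beyond equilibrium contract toward it at T=0
  sys <- toy_sim_system()
  pair <- init_sim(sys$beads[1:2, ], 0, semiaxes = c(500, 500, 500))
  pair$beads <- sys$beads[1:2, ]
  pair$bead_xyz <- matrix(c(0, 0, 0, 1.5, 0, 0), 2, 3, byrow = TRUE)
  sep <- sapply(1:2, function(k) {
    pair <<- sim_step(pair, forcefield(), cold, nsteps = 2L,
                      switching = FALSE)
    pair$bead_xyz[2, 1] - pair$bead_xyz[1, 1]
  })
  expect_true(all(diff(c(1.5, sep)) < 0))

  # identical seeds give bit-identical trajectories
  cfg <- fast_cfg()
  r1 <- run_sim(sys$beads, 6, cfg = cfg, seed = 99)
  r2 <- run_sim(sys$beads, 6, cfg = cfg, seed = 99)
  expect_identical(r1$trajectory$bead, r2$trajectory$bead)
  expect_identical(r1$trajectory$tf, r2$trajectory$tf)
})

test_that("FENE overstretch aborts with a bond-naming error", {
  sys <- toy_sim_system()
  st <- init_sim(sys$beads[1:3, ], 0)
  st$bead_xyz <- matrix(c(0, 0, 0, 1.7, 0, 0, 3.4, 0, 0), 3, 3,
                        byrow = TRUE)
  expect_error(sim_step(st, forcefield(),
                        sim_config(pushoff_steps = 0L), nsteps = 1L),
               "FENE bond 1-2")
})

test_that("halving dt leaves the trajectory-averaged energy stable", {
  pr <- make_promoters(seq(1500, by = 6000, length.out = 10),
                       rep(c("genic", "other"), 5))
  beads <- build_beads(pr, 100 * 3000)
  mean_pe <- function(dt) {
    cfg <- sim_config(dt = dt, equil_steps = round(4 / dt / 1000) * 1000,
                      prod_steps = round(16 / dt / 500) * 500,
                      sample_every = 100L)
    st <- run_sim(beads, 5, cfg = cfg, seed = 12)
    mean(st$trajectory$energy)
  }
  e1 <- mean_pe(5e-4)
  e2 <- mean_pe(2.5e-4)
  expect_lt(abs(e1 - e2) / abs(e2), 0.05)
})

test_that("switching preserves rates and the stationary active fraction", {
  set.seed(3)
  act <- rep(c(TRUE, FALSE), 50)
  # rate_off = 0: active particles never inactivate
  always <- switch_tfpols(act, rate_on = 0.5, rate_off = 0, dt = 0.5)
  expect_true(all(always[act]))
  expect_error(switch_tfpols(act, 3, 3, 0.5), "probability")

  # symmetric rates: long-run active fraction 1/2 (two-state Markov law)
  a <- rep(FALSE, 200)
  frac <- numeric(2000)
  for (t in seq_along(frac)) {
    a <- switch_tfpols(a, rate_on = 0.05, rate_off = 0.05, dt = 1)
    frac[t] <- mean(a)
  }
  expect_equal(mean(frac[-(1:200)]), 0.5, tolerance = 0.05)

  # asymmetric rates: fraction = on / (on + off)
  a <- rep(FALSE, 200)
  for (t in seq_along(frac)) {
    a <- switch_tfpols(a, rate_on = 0.09, rate_off = 0.03, dt = 1)
    frac[t] <- mean(a)
  }
  expect_equal(mean(frac[-(1:200)]), 0.75, tolerance = 0.05)
})

test_that("residence fractions respond to TF:pol presence and pinning", {
  sys <- toy_sim_system()
  cfg <- fast_cfg()
  # no TF:pols -> all residence zero
  st <- run_sim(sys$beads, 0, cfg = cfg, seed = 4)
  expect_true(all(residence_ptrans(st)$residence == 0))
  # a TF:pol glued within rc of one TU for every frame -> residence 1 there
  st2 <- st
  tu <- which(grepl("_tu$", sys$beads$type))[1]
  nf <- st$trajectory$n_frames
  tft <- array(0, c(1, 3, nf))
  for (f in seq_len(nf)) {
    tft[1, , f] <- matrix(st$trajectory$bead[, , f], ncol = 3)[tu, ] +
      c(0.5, 0, 0)
  }
  st2$trajectory$tf <- tft
  st2$trajectory$active <- matrix(TRUE, 1, nf)
  res <- residence_ptrans(st2)
  expect_equal(res$residence[res$bead == tu], 1)
})

test_that("single-linkage clustering is transitive with threshold d_cl", {
  # all pairwise beyond d_cl: no clusters
  far <- matrix(c(0, 0, 0, 5, 0, 0, 0, 5, 0), 3, 3, byrow = TRUE)
  none <- detect_clusters(far, d_cl = 1.8)
  expect_equal(length(none$clusters), 0L)
  expect_equal(none$largest_size, 1L)
  # chain at 0.9 d_cl spacing links transitively into one cluster of 3
  chain <- matrix(c(0, 0, 0, 1.62, 0, 0, 3.24, 0, 0), 3, 3, byrow = TRUE)
  one <- detect_clusters(chain, d_cl = 1.8)
  expect_equal(length(one$clusters), 1L)
  expect_equal(one$largest_size, 3L)
  # two tight groups far apart: exactly two clusters
  set.seed(31)
  g <- rbind(matrix(rnorm(9, sd = 0.1), 3, 3),
             matrix(rnorm(9, sd = 0.1) + 18, 3, 3))
  two <- detect_clusters(g, d_cl = 1.8)
  expect_equal(length(two$clusters), 2L)
  expect_equal(sort(lengths(two$clusters)), c(3L, 3L))
})

test_that("peripheral fraction is 1/2 for uniform points, 1 on the shell", {
  semi <- c(4, 6, 8)
  expect_equal(peripheral_fraction(matrix(0, 1, 3), semi), 0)
  set.seed(14)
  n <- 0; pts <- matrix(numeric(), 0, 3)
  while (nrow(pts) < 20000) {
    cand <- matrix(runif(30000, -1, 1), ncol = 3)
    cand <- sweep(cand, 2, semi, "*")
    keep <- rowSums(sweep(cand, 2, semi, "/")^2) < 1
    pts <- rbind(pts, cand[keep, ])
  }
  expect_equal(peripheral_fraction(pts, semi), 0.5, tolerance = 0.02)
  v <- matrix(rnorm(300), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  shell <- sweep(v, 2, semi, "*")
  expect_equal(peripheral_fraction(shell, semi), 1)
})
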