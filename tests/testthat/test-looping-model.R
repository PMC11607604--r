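# the five-promoter worked example: p,q,r,s,t at 0,10,40,64,84 kbp with
# states other, genic, non_genic x3
wx <- worked_example_promoters()

test_that("nearest-active distance is the minimum over both neighbours", {
  pr <- make_promoters(c(0, 10000, 40000),
                       c("other", "genic", "non_genic"))
  expect_equal(nearest_active_distance(pr), c(10000, 10000, 30000))
  # r loops to s, 24 kbp away
  expect_equal(nearest_active_distance(wx, i = 3), 24000)
  two <- make_promoters(c(0, 7000), c("genic", "genic"))
  expect_equal(nearest_active_distance(two), c(7000, 7000))
  one <- make_promoters(5000, "genic")
  expect_true(is.na(nearest_active_distance(one)))
})

test_that("nearest-genic distance skips self and flags absent partners", {
  # only q (10 kbp) is genic: r is 30 kbp away, s 54 kbp
  expect_equal(nearest_genic_distance(wx, i = 3), 30000)
  expect_equal(nearest_genic_distance(wx, i = 4), 54000)
  # q itself has no other genic promoter
  expect_true(is.na(nearest_genic_distance(wx, i = 2)))
})

test_that("the looping formula matches its printed worked values", {
  expect_equal(ptrans_formula(24000, b = 1, c = 86000), 1 + 86 / 24)
  expect_equal(signif(ptrans_formula(24000, 1, 86000), 3), 4.58)
  expect_equal(ptrans_formula(NA, b = 13.1, c = 86000), 13.1)
  expect_error(ptrans_formula(0, 1, 86000), "l must be > 0")
  # loop term vanishes at large distance
  expect_equal(ptrans_formula(1e12, 2, 86000), 2, tolerance = 1e-6)
})

test_that("looped:unlooped weights are 10:1, 1:1, 1:10 at 8.6/86/860 kbp", {
  expect_identical(loop_weight_ratio(c(8600, 86000, 860000), 86000),
                   c(10, 1, 0.1))
})

test_that("the formula is monotone in l, b and c", {
  l <- seq(1000, 500000, length.out = 200)
  v <- ptrans_formula(l, b = 2, c = 86000)
  expect_true(all(diff(v) < 0))
  expect_true(all(ptrans_formula(l, 3, 86000) > v))
  expect_true(all(ptrans_formula(l, 2, 90000) > v))
})

test_that("Boltzmann weights reduce to the looping formula algebraically", {
  grid <- expand.grid(beta_eps = c(0.5, 1, 2, 3.5),
                      n = c(1, 10, 60),
                      a = c(500, 2000, 10000),
                      Z = c(1, 7.3))
  l <- seq(15000, 2e6, length.out = 1000)
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    bw <- boltzmann_ptrans(g$beta_eps, g$n, g$a, g$Z, l)
    b <- g$n * exp(g$beta_eps) / g$Z
    cc <- (exp(g$beta_eps) - 1) * g$a
    expect_equal(bw$ptrans, ptrans_formula(l, b, cc), tolerance = 1e-12)
    # the two configuration weights recompose the total
    expect_equal((bw$unlooped + bw$looped) / g$Z, bw$ptrans,
                 tolerance = 1e-12)
  }
  # no binding advantage: the loop term vanishes
  flat <- boltzmann_ptrans(0, 10, 1000, 1, c(2000, 20000, 2e5))
  expect_equal(diff(flat$ptrans), c(0, 0))
  expect_error(boltzmann_ptrans(1, 1, 5000, 1, 4000), "a/l")
})

test_that("1-state prediction reproduces the worked example", {
  pred <- predict_firing(wx, looping_params(mode = "one_state"))
  expect_equal(signif(pred$ptrans, 3), c(9.6, 9.6, 4.58, 5.3, 5.3))
  # rank order p = q > s = t > r
  expect_equal(pred$rank, c(1.5, 1.5, 5, 3.5, 3.5))
})

test_that("3-state prediction reproduces the worked example", {
  pred <- predict_firing(wx, looping_params())
  b <- c(1, 13.1, 3.3, 3.3, 3.3)
  expect_equal(signif(pred$ptrans / b, 3), c(9.6, 13.1 / 13.1, 3.87, 2.59, 2.16))
  # rank order q, r, p, s, t
  expect_equal(pred$id[order(pred$rank)], c("q", "r", "p", "s", "t"))
})

test_that("a single promoter falls back to its unlooped weight", {
  one <- make_promoters(5000, "non_genic")
  pred <- predict_firing(one, looping_params())
  expect_equal(pred$ptrans, 3.3)
  expect_equal(pred$rank, 1)
})

test_that("1-state rank order depends only on distances, not on b or c", {
  set.seed(42)
  for (rep in 1:5) {
    pr <- make_promoters(sort(sample.int(5e6, 30)) * 7,
                         sample(promoter_states(), 30, TRUE))
    base <- predict_firing(pr, looping_params(mode = "one_state"))$rank
    for (b in c(0.1, 1, 10)) for (cc in c(3000, 86000, 300000)) {
      p <- looping_params(c = cc, b_g = b, b_ng = b, b_o = b,
                          mode = "one_state")
      expect_equal(predict_firing(pr, p)$rank, base)
    }
    # rank order equals the order of increasing nearest-promoter distance
    expect_equal(rank(nearest_active_distance(pr)), base)
  }
})

test_that("ranks are a tie-averaged permutation summing to N(N+1)/2", {
  set.seed(9)
  for (n in c(2, 5, 23)) {
    pr <- make_promoters(sort(sample.int(1e6, n)) * 11,
                         sample(promoter_states(), n, TRUE))
    for (mode in c("one_state", "three_state")) {
      r <- predict_firing(pr, looping_params(mode = mode))$rank
      expect_equal(sum(r), n * (n + 1) / 2)
    }
  }
})

test_that("3-state collapses to genic-restricted 1-state when degenerate", {
  set.seed(5)
  pr <- make_promoters(sort(sample.int(1e6, 20)) * 13,
                       rep("genic", 20))
  three <- predict_firing(pr, looping_params(b_g = 1, b_ng = 1, b_o = 1))
  one <- predict_firing(pr, looping_params(mode = "one_state"))
  expect_equal(three$ptrans, one$ptrans)
  expect_equal(three$rank, one$rank)
})

test_that("state weights are recovered from a noiseless synthetic track", {
  sys <- toy_sim_system(seed = 21, n_promoters = 400, chrom_length = 40e6)
  pr <- sys$chr$promoters
  truth <- looping_params()
  track <- synth_signal(pr, truth, noise_sigma = 0, seed = 1,
                        chrom_length = 40e6)
  # identical signal everywhere -> weights all 1
  flat <- track
  flat$values[flat$values > 0] <- 2.2
  expect_equal(unname(estimate_state_weights(pr, flat)), c(1, 1, 1))
  # dividing out the loop factor makes recovery exact at sigma = 0
  w <- estimate_state_weights(pr, track, params = truth)
  expect_equal(unname(w), c(13.1, 3.3, 1), tolerance = 1e-9)
})
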