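test_that("tuning curves follow the von-Mises-shaped law", {
  cfg <- pop_config(100, kappa = 3.21)
  # peak response gamma/n at the preferred value
  j <- 17
  r <- tuning_response(cfg$preferred[j], gain = 59.8, cfg)
  expect_equal(r[j], 59.8 / 100)
  expect_equal(which.max(r), j)
  # trough at the anti-preferred value: (gamma/n) e^(-2 kappa)
  r2 <- tuning_response(wrap_pi(cfg$preferred[j] + pi), gain = 59.8, cfg)
  expect_equal(r2[j], (59.8 / 100) * exp(-2 * 3.21))
  # zero gain silences the population
  expect_equal(tuning_response(1.1, 0, cfg), rep(0, 100))
  expect_error(tuning_response(0, -1, cfg), "non-negative")
  # total expected activity is independent of the encoded value
  tot <- vapply(seq(-pi, pi, length.out = 33), function(th) {
    sum(tuning_response(th, 59.8, cfg))
  }, numeric(1))
  expect_equal(max(tot) - min(tot), 0, tolerance = 1e-8)
  expect_equal(tot[1], gain_total(59.8, cfg))
})

test_that("spike sampling is Poisson with the tuning means", {
  cfg <- pop_config(64, kappa = 2)
  rates <- tuning_response(0.3, 40, cfg)
  set.seed(21)
  draws <- t(replicate(4000, sample_spikes(rates)))
  m <- colMeans(draws)
  se <- sqrt(rates / 4000)
  expect_true(all(abs(m - rates) < 3.5 * se + 1e-9))
  # total spike count has mean gain_total
  tot <- rowSums(draws)
  expect_equal(mean(tot), gain_total(40, cfg),
               tolerance = 3 * sd(tot) / sqrt(4000) / gain_total(40, cfg))
  expect_equal(sample_spikes(rep(0, 64)), rep(0L, 64))
})

test_that("resultant-vector decoding maximizes the Poisson likelihood", {
  cfg <- pop_config(100, kappa = 3.21)
  # single spike decodes to that neuron's preferred value
  sp <- rep(0L, 100); sp[40] <- 1L
  expect_equal(ml_decode(sp, cfg)$theta_hat, cfg$preferred[40])
  # symmetric pair of spikes decodes to the midpoint
  sp <- rep(0L, 100)
  sp[51 + 10] <- 1L; sp[51 - 10] <- 1L  # preferred[51] = 0
  expect_equal(ml_decode(sp, cfg)$theta_hat, 0, tolerance = 1e-12)
  # zero spikes: a uniform guess, flagged
  set.seed(5)
  g <- replicate(200, ml_decode(rep(0L, 100), cfg)$theta_hat)
  expect_true(all(ml_decode(rep(0L, 100), cfg)$is_guess))
  expect_lt(circ_r(g), 0.2)
})

test_that("resultant decode matches the brute-force grid argmax", {
  # the decoder-equivalence oracle at reduced scale (the full-size check
  # lives in the acceptance suite)
  set.seed(31)
  for (i in 1:25) {
    kappa <- exp(runif(1, log(1), log(20)))
    gain <- exp(runif(1, log(2), log(300)))
    cfg <- pop_config(100, kappa)
    th <- runif(1, -pi, pi)
    sp <- sample_spikes(tuning_response(th, gain, cfg))
    if (sum(sp) == 0) next
    dec <- ml_decode(sp, cfg)$theta_hat
    oracle <- grid_decode(sp, gain, cfg, n_grid = 1e4)
    expect_lt(abs(wrap_pi(dec - oracle)), 2 * pi / 1e4 + 1e-9)
  }
})

test_that("vectorized decode draws match per-neuron Poisson simulation", {
  cfg <- pop_config(100, kappa = 3.21)
  gain <- 25
  set.seed(41)
  fast <- decode_draws(3e4, theta = 0.5, gain = gain, cfg = cfg)
  slow <- replicate(3e4, {
    sp <- sample_spikes(tuning_response(0.5, gain, cfg))
    if (sum(sp) == 0) runif(1, -pi, pi) else ml_decode(sp, cfg)$theta_hat
  })
  d1 <- error_hist_density(fast$theta_hat - 0.5, 72)
  d2 <- error_hist_density(slow - 0.5, 72)
  expect_lt(tv_dist(d1, d2), 0.03)
  # guess frequency matches the analytic zero-spike probability
  p0 <- exp(-gain_total(gain, cfg))
  expect_lt(abs(mean(fast$is_guess) - p0), 4 * sqrt(p0 / 3e4) + 1e-4)
})

test_that("decode-error density normalizes, is symmetric, tightens with gain", {
  cfg <- pop_config(100, kappa = 3.21)
  h <- 2 * pi / 360
  set.seed(51)
  gains <- c(0, 2, 10, 59.8, 200)
  disp <- vapply(gains, function(g) {
    d <- decode_error_density(g, cfg, n_samples = 2e4)
    expect_equal(sum(d$density) * h, 1, tolerance = 1e-6)
    expect_true(all(d$density >= 0))
    # symmetry about zero within Monte-Carlo error (first sine moment; the
    # mean *direction* is undefined for near-uniform densities)
    w <- d$density / sum(d$density)
    expect_lt(abs(sum(w * sin(d$grid))), 0.02)
    circ_dispersion(d$grid, d$density)
  }, numeric(1))
  expect_equal(disp[1], circ_dispersion(error_grid(360),
                                        rep(1 / (2 * pi), 360)))
  expect_true(all(diff(disp) < 0))  # monotone in gain
  # gain 0 is exactly uniform
  d0 <- decode_error_density(0, cfg)
  expect_equal(d0$density, rep(1 / (2 * pi), 360))
  expect_equal(d0$p_guess, 1)
})

test_that("decoding density is translation-equivariant", {
  cfg <- pop_config(100, kappa = 3.21)
  set.seed(61)
  shift <- 1.234
  a <- decode_draws(4e4, theta = 0, gain = 15, cfg = cfg)$theta_hat
  b <- decode_draws(4e4, theta = shift, gain = 15, cfg = cfg)$theta_hat
  da <- error_hist_density(a, 60)
  db <- error_hist_density(b - shift, 60)
  expect_lt(tv_dist(da, db), 0.03)
})

test_that("two independent density estimates converge with sample size", {
  cfg <- pop_config(100, kappa = 3.21)
  gap <- vapply(c(1e4, 8e4), function(ns) {
    set.seed(71); d1 <- decode_error_density(59.8, cfg, n_samples = ns)
    set.seed(72); d2 <- decode_error_density(59.8, cfg, n_samples = ns)
    max(abs(d1$density - d2$density))
  }, numeric(1))
  expect_lt(gap[2], gap[1])
})
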