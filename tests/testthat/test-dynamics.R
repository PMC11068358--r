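test_that("sensory filter rises and decays with the stated closed form", {
  expect_equal(sensory_gain(0, 0.33, 0.21, 0.5), 0)
  # instantaneous-rise limit reaches the maximum during exposure
  expect_equal(sensory_gain(0.2, 0, 0.21, 0.2), 1)
  # finite rise: 1 - exp(-t/tau_rise) at offset
  expect_equal(sensory_gain(0.5, 0.33, 0.21, 0.5),
               1 - exp(-0.5 / 0.33))
  # decay continues from the offset amplitude
  a_off <- 1 - exp(-0.5 / 0.33)
  expect_equal(sensory_gain(0.71, 0.33, 0.21, 0.5),
               a_off * exp(-0.21 / 0.21))
  # mask termination zeroes the post-offset signal
  expect_equal(sensory_gain(0.51, 0.33, 0.21, 0.5, persists = FALSE), 0)
  expect_equal(sensory_gain(0.4, 0.33, 0.21, 0.5, persists = FALSE),
               sensory_gain(0.4, 0.33, 0.21, 0.5))
})

test_that("sensory integral matches numeric quadrature", {
  for (persists in c(TRUE, FALSE)) {
    f <- function(t) sensory_gain(t, 0.33, 0.21, 0.3, persists = persists)
    for (iv in list(c(0, 0.2), c(0.1, 0.9), c(0.35, 2), c(0, 5))) {
      expect_equal(
        sensory_integral(iv[1], iv[2], 0.33, 0.21, 0.3, persists = persists),
        stats::integrate(f, iv[1], iv[2], rel.tol = 1e-10,
                         subdivisions = 500)$value,
        tolerance = 1e-7)
    }
    expect_equal(
      sensory_integral(0.4, Inf, 0.33, 0.21, 0.3, persists = persists),
      if (persists) sensory_gain(0.4, 0.33, 0.21, 0.3) * 0.21 else 0)
  }
})

test_that("cue identification time follows Hick's law and its variants", {
  expect_equal(cue_identification_time(0.2, 1, 0.171), 0.2)
  expect_equal(cue_identification_time(0.2, 4, 0), 0.2)
  expect_equal(cue_identification_time(0.2, 4, 0.171), 0.542)
  expect_equal(cue_identification_time(0.2, 10, 0.171, "zero"), 0.2)
  expect_equal(cue_identification_time(0.2, 10, 0.171, "constant"), 0.371)
  expect_equal(items_in_memory(c(0.1, 0.542, 0.543), 10, 0.542),
               c(10L, 10L, 1L))
})

test_that("closed-form memory trace matches adaptive ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(81)
  for (i in 1:12) {
    p <- dynr_params(
      sample(c("exp1", "exp2"), 1),
      gamma_wm = runif(1, 10, 300), kappa = runif(1, 1, 10),
      tau_rise = runif(1, 0.02, 0.6), tau_decay = runif(1, 0.05, 0.8),
      tau_wm = runif(1, 0.03, 1.2), b = runif(1, 0, 0.3),
      variant = dynr_variant(sample(c("full", "constant_accumulation",
                                      "mask_terminated"), 1)))
    cond <- list(set_size = sample(c(1, 4, 10), 1),
                 exposure = runif(1, 0.03, 0.5),
                 delay = runif(1, 0, 1), simultaneous = FALSE)
    tm <- dynres:::condition_times(cond)
    t_star <- cue_identification_time(tm$t_cue, cond$set_size, p$b,
                                      p$variant$cue_time)
    times <- sort(unique(c(seq(0, 2.5, length.out = 120), tm$t_offset,
                           t_star)))
    tr <- vwm_gain_trace(times, p, cond)
    linear <- identical(p$variant$accumulation, "linear")
    rhs <- function(t, y, parms) {
      gs <- sensory_gain(t, p$tau_rise, p$tau_decay, tm$t_offset,
                         persists = p$variant$sensory_persists)
      M <- items_in_memory(t, cond$set_size, t_star)
      ceiling_ <- p$gamma_wm / M
      dy <- if (linear) {
        if (y[1] < ceiling_) gs / (M * p$tau_wm) else 0
      } else {
        gs * (ceiling_ - y[1]) / p$tau_wm
      }
      list(dy)
    }
    # integrate piecewise so the solver never steps across the
    # discontinuities at offset and cue identification
    brks <- sort(unique(c(0, tm$t_offset, t_star, max(times))))
    brks <- brks[brks <= max(times)]
    y0 <- 0; num <- NULL
    for (s in seq_len(length(brks) - 1)) {
      seg_times <- sort(unique(c(brks[s], times[times > brks[s] &
                                                 times <= brks[s + 1]],
                                 brks[s + 1])))
      sol <- deSolve::ode(c(g = y0), seg_times, rhs, NULL,
                          rtol = 1e-10, atol = 1e-12)
      num <- rbind(num, sol[-1, , drop = FALSE])
      y0 <- sol[nrow(sol), 2]
    }
    num_at <- stats::approx(num[, 1], num[, 2], xout = times[times > 0])$y
    rel_err <- max(abs(tr$gamma_wm[times > 0] - num_at)) / p$gamma_wm
    expect_lt(rel_err, 1e-6)
  }
})

test_that("memory trace invariants hold", {
  p <- dynr_params("exp2")
  cond <- list(set_size = 4, exposure = 0.3, delay = 0.1,
               simultaneous = FALSE)
  tr <- vwm_gain_trace(seq(0, 3, 0.01), p, cond)
  expect_true(all(tr$gamma_wm >= -1e-12))
  expect_true(all(tr$gamma_wm <= p$gamma_wm + 1e-9))
  expect_true(all(diff(tr$gamma_wm) >= -1e-9))  # input never removes signal
  # without sensory input the amplitude is constant
  p0 <- p; p0$gamma_s_max <- 1e-12
  tr0 <- vwm_gain_trace(seq(0, 2, 0.05), p0, cond, gamma_wm0 = 5)
  expect_equal(tr0$gamma_wm[-1], rep(5, sum(seq(0, 2, 0.05) > 0)),
               tolerance = 1e-6)
  # long pre-cue exposure saturates at the normalized ceiling
  pl <- dynr_params("exp2", tau_wm = 0.05)
  trl <- vwm_gain_trace(c(0, 4.999), pl,
                        list(set_size = 4, exposure = 5, delay = 0.1,
                             simultaneous = FALSE))
  expect_equal(trl$gamma_wm[2], pl$gamma_wm / 4, tolerance = 1e-6)
})

test_that("gain at decoding obeys its bounds and limits", {
  p <- dynr_params("exp1")
  cond <- function(N, delay, sim = FALSE) {
    list(set_size = N, exposure = 0.2, delay = delay, simultaneous = sim)
  }
  # one item: the full resource is already allocated; no early-cue benefit
  for (d in c(0, 0.1, 1)) {
    expect_equal(gain_at_decode(p, cond(1, d)), p$gamma_wm)
  }
  # late cue: the sensory trace has decayed, gain is the normalized share
  expect_equal(gain_at_decode(p, cond(4, 50)), p$gamma_wm / 4,
               tolerance = 1e-9)
  # simultaneous cue: maximum amplitude irrespective of set size
  expect_equal(gain_at_decode(p, cond(10, 0, sim = TRUE)), p$gamma_wm)
  # residual set-size effect at zero delay when cue processing takes time
  g0 <- gain_at_decode(p, cond(4, 0))
  expect_lt(g0, p$gamma_wm)
  expect_gt(g0, p$gamma_wm / 4)
  expect_equal(g0 / p$gamma_wm, 0.5117, tolerance = 1e-3)
  # monotone non-increasing in delay and in set size
  gd <- vapply(c(0, 0.1, 0.2, 0.4, 1), function(d) {
    gain_at_decode(p, cond(4, d))
  }, numeric(1))
  expect_true(all(diff(gd) < 0))
  gn <- vapply(c(1, 2, 4, 8, 10), function(N) {
    gain_at_decode(p, cond(N, 0.1))
  }, numeric(1))
  expect_true(all(diff(gn) < 0))
  # always within [gamma_wm/N, gamma_wm]
  set.seed(91)
  for (i in 1:40) {
    N <- sample(1:10, 1)
    pp <- dynr_params("exp1", tau_decay = runif(1, 0.05, 1),
                      tau_wm = runif(1, 0.02, 1), b = runif(1, 0, 0.5))
    g <- gain_at_decode(pp, cond(N, runif(1, 0, 2)))
    expect_gte(g, pp$gamma_wm / N - 1e-9)
    expect_lte(g, pp$gamma_wm + 1e-9)
  }
})

test_that("variant structure changes the decode gain as designed", {
  p <- dynr_params("exp1")
  cond <- list(set_size = 4, exposure = 0.2, delay = 0, simultaneous = FALSE)
  # fixed signal: no post-cue boost, gain pinned at the normalized share
  pf <- dynr_params("exp1", variant = dynr_variant("fixed_signal"))
  expect_equal(gain_at_decode(pf, cond), pf$gamma_wm / 4)
  # zero cue time: earlier identification, more sensory residue, more gain
  pz <- dynr_params("exp1", variant = dynr_variant("zero_cue_time"))
  expect_gt(gain_at_decode(pz, cond), gain_at_decode(p, cond))
  # direct read-out adds the sensory signal on the memory scale
  ps <- dynr_params("exp1", variant = dynr_variant("direct_readout"))
  c1 <- list(set_size = 1, exposure = 0.2, delay = 0, simultaneous = FALSE)
  expect_gt(gain_at_decode(ps, c1), p$gamma_wm)
  # constant accumulation reaches the same late-cue limit
  pc <- dynr_params("exp1", variant = dynr_variant("constant_accumulation"))
  expect_equal(gain_at_decode(pc, list(set_size = 4, exposure = 0.2,
                                       delay = 50, simultaneous = FALSE)),
               pc$gamma_wm / 4, tolerance = 1e-9)
})
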