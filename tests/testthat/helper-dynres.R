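# shared fixtures: one decode-density cache reused across test files
# (memoized in the package environment by default_decode_cache)

shared_cache <- function() default_decode_cache(100L)

# group ML parameter sets used as generating truth in recovery checks
exp1_truth <- function() dynr_params("exp1")
exp2_truth <- function() dynr_params("exp2")

# numeric Fisher information of the population code at theta = 0
numeric_fisher_info <- function(gain, cfg, h = 1e-5) {
  f0 <- tuning_response(0, gain, cfg)
  fp <- tuning_response(h, gain, cfg)
  fm <- tuning_response(-h, gain, cfg)
  sum(((fp - fm) / (2 * h))^2 / f0)
}

# brute-force grid maximizer of the exact Poisson log-likelihood
grid_decode <- function(spikes, gain, cfg, n_grid = 1e4) {
  grid <- seq(-pi, pi, length.out = n_grid + 1)[seq_len(n_grid)]
  logF <- outer(cfg$preferred, grid, function(ph, th) {
    cfg$kappa * (cos(th - ph) - 1)
  }) + log(gain / cfg$n_neurons)
  ll <- as.numeric(crossprod(spikes, logF)) - colSums(exp(logF))
  grid[which.max(ll)]
}

# total-variation distance between two binned densities on error_grid(n)
tv_dist <- function(d1, d2) {
  n <- length(d1)
  0.5 * sum(abs(d1 - d2)) * 2 * pi / n
}

# histogram density of errors on error_grid(n_bins)
error_hist_density <- function(err, n_bins = 360L) {
  h <- 2 * pi / n_bins
  bins <- pmin(pmax(floor((wrap_pi(err) + pi) / h) + 1, 1L), n_bins)
  tabulate(bins, nbins = n_bins) / (length(err) * h)
}
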