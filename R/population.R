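#' Idealized orientation-tuned population code
#'
#' Configuration of the population that represents a single feature value:
#' `n_neurons` neurons with von-Mises-shaped tuning of width `kappa`, their
#' preferred values evenly spaced over the doubled-angle circle
#' \eqn{[-\pi, \pi)}. The mean response of neuron *i* to feature
#' \eqn{\theta} at population gain \eqn{\gamma} is
#' \deqn{f_i(\theta, \gamma) = \frac{\gamma}{n}
#'   \exp\{\kappa(\cos(\theta - \varphi_i) - 1)\}.}
#'
#' @param n_neurons number of neurons (>= 8). The default of 100 is not a
#'   critical choice; decode densities are insensitive to it for
#'   `n_neurons >= 50`.
#' @param kappa tuning-curve concentration (> 0).
#' @return object of class `pop_config` with elements `n_neurons`, `kappa`,
#'   `preferred`.
#' @examples
#' cfg <- pop_config(kappa = 3.21)
#' r <- tuning_response(0, gain = 59.8, cfg)
#' sum(r)  # expected total spike count, gain_total(59.8, cfg)
#' @export
pop_config <- function(n_neurons = 100L, kappa = 3.21) {
  n_neurons <- as.integer(n_neurons)
  stopifnot(n_neurons >= 8L, kappa > 0)
  structure(
    list(
      n_neurons = n_neurons,
      kappa = kappa,
      preferred = seq(-pi, pi, length.out = n_neurons + 1L)[seq_len(n_neurons)]
    ),
    class = "pop_config"
  )
}

#' @export
print.pop_config <- function(x, ...) {
  cat(sprintf("Population code: %d neurons, kappa = %g\n", x$n_neurons, x$kappa))
  invisible(x)
}

#' Mean firing rates of the tuned population
#'
#' @param theta encoded feature value (doubled radians).
#' @param gain population gain \eqn{\gamma \ge 0}.
#' @param cfg a [pop_config()].
#' @return vector of `cfg$n_neurons` mean rates.
#' @export
tuning_response <- function(theta, gain, cfg) {
  if (gain < 0) stop("gain must be non-negative")
  (gain / cfg$n_neurons) * exp(cfg$kappa * (cos(theta - cfg$preferred) - 1))
}

#' Expected total spike count at a given gain
#'
#' Sum of the tuning curves, \eqn{\gamma \, e^{-\kappa} I_0(\kappa)} up to
#' the (negligible for `n_neurons >= 50`) discretization of the preferred
#' values; independent of the encoded value.
#'
#' @inheritParams tuning_response
#' @export
gain_total <- function(gain, cfg) {
  gain * mean(exp(cfg$kappa * (cos(cfg$preferred) - 1)))
}

#' Draw a Poisson spike pattern
#'
#' Each neuron's count is an independent Poisson draw with the given mean.
#' Reproducible under `set.seed()`.
#'
#' @param rates non-negative mean rates.
#' @return integer vector of spike counts.
#' @export
sample_spikes <- function(rates) {
  stopifnot(all(rates >= 0))
  stats::rpois(length(rates), rates)
}

#' Maximum-likelihood decoding of a spike pattern
#'
#' The Poisson log-likelihood of \eqn{\theta} given counts \eqn{r_i} is
#' \eqn{\sum_i r_i \log f_i(\theta) - \sum_i f_i(\theta)}; with evenly spaced
#' preferred values the second term is constant in \eqn{\theta} (up to
#' discretization) and the maximizer is the direction of the spike-weighted
#' resultant \eqn{\sum_i r_i (\cos\varphi_i, \sin\varphi_i)}. A pattern with
#' zero total spikes carries a flat likelihood: the estimate is drawn
#' uniformly on the circle and flagged as a guess.
#'
#' @param spikes integer spike counts (length `cfg$n_neurons`).
#' @param cfg a [pop_config()].
#' @return list with `theta_hat` (doubled radians) and `is_guess`.
#' @export
ml_decode <- function(spikes, cfg) {
  stopifnot(length(spikes) == cfg$n_neurons, all(spikes >= 0))
  if (sum(spikes) == 0) {
    return(list(theta_hat = stats::runif(1, -pi, pi), is_guess = TRUE))
  }
  list(
    theta_hat = atan2(sum(spikes * sin(cfg$preferred)),
                      sum(spikes * cos(cfg$preferred))),
    is_guess = FALSE
  )
}

# Vectorized decode-error sampler used by the simulator and the density
# estimator. Draws `n` independent encode->decode rounds at encoded values
# `theta` (recycled) and gain(s) `gain` (recycled), returning the decoded
# angle. Exploits the Poisson thinning identity: total count T ~
# Poisson(gain_total), spike positions i.i.d. across neurons with probability
# proportional to the tuning profile; the resultant of the spike unit vectors
# is the ML estimate. Zero-count rounds decode to a uniform draw.
decode_draws <- function(n, theta, gain, cfg) {
  theta <- rep_len(theta, n)
  gain <- rep_len(gain, n)
  gt <- gain * mean(exp(cfg$kappa * (cos(cfg$preferred) - 1)))
  tot <- stats::rpois(n, gt)
  out <- numeric(n)
  guess <- tot == 0L
  out[guess] <- stats::runif(sum(guess), -pi, pi)
  live <- which(!guess)
  if (length(live)) {
    # spike angles relative to the encoded value; the tuning profile is
    # sampled at the neuron offsets (preferred - theta). For efficiency all
    # rounds share the offset grid anchored at theta = 0, which is exact up
    # to the preferred-value discretization; decoded angle = theta + offset
    # resultant.
    w <- exp(cfg$kappa * (cos(cfg$preferred) - 1))
    tt <- tot[live]
    idx <- sample.int(cfg$n_neurons, sum(tt), replace = TRUE, prob = w)
    cs <- cumsum(cos(cfg$preferred[idx]))
    sn <- cumsum(sin(cfg$preferred[idx]))
    ends <- cumsum(tt)
    starts <- ends - tt
    csum <- cs[ends] - c(0, cs[starts[-1]])
    ssum <- sn[ends] - c(0, sn[starts[-1]])
    out[live] <- wrap_pi(theta[live] + atan2(ssum, csum))
  }
  list(theta_hat = out, is_guess = guess)
}

#' Monte-Carlo decode-error density at a given gain
#'
#' Simulates encode-decode rounds at a fixed encoded value (translation
#' invariance makes the choice irrelevant) and tabulates the decoding error
#' \eqn{\hat\theta - \theta} on a fixed circular grid. The uniform component
#' contributed by zero-spike guesses is mixed in analytically with its exact
#' weight \eqn{e^{-\gamma_{\rm tot}}}, so no samples are wasted on guesses.
#'
#' @param gain population gain \eqn{\gamma \ge 0}. `gain = 0` returns the
#'   exact uniform density.
#' @param cfg a [pop_config()].
#' @param n_samples Monte-Carlo rounds (>= 1e4 recommended for fitting-grade
#'   densities).
#' @param n_bins bins on the circle.
#' @return object of class `decode_density`: list with `gain`, `grid`
#'   (bin centers, doubled radians), `density` (per radian), `p_guess`,
#'   `n_samples`.
#' @export
decode_error_density <- function(gain, cfg, n_samples = 2e4, n_bins = 360L) {
  stopifnot(gain >= 0)
  grid <- error_grid(n_bins)
  h <- 2 * pi / n_bins
  gt <- gain_total(gain, cfg)
  p0 <- exp(-gt)
  if (gain == 0 || p0 > 1 - 1e-12) {
    dens <- rep(1 / (2 * pi), n_bins)
    return(structure(list(gain = gain, grid = grid, density = dens,
                          p_guess = 1, n_samples = 0L),
                     class = "decode_density"))
  }
  # conditional (>=1 spike) sample: draw totals, drop zeros
  n_samples <- as.integer(n_samples)
  tot <- stats::rpois(n_samples, gt)
  tot <- tot[tot > 0L]
  w <- exp(cfg$kappa * (cos(cfg$preferred) - 1))
  idx <- sample.int(cfg$n_neurons, sum(tot), replace = TRUE, prob = w)
  cs <- cumsum(cos(cfg$preferred[idx]))
  sn <- cumsum(sin(cfg$preferred[idx]))
  ends <- cumsum(tot)
  starts <- ends - tot
  csum <- cs[ends] - c(0, cs[starts[-1]])
  ssum <- sn[ends] - c(0, sn[starts[-1]])
  err <- atan2(ssum, csum)
  # at small total counts the error distribution has atoms exactly on
  # neuron angles, some of which coincide with bin edges; round before
  # binning so edge assignment is reproducible across samplers
  bins <- pmin(pmax(floor((round(err, 9) + pi) / h) + 1, 1L), n_bins)
  counts <- tabulate(bins, nbins = n_bins)
  cond <- counts / (sum(counts) * h)
  dens <- p0 / (2 * pi) + (1 - p0) * cond
  structure(list(gain = gain, grid = grid, density = dens, p_guess = p0,
                 n_samples = n_samples),
            class = "decode_density")
}

#' @export
print.decode_density <- function(x, ...) {
  cat(sprintf(
    "Decode-error density: gain %.3g, %d bins, %g MC rounds, p(guess) %.3g\n",
    x$gain, length(x$grid), x$n_samples, x$p_guess))
  cat(sprintf("  circular dispersion (-2 log R): %.4g rad^2 (doubled space)\n",
              circ_dispersion(x$grid, x$density)))
  invisible(x)
}
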