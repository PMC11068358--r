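#' Accumulated diffusion variance of a stored feature
#'
#' Stored feature values drift as Brownian motion from stimulus offset, so
#' the wrapped-normal variance grows linearly with elapsed retention time:
#' \eqn{\sigma^2 = \max(0, t - t_{offset})\,\dot\sigma^2_{diff}} (times N
#' for the set-size-scaled variant). The model evaluates diffusion once, at
#' the cue identification time \eqn{t^*_{cue}}: diffusion is slow relative
#' to sensory decay, so drift during the brief post-cue accumulation window
#' is neglected. Negative elapsed times (a cue resolved before offset)
#' clamp to zero.
#'
#' @param t evaluation time, normally \eqn{t^*_{cue}} (s).
#' @param t_offset stimulus offset time (s).
#' @param N set size.
#' @param rate base diffusion rate (doubled rad^2 / s).
#' @param scale_with_set_size multiply the rate by `N`?
#' @return variance in doubled rad^2.
#' @export
diffusion_variance <- function(t, t_offset, N, rate,
                               scale_with_set_size = FALSE) {
  stopifnot(rate >= 0, N >= 1)
  v <- pmax(0, t - t_offset) * rate
  if (scale_with_set_size) v <- v * N
  v
}

#' Apply diffusion noise to a stored feature value
#'
#' @param theta true feature value(s), doubled radians.
#' @param sigma2 wrapped-normal variance (doubled rad^2).
#' @return diffused value(s) wrapped to \eqn{[-\pi, \pi)}.
#' @export
apply_diffusion <- function(theta, sigma2) {
  stopifnot(sigma2 >= 0)
  rwrapped_normal(length(theta), theta, sigma2)
}

#' Probability of reporting a non-target (swap error)
#'
#' Swap errors arise from uncertainty in memory for the items' locations
#' (the cue dimension), which mirrors the dynamics of the report feature:
#' spatial uncertainty shrinks exponentially with presentation duration and
#' grows with retention. The law is
#' \deqn{p_{swap} = (N-1)\left[(1/N - q)\, e^{-t_{offset}/\tau_{spatial}}
#'   + q\right]}
#' with the retention term \eqn{q} floored at 0 inside the bracket and the
#' result clipped to \eqn{[0, 1]}. Two parameterizations are supported:
#'
#' * `constant_p` set: a constant total swap probability
#'   `constant_p * (N > 1)`, the parameterization used for fixed-exposure
#'   fits where exposure never varies;
#' * otherwise the exposure-dependent law above, with `q = p_late /
#'   max(N - 1, 1)` so that `p_late` is the asymptotic (long-exposure) total
#'   swap probability for every set size.
#'
#' @param N set size (>= 1). Always returns 0 for `N = 1`.
#' @param t_offset presentation duration (s).
#' @param tau_spatial exposure time constant (s).
#' @param p_late asymptotic total swap probability (retention term folded
#'   into a scalar; the cue delay is fixed in the masked design).
#' @param constant_p optional constant total swap probability overriding the
#'   dynamic law.
#' @return swap probability in \eqn{[0, 1]}.
#' @examples
#' swap_probability(4, t_offset = 0.03, tau_spatial = 0.013, p_late = 0.03)
#' swap_probability(4, constant_p = 0.027)
#' @export
swap_probability <- function(N, t_offset = NULL, tau_spatial = NULL,
                             p_late = NULL, constant_p = NULL) {
  stopifnot(N >= 1)
  if (N == 1) return(0)
  if (!is.null(constant_p)) {
    stopifnot(constant_p >= 0, constant_p <= 1)
    return(constant_p)
  }
  stopifnot(!is.null(t_offset), !is.null(tau_spatial), !is.null(p_late),
            tau_spatial > 0, p_late >= 0)
  q <- p_late / (N - 1)
  inner <- pmax(0, 1 / N - q) * exp(-t_offset / tau_spatial) + q
  min(max((N - 1) * inner, 0), 1)
}

# swap probability for a condition under a parameter object
cond_swap_probability <- function(p, cond, t_star) {
  if (isTRUE(cond$simultaneous)) return(0)  # perceptual report, no misbinding
  if (cond$set_size == 1) return(0)
  if (p$experiment == "exp1") {
    swap_probability(cond$set_size, constant_p = p$swap_p)
  } else {
    swap_probability(cond$set_size, t_offset = cond$exposure,
                     tau_spatial = p$tau_spatial, p_late = p$swap_p)
  }
}
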