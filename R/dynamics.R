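#' Sensory signal amplitude under low-pass temporal filtering
#'
#' The sensory population's response to a stimulus step of duration
#' `t_offset` rises exponentially toward the maximum amplitude with time
#' constant `tau_rise` and, after offset, decays exponentially with constant
#' `tau_decay` from the amplitude attained at offset. `tau_rise = 0` gives
#' the instantaneous-rise limit (amplitude at the maximum throughout the
#' exposure). If the signal does not persist beyond offset (a backward mask
#' that terminates sensory processing), the amplitude is 0 for
#' `t > t_offset`.
#'
#' @param t time(s) since stimulus onset (s), vectorized.
#' @param tau_rise,tau_decay filter time constants (s); `tau_rise >= 0`,
#'   `tau_decay > 0`.
#' @param t_offset stimulus offset time (s).
#' @param gamma_s_max maximum sensory amplitude (fixed at 1 by convention).
#' @param persists does activity outlast the offset?
#' @return amplitude at each `t`.
#' @export
sensory_gain <- function(t, tau_rise, tau_decay, t_offset,
                         gamma_s_max = 1, persists = TRUE) {
  stopifnot(tau_rise >= 0, tau_decay > 0, t_offset >= 0)
  rise <- function(x) {
    if (tau_rise == 0) gamma_s_max * as.numeric(x > 0)
    else gamma_s_max * (1 - exp(-x / tau_rise))
  }
  a_off <- rise(t_offset)
  out <- numeric(length(t))
  pre <- t <= t_offset
  out[pre] <- rise(t[pre])
  if (any(!pre)) {
    out[!pre] <- if (persists) {
      a_off * exp(-(t[!pre] - t_offset) / tau_decay)
    } else 0
  }
  out[t < 0] <- 0
  out
}

# integral of the sensory amplitude over [t1, t2] (t2 may be Inf);
# closed form per phase.
sensory_integral <- function(t1, t2, tau_rise, tau_decay, t_offset,
                             gamma_s_max = 1, persists = TRUE) {
  stopifnot(t1 <= t2, t1 >= 0)
  rise_int <- function(x) {
    # integral of rise amplitude over [0, x], x <= t_offset
    if (tau_rise == 0) gamma_s_max * x
    else gamma_s_max * (x - tau_rise * (1 - exp(-x / tau_rise)))
  }
  a_off <- if (tau_rise == 0) gamma_s_max else
    gamma_s_max * (1 - exp(-t_offset / tau_rise))
  decay_int <- function(a, b) {
    # integral of decay amplitude over [a, b], a,b >= t_offset
    if (!persists) return(0)
    eb <- if (is.infinite(b)) 0 else exp(-(b - t_offset) / tau_decay)
    a_off * tau_decay * (exp(-(a - t_offset) / tau_decay) - eb)
  }
  lo <- min(t1, t_offset); hi <- min(t2, t_offset)
  out <- rise_int(hi) - rise_int(lo)
  if (t2 > t_offset) out <- out + decay_int(max(t1, t_offset), t2)
  out
}

#' Time at which the cued item is identified
#'
#' Cue interpretation takes time that grows logarithmically with the number
#' of alternatives (Hick's law): \eqn{t^*_{cue} = t_{cue} + b \log_2 N}.
#' Variants: `"zero"` ignores cue processing time, `"constant"` adds `b`
#' seconds independent of set size.
#'
#' @param t_cue cue onset time (s since stimulus onset).
#' @param N set size (>= 1).
#' @param b scaling constant (s per bit, or s for the `"constant"` mode).
#' @param mode `"hicks"`, `"zero"`, or `"constant"`.
#' @return identification time \eqn{t^*_{cue}} (s).
#' @export
cue_identification_time <- function(t_cue, N, b, mode = "hicks") {
  stopifnot(N >= 1, b >= 0)
  switch(mode,
    hicks = t_cue + b * log2(N),
    zero = t_cue,
    constant = t_cue + b,
    stop("unknown cue-time mode '", mode, "'")
  )
}

#' Number of items represented in memory at time t
#'
#' All `N` items compete for the normalized signal until the cued item is
#' identified at `t_star`; afterwards only the cued item is retained. The
#' boundary instant belongs to the pre-cue regime.
#'
#' @param t time(s), vectorized.
#' @param N set size.
#' @param t_star cue identification time from [cue_identification_time()].
#' @return integer vector of item counts.
#' @export
items_in_memory <- function(t, N, t_star) {
  ifelse(t <= t_star, as.integer(N), 1L)
}

# timing of a condition: offset and cue onset in seconds since stimulus onset
condition_times <- function(cond) {
  t_offset <- cond$exposure
  t_cue <- if (isTRUE(cond$simultaneous)) 0 else t_offset + cond$delay
  list(t_offset = t_offset, t_cue = t_cue)
}

#' Closed-form trace of sensory and memory signal amplitudes
#'
#' Solves the accumulation dynamics
#' \deqn{\dot\gamma_{wm}(t) = \gamma_s(t)\,
#'   (\check\gamma_{wm}/M(t) - \gamma_{wm}(t))/\tau_{wm}}
#' piecewise in closed form (the equation is linear in \eqn{\gamma_{wm}}
#' with integrating factor \eqn{\exp(\int \gamma_s\,dt/\tau_{wm})}, and the
#' sensory integral has a closed form in each phase). For the
#' constant-accumulation variant the rate is
#' \eqn{\gamma_s(t)/(M(t)\tau_{wm})} up to the normalized ceiling.
#'
#' @param times sorted sample times starting at 0 (s).
#' @param p a [dynr_params()].
#' @param cond a single condition: list or one-row data frame with
#'   `set_size`, `exposure`, `delay`, `simultaneous`.
#' @param gamma_wm0 initial memory amplitude at `t = 0`.
#' @return data frame with columns `time`, `gamma_s`, `gamma_wm`.
#' @examples
#' p <- dynr_params("exp2")
#' tr <- vwm_gain_trace(seq(0, 1, 0.01), p,
#'                      list(set_size = 4, exposure = 0.2, delay = 0.1,
#'                           simultaneous = FALSE))
#' @export
vwm_gain_trace <- function(times, p, cond, gamma_wm0 = 0) {
  stopifnot(!is.unsorted(times), times[1] >= 0)
  tm <- condition_times(cond)
  N <- cond$set_size
  t_star <- cue_identification_time(tm$t_cue, N, p$b, p$variant$cue_time)
  s_int <- function(a, b) sensory_integral(
    a, b, p$tau_rise, p$tau_decay, tm$t_offset, p$gamma_s_max,
    persists = p$variant$sensory_persists)
  gs <- sensory_gain(times, p$tau_rise, p$tau_decay, tm$t_offset,
                     p$gamma_s_max, persists = p$variant$sensory_persists)

  linear <- identical(p$variant$accumulation, "linear")
  gwm <- numeric(length(times))
  # segment boundaries where M or the sensory phase changes
  brks <- sort(unique(c(0, tm$t_offset, max(t_star, 0))))
  brks <- brks[brks >= 0]
  state_t <- 0
  state_g <- gamma_wm0
  seg_ends <- c(brks[-1], Inf)
  for (s in seq_along(brks)) {
    a <- brks[s]; bnd <- seg_ends[s]
    # segment (a, bnd]; t = t_star itself belongs to the pre-cue regime,
    # so a segment that starts at t_star is post-cue
    M <- items_in_memory(a + 1e-12, N, t_star)
    ceiling_ <- p$gamma_wm / M
    sel <- which(times > a & times <= bnd)
    if (length(sel)) {
      S <- vapply(times[sel], function(tt) s_int(a, tt), numeric(1))
      gwm[sel] <- if (linear) {
        pmin(ceiling_, state_g + S / (M * p$tau_wm))
      } else {
        ceiling_ - (ceiling_ - state_g) * exp(-S / p$tau_wm)
      }
    }
    if (is.finite(bnd)) {
      Sfull <- s_int(a, bnd)
      state_g <- if (linear) {
        min(ceiling_, state_g + Sfull / (M * p$tau_wm))
      } else {
        ceiling_ - (ceiling_ - state_g) * exp(-Sfull / p$tau_wm)
      }
      state_t <- bnd
    }
  }
  gwm[times == 0] <- gamma_wm0
  data.frame(time = times, gamma_s = gs, gamma_wm = gwm)
}

#' Memory signal amplitude available at decoding
#'
#' The asymptotic post-cue amplitude: once the cued item is identified the
#' normalization ceiling rises to \eqn{\check\gamma_{wm}} and the residual
#' sensory trace is accumulated until it has fully decayed. In the
#' fixed-exposure design, initial encoding is assumed complete by stimulus
#' offset (\eqn{\gamma_{wm}(t_{offset}) = \check\gamma_{wm}/N}); in the
#' variable-exposure design the pre-cue amplitude is accumulated
#' dynamically from onset. A simultaneous cue yields the maximum amplitude
#' \eqn{\check\gamma_{wm}} irrespective of set size (only the cued feature
#' is encoded). For the direct-read-out variant the returned gain is the sum
#' of memory and sensory activity at cue identification, with the sensory
#' population expressed on the memory spike-count scale.
#'
#' @inheritParams vwm_gain_trace
#' @param encoding `"auto"` (complete-at-offset for `"exp1"`, dynamic for
#'   `"exp2"`), `"complete"`, or `"dynamic"`; exposed for sensitivity
#'   checks.
#' @return scalar gain \eqn{\gamma^*_{wm}}; never exceeds
#'   \eqn{\check\gamma_{wm}} for the memory read-out.
#' @examples
#' p <- dynr_params("exp1")
#' gain_at_decode(p, list(set_size = 4, exposure = 0.2, delay = 0,
#'                        simultaneous = FALSE))
#' @export
gain_at_decode <- function(p, cond, encoding = c("auto", "complete", "dynamic")) {
  encoding <- match.arg(encoding)
  if (encoding == "auto") {
    encoding <- if (p$experiment == "exp1") "complete" else "dynamic"
  }
  tm <- condition_times(cond)
  N <- cond$set_size
  sum_readout <- identical(p$variant$readout, "sum")
  if (isTRUE(cond$simultaneous) && !sum_readout) {
    return(p$gamma_wm)
  }
  t_star <- cue_identification_time(tm$t_cue, N, p$b, p$variant$cue_time)
  t_star <- max(t_star, 0)
  linear <- identical(p$variant$accumulation, "linear")
  s_int <- function(a, b) sensory_integral(
    a, b, p$tau_rise, p$tau_decay, tm$t_offset, p$gamma_s_max,
    persists = p$variant$sensory_persists)

  # amplitude of the cued item's representation at cue identification
  g_star <- if (encoding == "complete") {
    if (t_star >= tm$t_offset) p$gamma_wm / N else p$gamma_wm / N
  } else {
    ceiling_pre <- p$gamma_wm / N
    S <- s_int(0, t_star)
    if (linear) min(ceiling_pre, S / (N * p$tau_wm))
    else ceiling_pre * (1 - exp(-S / p$tau_wm))
  }

  if (sum_readout) {
    gs <- sensory_gain(t_star, p$tau_rise, p$tau_decay, tm$t_offset,
                       p$gamma_s_max, persists = p$variant$sensory_persists)
    base <- if (isTRUE(cond$simultaneous)) p$gamma_wm else g_star
    return(base + p$gamma_wm * gs / p$gamma_s_max)
  }

  S_inf <- s_int(max(t_star, tm$t_offset), Inf)
  if (t_star < tm$t_offset) {
    # cue identified while the stimulus is still visible: remaining rise
    # phase also feeds the boosted ceiling
    S_inf <- S_inf + s_int(t_star, tm$t_offset)
  }
  out <- if (linear) {
    min(p$gamma_wm, g_star + S_inf / p$tau_wm)
  } else {
    p$gamma_wm - (p$gamma_wm - g_star) * exp(-S_inf / p$tau_wm)
  }
  min(out, p$gamma_wm)
}
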