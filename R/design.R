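#' Build the trial conditions of a standard delayed-estimation design
#'
#' Two designs are built in, crossing set sizes \{1, 4, 10\} with timing
#' cells:
#'
#' * `"exp1"`: fixed 200 ms exposure; cue after a blank delay of 0, 100,
#'   200, 400, or 1000 ms, plus a simultaneous-cue (perceptual) condition —
#'   6 timing cells.
#' * `"exp2"`: variable exposure of 30, 48, 77, 122, 196, 313, or 500 ms,
#'   followed by a 100 ms backward mask; the cue replaces the mask, so cue
#'   onset is offset + 0.1 s — 7 timing cells.
#'
#' Orientations (the target and any non-targets) are drawn independently
#' and uniformly on the orientation circle at simulation time, not here.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param trials_per_cell number of trials per (set size x timing) cell.
#' @param set_sizes set sizes to cross with the timing cells.
#' @return data frame of conditions with columns `set_size`, `exposure`,
#'   `delay`, `simultaneous`, `trials`.
#' @examples
#' nrow(make_design("exp1"))  # 18 conditions
#' nrow(make_design("exp2"))  # 21 conditions
#' @export
make_design <- function(experiment = c("exp1", "exp2"), trials_per_cell = 1L,
                        set_sizes = c(1L, 4L, 10L)) {
  experiment <- match.arg(experiment)
  stopifnot(trials_per_cell >= 1)
  if (experiment == "exp1") {
    timing <- data.frame(
      exposure = 0.2,
      delay = c(0, 0.1, 0.2, 0.4, 1.0, 0),
      simultaneous = c(rep(FALSE, 5), TRUE)
    )
  } else {
    timing <- data.frame(
      exposure = c(0.030, 0.048, 0.077, 0.122, 0.196, 0.313, 0.500),
      delay = 0.1,
      simultaneous = FALSE
    )
  }
  out <- merge(data.frame(set_size = as.integer(set_sizes)), timing)
  out <- out[order(out$set_size, out$simultaneous, out$exposure, out$delay), ]
  rownames(out) <- NULL
  out$trials <- as.integer(trials_per_cell)
  out$experiment <- experiment
  out
}

# per-condition latent quantities of the generative model
condition_latents <- function(p, cond) {
  tm <- condition_times(cond)
  t_star <- if (isTRUE(cond$simultaneous)) {
    cue_identification_time(0, cond$set_size, p$b, p$variant$cue_time)
  } else {
    cue_identification_time(tm$t_cue, cond$set_size, p$b, p$variant$cue_time)
  }
  sigma2 <- if (isTRUE(cond$simultaneous)) 0 else {
    diffusion_variance(
      t_star, tm$t_offset, cond$set_size,
      rate = if (identical(p$variant$diffusion, "none")) 0 else p$diff_rate,
      scale_with_set_size = identical(p$variant$diffusion, "scaled"))
  }
  list(
    t_star = t_star,
    gain = gain_at_decode(p, cond),
    sigma2 = sigma2,
    p_swap = cond_swap_probability(p, cond, t_star)
  )
}
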