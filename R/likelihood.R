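#' Predicted error density for one condition
#'
#' Composes the model's components into the predicted circular density of
#' report errors for a condition: the decode-error density at the
#' condition's gain at decoding, circularly convolved with the wrapped
#' normal of the accumulated diffusion variance, mixed with a swap
#' component weighted by the condition's swap probability. The swap
#' component is the same smeared kernel centred on each non-target's offset
#' from the target when offsets are supplied, and the uniform marginal
#' otherwise (non-target features are independently uniform in the standard
#' designs, so the marginal swap density is exactly uniform).
#'
#' @param cond condition: list or one-row data frame with `set_size`,
#'   `exposure`, `delay`, `simultaneous`.
#' @param p a [dynr_params()].
#' @param cache optional [build_decode_cache()] table; if supplied the
#'   decode kernel is interpolated from it, otherwise (`exact` path) a
#'   fresh Monte-Carlo density is computed at the condition's exact gain.
#' @param nontarget_offsets optional non-target minus target offsets
#'   (doubled radians) for a location-specific swap component.
#' @param n_samples Monte-Carlo rounds for the exact path.
#' @param n_bins circular bins (exact path; the cache fixes its own).
#' @return object of class `dynr_density`: list with `grid`, `density`,
#'   `target` and `swap` component densities, `p_swap`, `latents`.
#' @examples
#' p <- dynr_params("exp1")
#' pd <- predict_error_density(list(set_size = 4, exposure = 0.2,
#'                                  delay = 0.2, simultaneous = FALSE), p)
#' sum(pd$density) * 2 * pi / length(pd$grid)  # integrates to 1
#' @export
predict_error_density <- function(cond, p, cache = NULL,
                                  nontarget_offsets = NULL,
                                  n_samples = 1e5, n_bins = 360L) {
  lat <- condition_latents(p, cond)
  if (is.null(cache)) {
    cfg <- pop_config(p$n_neurons, p$kappa)
    kern <- decode_error_density(lat$gain, cfg, n_samples = n_samples,
                                 n_bins = n_bins)$density
    grid <- error_grid(n_bins)
  } else {
    kern <- cached_decode_density(lat$gain, p$kappa, cache)
    grid <- cache$grid
  }
  kern <- conv_wrapped_normal(kern, lat$sigma2)
  swap_dens <- if (lat$p_swap > 0 && !is.null(nontarget_offsets) &&
                   length(nontarget_offsets)) {
    Reduce(`+`, lapply(nontarget_offsets, function(d) {
      interp_circular(grid, kern, grid - d)
    })) / length(nontarget_offsets)
  } else {
    rep(1 / (2 * pi), length(grid))
  }
  dens <- (1 - lat$p_swap) * kern + lat$p_swap * swap_dens
  dens <- dens / (sum(dens) * 2 * pi / length(grid))
  structure(
    list(grid = grid, density = dens, target = kern, swap = swap_dens,
         p_swap = lat$p_swap, latents = lat, condition = cond),
    class = "dynr_density"
  )
}

#' @export
print.dynr_density <- function(x, ...) {
  cat(sprintf(
    "Predicted error density: N=%d, exposure %.3g s, delay %.3g s%s\n",
    x$condition$set_size, x$condition$exposure, x$condition$delay,
    if (isTRUE(x$condition$simultaneous)) " (simultaneous cue)" else ""))
  cat(sprintf("  gain %.3g, diffusion var %.3g, p(swap) %.3g, RMSE %.3g deg\n",
              x$latents$gain, x$latents$sigma2, x$p_swap, density_rmse_deg(x)))
  invisible(x)
}

#' Root-mean-square error implied by a predicted density
#'
#' @param x a `dynr_density`.
#' @return RMSE in orientation degrees.
#' @export
density_rmse_deg <- function(x) {
  h <- 2 * pi / length(x$grid)
  sqrt(sum(x$density * h * rad_to_err_deg(x$grid)^2))
}

# group trials into condition cells; returns list of (cond, rows)
split_conditions <- function(trials) {
  key <- interaction(trials$set_size, trials$exposure, trials$delay,
                     trials$simultaneous, drop = TRUE)
  lapply(split(seq_len(nrow(trials)), key), function(idx) {
    r1 <- trials[idx[1], ]
    list(cond = list(set_size = r1$set_size, exposure = r1$exposure,
                     delay = r1$delay, simultaneous = r1$simultaneous),
         rows = idx)
  })
}

# precompute everything the objective needs per condition cell, so repeated
# likelihood evaluations during optimization touch no data frames
prepare_nll <- function(trials, swap_component = "uniform") {
  use_nt <- identical(swap_component, "nontargets") &&
    "nontargets" %in% names(trials)
  nt_list <- if (use_nt) parse_nontargets(trials$nontargets) else NULL
  lapply(split_conditions(trials), function(cell) {
    err <- trials$error[cell$rows]
    swap_at <- NULL; swap_idx <- NULL; swap_len <- NULL
    if (use_nt && cell$cond$set_size > 1) {
      tgt <- trials$target[cell$rows]
      offs <- lapply(seq_along(cell$rows), function(j) {
        wrap_pi(nt_list[[cell$rows[j]]] - tgt[j])
      })
      swap_len <- lengths(offs)
      swap_idx <- rep(seq_along(err), swap_len)
      # error relative to each non-target: evaluate the kernel there
      swap_at <- err[swap_idx] - unlist(offs)
    }
    list(cond = cell$cond, err = err, swap_at = swap_at,
         swap_idx = swap_idx, swap_len = swap_len, n = length(err))
  })
}

# likelihood core on a prepared cell structure
nll_prepared <- function(prep, p, cache, floor = 1e-10) {
  nll <- 0
  n_floored <- 0L
  for (cell in prep) {
    lat <- condition_latents(p, cell$cond)
    kern <- cached_decode_density(lat$gain, p$kappa, cache)
    kern <- conv_wrapped_normal(kern, lat$sigma2)
    f_t <- interp_circular(cache$grid, kern, cell$err)
    if (lat$p_swap > 0) {
      f_s <- if (!is.null(cell$swap_at)) {
        as.numeric(rowsum(interp_circular(cache$grid, kern, cell$swap_at),
                          cell$swap_idx)) / cell$swap_len
      } else {
        1 / (2 * pi)
      }
      f <- (1 - lat$p_swap) * f_t + lat$p_swap * f_s
    } else {
      f <- f_t
    }
    bad <- !is.finite(f) | f < floor
    if (any(bad)) {
      n_floored <- n_floored + sum(bad)
      f[bad] <- floor
    }
    nll <- nll - sum(log(f))
  }
  attr(nll, "n_floored") <- n_floored
  nll
}

#' Negative log-likelihood of a trial table
#'
#' Per-trial circular-density likelihood of the observed wrapped errors:
#' \eqn{-\sum_i \log f(\mathrm{error}_i \mid \mathrm{condition}_i)}, with
#' densities built per condition cell from the decode cache. With
#' `swap_component = "nontargets"` the swap term uses each trial's own
#' non-target offsets; the default `"uniform"` uses the exact uniform
#' marginal (non-targets are i.i.d. uniform in the standard designs).
#' Non-finite densities are floored at a small positive constant with a
#' warning.
#'
#' @param trials trial table with `error` in doubled radians.
#' @param p a [dynr_params()].
#' @param cache decode-density cache; built on demand if `NULL`.
#' @param swap_component `"uniform"` or `"nontargets"`.
#' @param floor density floor.
#' @return scalar negative log-likelihood (nats, doubled-radian measure).
#' @export
dynr_nll <- function(trials, p, cache = NULL,
                     swap_component = c("uniform", "nontargets"),
                     floor = 1e-10) {
  swap_component <- match.arg(swap_component)
  if (is.null(cache)) cache <- default_decode_cache(p$n_neurons)
  prep <- prepare_nll(trials, swap_component)
  out <- nll_prepared(prep, p, cache, floor)
  if (attr(out, "n_floored") > 0L) {
    warning(sprintf("floored %d trial densities at %g",
                    attr(out, "n_floored"), floor))
  }
  as.numeric(out)
}
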