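# package-level cache environment for decode-error density tables
.dynr_env <- new.env(parent = emptyenv())

#' Tabulated decode-error densities
#'
#' Fitting needs thousands of decode-error density evaluations at arbitrary
#' gains and tuning widths. The decoded error given a *total* spike count
#' \eqn{T} does not depend on the gain: spike positions are i.i.d. across
#' neurons with probability proportional to the tuning profile, so only the
#' Poisson weight of each \eqn{T} moves with gain. The cache therefore
#' tabulates, for each tuning width on a log-spaced grid, the conditional
#' error densities \eqn{g_T(\varepsilon)} for \eqn{T = 1, \dots, T_{max}}
#' by stratified Monte-Carlo (one running resultant per sample stream,
#' histogrammed at every \eqn{T}), under a fixed internal RNG stream. A
#' density at arbitrary `(gain, kappa)` is then the exact Poisson mixture
#' over \eqn{T} (including the analytic uniform guess component at
#' \eqn{T = 0}) at the two neighbouring kappa nodes, interpolated linearly
#' in log kappa. Gains above `gain_max` are clamped.
#'
#' @param n_neurons neurons in the population code.
#' @param kappa_grid log-spaced tuning widths to tabulate.
#' @param gain_max largest population gain the table must serve.
#' @param n_streams Monte-Carlo sample streams per kappa node.
#' @param n_bins circular bins.
#' @param seed internal RNG stream for the tabulation.
#' @return object of class `decode_cache`.
#' @export
build_decode_cache <- function(n_neurons = 100L,
                               kappa_grid = default_kappa_grid(),
                               gain_max = 640,
                               n_streams = 100000L,
                               n_bins = 360L,
                               seed = 1203L) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  h <- 2 * pi / n_bins
  strata <- vector("list", length(kappa_grid))
  c_kappa <- numeric(length(kappa_grid))
  for (k in seq_along(kappa_grid)) {
    cfg <- pop_config(n_neurons, kappa_grid[k])
    w <- exp(cfg$kappa * (cos(cfg$preferred) - 1))
    c_kappa[k] <- mean(w)
    t_max <- stats::qpois(1 - 1e-9, gain_max * c_kappa[k]) + 10L
    counts <- matrix(0L, n_bins, t_max)
    block <- 5000L
    done <- 0L
    while (done < n_streams) {
      nb <- min(block, n_streams - done)
      idx <- sample.int(n_neurons, nb * t_max, replace = TRUE, prob = w)
      ph <- cfg$preferred[idx]
      cs <- matrix(cos(ph), nb, t_max)
      sn <- matrix(sin(ph), nb, t_max)
      for (t in 2:t_max) {
        cs[, t] <- cs[, t] + cs[, t - 1L]
        sn[, t] <- sn[, t] + sn[, t - 1L]
      }
      bins <- floor((round(atan2(sn, cs), 9) + pi) / h) + 1L
      bins[bins > n_bins] <- n_bins
      bins[bins < 1L] <- 1L
      combined <- as.vector(bins) +
        n_bins * rep(0:(t_max - 1L), each = nb)
      counts <- counts + matrix(tabulate(combined, nbins = n_bins * t_max),
                                n_bins, t_max)
      done <- done + nb
    }
    strata[[k]] <- counts / (n_streams * h)  # conditional densities g_T
  }
  structure(
    list(strata = strata, c_kappa = c_kappa, kappa_grid = kappa_grid,
         gain_max = gain_max, n_neurons = as.integer(n_neurons),
         n_bins = as.integer(n_bins), n_streams = as.integer(n_streams),
         seed = as.integer(seed), grid = error_grid(n_bins)),
    class = "decode_cache"
  )
}

#' @rdname build_decode_cache
#' @export
default_kappa_grid <- function() exp(seq(log(0.55), log(30), length.out = 25))

#' @rdname build_decode_cache
#' @export
default_decode_cache <- function(n_neurons = 100L) {
  key <- paste0("cache_n", n_neurons)
  if (is.null(.dynr_env[[key]])) {
    .dynr_env[[key]] <- build_decode_cache(n_neurons = n_neurons)
  }
  .dynr_env[[key]]
}

#' @export
print.decode_cache <- function(x, ...) {
  cat(sprintf(
    "Decode-density cache: %d neurons, %d kappas [%.3g, %.3g], gains up to %.3g, %d bins, %d MC streams\n",
    x$n_neurons, length(x$kappa_grid), min(x$kappa_grid),
    max(x$kappa_grid), x$gain_max, x$n_bins, x$n_streams))
  invisible(x)
}

# Poisson mixture over total spike count at one kappa node
mixture_at_node <- function(gain, node, cache) {
  g_eff <- gain * cache$c_kappa[node]
  G <- cache$strata[[node]]
  t_max <- ncol(G)
  p0 <- stats::dpois(0, g_eff)
  if (g_eff < 1e-12) return(rep(1 / (2 * pi), cache$n_bins))
  sd_t <- sqrt(g_eff)
  lo <- max(1L, floor(g_eff - 8 * sd_t))
  hi <- min(t_max, ceiling(g_eff + 8 * sd_t) + 5L)
  wts <- stats::dpois(lo:hi, g_eff)
  if (hi == t_max) {
    # lump the (tiny) upper tail into the last tabulated stratum
    wts[length(wts)] <- wts[length(wts)] +
      stats::ppois(t_max - 1L, g_eff, lower.tail = FALSE) -
      stats::dpois(t_max, g_eff)
  }
  dens <- as.numeric(G[, lo:hi, drop = FALSE] %*% wts) + p0 / (2 * pi)
  dens / (sum(dens) * 2 * pi / cache$n_bins)
}

#' @rdname build_decode_cache
#' @param gain,kappa query point; `kappa` is clamped to the grid range and
#'   `gain` to `[0, gain_max]`.
#' @param cache a `decode_cache`.
#' @export
cached_decode_density <- function(gain, kappa, cache) {
  gain <- min(max(gain, 0), cache$gain_max)
  lk <- log(min(max(kappa, cache$kappa_grid[1]),
                cache$kappa_grid[length(cache$kappa_grid)]))
  kk <- log(cache$kappa_grid)
  ki <- findInterval(lk, kk, all.inside = TRUE)
  wk <- (lk - kk[ki]) / (kk[ki + 1] - kk[ki])
  d <- (1 - wk) * mixture_at_node(gain, ki, cache) +
    wk * mixture_at_node(gain, ki + 1L, cache)
  d / (sum(d) * 2 * pi / cache$n_bins)
}
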