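#' Fit the dynamic neural resource model by maximum likelihood
#'
#' Multi-start Nelder-Mead maximization of the trial-level circular
#' likelihood. Positive parameters are optimized on the log scale and the
#' swap probability on the logit scale; a smooth penalty keeps parameters
#' inside the ranges covered by the decode-density cache. Starts are drawn
#' log-uniformly over dispersed plausible ranges under a fixed seed; each
#' start runs a short exploration, the best continues to convergence.
#'
#' @param trials trial table ([simulate_dataset()] or [read_trials()]).
#' @param variant variant name from [dynr_variants()], or a variant
#'   configuration list.
#' @param experiment `"exp1"` or `"exp2"`; defaults to the table's
#'   `experiment` attribute.
#' @param start a [dynr_params()] supplying fixed values for parameters not
#'   fitted under this experiment/variant; free parameters ignore it.
#' @param restarts number of dispersed starting points.
#' @param seed RNG seed for start generation (fits are deterministic given
#'   `(trials, seed)`).
#' @param cache decode-density cache; the memoized default if `NULL`.
#' @param swap_component passed to [dynr_nll()].
#' @param control list: `explore_maxit` (iterations per exploratory start),
#'   `polish_maxit`, `reltol`.
#' @return object of class `dynr_fit` with components `params` (full
#'   parameter object at the optimum), `coefficients` (free parameters),
#'   `nll`, `aic` (`2k + 2 nll`), `k`, `converged`, `restarts` (per-start
#'   table), `variant`, `experiment`, `n_trials`, `seed`.
#' @seealso [compare_dynr()], [recover_params()]
#' @export
fit_dynr <- function(trials, variant = "full", experiment = NULL,
                     start = NULL, restarts = 10L, seed = 1L,
                     cache = NULL,
                     swap_component = c("uniform", "nontargets"),
                     control = list()) {
  swap_component <- match.arg(swap_component)
  if (is.character(variant)) variant <- dynr_variant(variant)
  experiment <- experiment %||% attr(trials, "experiment") %||% "exp1"
  if (nrow(trials) < 1) stop("no trials to fit")
  if (is.null(start)) start <- dynr_params(experiment, variant = variant)
  start$variant <- variant
  start$experiment <- experiment
  if (is.null(cache)) cache <- default_decode_cache(start$n_neurons)
  ctl <- utils::modifyList(
    list(explore_maxit = 300L, polish_maxit = 2000L, polish_top = 3L,
         reltol = 1e-8), control)

  free <- free_param_names(experiment, variant)
  k <- length(free)
  prep <- prepare_nll(trials, swap_component)
  objective <- function(z) {
    vals <- from_unconstrained(z, free)
    pen <- box_penalty(vals, free)
    vals <- clamp_to_box(vals, free)
    names(vals) <- free
    p <- set_params(start, vals)
    as.numeric(nll_prepared(prep, p, cache)) + pen
  }

  # dispersed log-uniform starts over plausible ranges
  start_range <- list(
    gamma_wm = c(5, 400), kappa = c(1, 20), tau_rise = c(0.02, 1.5),
    tau_decay = c(0.03, 1.5), tau_wm = c(0.02, 2), b = c(0.01, 0.6),
    diff_rate = c(0.005, 1), swap_p = c(0.005, 0.3),
    tau_spatial = c(0.005, 0.2)
  )
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  starts <- lapply(seq_len(restarts), function(i) {
    vals <- vapply(free, function(nm) {
      r <- start_range[[nm]]
      exp(stats::runif(1, log(r[1]), log(r[2])))
    }, numeric(1))
    names(vals) <- free
    to_unconstrained(vals, free)
  })
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  explore <- lapply(starts, function(z0) {
    stats::optim(z0, objective, method = "Nelder-Mead",
                 control = list(maxit = ctl$explore_maxit,
                                reltol = ctl$reltol))
  })
  nlls <- vapply(explore, `[[`, numeric(1), "value")
  # polish the leading exploratory optima to convergence; simplex searches
  # are initialization-sensitive, so several basins are pursued
  top <- order(nlls)[seq_len(min(ctl$polish_top, length(nlls)))]
  polished <- lapply(top, function(i) {
    stats::optim(explore[[i]]$par, objective, method = "Nelder-Mead",
                 control = list(maxit = ctl$polish_maxit,
                                reltol = ctl$reltol))
  })
  pv <- vapply(polished, `[[`, numeric(1), "value")
  best <- top[which.min(pv)]
  polish <- polished[[which.min(pv)]]
  est <- from_unconstrained(polish$par, free)
  est <- clamp_to_box(est, free)
  names(est) <- free
  params <- set_params(start, est)
  nll <- dynr_nll(trials, params, cache, swap_component = swap_component)

  restart_tab <- data.frame(
    start = seq_len(restarts),
    nll = nlls,
    t(vapply(starts, function(z) from_unconstrained(z, free), numeric(k)))
  )
  names(restart_tab)[-(1:2)] <- free

  structure(
    list(params = params, coefficients = est, nll = nll,
         aic = 2 * k + 2 * nll, k = k,
         converged = polish$convergence == 0L,
         restarts = restart_tab, best_start = best,
         variant = variant, experiment = experiment,
         n_trials = nrow(trials), seed = seed,
         swap_component = swap_component,
         trials = trials),
    class = "dynr_fit"
  )
}

#' @export
print.dynr_fit <- function(x, ...) {
  cat(sprintf(
    "Dynamic neural resource fit (%s, variant '%s'): %d trials, %d parameters\n",
    x$experiment, x$variant$name %||% "custom", x$n_trials, x$k))
  print(signif(x$coefficients, 4))
  cat(sprintf("nll = %.2f, AIC = %.2f%s\n", x$nll, x$aic,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
summary.dynr_fit <- function(object, ...) {
  cat(sprintf(
    "Maximum-likelihood fit of the dynamic neural resource model\n"))
  cat(sprintf("  experiment: %s   variant: %s   trials: %d\n",
              object$experiment, object$variant$name %||% "custom",
              object$n_trials))
  cat(sprintf("  free parameters (%d):\n", object$k))
  print(signif(object$coefficients, 4))
  cat(sprintf("  nll %.2f | AIC %.2f | converged: %s (best of %d starts)\n",
              object$nll, object$aic, object$converged,
              nrow(object$restarts)))
  spread <- range(object$restarts$nll)
  cat(sprintf("  exploratory nll range: [%.2f, %.2f]\n",
              spread[1], spread[2]))
  invisible(object)
}

#' @export
coef.dynr_fit <- function(object, ...) object$coefficients

#' @export
logLik.dynr_fit <- function(object, ...) {
  structure(-object$nll, df = object$k, nobs = object$n_trials,
            class = "logLik")
}

#' Model predictions for a fitted dynamic neural resource model
#'
#' `type = "rmse"` returns the per-condition latent quantities and implied
#' RMSE; `type = "density"` returns the list of predicted error densities.
#'
#' @param object a `dynr_fit`.
#' @param newdata design data frame (defaults to the fitted conditions).
#' @param type `"rmse"` or `"density"`.
#' @param ... unused.
#' @export
predict.dynr_fit <- function(object, newdata = NULL,
                             type = c("rmse", "density"), ...) {
  type <- match.arg(type)
  design <- newdata %||% unique(object$trials[
    c("set_size", "exposure", "delay", "simultaneous")])
  dens <- lapply(seq_len(nrow(design)), function(i) {
    predict_error_density(as.list(design[i, ]), object$params,
                          cache = default_decode_cache(object$params$n_neurons))
  })
  if (type == "density") return(dens)
  out <- design
  out$gain <- vapply(dens, function(d) d$latents$gain, numeric(1))
  out$sigma2 <- vapply(dens, function(d) d$latents$sigma2, numeric(1))
  out$p_swap <- vapply(dens, function(d) d$p_swap, numeric(1))
  out$rmse_deg <- vapply(dens, density_rmse_deg, numeric(1))
  rownames(out) <- NULL
  out
}

#' @export
simulate.dynr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::aggregate(
    list(trials = object$trials$set_size),
    by = object$trials[c("set_size", "exposure", "delay", "simultaneous")],
    FUN = length)
  counts$experiment <- object$experiment
  out <- lapply(seq_len(nsim), function(i) {
    simulate_dataset(counts, object$params)
  })
  if (nsim == 1) out[[1]] else out
}

#' @export
residuals.dynr_fit <- function(object, ...) {
  obs <- summarize_rmse(object$trials, n_boot = 0L)
  fit <- predict(object)
  m <- merge(obs, fit, by = c("set_size", "exposure", "delay", "simultaneous"))
  m$residual_deg <- m$rmse_deg.x - m$rmse_deg.y
  m[c("set_size", "exposure", "delay", "simultaneous", "rmse_deg.x",
      "rmse_deg.y", "residual_deg")]
}

#' @export
plot.dynr_fit <- function(x, ...) {
  obs <- summarize_rmse(x$trials)
  fit <- predict(x)
  xvar <- if (x$experiment == "exp1") "delay" else "exposure"
  xlab <- if (x$experiment == "exp1") "cue delay (s)" else "exposure (s)"
  sizes <- sort(unique(obs$set_size))
  cols <- grDevices::hcl.colors(max(3, length(sizes)), "Dark 2")
  ns <- !obs$simultaneous
  graphics::plot(range(obs[[xvar]][ns]), range(c(obs$rmse_deg, fit$rmse_deg)),
                 type = "n", xlab = xlab, ylab = "RMSE (deg)", ...)
  for (i in seq_along(sizes)) {
    oo <- obs[obs$set_size == sizes[i] & !obs$simultaneous, ]
    ff <- fit[fit$set_size == sizes[i] & !fit$simultaneous, ]
    oo <- oo[order(oo[[xvar]]), ]; ff <- ff[order(ff[[xvar]]), ]
    graphics::points(oo[[xvar]], oo$rmse_deg, col = cols[i], pch = 16)
    graphics::arrows(oo[[xvar]], oo$rmse_deg - oo$se_deg,
                     oo[[xvar]], oo$rmse_deg + oo$se_deg,
                     angle = 90, code = 3, length = 0.02, col = cols[i])
    graphics::lines(ff[[xvar]], ff$rmse_deg, col = cols[i])
  }
  graphics::legend("topleft", legend = paste("N =", sizes), col = cols,
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Compare model variants by AIC
#'
#' Fits each variant to the same data and tabulates AIC differences
#' relative to the best variant. Pass a list of trial tables (e.g. one per
#' subject) to fit each subject separately and sum AICs.
#'
#' @param trials trial table or list of trial tables.
#' @param variants character vector of variant names.
#' @param ... passed to [fit_dynr()].
#' @return data frame with `variant`, `k`, `nll`, `aic`, `delta_aic`
#'   (class `dynr_aic`); the per-fit objects are attached as the `fits`
#'   attribute.
#' @export
compare_dynr <- function(trials, variants = c("full", "fixed_signal"), ...) {
  tables <- if (is.data.frame(trials)) list(trials) else trials
  fits <- lapply(variants, function(v) {
    lapply(tables, function(tab) fit_dynr(tab, variant = v, ...))
  })
  names(fits) <- variants
  out <- data.frame(
    variant = variants,
    k = vapply(fits, function(fl) fl[[1]]$k, numeric(1)),
    nll = vapply(fits, function(fl) sum(vapply(fl, `[[`, numeric(1), "nll")),
                 numeric(1)),
    aic = vapply(fits, function(fl) sum(vapply(fl, `[[`, numeric(1), "aic")),
                 numeric(1)),
    failed = vapply(fits, function(fl) {
      sum(!vapply(fl, `[[`, logical(1), "converged"))
    }, numeric(1))
  )
  out$delta_aic <- out$aic - min(out$aic)
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("dynr_aic", "data.frame")
  out
}

#' Parameter-recovery study
#'
#' Simulates replicate synthetic datasets from known generating parameters
#' under a standard design and refits the model to each, reporting the
#' recovered estimates. The package's acceptance checks run this at the
#' group maximum-likelihood estimates of the two built-in designs.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param truth generating [dynr_params()]; the experiment's defaults if
#'   `NULL`.
#' @param replicates number of synthetic datasets.
#' @param trials_per_cell trials per design cell.
#' @param restarts,seed,cache,control passed to [fit_dynr()].
#' @return list with `truth` (free-parameter truth vector), `estimates`
#'   (replicates x parameters matrix), `median` (named vector), `fits`.
#' @export
recover_params <- function(experiment = "exp1", truth = NULL,
                           replicates = 5L, trials_per_cell = 300L,
                           restarts = 10L, seed = 1L, cache = NULL,
                           swap_component = c("uniform", "nontargets"),
                           control = list()) {
  swap_component <- match.arg(swap_component)
  truth <- truth %||% dynr_params(experiment)
  design <- make_design(experiment, trials_per_cell)
  free <- free_param_names(experiment, truth$variant)
  fits <- vector("list", replicates)
  est <- matrix(NA_real_, replicates, length(free),
                dimnames = list(NULL, free))
  for (r in seq_len(replicates)) {
    set.seed(seed + r - 1L)
    trials <- simulate_dataset(design, truth)
    fits[[r]] <- fit_dynr(trials, variant = truth$variant,
                          experiment = experiment, restarts = restarts,
                          seed = seed + 1000L * r, cache = cache,
                          swap_component = swap_component,
                          control = control)
    est[r, ] <- fits[[r]]$coefficients[free]
  }
  tv <- vapply(free, function(nm) truth[[nm]], numeric(1))
  list(truth = tv, estimates = est,
       median = apply(est, 2, stats::median), fits = fits)
}
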