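#' Simulate a single continuous-report trial
#'
#' Runs the full generative pipeline for one trial: (1) compute the cue
#' identification time; (2) pick the reported item — a non-target with the
#' condition's swap probability (uniformly among the `N - 1` non-targets),
#' otherwise the target; (3) diffuse its true value by the accumulated
#' diffusion variance; (4) compute the memory gain at decoding; (5) encode
#' the diffused value in Poisson spikes of the tuned population and decode
#' by maximum likelihood. The error is the circular difference between the
#' decoded report and the *target*, so swapped reports cluster at
#' non-target offsets.
#'
#' @param cond list or one-row data frame with `set_size`, `exposure`,
#'   `delay`, `simultaneous`.
#' @param p a [dynr_params()].
#' @param orientations optional true feature values (doubled radians),
#'   target first, length `set_size`; drawn uniformly if missing.
#' @return one-row data frame (a trial record): condition columns plus
#'   `target`, `response`, `error` (doubled radians), and the latent
#'   indicators `swapped`, `guess`.
#' @examples
#' set.seed(1)
#' simulate_trial(list(set_size = 4, exposure = 0.2, delay = 0.1,
#'                     simultaneous = FALSE), dynr_params("exp1"))
#' @export
simulate_trial <- function(cond, p, orientations = NULL) {
  if (is.null(orientations)) {
    orientations <- stats::runif(cond$set_size, -pi, pi)
  }
  stopifnot(length(orientations) == cond$set_size)
  lat <- condition_latents(p, cond)
  swapped <- cond$set_size > 1 && stats::runif(1) < lat$p_swap
  item <- if (swapped) sample(2:cond$set_size, 1L) else 1L
  theta_star <- apply_diffusion(orientations[item], lat$sigma2)
  cfg <- pop_config(p$n_neurons, p$kappa)
  dec <- decode_draws(1L, theta_star, lat$gain, cfg)
  response <- dec$theta_hat
  data.frame(
    set_size = cond$set_size, exposure = cond$exposure, delay = cond$delay,
    simultaneous = isTRUE(cond$simultaneous),
    target = orientations[1], response = response,
    error = wrap_pi(response - orientations[1]),
    swapped = swapped, guess = dec$is_guess
  )
}

#' Simulate a full dataset under a design
#'
#' Vectorized application of the generative pipeline of [simulate_trial()]
#' to every condition of a design, drawing all orientations independently
#' and uniformly. Deterministic under `set.seed()`.
#'
#' @param design data frame from [make_design()] (columns `set_size`,
#'   `exposure`, `delay`, `simultaneous`, `trials`).
#' @param p a [dynr_params()].
#' @return trial table: one row per trial with columns `trial`, `set_size`,
#'   `exposure`, `delay`, `simultaneous`, `target`, `nontargets`
#'   (semicolon-joined doubled radians, empty for set size 1), `response`,
#'   `error` (doubled radians), `swapped`, `guess`. Class
#'   `c("dynr_trials", "data.frame")`.
#' @examples
#' set.seed(7)
#' trials <- simulate_dataset(make_design("exp1", 5), dynr_params("exp1"))
#' summarize_rmse(trials)
#' @export
simulate_dataset <- function(design, p) {
  cfg <- pop_config(p$n_neurons, p$kappa)
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    cond <- as.list(design[i, ])
    k <- cond$trials
    N <- cond$set_size
    lat <- condition_latents(p, cond)
    oris <- matrix(stats::runif(k * N, -pi, pi), nrow = k)
    swapped <- if (N > 1) stats::runif(k) < lat$p_swap else rep(FALSE, k)
    item <- rep(1L, k)
    if (any(swapped)) {
      item[swapped] <- 1L + sample.int(N - 1L, sum(swapped), replace = TRUE)
    }
    chosen <- oris[cbind(seq_len(k), item)]
    theta_star <- apply_diffusion(chosen, lat$sigma2)
    dec <- decode_draws(k, theta_star, lat$gain, cfg)
    nons <- if (N > 1) {
      apply(oris[, -1, drop = FALSE], 1,
            function(r) paste(formatC(r, digits = 9, format = "g"),
                              collapse = ";"))
    } else ""
    out[[i]] <- data.frame(
      set_size = N, exposure = cond$exposure, delay = cond$delay,
      simultaneous = isTRUE(cond$simultaneous),
      target = oris[, 1], nontargets = nons,
      response = dec$theta_hat,
      error = wrap_pi(dec$theta_hat - oris[, 1]),
      swapped = swapped, guess = dec$is_guess,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- cbind(trial = seq_len(nrow(res)), res)
  class(res) <- c("dynr_trials", "data.frame")
  attr(res, "experiment") <- design$experiment[1] %||% p$experiment
  res
}

# parse the semicolon-joined non-target column into a list of numeric vectors
parse_nontargets <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    if (!length(v)) numeric(0) else as.numeric(v)
  })
}

#' Per-condition root-mean-square error summary
#'
#' Wrapped-error RMSE in orientation degrees per (set size x timing) cell,
#' pooled over any other grouping, with a bootstrap standard error.
#'
#' @param trials a trial table ([simulate_dataset()] or [read_trials()]).
#' @param n_boot bootstrap resamples for the standard error (0 to skip).
#' @return data frame with `set_size`, `exposure`, `delay`, `simultaneous`,
#'   `n`, `rmse_deg`, `se_deg`.
#' @export
summarize_rmse <- function(trials, n_boot = 200L) {
  key <- interaction(trials$set_size, trials$exposure, trials$delay,
                     trials$simultaneous, drop = TRUE)
  cells <- split(trials, key)
  rows <- lapply(cells, function(cell) {
    err <- cell$error
    se <- if (n_boot > 0) {
      stats::sd(vapply(seq_len(n_boot), function(i) {
        rmse_deg(sample(err, replace = TRUE))
      }, numeric(1)))
    } else NA_real_
    data.frame(
      set_size = cell$set_size[1], exposure = cell$exposure[1],
      delay = cell$delay[1], simultaneous = cell$simultaneous[1],
      n = nrow(cell), rmse_deg = rmse_deg(err), se_deg = se
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$set_size, out$simultaneous, out$exposure, out$delay), ]
  rownames(out) <- NULL
  out
}
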