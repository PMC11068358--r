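#' Dynamic neural resource model parameters
#'
#' Bundles the full parameter vector of the dynamic neural resource model of
#' visual working memory together with the structural switches that select a
#' model variant. Defaults are the group maximum-likelihood estimates for the
#' two standard designs supported by the package: a fixed 200 ms exposure
#' with variable cue delay (`"exp1"`), and variable exposure terminated by a
#' 100 ms backward mask (`"exp2"`).
#'
#' @param experiment `"exp1"` or `"exp2"`; selects defaults and the
#'   experiment-specific swap parameterization (see Details).
#' @param gamma_wm maximum working-memory signal amplitude \eqn{\check\gamma_{wm}}
#'   (population gain of a lone item; dimensionless spike-count scale).
#' @param kappa tuning-curve width of the population code.
#' @param tau_rise rise time constant of the sensory temporal filter (s);
#'   `0` means an instantaneous rise (the fixed-exposure design assumes
#'   encoding is complete at stimulus offset, so the rise plays no role
#'   there).
#' @param tau_decay decay time constant of the sensory filter (s). In the
#'   masked design this is the (faster) decay under a backward mask.
#' @param tau_wm time constant of accumulation into working memory (s).
#' @param b cue-processing (Hick's-law) scaling constant, seconds per bit:
#'   the cued item is identified at \eqn{t^*_{cue} = t_{cue} + b \log_2 N}.
#' @param diff_rate base diffusion rate \eqn{\dot\sigma^2_{diff}}
#'   (doubled-orientation rad^2 per second; divide by 4 and multiply by
#'   \eqn{(180/\pi)^2} for orientation deg^2 per second).
#' @param swap_p swap probability parameter. In `"exp1"` mode this is the
#'   constant total probability of reporting a non-target (for `N > 1`). In
#'   `"exp2"` mode it is the asymptotic (long-exposure) total swap
#'   probability entering the exposure-dependent swap law, see
#'   [swap_probability()].
#' @param tau_spatial exposure time constant of the swap law (s; `"exp2"`).
#' @param n_neurons neurons in the population code.
#' @param gamma_s_max maximum sensory amplitude. Fixed at 1 by convention:
#'   only the ratio \eqn{\gamma_s/\tau_{wm}} enters the accumulation
#'   equation, so a free sensory scale would be degenerate with `tau_wm`.
#' @param variant structural switches, normally produced by
#'   [dynr_variants()]; see that help page.
#' @return object of class `dynr_params` (a named list).
#' @examples
#' p1 <- dynr_params("exp1")
#' p2 <- dynr_params("exp2", tau_wm = 0.5)
#' @export
dynr_params <- function(experiment = c("exp1", "exp2"),
                        gamma_wm = NULL, kappa = NULL,
                        tau_rise = NULL, tau_decay = NULL, tau_wm = NULL,
                        b = NULL, diff_rate = NULL, swap_p = NULL,
                        tau_spatial = NULL, n_neurons = 100L,
                        gamma_s_max = 1,
                        variant = dynr_variant("full")) {
  experiment <- match.arg(experiment)
  def <- if (experiment == "exp1") {
    list(gamma_wm = 59.8, kappa = 3.21, tau_rise = 0, tau_decay = 0.21,
         tau_wm = 0.096, b = 0.171, diff_rate = 0.03, swap_p = 0.027,
         tau_spatial = 0.013)
  } else {
    list(gamma_wm = 188.5, kappa = 10.2, tau_rise = 0.33, tau_decay = 0.61,
         tau_wm = 0.8, b = 0.2, diff_rate = 0.28, swap_p = 0.053,
         tau_spatial = 0.013)
  }
  p <- list(
    experiment = experiment,
    gamma_wm = gamma_wm %||% def$gamma_wm,
    kappa = kappa %||% def$kappa,
    tau_rise = tau_rise %||% def$tau_rise,
    tau_decay = tau_decay %||% def$tau_decay,
    tau_wm = tau_wm %||% def$tau_wm,
    b = b %||% def$b,
    diff_rate = diff_rate %||% def$diff_rate,
    swap_p = swap_p %||% def$swap_p,
    tau_spatial = tau_spatial %||% def$tau_spatial,
    n_neurons = as.integer(n_neurons),
    gamma_s_max = gamma_s_max,
    variant = variant
  )
  validate_dynr_params(p)
  structure(p, class = "dynr_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_dynr_params <- function(p) {
  stopifnot(
    p$gamma_wm > 0, p$kappa > 0, p$tau_rise >= 0, p$tau_decay > 0,
    p$tau_wm > 0, p$b >= 0, p$diff_rate >= 0,
    p$swap_p >= 0, p$swap_p <= 1, p$tau_spatial > 0,
    p$n_neurons >= 8L, p$gamma_s_max > 0
  )
  stopifnot(is.list(p$variant),
            all(c("sensory_persists", "diffusion", "cue_time", "readout",
                  "accumulation") %in% names(p$variant)))
  invisible(p)
}

#' @export
print.dynr_params <- function(x, ...) {
  cat(sprintf("Dynamic neural resource parameters (%s mode, variant '%s'):\n",
              x$experiment, x$variant$name %||% "custom"))
  v <- unlist(x[c("gamma_wm", "kappa", "tau_rise", "tau_decay", "tau_wm",
                  "b", "diff_rate", "swap_p", "tau_spatial")])
  print(signif(v, 4))
  invisible(x)
}

#' Model variant registry
#'
#' `dynr_variants()` returns the ten structural configurations of the model
#' examined by the package: the full dynamic model and nine reduced or
#' alternative architectures. `dynr_variant(name)` returns a single
#' configuration by name. Each configuration is a list of switches:
#'
#' * `sensory_persists`: does sensory activity outlast stimulus offset
#'   (feeding post-cue accumulation)? `FALSE` freezes the memory signal at
#'   its normalized level (`fixed_signal*` variants, and the mask-terminated
#'   variant in the masked design).
#' * `diffusion`: `"constant"`, `"none"`, or `"scaled"` (rate multiplied by
#'   set size).
#' * `cue_time`: `"hicks"` (\eqn{t_{cue} + b\log_2 N}), `"zero"`
#'   (\eqn{t_{cue}}), or `"constant"` (\eqn{t_{cue} + b}, independent of N).
#' * `readout`: `"wm"` (decode the working-memory population after post-cue
#'   accumulation) or `"sum"` (direct read-out: decode the summed sensory
#'   and memory activity at cue identification, with the sensory population
#'   expressed on the same spike-count scale as memory).
#' * `accumulation`: `"exponential"` (rate proportional to unfilled
#'   normalized capacity) or `"linear"` (constant rate per item until the
#'   normalized ceiling).
#'
#' @param name variant name, one of
#'   `names(dynr_variants())`.
#' @return `dynr_variants()`: named list of variant configurations;
#'   `dynr_variant()`: one configuration.
#' @examples
#' names(dynr_variants())
#' dynr_variant("no_diffusion")$diffusion
#' @export
dynr_variants <- function() {
  base <- list(sensory_persists = TRUE, diffusion = "constant",
               cue_time = "hicks", readout = "wm",
               accumulation = "exponential")
  mk <- function(name, ...) {
    v <- utils::modifyList(base, list(...))
    v$name <- name
    v
  }
  list(
    full = mk("full"),
    fixed_signal = mk("fixed_signal", sensory_persists = FALSE,
                      cue_time = "zero"),
    fixed_signal_scaled_diffusion =
      mk("fixed_signal_scaled_diffusion", sensory_persists = FALSE,
         cue_time = "zero", diffusion = "scaled"),
    no_diffusion = mk("no_diffusion", diffusion = "none"),
    scaled_diffusion = mk("scaled_diffusion", diffusion = "scaled"),
    direct_readout = mk("direct_readout", readout = "sum"),
    zero_cue_time = mk("zero_cue_time", cue_time = "zero"),
    constant_cue_time = mk("constant_cue_time", cue_time = "constant"),
    mask_terminated = mk("mask_terminated", sensory_persists = FALSE),
    constant_accumulation = mk("constant_accumulation",
                               accumulation = "linear")
  )
}

#' @rdname dynr_variants
#' @export
dynr_variant <- function(name) {
  reg <- dynr_variants()
  if (!name %in% names(reg)) {
    stop("unknown variant '", name, "'; see names(dynr_variants())")
  }
  reg[[name]]
}

# Free parameters fitted for a given experiment/variant; all others stay at
# the values in the start parameter object.
free_param_names <- function(experiment, variant) {
  base <- c("gamma_wm", "kappa", "tau_decay", "tau_wm", "b",
            "diff_rate", "swap_p")
  if (experiment == "exp2") {
    base <- c("gamma_wm", "kappa", "tau_rise", "tau_decay", "tau_wm", "b",
              "diff_rate", "swap_p", "tau_spatial")
  }
  if (!variant$sensory_persists) {
    drop <- c("tau_decay", "tau_wm")
    if (identical(variant$cue_time, "zero")) drop <- c(drop, "b")
    if (experiment == "exp2" && identical(variant$name, "mask_terminated")) {
      # accumulation during exposure still needs tau_rise and tau_wm;
      # only the post-offset decay disappears
      drop <- "tau_decay"
    }
    base <- setdiff(base, drop)
  }
  if (identical(variant$diffusion, "none")) base <- setdiff(base, "diff_rate")
  if (identical(variant$cue_time, "zero")) base <- setdiff(base, "b")
  base
}

# ---- parameter transforms for optimization -------------------------------
# log scale for positive parameters, logit for probabilities, with box
# limits that keep gains and tuning widths inside the decode-density cache.

param_box <- function(name) {
  switch(name,
    gamma_wm = c(1, 600),
    kappa = c(0.55, 30),
    tau_rise = c(1e-3, 5),
    tau_decay = c(5e-3, 5),
    tau_wm = c(5e-3, 10),
    b = c(1e-4, 2),
    diff_rate = c(1e-5, 10),
    swap_p = c(1e-6, 0.9),
    tau_spatial = c(1e-3, 1),
    stop("no box for parameter ", name)
  )
}

to_unconstrained <- function(values, names) {
  vapply(seq_along(names), function(i) {
    bx <- param_box(names[i])
    x <- min(max(values[i], bx[1]), bx[2])
    if (names[i] == "swap_p") stats::qlogis(x) else log(x)
  }, numeric(1))
}

from_unconstrained <- function(z, names) {
  out <- vapply(seq_along(names), function(i) {
    if (names[i] == "swap_p") stats::plogis(z[i]) else exp(z[i])
  }, numeric(1))
  names(out) <- names
  out
}

# smooth penalty keeping transformed parameters inside their boxes
box_penalty <- function(values, names) {
  pen <- 0
  for (i in seq_along(names)) {
    bx <- param_box(names[i])
    if (values[i] < bx[1]) pen <- pen + 1e4 * (log(bx[1] / values[i]))^2
    if (values[i] > bx[2]) pen <- pen + 1e4 * (log(values[i] / bx[2]))^2
  }
  pen
}

clamp_to_box <- function(values, names) {
  vapply(seq_along(names), function(i) {
    bx <- param_box(names[i])
    min(max(values[i], bx[1]), bx[2])
  }, numeric(1))
}

# update a dynr_params object with a named vector of free values
set_params <- function(p, values) {
  for (nm in names(values)) p[[nm]] <- unname(values[nm])
  p
}
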