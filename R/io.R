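#' Read and write trial tables
#'
#' The external trial-table format is a plain CSV with columns
#' `subject_id`, `experiment`, `set_size`, `exposure_s`, `delay_s`,
#' `simultaneous`, `target_ori_deg`, `nontarget_oris_deg` (semicolon-joined,
#' empty for set size 1), `response_deg`. Orientations are degrees in
#' \eqn{[0, 180)} externally and doubled radians internally; `read_trials()`
#' validates rows (reporting offending line numbers) and converts,
#' recomputing the wrapped error. `write_trials()` is its inverse.
#'
#' @param path file path.
#' @param trials internal trial table ([simulate_dataset()]).
#' @param subject_id,experiment values for the external columns when the
#'   internal table lacks them.
#' @return `read_trials()`: a `dynr_trials` data frame (empty, with a
#'   warning, for an empty file); `write_trials()`: `path`, invisibly.
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "experiment", "set_size", "exposure_s", "delay_s",
            "simultaneous", "target_ori_deg", "nontarget_oris_deg",
            "response_deg")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing trial-table columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    warning("empty trial table: ", path)
    out <- data.frame(trial = integer(), subject_id = character(),
                      set_size = integer(), exposure = numeric(),
                      delay = numeric(), simultaneous = logical(),
                      target = numeric(), nontargets = character(),
                      response = numeric(), error = numeric())
    class(out) <- c("dynr_trials", "data.frame")
    return(out)
  }
  ok_ori <- function(x) is.finite(x) & x >= 0 & x < 180
  bad <- which(!ok_ori(raw$target_ori_deg) | !ok_ori(raw$response_deg) |
                 raw$set_size < 1)
  if (length(bad)) {
    stop("invalid orientation/set size in rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  nts <- parse_nontargets(raw$nontarget_oris_deg)
  n_nt <- lengths(nts)
  bad <- which(n_nt != raw$set_size - 1)
  if (length(bad)) {
    stop("non-target count does not match set_size - 1 in rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  bad <- which(vapply(nts, function(v) any(!ok_ori(v)), logical(1)))
  if (length(bad)) {
    stop("non-target orientations out of [0, 180) in rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  target <- ori_deg_to_rad(raw$target_ori_deg)
  response <- ori_deg_to_rad(raw$response_deg)
  out <- data.frame(
    trial = seq_len(nrow(raw)),
    subject_id = raw$subject_id,
    set_size = as.integer(raw$set_size),
    exposure = raw$exposure_s,
    delay = raw$delay_s,
    simultaneous = as.logical(raw$simultaneous),
    target = target,
    nontargets = vapply(nts, function(v) {
      if (!length(v)) "" else
        paste(formatC(ori_deg_to_rad(v), digits = 9, format = "g"),
              collapse = ";")
    }, character(1)),
    response = response,
    error = wrap_pi(response - target),
    stringsAsFactors = FALSE
  )
  class(out) <- c("dynr_trials", "data.frame")
  attr(out, "experiment") <- raw$experiment[1]
  out
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path, subject_id = "sim",
                         experiment = NULL) {
  experiment <- experiment %||% attr(trials, "experiment") %||% "exp1"
  nts <- parse_nontargets(if ("nontargets" %in% names(trials)) {
    trials$nontargets
  } else rep("", nrow(trials)))
  out <- data.frame(
    subject_id = if ("subject_id" %in% names(trials)) {
      trials$subject_id
    } else subject_id,
    experiment = experiment,
    set_size = trials$set_size,
    exposure_s = trials$exposure,
    delay_s = trials$delay,
    simultaneous = trials$simultaneous,
    target_ori_deg = rad_to_ori_deg(trials$target),
    nontarget_oris_deg = vapply(nts, function(v) {
      if (!length(v)) "" else
        paste(formatC(rad_to_ori_deg(v), digits = 10, format = "g"),
              collapse = ";")
    }, character(1)),
    response_deg = rad_to_ori_deg(trials$response)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write model parameters as flat YAML
#'
#' A parameter file is a flat key/value mapping of any subset of the
#' [dynr_params()] arguments plus optional `experiment` and `variant`
#' (a registry name).
#'
#' @param path file path.
#' @param p a [dynr_params()].
#' @return `read_params_file()`: a `dynr_params`;
#'   `write_params_file()`: `path`, invisibly.
#' @export
read_params_file <- function(path) {
  kv <- yaml::read_yaml(path)
  experiment <- kv$experiment %||% "exp1"
  variant <- dynr_variant(kv$variant %||% "full")
  keep <- intersect(names(kv),
                    c("gamma_wm", "kappa", "tau_rise", "tau_decay", "tau_wm",
                      "b", "diff_rate", "swap_p", "tau_spatial", "n_neurons"))
  do.call(dynr_params,
          c(list(experiment = experiment, variant = variant), kv[keep]))
}

#' @rdname read_params_file
#' @export
write_params_file <- function(p, path) {
  yaml::write_yaml(
    list(experiment = p$experiment,
         variant = p$variant$name %||% "full",
         gamma_wm = p$gamma_wm, kappa = p$kappa, tau_rise = p$tau_rise,
         tau_decay = p$tau_decay, tau_wm = p$tau_wm, b = p$b,
         diff_rate = p$diff_rate, swap_p = p$swap_p,
         tau_spatial = p$tau_spatial, n_neurons = p$n_neurons),
    path)
  invisible(path)
}

#' Serialize a fit to JSON
#'
#' Writes estimates, likelihood, AIC, convergence diagnostics and
#' provenance (seed, variant, package version) for a fitted model.
#'
#' @param fit a `dynr_fit`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(
      package = "dynres",
      version = as.character(utils::packageVersion("dynres")),
      experiment = fit$experiment,
      variant = fit$variant$name %||% "custom",
      n_trials = fit$n_trials,
      seed = fit$seed,
      estimates = as.list(fit$coefficients),
      nll = fit$nll, aic = fit$aic, k = fit$k,
      converged = fit$converged
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
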