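test_that("fitting machinery recovers parameters on a reduced problem", {
  cache <- shared_cache()
  # a 3-parameter stationary submodel (gain, tuning width, swap) keeps this
  # unit test fast; full-scale recovery lives in the acceptance suite
  variant <- dynr_variant("fixed_signal")
  truth <- dynr_params("exp1", variant = variant)
  set.seed(181)
  trials <- simulate_dataset(make_design("exp1", 120), truth)
  fit <- fit_dynr(trials, variant = variant, restarts = 4, seed = 9,
                  cache = cache,
                  control = list(explore_maxit = 150, polish_maxit = 600))
  expect_s3_class(fit, "dynr_fit")
  expect_equal(fit$k, 4)
  est <- coef(fit)
  expect_equal(unname(est["gamma_wm"]), truth$gamma_wm, tolerance = 0.25)
  expect_equal(unname(est["kappa"]), truth$kappa, tolerance = 0.25)
  expect_equal(unname(est["swap_p"]), truth$swap_p, tolerance = 0.8)
  # aic arithmetic is exact
  expect_equal(fit$aic, 2 * fit$k + 2 * fit$nll)
  expect_equal(AIC(fit), fit$aic)
  expect_equal(as.numeric(logLik(fit)), -fit$nll)
  expect_equal(attr(logLik(fit), "df"), fit$k)
})

test_that("fits are deterministic given data and seed", {
  cache <- shared_cache()
  variant <- dynr_variant("fixed_signal")
  truth <- dynr_params("exp1", variant = variant)
  set.seed(191)
  trials <- simulate_dataset(make_design("exp1", 30), truth)
  f1 <- fit_dynr(trials, variant = variant, restarts = 2, seed = 5,
                 cache = cache,
                 control = list(explore_maxit = 60, polish_maxit = 100))
  f2 <- fit_dynr(trials, variant = variant, restarts = 2, seed = 5,
                 cache = cache,
                 control = list(explore_maxit = 60, polish_maxit = 100))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$nll, f2$nll)
})

test_that("refitting data simulated from a fit reproduces its likelihood", {
  cache <- shared_cache()
  variant <- dynr_variant("fixed_signal")
  truth <- dynr_params("exp1", variant = variant)
  set.seed(201)
  trials <- simulate_dataset(make_design("exp1", 80), truth)
  fit <- fit_dynr(trials, variant = variant, restarts = 3, seed = 7,
                  cache = cache,
                  control = list(explore_maxit = 120, polish_maxit = 400))
  resim <- simulate(fit, seed = 202)
  expect_equal(nrow(resim), nrow(trials))
  nll_resim <- dynr_nll(resim, fit$params, cache)
  # per-trial average log-likelihood agrees within stochastic tolerance
  expect_equal(nll_resim / nrow(resim), fit$nll / nrow(trials),
               tolerance = 0.1)
})

test_that("fit methods expose predictions, residuals and summaries", {
  cache <- shared_cache()
  variant <- dynr_variant("fixed_signal")
  truth <- dynr_params("exp1", variant = variant)
  set.seed(211)
  trials <- simulate_dataset(make_design("exp1", 40), truth)
  fit <- fit_dynr(trials, variant = variant, restarts = 2, seed = 3,
                  cache = cache,
                  control = list(explore_maxit = 80, polish_maxit = 200))
  pr <- predict(fit)
  expect_true(all(c("gain", "sigma2", "p_swap", "rmse_deg") %in% names(pr)))
  expect_equal(nrow(pr), 18)
  expect_true(all(pr$rmse_deg > 0 & pr$rmse_deg < 90 / sqrt(3) + 1))
  res <- residuals(fit)
  expect_true(all(is.finite(res$residual_deg)))
  expect_output(print(fit), "Dynamic neural resource fit")
  expect_output(summary(fit), "free parameters")
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp)); unlink(tmp)
  tmp <- tempfile(fileext = ".json")
  write_fit_json(fit, tmp)
  j <- jsonlite::read_json(tmp)
  expect_equal(j$variant, "fixed_signal")
  expect_equal(j$k, 4)
  unlink(tmp)
})

test_that("aic comparison prefers the generating structure", {
  cache <- shared_cache()
  # stationary data (no dynamics, no diffusion): the 7-parameter dynamic
  # model pays its parameter penalty and the reduced model wins
  variant <- dynr_variant("fixed_signal")
  truth <- dynr_params("exp1", variant = variant)
  set.seed(221)
  trials <- simulate_dataset(make_design("exp1", 100), truth)
  cmp <- compare_dynr(trials, variants = c("full", "fixed_signal"),
                      restarts = 3, seed = 11, cache = cache,
                      control = list(explore_maxit = 150,
                                     polish_maxit = 500))
  expect_s3_class(cmp, "dynr_aic")
  expect_equal(cmp$delta_aic[1], 0)
  # identical variant listed twice: delta AIC ~ 0
  cmp2 <- compare_dynr(trials, variants = c("fixed_signal", "fixed_signal"),
                       restarts = 2, seed = 13, cache = cache,
                       control = list(explore_maxit = 80,
                                      polish_maxit = 200))
  expect_lt(max(abs(cmp2$delta_aic)), 1e-6)
})
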