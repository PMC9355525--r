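test_that("linear predictor reproduces the published score arithmetic", {
  c0 <- published_coefficients()
  expect_equal(linear_predictor(0, 0, 0, c0), 0)
  expect_equal(linear_predictor(1, 1.0, 166, c0), 1.347 + 8.363 + 0.664)
  # linearity in ALP
  s1 <- linear_predictor(1, 1.2, 100, c0)
  s2 <- linear_predictor(1, 1.2, 200, c0)
  expect_equal(s2 - s1, c0$beta_alp * 100)
  expect_error(linear_predictor(1, Inf, 100, c0), "non-finite")
})

test_that("predict_prob is the inverse logit", {
  expect_equal(predict_prob(0), 0.5)
  expect_equal(predict_prob(100), 1, tolerance = 1e-12)
  for (s in c(-3, -0.5, 0.7, 4)) {
    expect_equal(predict_prob(s) + predict_prob(-s), 1)
  }
})

test_that("intercept-only fit equals the closed-form log odds", {
  y <- c(rep(1, 7), rep(0, 13))
  fit <- fit_logistic(matrix(numeric(0), nrow = 20, ncol = 0), y)
  expect_equal(unname(fit$coef), log(7 / 13), tolerance = 1e-9)
})

test_that("2x2 design recovers the contingency-table odds ratio", {
  # x=0: 10/40 events; x=1: 15/30 events -> OR = (15/15)/(10/30) = 3
  x <- c(rep(0, 40), rep(1, 30))
  y <- c(rep(1, 10), rep(0, 30), rep(1, 15), rep(0, 15))
  fit <- fit_logistic(cbind(x = x), y)
  expect_equal(unname(fit$coef["x"]), log(3), tolerance = 1e-8)
  expect_equal(unname(fit$coef["(Intercept)"]), log(10 / 30), tolerance = 1e-8)
  expect_equal(unname(fit$or["x"]), 3, tolerance = 1e-7)
  # odds ratio = exp(coefficient) exactly as constructed
  expect_equal(fit$or, exp(fit$coef))
})

test_that("IRLS agrees with glm and with brute-force grid maximization", {
  set.seed(42)
  x <- rnorm(80)
  y <- rbinom(80, 1, plogis(-0.5 + 1.2 * x))
  fit <- fit_logistic(cbind(x = x), y)
  ref <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)

  # single-coefficient model vs a two-stage grid search of the likelihood
  fit1 <- fit_logistic(cbind(x = x), y, add_intercept = FALSE)
  ll <- function(b) sum(y * (b * x) - log1p(exp(b * x)))
  coarse <- seq(-5, 5, by = 0.01)
  b0 <- coarse[which.max(vapply(coarse, ll, 0))]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  best <- fine[which.max(vapply(fine, ll, 0))]
  expect_equal(unname(fit1$coef), best, tolerance = 1e-3)
})

test_that("fit_logistic flags separation, constants and singularity", {
  x <- c(rep(0, 10), rep(1, 10))
  y <- c(rep(0, 10), rep(1, 10))
  expect_error(fit_logistic(cbind(x = x), y), "separation")
  expect_error(fit_logistic(cbind(k = rep(1, 20)), rep(c(0, 1), 10)),
               "constant")
  set.seed(1)
  x1 <- rnorm(30)
  expect_error(fit_logistic(cbind(a = x1, b = 2 * x1), rep(c(0, 1), 15)),
               "singular|separation")
  expect_error(fit_logistic(cbind(x = rnorm(10)), rep(0, 10)), "both classes")
})

test_that("parameter recovery on a simulated cohort within 3 SE", {
  set.seed(77)
  n <- 2000
  dsp <- rbinom(n, 1, 0.35)
  inr <- rlnorm(n, log(1.1), 0.2)
  alp <- rlnorm(n, log(170), 0.35)
  truth <- c(dsp = 1.363, inr = 2.468, alp = 0.004)
  eta <- -7 + truth["dsp"] * dsp + truth["inr"] * inr + truth["alp"] * alp
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(cbind(dsp = dsp, inr = inr, alp = alp), y)
  for (v in names(truth)) {
    expect_lt(abs(fit$coef[[v]] - truth[[v]]), 3 * fit$se[[v]])
  }
})

test_that("univariate screening keeps signal and drops pure noise", {
  set.seed(11)
  n <- 600
  signal <- rnorm(n)
  noise <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 1.5 * signal))
  sc <- univariate_screen(cbind(signal = signal, noise = noise), y)
  expect_true(sc$keep[sc$variable == "signal"])
  expect_equal(sort(sc$variable), c("noise", "signal"))
})

test_that("forward LR selection enters the true covariate first", {
  set.seed(13)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 2 * x1))
  fwd <- forward_lr_select(cbind(a_noise = x2, signal = x1, z_noise = x3), y)
  expect_equal(fwd$selected[1], "signal")
  # the selection-path log-likelihood is non-decreasing (nested models)
  expect_true(all(diff(c(-Inf, fwd$path$loglik)) >= 0))
  # no candidate passing -> intercept-only model
  fwd0 <- forward_lr_select(cbind(a = x2, b = x3), y, alpha_in = 1e-6)
  expect_length(fwd0$selected, 0)
  expect_named(fwd0$fit$coef, "(Intercept)")
})

test_that("calibrated intercept hits the target prevalence", {
  set.seed(3)
  score <- rnorm(200, 2, 1.5)
  for (prev in c(0.046, 0.2, 0.7)) {
    ic <- calibrate_intercept(score, prev)
    expect_equal(mean(plogis(ic + score)), prev, tolerance = 1e-9)
  }
  expect_error(calibrate_intercept(score, 0), "in \\(0,1\\)")
})
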