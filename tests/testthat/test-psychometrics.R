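test_that("psi evaluates the four-parameter sigmoid and its asymptotes", {
  p <- psychometric_params(m = 40, w = 20, lambda = 0.05, gamma = 0.1)
  expect_equal(psi(40, p), 0.1 + (1 - 0.05 - 0.1) * 0.5)
  expect_equal(psi(1e6, p), 1 - 0.05, tolerance = 1e-9)
  expect_equal(psi(-1e6, p), 0.1, tolerance = 1e-9)

  p0 <- psychometric_params(m = 40, w = 20)
  expect_equal(psi(40, p0), 0.5)
  # width convention: default w spans S = 0.5 to S = 0.95
  expect_equal(psi(60, p0), 0.95, tolerance = 1e-9)
  p_alt <- psychometric_params(m = 40, w = 20, width_conv = "0.05-0.95")
  expect_equal(psi(50, p_alt), 0.95, tolerance = 1e-9)

  expect_error(psychometric_params(40, -1), "parameter error")
  expect_error(psychometric_params(40, 10, lambda = 0.6), "parameter error")
})

test_that("psi is monotone non-decreasing for random valid parameter draws", {
  set.seed(123)
  x <- seq(-50, 150, length.out = 200)
  for (i in 1:50) {
    p <- psychometric_params(m = runif(1, 0, 80), w = runif(1, 1, 60),
                             lambda = runif(1, 0, 0.45),
                             gamma = runif(1, 0, 0.45))
    expect_true(all(diff(psi(x, p)) >= 0))
  }
})

test_that("the half-rise of psi sits at the threshold m", {
  set.seed(124)
  for (i in 1:20) {
    p <- psychometric_params(m = runif(1, 10, 70), w = runif(1, 5, 40),
                             lambda = runif(1, 0, 0.4),
                             gamma = runif(1, 0, 0.4))
    half <- p$gamma + (1 - p$lambda - p$gamma) / 2
    root <- uniroot(function(x) psi(x, p) - half, c(-200, 300),
                    tol = 1e-12)$root
    expect_lt(abs(root - p$m), 1e-9)
  }
})

test_that("refitting noise-free expected proportions recovers the parameters", {
  gen <- psychometric_params(m = 40, w = 20, lambda = 0.02, gamma = 0.05)
  lv <- c(0, 15, 30, 45, 60, 70, 80)
  d <- data.frame(level_db = lv, n = 1e6, k = 1e6 * psi(lv, gen))
  fit <- fit_psychometric(d)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(40, 20, 0.02, 0.05), tolerance = 1e-3)
  # fit log-likelihood is not worse than at the generating parameters
  p_gen <- pmin(pmax(psi(lv, gen), 1e-10), 1 - 1e-10)
  ll_gen <- sum(d$k * log(p_gen) + (d$n - d$k) * log(1 - p_gen))
  # the fit maximises a weakly lapse/guess-penalised likelihood, so its raw
  # log-likelihood can sit a hair below the generating value
  expect_gte(fit$log_likelihood, ll_gen - 0.05)
})

test_that("simulated observer data recover the threshold within its own CI", {
  gen <- psychometric_params(m = 40, w = 20, lambda = 0.02, gamma = 0.05)
  lv <- c(0, 15, 30, 45, 60, 70, 80)
  set.seed(200)
  d <- data.frame(level_db = lv, n = 200,
                  k = rbinom(7, 200, psi(lv, gen)))
  fit <- fit_psychometric(d)
  expect_true(fit$converged)
  ci <- bootstrap_ci(fit, n_boot = 100, seed = 1)
  expect_lte(ci["m", "lower"], coef(fit)[["m"]])
  expect_gte(ci["m", "upper"], coef(fit)[["m"]])
})

test_that("degenerate or under-determined data are flagged, never estimated", {
  lv <- c(10, 20, 30, 40)
  expect_warning(
    fit <- fit_psychometric(data.frame(level_db = lv, n = 50, k = 0)),
    "non-convergence")
  expect_false(fit$converged)
  expect_true(all(is.na(coef(fit))))
  expect_error(predict(fit, 25), "input error")
  expect_error(bootstrap_ci(fit), "input error")

  expect_error(fit_psychometric(data.frame(level_db = c(10, 20), n = 50,
                                           k = c(5, 45))),
               "input error")
})

test_that("bootstrap intervals narrow with sample size and are reproducible", {
  gen <- psychometric_params(m = 40, w = 20, lambda = 0.02, gamma = 0.05)
  lv <- c(0, 15, 30, 45, 60, 70, 80)
  widths <- vapply(c(50, 800), function(n_per) {
    set.seed(300)
    d <- data.frame(level_db = lv, n = n_per,
                    k = rbinom(7, n_per, psi(lv, gen)))
    fit <- fit_psychometric(d)
    ci <- bootstrap_ci(fit, n_boot = 100, seed = 2)
    unname(ci["m", "upper"] - ci["m", "lower"])
  }, 0)
  expect_gt(widths[1], widths[2])

  set.seed(301)
  d <- data.frame(level_db = lv, n = 200, k = rbinom(7, 200, psi(lv, gen)))
  fit <- fit_psychometric(d)
  ci_a <- bootstrap_ci(fit, n_boot = 100, seed = 7)
  ci_b <- bootstrap_ci(fit, n_boot = 100, seed = 7)
  expect_identical(ci_a, ci_b)
  expect_error(bootstrap_ci(fit, n_boot = 10), "input error")
})

test_that("psychfit methods behave like a standard fitted model object", {
  gen <- psychometric_params(m = 40, w = 20, lambda = 0.02, gamma = 0.05)
  lv <- c(0, 15, 30, 45, 60, 70, 80)
  set.seed(400)
  d <- data.frame(level_db = lv, n = 200, k = rbinom(7, 200, psi(lv, gen)))
  fit <- fit_psychometric(d)

  expect_named(coef(fit), c("m", "w", "lambda", "gamma"))
  expect_s3_class(logLik(fit), "logLik")
  expect_equal(predict(fit), psi(lv, fit$params))
  expect_equal(predict(fit, data.frame(level_db = 40)),
               psi(40, fit$params))
  expect_length(residuals(fit), 7)
  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_length(sims, 3)
  expect_true(all(sims[[1]]$k <= sims[[1]]$n))
  expect_output(print(fit), "threshold")
  ci <- confint(fit, n_boot = 100, seed = 3)
  expect_equal(dim(ci), c(4, 2))

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("fixed parameters are honored by the fit", {
  gen <- psychometric_params(m = 40, w = 20, lambda = 0, gamma = 0)
  lv <- c(0, 15, 30, 45, 60, 70, 80)
  set.seed(500)
  d <- data.frame(level_db = lv, n = 300, k = rbinom(7, 300, psi(lv, gen)))
  fit <- fit_psychometric(d, fixed = c(lambda = 0, gamma = 0))
  expect_equal(coef(fit)[["lambda"]], 0)
  expect_equal(coef(fit)[["gamma"]], 0)
  expect_equal(coef(fit)[["m"]], 40, tolerance = 2)
})
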