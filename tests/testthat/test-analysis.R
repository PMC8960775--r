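test_that("hit_rate_table counts scored, correct, and ignored trials", {
  log <- manual_log(c(rep(TRUE, 8), FALSE, NA))
  tab <- hit_rate_table(log)
  expect_equal(tab$n_trials, 10)
  expect_equal(tab$n_scored, 9)
  expect_equal(tab$n_ignored, 1)
  expect_equal(tab$hit_rate, 8 / 9, tolerance = 1e-12)

  expect_equal(nrow(hit_rate_table(log[0, ])), 0)
})

test_that("last-k windowing keeps only the final sessions per animal-task", {
  logs <- do.call(rbind, lapply(1:8, function(s)
    manual_log(rep(TRUE, 5), session = sprintf("s%d", s))))
  tab_all <- hit_rate_table(logs)
  tab_5 <- hit_rate_table(logs, last_k = 5)
  expect_equal(tab_all$n_trials, 40)
  expect_equal(tab_5$n_trials, 25)
})

test_that("per-stimulus d-prime uses the other stimulus's errors as false alarms", {
  log <- rbind(
    manual_log(c(rep(TRUE, 84), rep(FALSE, 16)), sound = "voc"),
    manual_log(c(rep(TRUE, 84), rep(FALSE, 16)), sound = "sTr",
               choice = NULL))
  tab <- hit_rate_table(log)
  expect_equal(tab$d_prime, rep(qnorm(0.84) - qnorm(0.16), 2),
               tolerance = 1e-9)
})

test_that("dprime matches the quantile oracle and stays finite at the extremes", {
  expect_equal(dprime(0.5, 0.5, 100, 100), 0)
  expect_equal(dprime(0.84, 0.84, 100, 100), qnorm(0.84) - qnorm(0.16),
               tolerance = 1e-9)
  # perfect rates clipped by the 1/(2N) rule
  expect_equal(dprime(1, 1, 10, 10), qnorm(0.95) - qnorm(0.05),
               tolerance = 1e-9)
  expect_true(is.finite(dprime(1, 1, 10, 10)))
  # antisymmetry under exchanging the two stimuli
  expect_equal(dprime(0.9, 0.6, 50, 80), -dprime(1 - 0.9, 1 - 0.6, 50, 80),
               tolerance = 1e-9)
  expect_error(dprime(0.5, 0.5, 0, 10), "input error")
})

test_that("binomial_vs_chance equals brute-force pmf enumeration for n <= 20", {
  for (n in 1:20) {
    for (p in c(0.5, 1 / 3)) {
      for (k in 0:n) {
        expect_equal(binomial_vs_chance(k, n, p), brute_binom_upper(k, n, p),
                     tolerance = 1e-12)
      }
    }
  }
  expect_equal(binomial_vs_chance(10, 10, 0.5), 2^-10)
  expect_equal(binomial_vs_chance(5, 10, 0.5), 0.6230469, tolerance = 1e-6)
  expect_equal(binomial_vs_chance(64, 70, 0.5), 1.221363e-13,
               tolerance = 1e-6)
  expect_error(binomial_vs_chance(1, 0, 0.5), "input error")
})

test_that("Bonferroni adjustment caps at one and reproduces the corrected alpha", {
  expect_equal(bonferroni_alpha(0.05, 26), 0.05 / 26)
  expect_equal(round(bonferroni_alpha(0.05, 26), 4), 0.0019)
  expect_equal(bonferroni_adjust(0.1, 26), 1)
  expect_equal(bonferroni_adjust(0.001, 26), 0.026)
  expect_equal(bonferroni_adjust(c(0.01, 0.2)), c(0.02, 0.4))
  expect_equal(bonferroni_adjust(0.3, 1), 0.3)
  expect_error(bonferroni_adjust(0.1, 0), "input error")
})

test_that("Kruskal-Wallis H matches the hand rank computation", {
  kw <- kruskal_wallis_ranks(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-9)
  expect_equal(kw$df, 1)

  same <- kruskal_wallis_ranks(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)

  expect_error(kruskal_wallis_ranks(list(c(1, 2))), "input error")
  expect_error(kruskal_wallis_ranks(list(numeric(0), 1:3)), "input error")
})

test_that("shifted reaction-time groups are detected by the rank test", {
  set.seed(77)
  hits <- replicate(20, {
    a <- rlnorm(200, log(1.3), 0.4)
    b <- rlnorm(200, log(1.8), 0.4)
    kruskal_wallis_ranks(list(a, b))$p_value < 0.05
  })
  expect_gt(mean(hits), 0.9)
})

test_that("engagement summary normalizes timestamps and tallies empty sessions", {
  log <- manual_log(rep(TRUE, 10))
  log$t_start_s <- seq(0.1, 1, by = 0.1) * 100
  durations <- data.frame(session_id = c("s1", "s2"),
                          animal_id = "a", duration_s = 100)
  es <- engagement_summary(log, durations)
  expect_equal(es$sessions$median_normalized_timestamp[1], 0.55)
  expect_equal(es$sessions$n_trials, c(10, 0))
  expect_equal(es$animals$n_zero_trial_sessions, 1)
  expect_true(all(na.omit(es$sessions$median_normalized_timestamp) >= 0 &
                    na.omit(es$sessions$median_normalized_timestamp) <= 1))

  one <- manual_log(TRUE)
  one$t_start_s <- 100
  es1 <- engagement_summary(one, durations[1, ])
  expect_equal(es1$sessions$median_normalized_timestamp, 1.0)

  expect_error(engagement_summary(log, transform(durations, duration_s = 0)),
               "input error")
  bad <- log
  bad$t_start_s[1] <- 200
  expect_error(engagement_summary(bad, durations), "input error")
})

test_that("learning-curve bins conserve trials on a shared percent axis", {
  log <- manual_log(rep(c(TRUE, FALSE), 50))
  bins <- learning_curve_bins(log, bin_percent = 5)
  expect_equal(nrow(bins), 20)
  expect_equal(unique(bins$n_trials), 5)
  expect_equal(sum(bins$n_trials), 100)

  all_correct <- manual_log(rep(TRUE, 40))
  expect_true(all(learning_curve_bins(all_correct, 10)$hit_rate == 1))

  # animals with different N land on the same axis
  two <- rbind(manual_log(rep(TRUE, 100), animal = "a"),
               manual_log(rep(TRUE, 60), animal = "b"))
  bins2 <- learning_curve_bins(two, bin_percent = 10)
  expect_equal(sort(unique(bins2$bin)), seq(10, 100, 10))
  expect_equal(sum(bins2$n_trials[bins2$animal_id == "b"]), 60)

  expect_error(learning_curve_bins(log, bin_percent = 7), "input error")
  expect_equal(nrow(learning_curve_bins(log[0, ], 5)), 0)
})

test_that("partial correlation removes the covariate's contribution", {
  set.seed(99)
  n <- 200
  z <- rnorm(n)
  # covariate unrelated to x and y: partial matches plain Pearson
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  pp <- partial_pearson(x, y, z)
  expect_equal(pp$r, cor(x, y), tolerance = 0.05)
  expect_true(pp$ci[1] <= pp$r && pp$r <= pp$ci[2])

  # y dominated by the covariate: partial r collapses to zero
  y2 <- z + rnorm(n, sd = 1e-3)
  expect_lt(abs(partial_pearson(x, y2, z)$r), 0.15)

  # matches the closed-form first-order partial correlation
  y3 <- 0.4 * z + rnorm(n)
  x3 <- 0.3 * z + rnorm(n)
  rxy <- cor(x3, y3); rxz <- cor(x3, z); ryz <- cor(y3, z)
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(partial_pearson(x3, y3, z)$r, closed, tolerance = 1e-10)

  expect_error(partial_pearson(1:3, 1:3, 1:3), "input error")
  expect_error(partial_pearson(rep(1, 10), rnorm(10), rnorm(10)),
               "input error")
})
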