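#' Psychometric function parameters
#'
#' The psychometric function used throughout the detection analysis is
#' \deqn{\psi(x; m, w, \lambda, \gamma) = \gamma + (1 - \lambda - \gamma)\, S(x; m, w)}
#' with a cumulative-normal core S. `m` is the threshold (the level at which
#' S crosses 0.5), `w` the width, `lambda` the lapse rate (distance of the
#' upper asymptote from 1) and `gamma` the guess rate (lower asymptote).
#'
#' Two width conventions are supported: the default `"0.5-0.95"` defines `w`
#' as the level difference between S = 0.5 and S = 0.95 (scale constant
#' `qnorm(0.95)`); `"0.05-0.95"` as the difference between S = 0.05 and
#' S = 0.95 (scale constant `2 * qnorm(0.95)`).
#'
#' @param m Threshold, in stimulus units (dB SPL).
#' @param w Width, in stimulus units; > 0.
#' @param lambda Lapse rate in `[0, 0.5)`.
#' @param gamma Guess rate in `[0, 0.5)`.
#' @param width_conv Width convention (see Details).
#' @return A list of class `psychometric_params`.
#' @export
psychometric_params <- function(m, w, lambda = 0, gamma = 0,
                                width_conv = c("0.5-0.95", "0.05-0.95")) {
  width_conv <- match.arg(width_conv)
  if (w <= 0) stop("parameter error: width w must be positive", call. = FALSE)
  if (lambda < 0 || lambda >= 0.5 || gamma < 0 || gamma >= 0.5)
    stop("parameter error: lambda and gamma must lie in [0, 0.5)", call. = FALSE)
  if (lambda + gamma >= 1)
    stop("parameter error: lambda + gamma must be < 1", call. = FALSE)
  structure(list(m = m, w = w, lambda = lambda, gamma = gamma,
                 width_conv = width_conv),
            class = "psychometric_params")
}

width_scale <- function(width_conv) {
  switch(width_conv,
         "0.5-0.95" = stats::qnorm(0.95),
         "0.05-0.95" = 2 * stats::qnorm(0.95))
}

#' Evaluate the psychometric function
#'
#' @param x Stimulus level(s), in the units of `m` and `w`.
#' @param params A [psychometric_params()].
#' @return Response probabilities in `(gamma, 1 - lambda)`, strictly
#'   increasing in `x`.
#' @examples
#' p <- psychometric_params(m = 40, w = 20)
#' psi(40, p)  # 0.5
#' @export
psi <- function(x, params) {
  stopifnot(inherits(params, "psychometric_params"))
  s <- stats::pnorm(width_scale(params$width_conv) * (x - params$m) / params$w)
  params$gamma + (1 - params$lambda - params$gamma) * s
}

psi_raw <- function(x, m, w, lambda, gamma, cnum) {
  gamma + (1 - lambda - gamma) * stats::pnorm(cnum * (x - m) / w)
}

neg_loglik <- function(par, level, n, k, cnum, fixed) {
  full <- c(par, fixed)
  m <- full[["m"]]; w <- full[["w"]]
  lambda <- full[["lambda"]]; gamma <- full[["gamma"]]
  p <- psi_raw(level, m, w, lambda, gamma, cnum)
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  nll <- -sum(k * log(p) + (n - k) * log(1 - p))
  # weak Beta(1, 10) priors keep the free lapse/guess rates from drifting
  nll <- nll - stats::dbeta(min(lambda / 0.5, 1 - 1e-9), 1, 10, log = TRUE)
  nll <- nll - stats::dbeta(min(gamma / 0.5, 1 - 1e-9), 1, 10, log = TRUE)
  nll
}

#' Fit the psychometric function by maximum likelihood
#'
#' Maximises the binomial log-likelihood of the level/count data under the
#' cumulative-normal psychometric function, with all four parameters free by
#' default (any subset can be fixed). Optimisation is L-BFGS-B from a
#' deterministic multi-start grid spanning the level range; weak Beta(1, 10)
#' priors on the lapse and guess rates (scaled to their [0, 0.5) range)
#' stabilise the free fit at small samples.
#'
#' @param data `data.frame` with columns `level_db`, `n` (trials) and `k`
#'   (target responses), one row per level; at least 3 distinct levels.
#' @param fixed Optional named numeric fixing parameters, e.g.
#'   `c(gamma = 0)`.
#' @param bounds Optional named list of `c(lower, upper)` pairs overriding
#'   the default box constraints.
#' @param width_conv Width convention, see [psychometric_params()].
#' @param n_starts Grid density of the multi-start (total starts is about
#'   `n_starts^2`).
#' @return An object of class `psychfit` with components `params`
#'   ([psychometric_params()]), `estimate` (named vector), `fixed`,
#'   `log_likelihood` (without the prior penalty), `converged`, `data`,
#'   `ci95` (`NULL` until [confint()] / [bootstrap_ci()] is called) and
#'   `width_conv`. Methods: `print`, `summary`, `coef`, `logLik`, `predict`,
#'   `plot`, `simulate`, `residuals`, `confint`.
#' @examples
#' p <- psychometric_params(m = 40, w = 20, lambda = 0.02, gamma = 0.05)
#' lv <- c(0, 15, 30, 45, 60, 70, 80)
#' d <- data.frame(level_db = lv, n = 200, k = round(200 * psi(lv, p)))
#' fit <- fit_psychometric(d)
#' coef(fit)
#' @export
fit_psychometric <- function(data, fixed = NULL, bounds = NULL,
                             width_conv = c("0.5-0.95", "0.05-0.95"),
                             n_starts = 4) {
  width_conv <- match.arg(width_conv)
  stopifnot(all(c("level_db", "n", "k") %in% names(data)))
  if (any(data$k < 0 | data$k > data$n))
    stop("input error: need 0 <= k <= n at every level", call. = FALSE)
  level <- data$level_db
  if (length(unique(level)) < 3)
    stop("input error: need at least 3 distinct levels", call. = FALSE)
  cnum <- width_scale(width_conv)

  rng <- range(level)
  span <- max(diff(rng), 1)
  default_bounds <- list(m = c(rng[1] - span, rng[2] + span),
                         w = c(span / 100, 4 * span),
                         lambda = c(0, 0.4999), gamma = c(0, 0.4999))
  if (!is.null(bounds)) default_bounds[names(bounds)] <- bounds
  bd <- default_bounds

  par_names <- setdiff(c("m", "w", "lambda", "gamma"), names(fixed))
  fixed <- if (is.null(fixed)) numeric(0) else unlist(fixed)

  # degenerate data carry no slope information: flag, do not estimate
  prop <- data$k / data$n
  degenerate <- all(prop <= 1e-12) || all(prop >= 1 - 1e-12) ||
    stats::sd(prop) == 0
  if (degenerate) {
    warning("non-convergence: response proportions carry no level information")
    fit <- list(params = NULL,
                estimate = stats::setNames(rep(NA_real_, 4),
                                           c("m", "w", "lambda", "gamma")),
                fixed = fixed, log_likelihood = NA_real_, converged = FALSE,
                data = data, ci95 = NULL, width_conv = width_conv)
    class(fit) <- "psychfit"
    return(fit)
  }

  m_grid <- seq(rng[1], rng[2], length.out = n_starts)
  w_grid <- span * c(0.25, 0.5, 1)[seq_len(min(3, n_starts))]
  starts <- expand.grid(m = m_grid, w = w_grid, lambda = 0.02, gamma = 0.05)

  lower <- vapply(par_names, function(nm) bd[[nm]][1], 0)
  upper <- vapply(par_names, function(nm) bd[[nm]][2], 0)
  results <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    p0 <- unlist(starts[i, par_names, drop = FALSE])
    p0 <- pmin(pmax(p0, lower), upper)
    res <- tryCatch(
      stats::optim(p0, neg_loglik, level = level, n = data$n, k = data$k,
                   cnum = cnum, fixed = fixed, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value)) results[[i]] <- res
  }
  results <- results[!vapply(results, is.null, TRUE)]
  if (length(results) == 0)
    stop("optimization error: no start converged", call. = FALSE)
  values <- vapply(results, `[[`, 0, "value")
  clean <- vapply(results, function(r) r$convergence == 0, TRUE)
  # prefer a cleanly converged start among those reaching the optimum;
  # a start may stop at the same minimum with a line-search code
  at_best <- values <= min(values) + 1e-6
  best <- if (any(clean & at_best)) results[clean & at_best][[1]]
          else results[[which.min(values)]]

  est <- c(best$par, fixed)[c("m", "w", "lambda", "gamma")]
  params <- psychometric_params(est[["m"]], est[["w"]], est[["lambda"]],
                                est[["gamma"]], width_conv)
  p_hat <- psi(level, params)
  p_hat <- pmin(pmax(p_hat, 1e-10), 1 - 1e-10)
  ll <- sum(data$k * log(p_hat) + (data$n - data$k) * log(1 - p_hat))

  fit <- list(params = params, estimate = est, fixed = fixed,
              log_likelihood = ll, converged = best$convergence == 0,
              data = data, ci95 = NULL, width_conv = width_conv,
              bounds = bd)
  class(fit) <- "psychfit"
  fit
}

#' Parametric bootstrap confidence intervals for a psychometric fit
#'
#' Resamples counts at each level from the fitted function, refits, and
#' takes percentile intervals. Refits start from the original estimate
#' (single start), which is fast and adequate because the bootstrap data
#' are draws from that very model.
#'
#' @param fit A converged `psychfit`.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param max_fail_frac Flag the intervals unreliable when more than this
#'   fraction of refits fail.
#' @return A 4 x 2 matrix of 95% limits (rows m, w, lambda, gamma) with
#'   attributes `n_fail` and `reliable`.
#' @export
bootstrap_ci <- function(fit, n_boot = 200, seed = 1, max_fail_frac = 0.2) {
  stopifnot(inherits(fit, "psychfit"))
  if (!fit$converged)
    stop("input error: bootstrap requires a converged fit", call. = FALSE)
  if (n_boot < 100)
    stop("input error: n_boot must be >= 100", call. = FALSE)
  set.seed(seed)
  level <- fit$data$level_db
  n <- fit$data$n
  p_hat <- psi(level, fit$params)
  cnum <- width_scale(fit$width_conv)
  par_names <- setdiff(c("m", "w", "lambda", "gamma"), names(fit$fixed))
  lower <- vapply(par_names, function(nm) fit$bounds[[nm]][1], 0)
  upper <- vapply(par_names, function(nm) fit$bounds[[nm]][2], 0)
  p0 <- fit$estimate[par_names]

  draws <- matrix(NA_real_, n_boot, 4,
                  dimnames = list(NULL, c("m", "w", "lambda", "gamma")))
  n_fail <- 0L
  for (b in seq_len(n_boot)) {
    k_star <- stats::rbinom(length(level), n, p_hat)
    res <- tryCatch(
      stats::optim(p0, neg_loglik, level = level, n = n, k = k_star,
                   cnum = cnum, fixed = fit$fixed, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) {
      n_fail <- n_fail + 1L
    } else {
      draws[b, ] <- c(res$par, fit$fixed)[c("m", "w", "lambda", "gamma")]
    }
  }
  ci <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  attr(ci, "n_fail") <- n_fail
  attr(ci, "reliable") <- n_fail <= max_fail_frac * n_boot
  if (!attr(ci, "reliable"))
    warning("bootstrap CI unreliable: too many refit failures")
  ci
}

#' @export
print.psychfit <- function(x, ...) {
  cat("<psychfit> cumulative-normal psychometric fit\n")
  if (!x$converged) {
    cat("  not converged\n")
    return(invisible(x))
  }
  cat(sprintf("  threshold m = %.2f, width w = %.2f (%s), lambda = %.3f, gamma = %.3f\n",
              x$estimate[["m"]], x$estimate[["w"]], x$width_conv,
              x$estimate[["lambda"]], x$estimate[["gamma"]]))
  cat(sprintf("  log-likelihood %.2f over %d levels\n", x$log_likelihood,
              nrow(x$data)))
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...) object$estimate

#' @export
logLik.psychfit <- function(object, ...) {
  structure(object$log_likelihood,
            df = 4 - length(object$fixed), class = "logLik")
}

#' @export
summary.psychfit <- function(object, ...) {
  print(object)
  if (!is.null(object$ci95)) {
    cat("  95% bootstrap CIs:\n")
    print(round(object$ci95, 3))
  }
  invisible(object)
}

#' @param object,x A `psychfit`.
#' @param newdata Numeric levels (or a data.frame with `level_db`) at which
#'   to evaluate the fitted function; defaults to the fitted levels.
#' @param ... Unused.
#' @rdname fit_psychometric
#' @export
predict.psychfit <- function(object, newdata = NULL, ...) {
  if (!object$converged)
    stop("input error: cannot predict from a non-converged fit", call. = FALSE)
  x <- if (is.null(newdata)) object$data$level_db
       else if (is.data.frame(newdata)) newdata$level_db
       else newdata
  psi(x, object$params)
}

#' @export
residuals.psychfit <- function(object, ...) {
  p <- predict(object)
  obs <- object$data$k / object$data$n
  sign(obs - p) * sqrt(2 * (ll_term(object$data$k, object$data$n, obs) -
                            ll_term(object$data$k, object$data$n, p)))
}

ll_term <- function(k, n, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  k * log(p) + (n - k) * log(1 - p)
}

#' @export
simulate.psychfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object)
  lapply(seq_len(nsim), function(i) {
    data.frame(level_db = object$data$level_db, n = object$data$n,
               k = stats::rbinom(nrow(object$data), object$data$n, p))
  })
}

#' @param parm,level Standard [stats::confint()] arguments (`level` is the
#'   confidence level; only 0.95 is supported).
#' @param n_boot,seed Bootstrap settings, see [bootstrap_ci()].
#' @rdname bootstrap_ci
#' @export
confint.psychfit <- function(object, parm = c("m", "w", "lambda", "gamma"),
                             level = 0.95, n_boot = 200, seed = 1, ...) {
  if (level != 0.95)
    stop("input error: only 95% intervals are supported", call. = FALSE)
  ci <- object$ci95
  if (is.null(ci)) ci <- bootstrap_ci(object, n_boot = n_boot, seed = seed)
  ci[parm, , drop = FALSE]
}

#' @export
plot.psychfit <- function(x, ...) {
  obs <- x$data$k / x$data$n
  graphics::plot(x$data$level_db, obs, pch = 19, ylim = c(0, 1),
                 xlab = "Level (dB SPL)", ylab = "P(target response)", ...)
  if (x$converged) {
    xx <- seq(min(x$data$level_db), max(x$data$level_db), length.out = 200)
    graphics::lines(xx, psi(xx, x$params))
    graphics::abline(v = x$estimate[["m"]], lty = 2)
  }
  invisible(x)
}
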