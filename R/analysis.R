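#' Per-stimulus performance table
#'
#' Summarises session logs into one row per (animal, task, sound): trial
#' counts, hit rate over scored (non-ignored) trials, a signal-detection
#' sensitivity index, and a one-sided binomial test of the hit rate against
#' chance with Bonferroni adjustment. Chance is 1/2 for two displayed options
#' and 1/3 for three unless overridden.
#'
#' @param logs Session-log `data.frame` (see [write_session_log()] for the
#'   column layout); several logs may be `rbind`ed.
#' @param last_k Restrict to each animal-task's last `last_k` sessions (in
#'   order of first appearance); `NULL` uses all sessions.
#' @param chance Chance success probability; default is inferred from the
#'   task variant (1/3 for `3ac`, otherwise 1/2).
#' @param family_size Bonferroni family size; defaults to the number of rows
#'   in the table.
#' @return A `data.frame` with columns `animal_id`, `task`, `sound_id`,
#'   `n_trials`, `n_scored`, `n_correct`, `n_ignored`, `hit_rate`, `d_prime`,
#'   `p_value_raw`, `p_value_adjusted`. Stimuli with zero scored trials get
#'   `NA` rates and are flagged via `n_scored = 0`.
#' @export
hit_rate_table <- function(logs, last_k = NULL, chance = NULL,
                           family_size = NULL) {
  if (is.null(logs) || nrow(logs) == 0) {
    return(data.frame(animal_id = character(), task = character(),
                      sound_id = character(), n_trials = integer(),
                      n_scored = integer(), n_correct = integer(),
                      n_ignored = integer(), hit_rate = numeric(),
                      d_prime = numeric(), p_value_raw = numeric(),
                      p_value_adjusted = numeric()))
  }
  logs <- filter_last_k(logs, last_k)

  key <- interaction(logs$animal_id, logs$task, logs$sound_id, drop = TRUE)
  rows <- lapply(split(logs, key), function(d) {
    scored <- d$choice != "ignored" & !is.na(d$correct)
    data.frame(animal_id = d$animal_id[1], task = d$task[1],
               sound_id = d$sound_id[1],
               n_trials = nrow(d),
               n_scored = sum(scored),
               n_correct = sum(d$correct[scored]),
               n_ignored = sum(!scored),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$hit_rate <- ifelse(tab$n_scored > 0, tab$n_correct / tab$n_scored, NA_real_)

  # d': hit rate on this stimulus vs false alarms taken as the errors on the
  # remaining stimuli of the same animal-task (pooled)
  tab$d_prime <- NA_real_
  for (i in seq_len(nrow(tab))) {
    others <- tab$animal_id == tab$animal_id[i] & tab$task == tab$task[i] &
      tab$sound_id != tab$sound_id[i]
    n_b <- sum(tab$n_scored[others])
    if (tab$n_scored[i] > 0 && n_b > 0) {
      hit_b <- sum(tab$n_correct[others]) / n_b
      tab$d_prime[i] <- dprime(tab$hit_rate[i], hit_b, tab$n_scored[i], n_b)
    }
  }

  p_chance <- if (is.null(chance)) ifelse(tab$task == "3ac", 1 / 3, 1 / 2)
              else rep(chance, nrow(tab))
  tab$p_value_raw <- NA_real_
  ok <- tab$n_scored > 0
  tab$p_value_raw[ok] <- mapply(binomial_vs_chance, tab$n_correct[ok],
                                tab$n_scored[ok], p_chance[ok])
  m <- if (is.null(family_size)) sum(ok) else family_size
  tab$p_value_adjusted <- NA_real_
  tab$p_value_adjusted[ok] <- bonferroni_adjust(tab$p_value_raw[ok], m)
  tab
}

filter_last_k <- function(logs, last_k) {
  if (is.null(last_k)) return(logs)
  keep <- rep(FALSE, nrow(logs))
  for (g in split(seq_len(nrow(logs)),
                  interaction(logs$animal_id, logs$task, drop = TRUE))) {
    sess <- unique(logs$session_id[g])
    use <- utils::tail(sess, last_k)
    keep[g] <- logs$session_id[g] %in% use
  }
  logs[keep, , drop = FALSE]
}

#' Signal-detection sensitivity index
#'
#' Yes/no d-prime between two stimulus classes: `z(H) - z(FA)`, where H is
#' the hit rate on A-trials and FA the error rate on B-trials
#' (`1 - hit_rate_b`). Extreme rates are clipped to `[1/(2N), 1 - 1/(2N)]`
#' before the quantile transform so perfect performance stays finite.
#'
#' @param hit_rate_a,hit_rate_b Hit rates in `[0, 1]` on the two stimulus
#'   classes.
#' @param n_a,n_b Scored trial counts (>= 1).
#' @param correction Apply the 1/(2N) extreme-rate rule (default `TRUE`).
#' @return The sensitivity index (unitless).
#' @examples
#' dprime(0.84, 0.84, 100, 100)  # about 1.99
#' @export
dprime <- function(hit_rate_a, hit_rate_b, n_a, n_b, correction = TRUE) {
  if (n_a < 1 || n_b < 1)
    stop("input error: trial counts must be >= 1", call. = FALSE)
  if (any(c(hit_rate_a, hit_rate_b) < 0) || any(c(hit_rate_a, hit_rate_b) > 1))
    stop("input error: rates must lie in [0, 1]", call. = FALSE)
  h <- hit_rate_a
  fa <- 1 - hit_rate_b
  if (correction) {
    h <- min(max(h, 1 / (2 * n_a)), 1 - 1 / (2 * n_a))
    fa <- min(max(fa, 1 / (2 * n_b)), 1 - 1 / (2 * n_b))
  }
  stats::qnorm(h) - stats::qnorm(fa)
}

#' One-sided binomial test against chance
#'
#' Exact upper-tail probability P(X >= k) under Binomial(n, p_chance),
#' testing whether performance exceeds the chance reward rate.
#'
#' @param k_correct Number of correct trials.
#' @param n_scored Number of scored trials (>= 1).
#' @param p_chance Chance success probability (1/2 for 2AC, 1/3 for 3AC).
#' @return The one-sided p-value.
#' @examples
#' binomial_vs_chance(10, 10, 0.5)  # 2^-10
#' @export
binomial_vs_chance <- function(k_correct, n_scored, p_chance = 0.5) {
  if (n_scored < 1) stop("input error: n_scored must be >= 1", call. = FALSE)
  if (k_correct < 0 || k_correct > n_scored)
    stop("input error: need 0 <= k <= n", call. = FALSE)
  stats::pbinom(k_correct - 1, n_scored, p_chance, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' `bonferroni_adjust()` returns `min(1, p * m)`; `bonferroni_alpha()` the
#' corrected significance level `alpha / m`. With the 26 animal-stimulus
#' comparisons of the audio-visual association family, the corrected alpha
#' is 0.05 / 26 = 0.0019.
#'
#' @param p_values Raw p-values in `[0, 1]`.
#' @param family_size Number of comparisons in the family (defaults to
#'   `length(p_values)`).
#' @param alpha Family-wise significance level.
#' @return Adjusted p-values, or the corrected alpha.
#' @export
bonferroni_adjust <- function(p_values, family_size = length(p_values)) {
  if (family_size < 1)
    stop("input error: family_size must be >= 1", call. = FALSE)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("input error: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "bonferroni",
                  n = max(family_size, length(p_values)))
}

#' @rdname bonferroni_adjust
#' @export
bonferroni_alpha <- function(alpha = 0.05, family_size) {
  if (family_size < 1)
    stop("input error: family_size must be >= 1", call. = FALSE)
  alpha / family_size
}

#' Kruskal-Wallis rank test on reaction-time groups
#'
#' Rank-based H with tie correction and a chi-square tail p-value on
#' `length(groups) - 1` degrees of freedom; used to compare reaction times
#' between auditory stimuli (two groups give df = 1).
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return `list(H, df, p_value)`.
#' @examples
#' kruskal_wallis_ranks(list(c(1, 2, 3), c(4, 5, 6)))$H  # about 3.857
#' @export
kruskal_wallis_ranks <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("input error: need at least two groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) == 0))
    stop("input error: groups must be non-empty", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Session engagement summary
#'
#' For each session: trial count, duration, and the median trial timestamp
#' normalized by the session duration (a value of about 0.5 means half the
#' trials fell within half the session). Per animal: median and IQR of
#' trials per session and the count of sessions without a single trial.
#'
#' @param logs Session-log `data.frame`; may omit sessions entirely (those
#'   appear only in `session_durations`).
#' @param session_durations `data.frame` with columns `session_id`,
#'   `animal_id`, `duration_s` covering every scheduled session.
#' @return A list of class `engagement_summary`: `sessions` (per-session
#'   table), `animals` (per-animal table), and `median_normalized_timestamp`
#'   (grand median across sessions with trials).
#' @export
engagement_summary <- function(logs, session_durations) {
  stopifnot(all(c("session_id", "animal_id", "duration_s") %in%
                  names(session_durations)))
  if (any(session_durations$duration_s <= 0))
    stop("input error: session durations must be positive", call. = FALSE)

  sd <- session_durations
  per_session <- lapply(seq_len(nrow(sd)), function(i) {
    d <- logs[logs$session_id == sd$session_id[i] &
                logs$animal_id == sd$animal_id[i], , drop = FALSE]
    if (nrow(d) > 0 &&
        (any(d$t_start_s < 0) || any(d$t_start_s > sd$duration_s[i])))
      stop("input error: timestamps outside [0, duration]", call. = FALSE)
    data.frame(session_id = sd$session_id[i], animal_id = sd$animal_id[i],
               n_trials = nrow(d), duration_s = sd$duration_s[i],
               median_normalized_timestamp =
                 if (nrow(d) > 0) stats::median(d$t_start_s) / sd$duration_s[i]
                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  sessions <- do.call(rbind, per_session)

  animals <- do.call(rbind, lapply(split(sessions, sessions$animal_id),
    function(a) {
      data.frame(animal_id = a$animal_id[1],
                 median_trials = stats::median(a$n_trials),
                 iqr_trials = stats::IQR(a$n_trials),
                 n_sessions = nrow(a),
                 n_zero_trial_sessions = sum(a$n_trials == 0),
                 stringsAsFactors = FALSE)
    }))
  rownames(animals) <- NULL

  structure(
    list(sessions = sessions, animals = animals,
         median_normalized_timestamp =
           stats::median(sessions$median_normalized_timestamp, na.rm = TRUE)),
    class = "engagement_summary"
  )
}

#' @export
print.engagement_summary <- function(x, ...) {
  cat(sprintf(paste0("<engagement_summary> %d session(s), %d animal(s); ",
                     "median normalized timestamp %.3f\n"),
              nrow(x$sessions), nrow(x$animals),
              x$median_normalized_timestamp))
  invisible(x)
}

#' Hit rate on a standardized percent-of-trials axis
#'
#' Maps each animal's scored trials 1..N onto a shared percentage axis and
#' computes the hit rate per bin, so learning curves of animals with very
#' different trial counts can be compared on one frame of reference.
#'
#' @param logs Session-log `data.frame`.
#' @param bin_percent Bin width in percent; must divide 100 (5 or 10
#'   typically).
#' @return A `data.frame` with `animal_id`, `bin` (upper edge, percent),
#'   `n_trials`, `hit_rate`. Bin trial counts sum to each animal's scored N.
#' @export
learning_curve_bins <- function(logs, bin_percent = 5) {
  if (100 %% bin_percent != 0)
    stop("input error: bin_percent must divide 100", call. = FALSE)
  if (is.null(logs) || nrow(logs) == 0)
    return(data.frame(animal_id = character(), bin = numeric(),
                      n_trials = integer(), hit_rate = numeric()))
  n_bins <- 100 / bin_percent
  out <- lapply(split(logs, logs$animal_id), function(d) {
    d <- d[d$choice != "ignored" & !is.na(d$correct), , drop = FALSE]
    n <- nrow(d)
    if (n == 0) return(NULL)
    bin <- ceiling(seq_len(n) / n * n_bins)
    data.frame(animal_id = d$animal_id[1],
               bin = as.numeric(sort(unique(bin))) * bin_percent,
               n_trials = as.integer(table(bin)),
               hit_rate = as.numeric(tapply(d$correct, bin, mean)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  res
}

#' Partial Pearson correlation
#'
#' Correlation of x and y after linearly removing one covariate (e.g. trials
#' per session vs session number, controlling for session duration), with a
#' two-sided t-test p-value and a Fisher-transform 95% confidence interval.
#'
#' @param x,y,covariate Equal-length numeric vectors, length >= 4.
#' @param conf_level Confidence level for the interval.
#' @return `list(r, p_value, ci, n)`.
#' @export
partial_pearson <- function(x, y, covariate, conf_level = 0.95) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n)
    stop("input error: inputs must have equal length", call. = FALSE)
  if (n < 4)
    stop("input error: need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(covariate) == 0)
    stop("input error: zero variance input", call. = FALSE)
  rx <- stats::resid(stats::lm(x ~ covariate))
  ry <- stats::resid(stats::lm(y ~ covariate))
  r <- stats::cor(rx, ry)
  df <- n - 3  # one covariate removed
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  z <- atanh(r)
  se <- 1 / sqrt(n - 4)  # Fisher SE for a first-order partial correlation
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(r = r, p_value = p, ci = tanh(c(z - q * se, z + q * se)), n = n)
}
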