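#' Simulated subjects
#'
#' Agents stand in for animals so that every task and every analysis in the
#' package can be exercised without data collection. Five response policies
#' are available:
#' \describe{
#'   \item{random}{chooses uniformly among the displayed visuals;}
#'   \item{ideal}{always touches the target;}
#'   \item{fixed-accuracy}{touches the target with probability `p_correct`;}
#'   \item{learning-curve}{accuracy follows the saturating exponential
#'     p(t) = p_asymptote - (p_asymptote - p_start) * exp(-t / tau_trials),
#'     with t the number of prior trials;}
#'   \item{psychometric-observer}{on detection trials answers "present"
#'     (face) with probability psi(level) under its own psychometric
#'     parameters (see [psi()]).}
#' }
#' Wrong choices fall uniformly on the distractors. Each trial is ignored
#' with probability `p_ignore`, independently of the stimulus. Latencies are
#' log-normal with a per-sound location so reaction-time contrasts have a
#' true effect to detect.
#'
#' @param policy One of `"random"`, `"ideal"`, `"fixed-accuracy"`,
#'   `"learning-curve"`, `"psychometric-observer"`.
#' @param p_correct Accuracy of the fixed-accuracy policy.
#' @param p_start,p_asymptote,tau_trials Learning-curve parameters
#'   (probabilities; time constant in trials, > 0).
#' @param psychometric A [psychometric_params()] for the observer policy.
#' @param p_ignore Per-trial probability of not responding.
#' @param rt_meanlog Named numeric: log-scale latency location per sound_id
#'   (unnamed single value applies to all sounds).
#' @param rt_sdlog Log-scale latency spread.
#' @return A list of class `agent_spec`.
#' @export
agent_spec <- function(policy = c("random", "ideal", "fixed-accuracy",
                                  "learning-curve", "psychometric-observer"),
                       p_correct = NULL,
                       p_start = 0.5, p_asymptote = 0.9, tau_trials = 200,
                       psychometric = NULL,
                       p_ignore = 0,
                       rt_meanlog = log(1.5), rt_sdlog = 0.4) {
  policy <- match.arg(policy)
  probs <- c(p_correct, p_start, p_asymptote, p_ignore)
  if (any(probs < 0 | probs > 1))
    stop("configuration error: probabilities must lie in [0, 1]", call. = FALSE)
  if (tau_trials <= 0)
    stop("configuration error: tau_trials must be positive", call. = FALSE)
  if (policy == "fixed-accuracy" && is.null(p_correct))
    stop("configuration error: fixed-accuracy policy needs p_correct", call. = FALSE)
  if (policy == "psychometric-observer" && is.null(psychometric))
    stop("configuration error: observer policy needs psychometric params", call. = FALSE)
  structure(
    list(policy = policy, p_correct = p_correct,
         p_start = p_start, p_asymptote = p_asymptote, tau_trials = tau_trials,
         psychometric = psychometric, p_ignore = p_ignore,
         rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog),
    class = "agent_spec"
  )
}

#' @rdname agent_spec
#' @param ... Passed on to [agent_spec()].
#' @export
agent_random <- function(...) agent_spec("random", ...)

#' @rdname agent_spec
#' @export
agent_ideal <- function(...) agent_spec("ideal", ...)

#' @rdname agent_spec
#' @export
agent_fixed <- function(p_correct, ...) agent_spec("fixed-accuracy", p_correct = p_correct, ...)

#' @rdname agent_spec
#' @export
agent_learning <- function(p_start = 0.5, p_asymptote = 0.9, tau_trials = 200, ...) {
  agent_spec("learning-curve", p_start = p_start, p_asymptote = p_asymptote,
             tau_trials = tau_trials, ...)
}

#' @rdname agent_spec
#' @export
agent_observer <- function(psychometric, ...) {
  agent_spec("psychometric-observer", psychometric = psychometric, ...)
}

# P(choosing the target) for policies defined by an accuracy, given the
# number of displayed options; t = number of prior trials.
agent_accuracy <- function(agent, n_options, t = 0) {
  switch(agent$policy,
    "random" = 1 / n_options,
    "ideal" = 1,
    "fixed-accuracy" = agent$p_correct,
    "learning-curve" = agent$p_asymptote -
      (agent$p_asymptote - agent$p_start) * exp(-t / agent$tau_trials),
    stop("configuration error: unknown policy", call. = FALSE)
  )
}

agent_latency <- function(agent, sound_id) {
  ml <- agent$rt_meanlog
  if (!is.null(names(ml)) && sound_id %in% names(ml)) ml <- ml[[sound_id]]
  else ml <- unname(ml[1])
  stats::rlnorm(1, meanlog = ml, sdlog = agent$rt_sdlog)
}

#' Generate one agent response to a trial
#'
#' @param agent An [agent_spec()].
#' @param trial A `trial_spec` from [draw_trial()].
#' @param n_prior_trials Number of trials the agent has already performed
#'   (drives the learning-curve policy).
#' @return `list(choice = <visual id or NA>, latency_s = <s or NA>)`.
#' @export
agent_respond <- function(agent, trial, n_prior_trials = 0) {
  stopifnot(inherits(agent, "agent_spec"), inherits(trial, "trial_spec"))
  if (length(trial$options) == 0)
    stop("input error: trial has no displayed options", call. = FALSE)
  if (agent$p_ignore > 0 && stats::runif(1) < agent$p_ignore)
    return(list(choice = NA_character_, latency_s = NA_real_))

  if (agent$policy == "psychometric-observer") {
    p_present <- psi(if (is.na(trial$level_db)) Inf else trial$level_db,
                     agent$psychometric)
    choice <- if (stats::runif(1) < p_present) "face" else "triangles"
  } else {
    p <- agent_accuracy(agent, length(trial$options), n_prior_trials)
    if (stats::runif(1) < p) {
      choice <- trial$target_visual
    } else {
      d <- trial$distractor_visuals
      choice <- if (length(d) == 1) d else d[sample.int(length(d), 1)]
    }
  }
  list(choice = choice, latency_s = agent_latency(agent, trial$sound_id))
}

#' Simulate a complete session
#'
#' Runs `n_trials` through [run_trial()] with an agent as the responder,
#' producing a session log with monotone timestamps. Byte-identical for a
#' fixed seed.
#'
#' @param task A [task_spec()].
#' @param agent An [agent_spec()].
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed for the session RNG stream.
#' @param session_id,animal_id Log bookkeeping fields.
#' @return A session-log `data.frame` (one row per trial; see
#'   [write_session_log()] for the column layout).
#' @examples
#' log <- simulate_session(task_audiovisual_2ac(), agent_random(), 100, seed = 1)
#' mean(log$rewarded)  # near 0.5
#' @export
simulate_session <- function(task, agent, n_trials, seed = 1,
                             session_id = "s1", animal_id = "sim") {
  stopifnot(n_trials >= 1)
  set.seed(seed)
  clock <- sim_clock()
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    responder <- function(trial) agent_respond(agent, trial, i - 1L)
    rows[[i]] <- run_trial(task, responder, clock, trial_index = i,
                           session_id = session_id, animal_id = animal_id)
  }
  do.call(rbind, rows)
}

#' Simulate training through the AUT schedule
#'
#' Drives [apply_outcome()] across sessions: in each session the agent
#' performs up to `session_length` trials at its current step, outcomes are
#' Bernoulli draws from the agent's accuracy model (random agents face one
#' touch option before the distractor milestone and two from step 46), and
#' the progression state persists between sessions, as on the device. Each
#' session draws its RNG stream from `seed + session`, so a run resumed from
#' a saved state reproduces the identical trajectory.
#'
#' @param agent An [agent_spec()] (accuracy policies; the observer policy is
#'   detection-specific and not accepted here).
#' @param schedule Step table from [build_aut_schedule()].
#' @param config A [progression_config()].
#' @param session_length Trials per session.
#' @param max_sessions Session cap.
#' @param seed Base integer seed.
#' @param state Optional `progression_state` to resume from.
#' @param start_session Session index to resume at (1 for a fresh run).
#' @param n_prior_scored Scored trials already performed before resuming
#'   (drives the learning-curve policy's trial clock across restarts).
#' @param animal_id Subject identifier for a fresh state.
#' @return A list of class `training_run`: `trajectory` (data.frame with
#'   session, trial, step, milestone, correct), `state` (final
#'   `progression_state`), `completed`, and `milestone_trials` (scored-trial
#'   counts per milestone).
#' @export
simulate_training <- function(agent, schedule = build_aut_schedule(),
                              config = progression_config(),
                              session_length = 200, max_sessions = 50,
                              seed = 1, state = NULL, start_session = 1L,
                              n_prior_scored = 0L, animal_id = "sim") {
  stopifnot(max_sessions >= 1)
  if (agent$policy == "psychometric-observer")
    stop("configuration error: observer policy is not an AUT agent", call. = FALSE)
  if (is.null(state)) state <- progression_state(animal_id, config = config)

  traj <- vector("list", max_sessions)
  n_done <- as.integer(n_prior_scored)
  for (s in seq(start_session, length.out = max_sessions)) {
    if (state$completed) break
    set.seed(seed + s)
    rec <- matrix(NA_real_, nrow = session_length, ncol = 3)
    k <- 0L
    for (i in seq_len(session_length)) {
      if (state$completed) break
      step_row <- schedule[schedule$step == state$current_step, ]
      n_options <- if (isTRUE(step_row$distractor_enabled)) 2L else 1L
      ignored <- agent$p_ignore > 0 && stats::runif(1) < agent$p_ignore
      correct <- if (ignored) NA else
        stats::runif(1) < agent_accuracy(agent, n_options, n_done)
      state <- apply_outcome(state, correct, config)
      if (!ignored) n_done <- n_done + 1L
      k <- k + 1L
      rec[k, ] <- c(i, state$current_step, as.numeric(correct))
    }
    if (k > 0) {
      traj[[s - start_session + 1L]] <- data.frame(
        session = s, trial = rec[seq_len(k), 1],
        step = as.integer(rec[seq_len(k), 2]),
        correct = as.logical(rec[seq_len(k), 3])
      )
    }
  }
  trajectory <- do.call(rbind, traj[!vapply(traj, is.null, TRUE)])
  if (is.null(trajectory)) {
    trajectory <- data.frame(session = integer(), trial = numeric(),
                             step = integer(), correct = logical(),
                             milestone = character())
    milestone_trials <- NULL
  } else {
    trajectory$milestone <- schedule$milestone[pmin(trajectory$step, 49L)]
    scored <- !is.na(trajectory$correct)
    milestone_trials <- tapply(scored, trajectory$milestone, sum)
  }

  structure(
    list(trajectory = trajectory, state = state,
         completed = state$completed, n_scored = n_done,
         milestone_trials = milestone_trials),
    class = "training_run"
  )
}

#' @export
print.training_run <- function(x, ...) {
  cat(sprintf("<training_run> %d trials over %d session(s); final step %d%s\n",
              nrow(x$trajectory), length(unique(x$trajectory$session)),
              x$state$current_step,
              if (x$completed) " (completed)" else ""))
  invisible(x)
}
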