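#' Stimulus pairs and task specifications
#'
#' A task is defined by a set of sound/visual stimulus pairs, the number of
#' simultaneously displayed visual options, and its timing and reward rules.
#' `target-capable` pairs can be drawn as the trial's sound and target;
#' `distractor-only` visuals (3AC) are never targets and carry no sound.
#'
#' @param sound_id,visual_id Opaque stimulus identifiers.
#' @param role `"target-capable"` or `"distractor-only"`.
#' @return `stimulus_pair()` returns a named list describing one pair.
#' @export
stimulus_pair <- function(sound_id, visual_id,
                          role = c("target-capable", "distractor-only")) {
  role <- match.arg(role)
  list(sound_id = as.character(sound_id), visual_id = as.character(visual_id),
       role = role)
}

#' @rdname stimulus_pair
#' @param variant Task variant: `"aut"`, `"2ac"`, `"3ac"`, or `"detection"`.
#' @param pairs List of [stimulus_pair()]s. Each sound maps to exactly one
#'   visual within a task.
#' @param n_choices Number of simultaneously displayed visual options (2 or 3).
#' @param levels_db Ordered sound pressure levels in dB SPL (detection only).
#' @param reward_rule `"choice-contingent"` (reward iff the target is touched)
#'   or `"detection-scheme"` (the level-dependent rule of
#'   [detection_reward()]).
#' @param timeout_s,response_window_s Durations in s.
#' @param iti_range_s Interval (min, max) in s for the uniform inter-trial
#'   interval.
#' @return `task_spec()` returns a list of class `task_spec`.
#' @export
task_spec <- function(variant = c("2ac", "3ac", "detection", "aut"),
                      pairs,
                      n_choices = 2,
                      levels_db = NULL,
                      reward_rule = c("choice-contingent", "detection-scheme"),
                      timeout_s = 5,
                      response_window_s = 7,
                      iti_range_s = c(0.8, 2.5)) {
  variant <- match.arg(variant)
  reward_rule <- match.arg(reward_rule)
  if (length(pairs) == 0)
    stop("configuration error: task needs at least one stimulus pair", call. = FALSE)
  sounds <- vapply(pairs, `[[`, "", "sound_id")
  if (anyDuplicated(sounds))
    stop("configuration error: each sound_id maps to exactly one visual_id", call. = FALSE)
  n_visuals <- length(unique(vapply(pairs, `[[`, "", "visual_id")))
  if (n_choices > n_visuals)
    stop("configuration error: n_choices exceeds the number of distinct visuals",
         call. = FALSE)
  if (variant == "detection" && length(levels_db) == 0)
    stop("configuration error: detection variant requires levels_db", call. = FALSE)
  if (timeout_s <= 0 || response_window_s <= 0)
    stop("configuration error: durations must be positive", call. = FALSE)
  structure(
    list(variant = variant, pairs = pairs, n_choices = as.integer(n_choices),
         levels_db = levels_db, reward_rule = reward_rule,
         timeout_s = timeout_s, response_window_s = response_window_s,
         iti_range_s = iti_range_s),
    class = "task_spec"
  )
}

#' Built-in task variants
#'
#' `task_audiovisual_2ac()` contrasts a conspecific juvenile vocalization
#' (`voc`, paired with a marmoset face image) with a pure-tone train (`sTr`,
#' paired with a geometric pattern). `task_audiovisual_3ac()` adds a
#' distractor-only visual, lowering chance reward from 1/2 to 1/3.
#' `task_detection()` is the vocalization-detection task of the
#' psychoacoustic assessment: report presence (face) or absence (triangles)
#' of the vocalization played at one of seven levels between 0 and 80 dB SPL.
#' `task_generalization()` swaps in novel sound/visual pairs with identical
#' 2AC logic.
#'
#' @param levels_db Sound levels for the detection task, in dB SPL.
#' @param sound_a,visual_a,sound_b,visual_b Stimulus identifiers for a
#'   generalization variant.
#' @param ... Passed on to [task_spec()].
#' @return A `task_spec`.
#' @export
task_audiovisual_2ac <- function(...) {
  task_spec("2ac",
            pairs = list(stimulus_pair("voc", "face"),
                         stimulus_pair("sTr", "pattern")),
            n_choices = 2, ...)
}

#' @rdname task_audiovisual_2ac
#' @export
task_audiovisual_3ac <- function(...) {
  task_spec("3ac",
            pairs = list(stimulus_pair("voc", "face"),
                         stimulus_pair("sTr", "pattern"),
                         stimulus_pair("none", "noise-image", "distractor-only")),
            n_choices = 3, ...)
}

#' @rdname task_audiovisual_2ac
#' @export
task_detection <- function(levels_db = c(0, 15, 30, 45, 60, 70, 80), ...) {
  task_spec("detection",
            pairs = list(stimulus_pair("voc", "face"),
                         stimulus_pair("silence", "triangles")),
            n_choices = 2, levels_db = levels_db,
            reward_rule = "detection-scheme", ...)
}

#' @rdname task_audiovisual_2ac
#' @export
task_generalization <- function(sound_a, visual_a, sound_b, visual_b, ...) {
  task_spec("2ac",
            pairs = list(stimulus_pair(sound_a, visual_a),
                         stimulus_pair(sound_b, visual_b)),
            n_choices = 2, ...)
}

target_pairs <- function(task) {
  Filter(function(p) p$role == "target-capable", task$pairs)
}

#' Draw one trial specification
#'
#' Samples the trial's sound (and level, for the detection task) uniformly
#' from the task's target-capable pairs, places the target uniformly on one
#' of the available sides, and fills the remaining sides with distractor
#' visuals. Uses the session RNG stream; call `set.seed()` (or let
#' [simulate_session()] do it) for reproducibility.
#'
#' @param task A [task_spec()].
#' @param trial_index Trial number within the session.
#' @return A list of class `trial_spec` with fields `trial_index`, `sound_id`,
#'   `level_db` (NA outside detection), `target_visual`, `target_side`,
#'   `distractor_visuals`, `distractor_sides`, and `options` (all displayed
#'   visuals).
#' @export
draw_trial <- function(task, trial_index = 1L) {
  stopifnot(inherits(task, "task_spec"))
  tp <- target_pairs(task)
  if (length(tp) == 0)
    stop("configuration error: no target-capable pairs", call. = FALSE)

  level_db <- NA_real_
  if (task$variant == "detection") {
    level_db <- sample(task$levels_db, 1)
    # level 0 is the silent trial type: absence of the vocalization
    pair <- if (level_db == 0) {
      Filter(function(p) p$sound_id == "silence", task$pairs)[[1]]
    } else {
      Filter(function(p) p$sound_id != "silence", tp)[[1]]
    }
  } else {
    pair <- tp[[sample.int(length(tp), 1)]]
  }

  sides <- if (task$n_choices == 2) c("left", "right")
           else c("left", "right", "extra-position")
  side_order <- sample(sides)
  target_side <- side_order[1]

  all_visuals <- unique(vapply(task$pairs, `[[`, "", "visual_id"))
  distractors <- setdiff(all_visuals, pair$visual_id)
  distractors <- distractors[seq_len(task$n_choices - 1)]
  distractor_sides <- side_order[-1][seq_along(distractors)]

  structure(
    list(trial_index = as.integer(trial_index),
         sound_id = pair$sound_id,
         level_db = level_db,
         target_visual = pair$visual_id,
         target_side = target_side,
         distractor_visuals = distractors,
         distractor_sides = distractor_sides,
         options = c(pair$visual_id, distractors)),
    class = "trial_spec"
  )
}

#' Score a touch response
#'
#' @param trial A `trial_spec` from [draw_trial()].
#' @param response Touched visual identifier, or `NA`/`NULL` for no touch.
#' @param latency_s Response latency in s (ignored when no response).
#' @param response_window_s Response window in s; later responses count as
#'   ignored, mirroring the 7-s abort rule.
#' @return `"correct"`, `"wrong"`, or `"ignored"`.
#' @export
adjudicate_response <- function(trial, response, latency_s = NA_real_,
                                response_window_s = 7) {
  stopifnot(inherits(trial, "trial_spec"))
  if (is.null(response) || length(response) == 0 || is.na(response))
    return("ignored")
  if (!response %in% trial$options)
    stop("input error: touched visual not displayed in this trial", call. = FALSE)
  if (is.na(latency_s) || latency_s < 0)
    stop("input error: a response requires a non-negative latency", call. = FALSE)
  if (latency_s > response_window_s) return("ignored")
  if (response == trial$target_visual) "correct" else "wrong"
}

#' Level-dependent reward rule of the detection task
#'
#' Near-threshold levels (15-45 dB SPL) are rewarded regardless of choice, to
#' prevent frustration when the vocalization is presented close to or below
#' the facility's background noise. Silent trials (0 dB SPL) are rewarded
#' only for the absence response (triangles); clearly audible levels
#' (>= 60 dB SPL) only for the presence response (face).
#'
#' @param level_db Presented level in dB SPL; must be one of `levels_db`.
#' @param choice `"face"` (vocalization present) or `"triangles"` (absent).
#' @param levels_db The task's configured level set.
#' @return Logical: was the trial rewarded?
#' @examples
#' detection_reward(30, "triangles")  # TRUE: rewarded regardless of choice
#' detection_reward(0, "face")        # FALSE
#' @export
detection_reward <- function(level_db, choice,
                             levels_db = c(0, 15, 30, 45, 60, 70, 80)) {
  if (!level_db %in% levels_db)
    stop("input error: level outside the configured set", call. = FALSE)
  if (!choice %in% c("face", "triangles"))
    stop("input error: choice must be 'face' or 'triangles'", call. = FALSE)
  if (level_db >= 15 && level_db <= 45) return(TRUE)
  if (level_db == 0) return(choice == "triangles")
  choice == "face"
}

#' Simulated session clock
#'
#' Trials are timed against an injectable clock so that simulations run
#' instantaneously while still producing realistic session-relative
#' timestamps.
#'
#' @param t0 Start time in s.
#' @return An environment with fields `t` (current time, s) and function
#'   `advance(dt)`.
#' @export
sim_clock <- function(t0 = 0) {
  clk <- new.env(parent = emptyenv())
  clk$t <- t0
  clk$advance <- function(dt) clk$t <<- clk$t + dt
  clk
}

#' Run one trial through the full phase sequence
#'
#' Phases: (trigger touch, implicit) -> sound lead of 1-1.5 s when the step
#' enables sound -> options displayed -> response window -> reward or
#' gray-screen timeout -> inter-trial interval drawn uniformly from the
#' task's range. Wrong touches trigger the timeout; ignored trials carry no
#' choice, no reward and no reaction time.
#'
#' @param task A [task_spec()].
#' @param responder Callback `function(trial)` returning
#'   `list(choice = <visual or NA>, latency_s = <s>)`.
#' @param clock A [sim_clock()]; advanced in place.
#' @param step_params Optional single row of the AUT step table; supplies
#'   sound lead/timeout overrides during training.
#' @param trial_index,session_id,animal_id Log bookkeeping fields.
#' @return A one-row `data.frame` in the session-log column layout (see
#'   [write_session_log()]).
#' @export
run_trial <- function(task, responder, clock = sim_clock(),
                      step_params = NULL, trial_index = 1L,
                      session_id = "s1", animal_id = "sim") {
  stopifnot(inherits(task, "task_spec"), is.function(responder))
  trial <- draw_trial(task, trial_index)

  iti <- stats::runif(1, task$iti_range_s[1], task$iti_range_s[2])
  sound_on <- if (!is.null(step_params)) isTRUE(step_params$sound_enabled)
              else task$variant %in% c("2ac", "3ac", "detection")
  lead <- if (sound_on) stats::runif(1, 1, 1.5) else 0
  clock$advance(lead)
  t_start <- clock$t

  resp <- tryCatch(responder(trial), error = function(e) e)
  if (inherits(resp, "error")) {
    clock$advance(task$response_window_s + iti)
    return(trial_record_row(session_id, animal_id, task, step_params, trial,
                            choice = "error", correct = NA, rewarded = FALSE,
                            rt = NA_real_, t_start = t_start))
  }

  outcome <- adjudicate_response(trial, resp$choice, resp$latency_s,
                                 task$response_window_s)
  if (outcome == "ignored") {
    clock$advance(task$response_window_s + iti)
    return(trial_record_row(session_id, animal_id, task, step_params, trial,
                            choice = "ignored", correct = NA, rewarded = FALSE,
                            rt = NA_real_, t_start = t_start))
  }

  rewarded <- if (task$reward_rule == "detection-scheme") {
    detection_reward(trial$level_db, resp$choice, task$levels_db)
  } else {
    outcome == "correct"
  }
  # timeout after a wrong touch, ITI after a reward
  clock$advance(resp$latency_s +
                (if (outcome == "wrong") task$timeout_s else 0) + iti)
  trial_record_row(session_id, animal_id, task, step_params, trial,
                   choice = resp$choice, correct = outcome == "correct",
                   rewarded = rewarded, rt = resp$latency_s, t_start = t_start)
}

trial_record_row <- function(session_id, animal_id, task, step_params, trial,
                             choice, correct, rewarded, rt, t_start) {
  data.frame(
    session_id = session_id,
    animal_id = animal_id,
    task = task$variant,
    step = if (is.null(step_params)) NA_integer_ else as.integer(step_params$step),
    trial = trial$trial_index,
    t_start_s = t_start,
    sound_id = trial$sound_id,
    level_db = trial$level_db,
    target_visual = trial$target_visual,
    target_side = trial$target_side,
    choice = choice,
    correct = correct,
    rewarded = rewarded,
    reaction_time_s = rt,
    stringsAsFactors = FALSE
  )
}
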