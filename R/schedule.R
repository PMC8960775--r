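#' Default constants for the automated unsupervised training (AUT) schedule
#'
#' The AUT unfolds through one entry step plus 48 dynamic steps grouped into
#' four milestones: shrinking of the touch trigger (steps 1-15), lateral
#' displacement of the trigger (16-30), introduction of sound with a delayed
#' visual target (31-45), and introduction of a visual distractor (46-49).
#' Completing step 49 places the subject at the virtual completion step 50,
#' at which the audio-visual association experiment proper begins.
#'
#' @param screen_edge_offset_mm Maximal horizontal displacement of the trigger
#'   from screen centre, in mm. The position milestone moves the trigger by
#'   5 mm per step until this edge offset is reached.
#' @param trigger_start_cm,trigger_final_cm Trigger edge length at step 1 and
#'   from step 15 onwards, in cm.
#' @param sound_start_db,sound_final_db Sound pressure level at the first
#'   sound-enabled step (36) and the final level reached at step 40, in dB SPL.
#' @param sound_step_db Per-step increment of the sound level, in dB.
#' @param sound_lead_range_s Interval (min, max) in s between sound onset and
#'   visual target onset; the per-trial lead is drawn uniformly from it.
#' @param distractor_start_cm,distractor_final_cm Distractor edge length at
#'   steps 46 and 49, in cm.
#' @param timeout_s Gray-screen timeout after a wrong touch, in s.
#' @param response_window_s Time allowed for a response before the trial is
#'   labelled ignored, in s.
#' @param iti_range_s Interval (min, max) in s from which the inter-trial
#'   interval is drawn uniformly.
#' @return A list of schedule constants accepted by [build_aut_schedule()].
#' @seealso [build_aut_schedule()], [progression_config()]
#' @export
aut_config <- function(screen_edge_offset_mm = 75,
                       trigger_start_cm = 6,
                       trigger_final_cm = 3,
                       sound_start_db = 32,
                       sound_final_db = 72,
                       sound_step_db = 10,
                       sound_lead_range_s = c(1, 1.5),
                       distractor_start_cm = 0.3,
                       distractor_final_cm = 2.8,
                       timeout_s = 5,
                       response_window_s = 7,
                       iti_range_s = c(0.8, 2.5)) {
  cfg <- list(
    screen_edge_offset_mm = screen_edge_offset_mm,
    trigger_start_cm = trigger_start_cm,
    trigger_final_cm = trigger_final_cm,
    sound_start_db = sound_start_db,
    sound_final_db = sound_final_db,
    sound_step_db = sound_step_db,
    sound_lead_range_s = sound_lead_range_s,
    distractor_start_cm = distractor_start_cm,
    distractor_final_cm = distractor_final_cm,
    timeout_s = timeout_s,
    response_window_s = response_window_s,
    iti_range_s = iti_range_s
  )
  validate_aut_config(cfg)
  cfg
}

validate_aut_config <- function(cfg) {
  if (!is.numeric(cfg$screen_edge_offset_mm) || cfg$screen_edge_offset_mm < 75)
    stop("configuration error: screen_edge_offset_mm must be >= 75 mm", call. = FALSE)
  if (cfg$trigger_start_cm <= cfg$trigger_final_cm || cfg$trigger_final_cm <= 0)
    stop("configuration error: trigger sizes must satisfy start > final > 0", call. = FALSE)
  if (cfg$timeout_s <= 0 || cfg$response_window_s <= 0)
    stop("configuration error: durations must be positive", call. = FALSE)
  if (length(cfg$iti_range_s) != 2 || any(cfg$iti_range_s <= 0) ||
      diff(cfg$iti_range_s) < 0)
    stop("configuration error: iti_range_s must be an increasing positive pair", call. = FALSE)
  if (length(cfg$sound_lead_range_s) != 2 || any(cfg$sound_lead_range_s <= 0) ||
      diff(cfg$sound_lead_range_s) < 0)
    stop("configuration error: sound_lead_range_s must be an increasing positive pair", call. = FALSE)
  if (cfg$sound_final_db < cfg$sound_start_db || cfg$sound_step_db <= 0)
    stop("configuration error: sound levels must ramp upwards", call. = FALSE)
  if (cfg$distractor_final_cm < cfg$distractor_start_cm)
    stop("configuration error: distractor sizes must be non-decreasing", call. = FALSE)
  invisible(cfg)
}

#' Build the expanded AUT step table
#'
#' Expands the schedule constants into the full 49-row step table (entry step
#' 1 plus 48 dynamic steps). Trigger size shrinks linearly from 6 x 6 cm to
#' 3 x 3 cm over steps 2-15; the trigger then moves laterally by 5 mm per step
#' over steps 16-30 until the screen edge; from step 31 a two-touch sequence
#' (centre trigger, then peripheral target) is required; from step 36 a sound
#' precedes the visual target by 1-1.5 s, ramping from 32 dB SPL in 10-dB
#' increments to 72 dB SPL at step 40 and staying there; from step 46 a visual
#' distractor appears opposite the target, growing from 0.3 to 2.8 cm by step
#' 49.
#'
#' @param config Schedule constants from [aut_config()].
#' @return A `data.frame` with one row per step and columns `step`,
#'   `milestone` (`size`, `position`, `delay`, `choice`), `trigger_edge_cm`,
#'   `trigger_offset_mm`, `two_touch`, `sound_enabled`, `sound_level_db`,
#'   `sound_lead_s`, `distractor_enabled`, `distractor_edge_cm`, `timeout_s`,
#'   `response_window_s`, `iti_min_s`, `iti_max_s`. Deterministic for a fixed
#'   config.
#' @examples
#' sched <- build_aut_schedule()
#' sched[sched$step == 36, c("sound_enabled", "sound_level_db")]
#' @export
build_aut_schedule <- function(config = aut_config()) {
  validate_aut_config(config)
  step <- 1:49
  milestone <- cut(step, breaks = c(0, 15, 30, 45, 49),
                   labels = c("size", "position", "delay", "choice"))
  milestone <- as.character(milestone)

  # size milestone: linear shrink over steps 1..15, constant afterwards
  trigger_edge_cm <- ifelse(
    step <= 15,
    config$trigger_start_cm +
      (config$trigger_final_cm - config$trigger_start_cm) * (step - 1) / 14,
    config$trigger_final_cm
  )

  # position milestone: 5 mm per step from step 16, capped at the screen edge
  trigger_offset_mm <- pmin(pmax(step - 15, 0) * 5, config$screen_edge_offset_mm)

  two_touch <- step >= 31
  sound_enabled <- step >= 36
  sound_level_db <- ifelse(
    sound_enabled,
    pmin(config$sound_start_db + config$sound_step_db * (step - 36),
         config$sound_final_db),
    NA_real_
  )
  sound_lead_s <- ifelse(sound_enabled, mean(config$sound_lead_range_s), NA_real_)

  distractor_enabled <- step >= 46
  distractor_edge_cm <- ifelse(
    distractor_enabled,
    config$distractor_start_cm +
      (config$distractor_final_cm - config$distractor_start_cm) * (step - 46) / 3,
    NA_real_
  )

  data.frame(
    step = step,
    milestone = milestone,
    trigger_edge_cm = round(trigger_edge_cm, 6),
    trigger_offset_mm = trigger_offset_mm,
    two_touch = two_touch,
    sound_enabled = sound_enabled,
    sound_level_db = sound_level_db,
    sound_lead_s = sound_lead_s,
    distractor_enabled = distractor_enabled,
    distractor_edge_cm = round(distractor_edge_cm, 6),
    timeout_s = config$timeout_s,
    response_window_s = config$response_window_s,
    iti_min_s = config$iti_range_s[1],
    iti_max_s = config$iti_range_s[2],
    stringsAsFactors = FALSE
  )
}

#' Write the expanded step table to CSV
#'
#' Emits the canonical 12-column step table (the per-trial ITI bounds live in
#' the schedule constants, not the table).
#'
#' @param schedule Step table from [build_aut_schedule()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  cols <- c("step", "milestone", "trigger_edge_cm", "trigger_offset_mm",
            "two_touch", "sound_enabled", "sound_level_db", "sound_lead_s",
            "distractor_enabled", "distractor_edge_cm", "timeout_s",
            "response_window_s")
  stopifnot(all(cols %in% names(schedule)))
  utils::write.csv(schedule[, cols], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Progression rule configuration
#'
#' Transitions between steps are driven by a sliding window of the most
#' recent scored (non-ignored) trial outcomes: the subject advances one step
#' after at least `advance_min_correct` correct of `window_len`, and retreats
#' one step when `retreat_max_correct` or fewer were correct (i.e. fewer than
#' 3 of 10 under the defaults).
#'
#' @param window_len Length of the sliding outcome window, in trials.
#' @param advance_min_correct Minimum correct trials in a full window to
#'   advance one step.
#' @param retreat_max_correct Maximum correct trials in a full window that
#'   still triggers a retreat.
#' @param entry_step First schedule step.
#' @param completion_step Virtual step marking completion of the schedule.
#' @return A list of class `progression_config`.
#' @export
progression_config <- function(window_len = 10,
                               advance_min_correct = 8,
                               retreat_max_correct = 2,
                               entry_step = 1,
                               completion_step = 50) {
  if (!(retreat_max_correct < advance_min_correct &&
        advance_min_correct <= window_len))
    stop("configuration error: need retreat_max_correct < advance_min_correct <= window_len",
         call. = FALSE)
  if (entry_step >= completion_step)
    stop("configuration error: entry_step must precede completion_step", call. = FALSE)
  structure(
    list(window_len = window_len,
         advance_min_correct = advance_min_correct,
         retreat_max_correct = retreat_max_correct,
         entry_step = entry_step,
         completion_step = completion_step),
    class = "progression_config"
  )
}

#' Create a fresh progression state for one subject
#'
#' @param animal_id Subject identifier.
#' @param step Starting step (defaults to the entry step).
#' @param config A [progression_config()].
#' @return A list of class `progression_state` with fields `animal_id`,
#'   `current_step`, `outcome_window` (logical, most recent last) and
#'   `completed`.
#' @export
progression_state <- function(animal_id, step = config$entry_step,
                              config = progression_config()) {
  if (step < config$entry_step || step > config$completion_step)
    stop("state error: step outside [entry_step, completion_step]", call. = FALSE)
  structure(
    list(animal_id = as.character(animal_id),
         current_step = as.integer(step),
         outcome_window = logical(0),
         completed = step == config$completion_step),
    class = "progression_state"
  )
}

#' Decide a step transition from a sliding outcome window
#'
#' @param outcome_window Logical vector of scored trial outcomes, most recent
#'   last. Windows shorter than `window_len` never trigger a transition.
#' @param config A [progression_config()].
#' @return `"advance"`, `"retreat"`, or `"stay"`.
#' @examples
#' window_decision(rep(c(TRUE, FALSE), c(8, 2)))  # "advance"
#' window_decision(rep(c(TRUE, FALSE), c(2, 8)))  # "retreat"
#' @export
window_decision <- function(outcome_window, config = progression_config()) {
  stopifnot(is.logical(outcome_window))
  if (length(outcome_window) < config$window_len) return("stay")
  n_correct <- sum(outcome_window)
  if (n_correct >= config$advance_min_correct) "advance"
  else if (n_correct <= config$retreat_max_correct) "retreat"
  else "stay"
}

#' Apply one trial outcome to a progression state
#'
#' Ignored trials (`NA`) leave the state untouched. Scored outcomes are
#' appended to the sliding window; when the window is full it is evaluated by
#' [window_decision()] and the step moves by at most one, clamped to the
#' configured range. On any step change the window is cleared, so consecutive
#' transitions each require fresh evidence. Reaching the completion step sets
#' `completed`; progress is retained across sessions by persisting the state
#' (see [save_progression()]).
#'
#' @param state A `progression_state`.
#' @param trial_correct `TRUE`, `FALSE`, or `NA` for an ignored trial.
#' @param config A [progression_config()].
#' @return The updated `progression_state`.
#' @export
apply_outcome <- function(state, trial_correct, config = progression_config()) {
  stopifnot(inherits(state, "progression_state"))
  if (state$completed)
    stop("state error: cannot apply outcomes to a completed state", call. = FALSE)
  if (is.na(trial_correct)) return(state)

  win <- c(state$outcome_window, as.logical(trial_correct))
  if (length(win) > config$window_len)
    win <- win[(length(win) - config$window_len + 1):length(win)]

  decision <- window_decision(win, config)
  step <- state$current_step
  if (decision == "advance") step <- min(step + 1L, config$completion_step)
  if (decision == "retreat") step <- max(step - 1L, config$entry_step)

  if (step != state$current_step) {
    state$outcome_window <- logical(0)
    state$current_step <- as.integer(step)
  } else {
    state$outcome_window <- win
  }
  state$completed <- state$current_step == config$completion_step
  state
}

#' Persist and restore progression states
#'
#' One JSON document per subject, so that a training run can resume from the
#' last step across breaks and sessions.
#'
#' @param state A `progression_state`.
#' @param path File path of the JSON document.
#' @return `save_progression()` returns `path` invisibly; `load_progression()`
#'   returns the restored `progression_state`.
#' @export
save_progression <- function(state, path) {
  stopifnot(inherits(state, "progression_state"))
  jsonlite::write_json(unclass(state), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_progression
#' @export
load_progression <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(animal_id = as.character(x$animal_id),
         current_step = as.integer(x$current_step),
         outcome_window = as.logical(x$outcome_window %||% logical(0)),
         completed = isTRUE(x$completed)),
    class = "progression_state"
  )
}

#' @export
print.progression_state <- function(x, ...) {
  cat(sprintf("<progression_state> animal %s: step %d%s, window %s\n",
              x$animal_id, x$current_step,
              if (x$completed) " (completed)" else "",
              if (length(x$outcome_window) == 0) "empty"
              else paste0(sum(x$outcome_window), "/", length(x$outcome_window),
                          " correct")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
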