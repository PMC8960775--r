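test_that("step table reproduces the published schedule constants", {
  s <- build_aut_schedule()

  expect_equal(nrow(s), 49)
  expect_equal(sum(s$step > 1), 48)  # entry step + 48 dynamic steps
  expect_equal(s$trigger_edge_cm[s$step == 1], 6.0)
  expect_equal(s$trigger_edge_cm[s$step == 15], 3.0)
  expect_true(s$sound_enabled[s$step == 36])
  expect_equal(s$sound_level_db[s$step == 36], 32)
  expect_equal(s$sound_level_db[s$step == 40], 72)
  expect_equal(s$trigger_offset_mm[s$step == 20], 25)
  expect_equal(s$distractor_edge_cm[s$step == 46], 0.3)
  expect_equal(s$distractor_edge_cm[s$step == 49], 2.8)
})

test_that("step table satisfies all ramp and milestone invariants", {
  s <- build_aut_schedule()

  expect_true(all(diff(s$trigger_edge_cm[2:15]) < 0))
  expect_true(all(s$trigger_edge_cm[s$step >= 15] == 3.0))
  expect_true(all(s$trigger_offset_mm[s$step <= 15] == 0))
  expect_equal(diff(s$trigger_offset_mm[16:30]), rep(5, 14))
  expect_true(all(s$trigger_offset_mm <= 75))
  expect_identical(s$sound_enabled, s$step >= 36)
  expect_equal(diff(s$sound_level_db[36:40]), rep(10, 4))
  expect_true(all(s$sound_level_db[41:49] == 72))
  expect_identical(s$distractor_enabled, s$step >= 46)
  expect_true(all(diff(s$distractor_edge_cm[46:49]) >= 0))
  expect_identical(s$milestone,
                   rep(c("size", "position", "delay", "choice"),
                       c(15, 15, 15, 4)))
  # deterministic for a fixed config
  expect_identical(s, build_aut_schedule())
})

test_that("invalid schedule constants are rejected", {
  expect_error(aut_config(screen_edge_offset_mm = 60), "configuration error")
  expect_error(aut_config(timeout_s = 0), "configuration error")
  expect_error(aut_config(iti_range_s = c(2.5, 0.8)), "configuration error")
  expect_error(progression_config(advance_min_correct = 11),
               "configuration error")
  expect_error(progression_config(retreat_max_correct = 9),
               "configuration error")
})

test_that("window_decision matches brute force on all 2^10 windows", {
  cfg <- progression_config()
  wins <- all_windows(10)
  got <- apply(wins, 1, function(w) window_decision(as.logical(w), cfg))
  want <- apply(wins, 1, function(w) brute_window_decision(as.logical(w)))
  expect_identical(got, want)
})

test_that("window boundaries: 8-of-10 advances, 2-of-10 retreats, partial stays", {
  cfg <- progression_config()
  expect_equal(window_decision(rep(c(TRUE, FALSE), c(8, 2)), cfg), "advance")
  expect_equal(window_decision(rep(c(TRUE, FALSE), c(2, 8)), cfg), "retreat")
  expect_equal(window_decision(rep(c(TRUE, FALSE), c(5, 5)), cfg), "stay")
  expect_equal(window_decision(rep(TRUE, 7), cfg), "stay")
})

test_that("apply_outcome moves steps, clamps, clears the window, completes", {
  cfg <- progression_config()
  st <- progression_state("a")

  # ten correct trials: one advance, window cleared
  for (i in 1:10) st <- apply_outcome(st, TRUE, cfg)
  expect_equal(st$current_step, 2L)
  expect_length(st$outcome_window, 0)

  # ignored trials leave the state untouched
  st2 <- apply_outcome(st, NA, cfg)
  expect_identical(st, st2)

  # floor clamp at the entry step
  st <- progression_state("a")
  for (i in 1:30) st <- apply_outcome(st, FALSE, cfg)
  expect_equal(st$current_step, 1L)

  # reaching step 49 with 8-of-10 completes at step 50
  st <- progression_state("a", step = 49, config = cfg)
  for (ok in c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
    st <- apply_outcome(st, ok, cfg)
  expect_equal(st$current_step, 50L)
  expect_true(st$completed)
  expect_error(apply_outcome(st, TRUE, cfg), "state error")
})

test_that("step trajectory stays in range and moves one step per scored trial", {
  set.seed(42)
  cfg <- progression_config()
  st <- progression_state("a")
  steps <- integer(0)
  for (i in 1:500) {
    st <- apply_outcome(st, runif(1) < 0.7, cfg)
    steps <- c(steps, st$current_step)
    if (st$completed) break
  }
  expect_true(all(steps >= 1 & steps <= 50))
  expect_true(all(abs(diff(steps)) <= 1))
})

test_that("progression state round-trips through JSON and resumes identically", {
  cfg <- progression_config()
  agent <- agent_fixed(0.85)
  sched <- build_aut_schedule()

  full <- simulate_training(agent, sched, cfg, session_length = 150,
                            max_sessions = 6, seed = 11)

  part <- simulate_training(agent, sched, cfg, session_length = 150,
                            max_sessions = 3, seed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  save_progression(part$state, path)
  restored <- load_progression(path)
  expect_identical(restored, part$state)

  resumed <- simulate_training(agent, sched, cfg, session_length = 150,
                               max_sessions = 3, seed = 11,
                               state = restored, start_session = 4L,
                               n_prior_scored = part$n_scored)
  combined <- rbind(part$trajectory, resumed$trajectory)
  rownames(combined) <- NULL
  rownames(full$trajectory) <- NULL
  expect_equal(combined, full$trajectory)
  expect_equal(resumed$state$current_step, full$state$current_step)
})

test_that("schedule CSV writer emits the canonical 12-column header", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(build_aut_schedule(), path)
  header <- readLines(path, n = 1)
  expect_identical(header,
    paste0("step,milestone,trigger_edge_cm,trigger_offset_mm,two_touch,",
           "sound_enabled,sound_level_db,sound_lead_s,distractor_enabled,",
           "distractor_edge_cm,timeout_s,response_window_s"))
  expect_equal(nrow(utils::read.csv(path)), 49)
})
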