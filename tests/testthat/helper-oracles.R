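# Independent oracles used across test files.

# Exact upper-tail binomial probability by direct pmf enumeration,
# independent of stats::pbinom.
brute_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j), 0))
}

# Brute-force window decision: count TRUEs against the two thresholds.
brute_window_decision <- function(window, window_len = 10, advance = 8,
                                  retreat = 2) {
  if (length(window) < window_len) return("stay")
  nc <- sum(window)
  if (nc >= advance) "advance" else if (nc <= retreat) "retreat" else "stay"
}

# All length-n logical windows as a matrix (2^n rows).
all_windows <- function(n) {
  m <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  dimnames(m) <- NULL
  m
}

# Small deterministic session log built directly, bypassing the simulator.
manual_log <- function(correct, choice = NULL, animal = "a", task = "2ac",
                       session = "s1", sound = "voc") {
  n <- length(correct)
  if (is.null(choice))
    choice <- ifelse(is.na(correct), "ignored",
                     ifelse(correct, "face", "pattern"))
  data.frame(
    session_id = rep(session, n), animal_id = rep(animal, n),
    task = rep(task, n), step = NA_integer_, trial = seq_len(n),
    t_start_s = seq_len(n) * 10, sound_id = rep(sound, n),
    level_db = NA_real_, target_visual = "face", target_side = "left",
    choice = choice, correct = correct,
    rewarded = !is.na(correct) & correct,
    reaction_time_s = ifelse(is.na(correct), NA_real_, 1.5),
    stringsAsFactors = FALSE
  )
}
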