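log_columns <- c("session_id", "animal_id", "task", "step", "trial",
                 "t_start_s", "sound_id", "level_db", "target_visual",
                 "target_side", "choice", "correct", "rewarded",
                 "reaction_time_s")
log_col_types <- c(session_id = "c", animal_id = "c", task = "c", step = "i",
                   trial = "i", t_start_s = "n", sound_id = "c",
                   level_db = "n", target_visual = "c", target_side = "c",
                   choice = "c", correct = "l", rewarded = "l",
                   reaction_time_s = "n")

#' Read and write session logs
#'
#' Session logs are tabular, one row per trial, with the fixed header
#' `session_id,animal_id,task,step,trial,t_start_s,sound_id,level_db,`
#' `target_visual,target_side,choice,correct,rewarded,reaction_time_s`.
#' Two dialects are supported: CSV (canonical; comma-separated, dot decimal,
#' UTF-8, header mandatory, empty fields for absent values) and JSON-lines
#' (one object per row, absent fields omitted). Both round-trip without
#' loss; the dialect is inferred from the file extension (`.jsonl` vs
#' anything else) unless given.
#'
#' @param log Session-log `data.frame` (as produced by
#'   [simulate_session()]).
#' @param path File path.
#' @param format `"csv"`, `"jsonl"`, or `NULL` to infer from the extension.
#' @return `write_session_log()` returns `path` invisibly;
#'   `read_session_log()` the parsed `data.frame`. Malformed rows raise an
#'   error naming the offending line; a wrong header is a format error.
#' @export
write_session_log <- function(log, path, format = NULL) {
  format <- infer_format(path, format)
  missing_cols <- setdiff(log_columns, names(log))
  if (length(missing_cols) > 0)
    stop("format error: log lacks columns ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  log <- log[, log_columns]
  if (format == "csv") {
    utils::write.csv(log, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(log))) {
      row <- as.list(log[i, ])
      row <- row[!vapply(row, function(v) is.na(v), TRUE)]
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("csv", "jsonl")))
  if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- infer_format(path, format)
  lines <- readLines(path, encoding = "UTF-8")
  if (format == "csv") parse_log_csv(lines) else parse_log_jsonl(lines)
}

parse_log_csv <- function(lines) {
  if (length(lines) == 0) stop("format error: empty file", call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(header, log_columns))
    stop("format error: header does not match the session-log column set",
         call. = FALSE)
  body <- lines[-1]
  cells <- strsplit(body, ",", fixed = TRUE)
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    v <- cells[[i]]
    # a trailing empty field is dropped by strsplit; restore it
    if (length(v) == length(log_columns) - 1 && grepl(",$", body[i]))
      v <- c(v, "")
    if (length(v) != length(log_columns))
      stop(sprintf("format error: line %d has %d fields, expected %d",
                   i + 1, length(v), length(log_columns)), call. = FALSE)
    rows[[i]] <- v
  }
  m <- do.call(rbind, rows)
  out <- data.frame(matrix(nrow = length(body), ncol = 0))
  for (j in seq_along(log_columns)) {
    col <- log_columns[j]
    raw <- if (length(body) > 0) m[, j] else character(0)
    raw[raw == ""] <- NA
    out[[col]] <- convert_log_col(raw, log_col_types[[col]], j)
  }
  out
}

convert_log_col <- function(raw, type, j) {
  if (type == "c") return(as.character(raw))
  conv <- switch(type, i = as.integer, n = as.numeric, l = as.logical)
  val <- suppressWarnings(conv(raw))
  bad <- which(!is.na(raw) & is.na(val))
  if (length(bad) > 0)
    stop(sprintf("format error: line %d, column %s: cannot parse '%s'",
                 bad[1] + 1, log_columns[j], raw[bad[1]]), call. = FALSE)
  val
}

parse_log_jsonl <- function(lines) {
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i]),
                  error = function(e)
                    stop(sprintf("format error: line %d: invalid JSON", i),
                         call. = FALSE))
    unknown <- setdiff(names(x), log_columns)
    if (length(unknown) > 0)
      stop(sprintf("format error: line %d: unknown field %s", i, unknown[1]),
           call. = FALSE)
    for (col in log_columns) if (is.null(x[[col]])) x[[col]] <- NA
    as.data.frame(x[log_columns], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- stats::setNames(data.frame(matrix(nrow = 0, ncol = 14)), log_columns)
  for (col in log_columns) {
    type <- log_col_types[[col]]
    out[[col]] <- switch(type, c = as.character(out[[col]]),
                         i = as.integer(out[[col]]),
                         n = as.numeric(out[[col]]),
                         l = as.logical(out[[col]]))
  }
  out
}

#' Read a run configuration file
#'
#' One YAML document holds the schedule constants, the progression rule, and
#' any task or agent definitions for a simulation run. Unknown top-level
#' keys are rejected so typos fail loudly before a simulation starts.
#'
#' @param path Path to the YAML file.
#' @return A list with (up to) elements `schedule` ([aut_config()]),
#'   `progression` ([progression_config()]), `tasks`, `agents`, `output`,
#'   `seed`; absent sections get the package defaults.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("schedule", "progression", "tasks", "agents", "output", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("configuration error: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  sched_args <- raw$schedule %||% list()
  prog_args <- raw$progression %||% list()
  list(
    schedule = do.call(aut_config, sched_args),
    progression = do.call(progression_config, prog_args),
    tasks = raw$tasks,
    agents = raw$agents,
    output = raw$output,
    seed = raw$seed %||% 1L
  )
}

#' Write a seeded fixture bundle
#'
#' Generates the small set of session logs used by the test suite and the
#' documentation: a random and an ideal agent on the 2AC task, a random
#' agent on the 3AC task, a learning-curve agent on the 2AC task, a
#' psychometric observer on the detection task, and the observer's
#' level/count table.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed controlling every log.
#' @param n_trials Trials per log.
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1, n_trials = 400) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- agent_observer(psychometric_params(m = 37, w = 15, lambda = 0.02,
                                            gamma = 0.05))
  specs <- list(
    random_2ac = list(task_audiovisual_2ac(), agent_random()),
    ideal_2ac = list(task_audiovisual_2ac(), agent_ideal()),
    random_3ac = list(task_audiovisual_3ac(), agent_random()),
    learning_2ac = list(task_audiovisual_2ac(),
                        agent_learning(0.5, 0.95, n_trials / 4)),
    observer_detection = list(task_detection(), obs)
  )
  files <- character(0)
  for (nm in names(specs)) {
    log <- simulate_session(specs[[nm]][[1]], specs[[nm]][[2]], n_trials,
                            seed = seed + match(nm, names(specs)),
                            session_id = paste0(nm, "_s1"), animal_id = nm)
    f <- file.path(dir, paste0(nm, ".csv"))
    write_session_log(log, f)
    files[nm] <- f
  }
  det <- read_session_log(files[["observer_detection"]])
  lc <- level_counts(det)
  f <- file.path(dir, "observer_level_counts.csv")
  utils::write.csv(lc, f, row.names = FALSE)
  files["observer_level_counts"] <- f
  invisible(files)
}

#' Tabulate detection responses into level counts
#'
#' Collapses a detection-task session log into the level/count rows needed
#' by [fit_psychometric()]: at each level, `n` scored trials and `k`
#' "present" (face) responses.
#'
#' @param logs Detection session-log `data.frame`.
#' @return `data.frame` with columns `level_db`, `n`, `k`.
#' @export
level_counts <- function(logs) {
  d <- logs[logs$choice %in% c("face", "triangles"), , drop = FALSE]
  if (nrow(d) == 0)
    return(data.frame(level_db = numeric(), n = integer(), k = integer()))
  lv <- sort(unique(d$level_db))
  data.frame(
    level_db = lv,
    n = vapply(lv, function(x) sum(d$level_db == x), 1L),
    k = vapply(lv, function(x) sum(d$level_db == x & d$choice == "face"), 1L)
  )
}
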