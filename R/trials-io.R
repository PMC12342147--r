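#' Session configuration for a respiratory discrimination session
#'
#' Timing and size parameters of a two-interval paced-breathing
#' discrimination session: a short practice round, then the measured trials
#' split over blocks, each trial comprising two paced breaths (inhale
#' 0.8 s, pause 0.5 s, exhale 3 s) with the obstruction applied to one of
#' the two inhalations and a 6 s response window.
#'
#' Analysis-grade sessions use at least 20 trials (the psychometric fitter
#' enforces this); smaller values are permitted here so that degenerate
#' sessions can be constructed in closed-loop simulations.
#'
#' @param n_practice Practice trials, default 6.
#' @param n_blocks Number of blocks, default 3.
#' @param n_trials_total Measured trials in the session, default 50.
#' @param inhale_s,pause_s,exhale_s Paced breath timing in seconds.
#' @param iti_range Inter-trial interval range in seconds.
#' @param max_obstruction Device ceiling in obstruction units, default 17.
#' @param deadline_s Response deadline in seconds, default 6.
#' @return A `session_config` list.
#' @export
session_config <- function(n_practice = 6, n_blocks = 3, n_trials_total = 50,
                           inhale_s = 0.8, pause_s = 0.5, exhale_s = 3.0,
                           iti_range = c(3.5, 4.0), max_obstruction = 17,
                           deadline_s = 6) {
  if (n_trials_total < 0 || n_blocks < 1 || n_practice < 0) {
    abort("session sizes must be non-negative (n_blocks >= 1).",
          class = "rrst_config_error")
  }
  if (any(c(inhale_s, pause_s, exhale_s, deadline_s, iti_range) <= 0) ||
      max_obstruction <= 0) {
    abort("timing fields and max_obstruction must be positive.",
          class = "rrst_config_error")
  }
  structure(
    list(n_practice = n_practice, n_blocks = n_blocks,
         n_trials_total = n_trials_total, inhale_s = inhale_s,
         pause_s = pause_s, exhale_s = exhale_s, iti_range = iti_range,
         max_obstruction = max_obstruction, deadline_s = deadline_s),
    class = "session_config"
  )
}

.trial_columns <- c("subject_id", "group", "block", "trial_index",
                    "stimulus_level", "stimulus_interval",
                    "response_interval", "correct", "confidence", "rt")

#' Validate a trial table
#'
#' Checks a trial-level table against the trial-record contract: group in
#' \{FND, HC\}, positive block/trial indices, stimulus level within the
#' device range, intervals in \{1, 2\}, `correct` consistent with the
#' stimulated and responded intervals, confidence in \[0, 100\], and RT
#' missing or in `(0, deadline]`. Violations raise a classed error naming
#' the offending row.
#'
#' @param trials A data frame of trials.
#' @param config A [session_config()].
#' @return The validated trials as a tibble (row order preserved), with
#'   `correct` logical and `rt` numeric (`NA` = missing).
#' @export
validate_trials <- function(trials, config = session_config()) {
  missing_cols <- setdiff(.trial_columns, names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "rrst_schema_error")
  }
  t <- as_tibble(trials)
  t$correct <- as.logical(t$correct)
  t$rt <- suppressWarnings(as.numeric(t$rt))

  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0) {
      abort(sprintf("%s at row %d.", what, i[1]),
            class = "rrst_validation_error")
    }
  }
  bad_row(is.na(t$subject_id) | t$subject_id == "", "empty subject_id")
  bad_row(!t$group %in% c("FND", "HC"), "group must be 'FND' or 'HC'")
  bad_row(is.na(t$block) | t$block < 1, "block must be >= 1")
  bad_row(is.na(t$trial_index) | t$trial_index < 1, "trial_index must be >= 1")
  bad_row(is.na(t$stimulus_level) | t$stimulus_level < 0 |
            t$stimulus_level > config$max_obstruction,
          sprintf("stimulus_level outside [0, %g]", config$max_obstruction))
  bad_row(!t$stimulus_interval %in% c(1, 2), "stimulus_interval must be 1 or 2")
  bad_row(!t$response_interval %in% c(1, 2), "response_interval must be 1 or 2")
  bad_row(is.na(t$correct), "correct must be logical")
  bad_row(t$correct != (t$stimulus_interval == t$response_interval),
          "correct inconsistent with stimulus/response intervals")
  bad_row(is.na(t$confidence) | t$confidence < 0 | t$confidence > 100,
          "confidence outside [0, 100]")
  bad_row(!is.na(t$rt) & (t$rt <= 0 | t$rt > config$deadline_s),
          sprintf("rt outside (0, %g]", config$deadline_s))
  t
}

#' Read a trial-level CSV
#'
#' Comma-separated, UTF-8, header required; missing values (notably RT)
#' encoded as empty cells. Every row is validated against the trial-record
#' contract; row order is preserved.
#'
#' @param path Path to a trials CSV.
#' @param config A [session_config()] supplying the device range and
#'   response deadline.
#' @return A tibble of validated trials.
#' @export
read_trials <- function(path, config = session_config()) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "rrst_io_error")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  validate_trials(raw, config)
}

#' Write a trial-level CSV
#'
#' @param trials A trial table (validated before writing).
#' @param path Output path.
#' @param config A [session_config()].
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, config = session_config()) {
  t <- validate_trials(trials, config)
  write.csv(t, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a subject-level CSV
#'
#' Subject-level tables carry one row per subject: group, derived task
#' measures (sensitivity, slope, metascore, mean RT) where already
#' computed, questionnaire totals, and covariates. Validation is
#' intentionally light: `subject_id` unique and non-empty, `group` in
#' \{FND, HC\}.
#'
#' @param path CSV path.
#' @return A tibble of subjects.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "rrst_io_error")
  }
  s <- as_tibble(read.csv(path, stringsAsFactors = FALSE, na.strings = ""))
  if (!"subject_id" %in% names(s) || !"group" %in% names(s)) {
    abort("subjects table needs `subject_id` and `group` columns.",
          class = "rrst_schema_error")
  }
  if (anyDuplicated(s$subject_id) > 0) {
    abort("duplicate subject_id in subjects table.",
          class = "rrst_validation_error")
  }
  if (!all(s$group %in% c("FND", "HC"))) {
    abort("group must be 'FND' or 'HC'.", class = "rrst_validation_error")
  }
  s
}

#' @rdname read_subjects
#' @param subjects Subject table to write.
#' @export
write_subjects <- function(subjects, path) {
  write.csv(subjects, path, row.names = FALSE, na = "")
  invisible(path)
}
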