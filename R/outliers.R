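#' Flag subjects deviating more than z standard deviations from the mean
#'
#' Implements the cohort-level outlier rule: a subject is flagged iff their
#' score deviates strictly more than `z_threshold` standard deviations from
#' the overall (pooled across groups) mean. A value at exactly the
#' threshold is not flagged. Flagged subjects are marked, never silently
#' dropped; the default pipeline applies the rule to respiratory
#' sensitivity.
#'
#' @param data A data frame with one row per subject, or a numeric vector
#'   of per-subject scores.
#' @param score Column to screen (tidy-eval), when `data` is a data frame.
#' @param z_threshold Flagging threshold in SD units, default 2.5.
#' @return For a data frame: the input with logical `excluded` and
#'   character `exclusion_reason` columns added. For a vector: a logical
#'   flag vector.
#' @examples
#' exclude_outliers(c(0, 0, 0, 0, 100))
#' @export
exclude_outliers <- function(data, score = NULL, z_threshold = 2.5) {
  if (is.numeric(data)) {
    return(.flag_outliers(data, z_threshold))
  }
  score <- rlang::enquo(score)
  if (rlang::quo_is_null(score)) {
    abort("supply the `score` column to screen.", class = "rrst_argument_error")
  }
  x <- rlang::eval_tidy(score, data)
  flags <- .flag_outliers(x, z_threshold)
  data$excluded <- flags
  data$exclusion_reason <- ifelse(
    flags,
    sprintf("score deviates more than %g SD from the overall mean",
            z_threshold),
    ""
  )
  data
}

.flag_outliers <- function(x, z_threshold) {
  ok <- is.finite(x)
  if (sum(ok) < 3) {
    abort("need at least 3 finite values to screen for outliers.",
          class = "rrst_argument_error")
  }
  m <- mean(x[ok])
  s <- sd(x[ok])
  if (s == 0) {
    warn("zero variance in scores; no outliers flagged.")
    return(rep(FALSE, length(x)))
  }
  flags <- rep(FALSE, length(x))
  flags[ok] <- abs(x[ok] - m) > z_threshold * s
  flags
}
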