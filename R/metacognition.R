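#' Type-II ROC metacognitive sensitivity (AUROC2)
#'
#' Scores how well trialwise confidence discriminates a subject's own
#' correct from incorrect trials, independently of first-order accuracy.
#' Thresholds are swept over the unique confidence values (inclusion by
#' `>=`); at each threshold the type-II hit rate is
#' `P(confidence >= thr | correct)` and the type-II false-alarm rate is
#' `P(confidence >= thr | incorrect)`. The area under the resulting ROC
#' curve is computed by the trapezoid rule. With tie handling this equals
#' the pairwise Mann-Whitney-type statistic (see
#' [auroc2_pairwise_oracle()]).
#'
#' When a subject has no correct or no incorrect trials the score is
#' undefined and is reported as `NA` with `defined = FALSE` — never silently
#' imputed at 0.5.
#'
#' @param confidence Numeric vector of confidence ratings (0-100 scale,
#'   used raw, no binning).
#' @param correct Logical vector of trial correctness, same length.
#' @return An object of class `metacog_result`: a list with `auroc2`,
#'   `n_correct`, `n_incorrect`, `defined`, and `roc_points` (a tibble of
#'   ordered `(fa, hit)` pairs from (0,0) to (1,1)).
#' @examples
#' r <- type2_roc(c(80, 60, 70, 20), c(TRUE, TRUE, FALSE, FALSE))
#' r$auroc2 # 0.75
#' @export
type2_roc <- function(confidence, correct) {
  if (length(confidence) != length(correct)) {
    abort("`confidence` and `correct` must have equal length.",
          class = "rrst_argument_error")
  }
  if (length(confidence) < 1) {
    abort("need at least one trial.", class = "rrst_argument_error")
  }
  correct <- as.logical(correct)
  keep <- !is.na(confidence) & !is.na(correct)
  confidence <- confidence[keep]
  correct <- correct[keep]
  n_correct <- sum(correct)
  n_incorrect <- sum(!correct)

  if (n_correct == 0 || n_incorrect == 0) {
    return(structure(
      list(auroc2 = NA_real_, n_correct = n_correct,
           n_incorrect = n_incorrect, defined = FALSE,
           roc_points = tibble(fa = c(0, 1), hit = c(0, 1))),
      class = "metacog_result"
    ))
  }

  thr <- sort(unique(confidence), decreasing = TRUE)
  hit <- vapply(thr, function(t) mean(confidence[correct] >= t), numeric(1))
  fa <- vapply(thr, function(t) mean(confidence[!correct] >= t), numeric(1))
  roc <- tibble(fa = c(0, fa), hit = c(0, hit))
  # trapezoidal area under the (fa, hit) polyline
  auc <- sum(diff(roc$fa) * (head(roc$hit, -1) + roc$hit[-1]) / 2)

  structure(
    list(auroc2 = auc, n_correct = n_correct, n_incorrect = n_incorrect,
         defined = TRUE, roc_points = roc),
    class = "metacog_result"
  )
}

#' Exhaustive pairwise AUROC2 (independent oracle)
#'
#' Computes the probability that a randomly chosen correct trial carries
#' higher confidence than a randomly chosen incorrect trial, with ties
#' counting one half, by exhaustive enumeration of all pairs. This is the
#' Mann-Whitney-type statistic that the trapezoidal type-II ROC area equals;
#' it is kept as a separate code path so the two can cross-check each other.
#'
#' @inheritParams type2_roc
#' @return The pairwise AUROC2 score in `[0, 1]`.
#' @export
auroc2_pairwise_oracle <- function(confidence, correct) {
  correct <- as.logical(correct)
  if (length(confidence) != length(correct)) {
    abort("`confidence` and `correct` must have equal length.",
          class = "rrst_argument_error")
  }
  cc <- confidence[correct]
  cw <- confidence[!correct]
  if (length(cc) == 0 || length(cw) == 0) {
    abort("AUROC2 undefined: need at least one correct and one incorrect trial.",
          class = "rrst_undefined_result_error")
  }
  cmp <- outer(cc, cw, ">") + 0.5 * outer(cc, cw, "==")
  mean(cmp)
}

#' @export
print.metacog_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("type-II ROC: AUROC2 = %.4f (%d correct / %d incorrect trials)\n",
                x$auroc2, x$n_correct, x$n_incorrect))
  } else {
    cat(sprintf("type-II ROC: undefined (%d correct / %d incorrect trials)\n",
                x$n_correct, x$n_incorrect))
  }
  invisible(x)
}

#' @rdname type2_roc
#' @param x A `metacog_result`.
#' @param ... Unused.
#' @export
glance.metacog_result <- function(x, ...) {
  tibble(auroc2 = x$auroc2, n_correct = x$n_correct,
         n_incorrect = x$n_incorrect, defined = x$defined)
}
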