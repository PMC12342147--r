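#' Initialise a psi adaptive staircase
#'
#' Builds the gridded joint posterior over candidate thresholds (Weibull
#' scale `alpha`) and slopes (`beta`) that drives Bayesian adaptive stimulus
#' selection. Each trial's obstruction level is chosen to minimise the
#' expected Shannon entropy of the joint posterior over the two possible
#' outcomes (the classic psi criterion), with the guess rate fixed at 0.5
#' (2AFC) and a small fixed lapse so no outcome has zero likelihood.
#'
#' Default grid: `alpha` evenly spaced on `[0.5, 17]` (60 points), `beta`
#' log-spaced on `[0.5, 32]` (30 points), candidate stimuli 61 evenly spaced
#' levels on `[0, 17]`.
#'
#' @param alpha_range,n_alpha Range and resolution of the threshold grid
#'   (obstruction units).
#' @param beta_range,n_beta Range and resolution of the (log-spaced) slope
#'   grid.
#' @param stimuli Candidate stimulus levels within `[0, max_obstruction]`.
#' @param guess Fixed guess rate (0.5 for 2AFC).
#' @param lapse Fixed lapse rate used during the staircase; default 0.02.
#' @param prior Optional non-negative weight vector over the
#'   `n_alpha * n_beta` grid nodes (alpha varying fastest); normalised
#'   internally. Uniform when `NULL`.
#' @return An object of class `psi_staircase`.
#' @examples
#' st <- init_psi()
#' sum(st$posterior) # 1
#' @export
init_psi <- function(alpha_range = c(0.5, 17), n_alpha = 60,
                     beta_range = c(0.5, 32), n_beta = 30,
                     stimuli = seq(0, 17, length.out = 61),
                     guess = 0.5, lapse = 0.02, prior = NULL) {
  if (n_alpha < 1 || n_beta < 1 || length(stimuli) < 1) {
    abort("empty psi grid or candidate set.", class = "rrst_config_error")
  }
  if (alpha_range[1] <= 0 || beta_range[1] <= 0) {
    abort("alpha and beta grid ranges must be positive.",
          class = "rrst_config_error")
  }
  alpha_grid <- seq(alpha_range[1], alpha_range[2], length.out = n_alpha)
  beta_grid <- exp(seq(log(beta_range[1]), log(beta_range[2]),
                       length.out = n_beta))
  nodes <- expand.grid(alpha = alpha_grid, beta = beta_grid,
                       KEEP.OUT.ATTRS = FALSE)
  n_nodes <- nrow(nodes)

  if (is.null(prior)) {
    posterior <- rep(1 / n_nodes, n_nodes)
  } else {
    if (length(prior) != n_nodes || any(prior < 0) || sum(prior) <= 0) {
      abort("`prior` must be a non-negative weight vector over the grid.",
            class = "rrst_config_error")
    }
    posterior <- prior / sum(prior)
  }

  stimuli <- sort(stimuli)
  # likelihood of a correct response at each candidate x grid node
  L <- vapply(
    seq_len(n_nodes),
    function(j) weibull_p_correct(stimuli, nodes$alpha[j], nodes$beta[j],
                                  guess, lapse),
    numeric(length(stimuli))
  )
  L <- matrix(L, nrow = length(stimuli))

  structure(
    list(
      alpha_grid = alpha_grid, beta_grid = beta_grid, nodes = nodes,
      posterior = posterior, stimuli = stimuli, likelihood = L,
      guess = guess, lapse = lapse,
      history = list(stimulus_level = numeric(), correct = logical())
    ),
    class = "psi_staircase"
  )
}

#' Select the next stimulus level of a psi staircase
#'
#' Returns the candidate obstruction level minimising the expected posterior
#' Shannon entropy of the joint (alpha, beta) posterior, where the outcome
#' probabilities are taken from the current posterior predictive. Exact ties
#' resolve to the lowest (least aversive) level; candidates are scanned in
#' ascending order.
#'
#' @param state A `psi_staircase` object.
#' @return A single stimulus level.
#' @export
select_stimulus <- function(state) {
  stopifnot(inherits(state, "psi_staircase"))
  eh <- .psi_expected_entropy_cpp(state$likelihood, state$posterior)
  state$stimuli[which.min(eh)]
}

#' Update a psi staircase posterior with a trial outcome
#'
#' Bayes update: each grid node's mass is multiplied by the Weibull
#' likelihood of the observed outcome at that node and the posterior is
#' renormalised; the trial is appended to the state's history.
#'
#' @param state A `psi_staircase` object.
#' @param stimulus The presented level; must be one of the candidate levels.
#' @param correct Logical outcome of the trial.
#' @return The updated `psi_staircase`.
#' @export
update_posterior <- function(state, stimulus, correct) {
  stopifnot(inherits(state, "psi_staircase"), is.logical(correct),
            length(correct) == 1L)
  row <- which(abs(state$stimuli - stimulus) < 1e-9)
  if (length(row) != 1L) {
    abort(sprintf("stimulus %g is not in the candidate set.", stimulus),
          class = "rrst_argument_error")
  }
  like <- if (correct) state$likelihood[row, ] else 1 - state$likelihood[row, ]
  post <- state$posterior * like
  total <- sum(post)
  if (!is.finite(total) || total <= 0) {
    abort("posterior mass vanished; outcome has zero likelihood everywhere.",
          class = "rrst_numeric_error")
  }
  state$posterior <- post / total
  state$history$stimulus_level <- c(state$history$stimulus_level, stimulus)
  state$history$correct <- c(state$history$correct, correct)
  state
}

#' Number of updates applied to a psi staircase
#'
#' @param state A `psi_staircase` object.
#' @return Integer trial count.
#' @export
psi_n_trials <- function(state) {
  length(state$history$stimulus_level)
}

#' Posterior summaries of a psi staircase
#'
#' Posterior means, standard deviations and central 95% credible intervals
#' of the threshold (`alpha`) and slope (`beta`) parameters by grid
#' summation over the joint posterior.
#'
#' @param state A `psi_staircase` object.
#' @param level Credible level, default 0.95.
#' @return A one-row tibble with columns `alpha_mean`, `alpha_sd`,
#'   `alpha_lo`, `alpha_hi`, `beta_mean`, `beta_sd`, `beta_lo`, `beta_hi`
#'   and `n_trials`.
#' @export
posterior_estimates <- function(state, level = 0.95) {
  stopifnot(inherits(state, "psi_staircase"))
  post <- state$posterior
  marg <- function(values) {
    m <- tapply(post, values, sum)
    v <- as.numeric(names(m))
    m <- as.numeric(m)
    mean <- sum(v * m)
    sdv <- sqrt(max(sum(v^2 * m) - mean^2, 0))
    cs <- cumsum(m)
    lo <- v[which(cs >= (1 - level) / 2)[1]]
    hi <- v[which(cs >= 1 - (1 - level) / 2)[1]]
    c(mean = mean, sd = sdv, lo = lo, hi = hi)
  }
  a <- unname(marg(state$nodes$alpha))
  b <- unname(marg(state$nodes$beta))
  tibble(
    alpha_mean = a[1], alpha_sd = a[2], alpha_lo = a[3], alpha_hi = a[4],
    beta_mean = b[1], beta_sd = b[2], beta_lo = b[3], beta_hi = b[4],
    n_trials = psi_n_trials(state)
  )
}

#' @export
print.psi_staircase <- function(x, ...) {
  cat("psi staircase:", length(x$alpha_grid), "x", length(x$beta_grid),
      "grid,", length(x$stimuli), "candidate levels,",
      psi_n_trials(x), "trials seen\n")
  if (psi_n_trials(x) > 0) {
    est <- posterior_estimates(x)
    cat(sprintf("  posterior alpha = %.2f (sd %.2f), beta = %.2f (sd %.2f)\n",
                est$alpha_mean, est$alpha_sd, est$beta_mean, est$beta_sd))
  }
  invisible(x)
}

#' Dump a psi staircase state to JSON (debugging aid)
#'
#' @param state A `psi_staircase` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
psi_dump_json <- function(state, path) {
  stopifnot(inherits(state, "psi_staircase"))
  est <- posterior_estimates(state)
  jsonlite::write_json(
    list(
      alpha_grid = state$alpha_grid, beta_grid = state$beta_grid,
      stimuli = state$stimuli, posterior = state$posterior,
      history = state$history, estimates = as.list(est)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
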