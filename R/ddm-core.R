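#' Drift-diffusion parameter set
#'
#' Parameters of the unbiased accuracy-coded drift-diffusion model used
#' throughout: drift rate `v` (evidence units/s; positive drift favours the
#' correct/upper boundary), boundary separation `a` (decision caution), and
#' non-decision time `t0` (sensory and motor delays, seconds). The starting
#' point is fixed at `a / 2` (no bias under accuracy coding) and the
#' diffusion scale at 1.
#'
#' @param v Drift rate.
#' @param a Boundary separation, `> 0`.
#' @param t0 Non-decision time in seconds, `>= 0`.
#' @return A `ddm_params` list.
#' @export
ddm_params <- function(v, a, t0) {
  if (!is.finite(a) || a <= 0) {
    abort("boundary separation `a` must be positive.",
          class = "rrst_argument_error")
  }
  if (!is.finite(t0) || t0 < 0) {
    abort("non-decision time `t0` must be non-negative.",
          class = "rrst_argument_error")
  }
  structure(list(v = v, a = a, t0 = t0, z = a / 2, s = 1),
            class = "ddm_params")
}

#' Simulate drift-diffusion trials
#'
#' Euler-Maruyama simulation of the diffusion from the unbiased start point
#' `a/2` with drift `v` and unit diffusion scale; the response time is the
#' boundary hitting time plus the non-decision time `t0`. Under accuracy
#' coding the upper boundary is the correct response.
#'
#' @param params A [ddm_params()] object.
#' @param n Number of trials.
#' @param dt Euler step in seconds, `<= 1e-3`.
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @return A tibble with columns `rt` (seconds) and `correct` (upper-boundary
#'   hit).
#' @export
simulate_ddm <- function(params, n, dt = 1e-3, seed = NULL) {
  stopifnot(inherits(params, "ddm_params"), n >= 1)
  if (dt > 1e-3) {
    abort("Euler step `dt` must be <= 1e-3 s.", class = "rrst_argument_error")
  }
  if (!is.null(seed)) set.seed(seed)
  sim <- .simulate_ddm_cpp(as.integer(n), params$v, params$a, params$t0, dt)
  tibble(rt = sim$rt, correct = sim$upper)
}

#' Wiener first-passage-time density
#'
#' Density of absorption at the chosen boundary at time `rt`, for the
#' unbiased diffusion (start `a/2`, scale 1). Evaluated with the standard
#' small-time/large-time series expansions, truncated adaptively to an
#' absolute tolerance of `1e-7`. Times at or before the non-decision time
#' have density 0.
#'
#' @param rt Response time(s) in seconds.
#' @param boundary `"upper"` (correct) or `"lower"` (error).
#' @param params A [ddm_params()] object.
#' @return Non-negative densities.
#' @export
wiener_fpt_density <- function(rt, boundary = c("upper", "lower"), params) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "ddm_params"))
  .wiener_density_cpp(rt, rep(boundary == "upper", length(rt)),
                      params$v, params$a, params$t0)
}

#' Closed-form absorption probability at the correct boundary
#'
#' For the unbiased diffusion with drift `v`, boundary separation `a` and
#' unit scale, the probability of hitting the upper (correct) boundary is
#' `plogis(v * a)`.
#'
#' @param v Drift rate.
#' @param a Boundary separation.
#' @return Probability of a correct response.
#' @export
ddm_p_correct <- function(v, a) {
  plogis(v * a)
}

#' EZ-diffusion moment inversion
#'
#' Closed-form method-of-moments estimator mapping (accuracy, RT mean, RT
#' variance) to drift rate, boundary separation and non-decision time
#' (diffusion scale 1). Used as a fast independent cross-check of the
#' likelihood-based fits. Accuracy exactly at 0.5 (or at 0/1) is nudged by
#' an edge correction of half a trial (`1/(2n)`; `5e-4` when `n` is
#' unknown) before inversion, since the logit is undefined at the boundary.
#'
#' @param accuracy Proportion correct in `(0, 1)`.
#' @param mean_rt Mean RT of correct trials, seconds.
#' @param var_rt RT variance of correct trials, seconds squared, `> 0`.
#' @param n Optional trial count used for the edge correction.
#' @return A [ddm_params()] object.
#' @export
ez_diffusion <- function(accuracy, mean_rt, var_rt, n = NULL) {
  if (var_rt <= 0) {
    abort("`var_rt` must be positive.", class = "rrst_argument_error")
  }
  if (accuracy < 0 || accuracy > 1) {
    abort("`accuracy` must lie in [0, 1].", class = "rrst_argument_error")
  }
  eps <- if (!is.null(n)) 1 / (2 * n) else 5e-4
  if (accuracy == 0.5) accuracy <- 0.5 + eps
  if (accuracy >= 1) accuracy <- 1 - eps
  if (accuracy <= 0) accuracy <- eps

  L <- qlogis(accuracy)
  x <- L * (accuracy^2 * L - accuracy * L + accuracy - 0.5) / var_rt
  v <- sign(accuracy - 0.5) * x^(1 / 4)
  a <- L / v
  mdt <- (a / (2 * v)) * (1 - exp(-v * a)) / (1 + exp(-v * a))
  ddm_params(v = v, a = a, t0 = mean_rt - mdt)
}

#' Posterior probability that one quantity exceeds another
#'
#' Fraction of aligned posterior draws with `samples_a > samples_b`
#' (strict inequality; identical draws contribute 0).
#'
#' @param samples_a,samples_b Equal-length aligned posterior sample
#'   vectors.
#' @return Probability in `[0, 1]`.
#' @export
posterior_prob_greater <- function(samples_a, samples_b) {
  if (length(samples_a) == 0 || length(samples_b) == 0) {
    abort("empty sample vector.", class = "rrst_argument_error")
  }
  if (length(samples_a) != length(samples_b)) {
    abort("sample vectors must be aligned and equal length.",
          class = "rrst_argument_error")
  }
  mean(samples_a > samples_b)
}
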