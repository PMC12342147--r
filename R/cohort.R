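#' Specification of a synthetic two-group discrimination cohort
#'
#' Defines the generative study conditions for a clinical respiratory
#' discrimination cohort: group sizes, per-subject Weibull threshold and
#' slope populations, lapse rate, the confidence-coupling strength that
#' controls metacognitive sensitivity, drift-diffusion population
#' parameters, questionnaire populations with a configurable per-group
#' coupling of somatoform-dissociation scores to respiratory sensitivity,
#' medication prevalence, and discomfort-rating effect sizes.
#'
#' Defaults are calibrated to published cohort summary statistics for a
#' functional neurological disorder (FND) vs healthy control (HC)
#' comparison: 43/48 subjects, group sensitivity means 2.88/3.53 (SD
#' 1.62/1.13; standardised difference ~0.47), a somatoform-dissociation
#' coupling giving r ~ -0.38 with sensitivity in the FND group and ~0 in
#' HC, median response times near 1 s, and a modest drift-rate deficit in
#' the FND group.
#'
#' @param n_fnd,n_hc Group sizes.
#' @param threshold_mean_fnd,threshold_mean_hc,threshold_sd_fnd,threshold_sd_hc
#'   Population mean/SD of the true 75%-correct threshold (obstruction
#'   units); sensitivity is `17 - threshold`.
#' @param slope_meanlog,slope_sdlog_hc,slope_sdlog_fnd Log-normal
#'   parameters of the true psychometric slope; the FND slope spread is a
#'   separate knob.
#' @param lapse Lapse rate, in `[0, 0.1]`.
#' @param confidence_coupling,confidence_noise,confidence_intercept
#'   Confidence model: the rating is a logistic transform of
#'   `intercept + coupling * |evidence| + noise`, scaled to 0-100. Coupling
#'   0 gives chance-level metacognition (AUROC2 = 0.5).
#' @param v_mean_hc,v_mean_fnd,v_sd Drift-rate population (evidence
#'   units/s).
#' @param a_mean_hc,a_mean_fnd,a_sd Boundary-separation population.
#' @param t_mean,t_sd Non-decision-time population (seconds), shared
#'   across groups.
#' @param sdq_mean_hc,sdq_sd_hc,sdq_mean_fnd,sdq_sd_fnd SDQ-20 population
#'   per group (marginal mean/SD).
#' @param sdq_slope_hc,sdq_slope_fnd Regression slope of SDQ-20 on true
#'   sensitivity per group; residual noise is chosen so the marginal SD is
#'   preserved, making the implied correlation `slope * sd_sens / sd_sdq`.
#' @param medication_prev_fnd,medication_prev_hc Psychotropic-medication
#'   prevalence per group.
#' @param max_obstruction Device ceiling.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(
    n_fnd = 43, n_hc = 48,
    threshold_mean_fnd = 14.12, threshold_sd_fnd = 1.62,
    threshold_mean_hc = 13.47, threshold_sd_hc = 1.13,
    slope_meanlog = log(3), slope_sdlog_hc = 0.5, slope_sdlog_fnd = 0.5,
    lapse = 0.02,
    confidence_coupling = 0.6, confidence_noise = 1.0,
    confidence_intercept = -0.3,
    v_mean_hc = 0.60, v_mean_fnd = 0.53, v_sd = 0.25,
    a_mean_hc = 1.85, a_mean_fnd = 1.75, a_sd = 0.30,
    t_mean = 0.33, t_sd = 0.08,
    sdq_mean_hc = 23.5, sdq_sd_hc = 3.7,
    sdq_mean_fnd = 36.8, sdq_sd_fnd = 12.2,
    sdq_slope_hc = 0, sdq_slope_fnd = -2.86,
    medication_prev_fnd = 19 / 43, medication_prev_hc = 2 / 46,
    max_obstruction = 17) {
  sds <- c(threshold_sd_fnd, threshold_sd_hc, v_sd, a_sd, t_sd,
           sdq_sd_hc, sdq_sd_fnd)
  if (any(sds <= 0)) {
    abort("all population SDs must be positive.", class = "rrst_config_error")
  }
  if (n_fnd < 2 || n_hc < 2) {
    abort("group sizes must be at least 2.", class = "rrst_config_error")
  }
  if (lapse < 0 || lapse > 0.1) {
    abort("lapse must lie in [0, 0.1].", class = "rrst_config_error")
  }
  # infeasible SDQ-sensitivity coupling: implied |r| >= 1
  for (g in c("hc", "fnd")) {
    b <- get(paste0("sdq_slope_", g))
    s_sens <- get(paste0("threshold_sd_", g))
    s_sdq <- get(paste0("sdq_sd_", g))
    if (abs(b) * s_sens >= s_sdq) {
      abort(sprintf(
        "sdq coupling in group %s implies |r| >= 1 (|slope| * sd_sens = %.2f >= sd_sdq = %.2f).",
        toupper(g), abs(b) * s_sens, s_sdq), class = "rrst_config_error")
    }
  }
  structure(as.list(environment())[setdiff(names(as.list(environment())),
                                           c("sds", "g", "b", "s_sens", "s_sdq"))],
            class = "cohort_spec")
}

# Weibull scale parameter that puts the 75%-correct point at `threshold`
.alpha_from_threshold <- function(threshold, beta, guess = 0.5, lapse = 0.02) {
  frac <- (0.75 - guess) / (1 - guess - lapse)
  threshold / (-log(1 - frac))^(1 / beta)
}

#' Generate a latent cohort
#'
#' Draws one subject-level cohort from a [cohort_spec()]: true psychometric
#' parameters (threshold, slope, derived Weibull scale), drift-diffusion
#' parameters, questionnaire totals generated from group means plus the
#' configured coupling of SDQ-20 to true sensitivity, medication status,
#' BMI and discomfort ratings. Deterministic given `seed`; group sizes are
#' exact.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A tibble with one row per subject carrying the latent ground
#'   truth (`*_true` columns) and observed covariates.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n_fnd + spec$n_hc
  group <- c(rep("FND", spec$n_fnd), rep("HC", spec$n_hc))
  is_fnd <- group == "FND"

  thr_mean <- ifelse(is_fnd, spec$threshold_mean_fnd, spec$threshold_mean_hc)
  thr_sd <- ifelse(is_fnd, spec$threshold_sd_fnd, spec$threshold_sd_hc)
  # The calibration targets are post-exclusion summary statistics, so the
  # latent population carries the upstream 2.5-SD screen: thresholds outside
  # the pooled-population exclusion band are redrawn (truncated mixture).
  w_fnd <- spec$n_fnd / n
  mu_pool <- w_fnd * spec$threshold_mean_fnd + (1 - w_fnd) * spec$threshold_mean_hc
  var_pool <- w_fnd * (spec$threshold_sd_fnd^2 + spec$threshold_mean_fnd^2) +
    (1 - w_fnd) * (spec$threshold_sd_hc^2 + spec$threshold_mean_hc^2) -
    mu_pool^2
  band <- mu_pool + c(-2.5, 2.5) * sqrt(var_pool)
  threshold <- rnorm(n, thr_mean, thr_sd)
  for (k in 1:50) {
    bad <- threshold < band[1] | threshold > band[2]
    if (!any(bad)) break
    threshold[bad] <- rnorm(sum(bad), thr_mean[bad], thr_sd[bad])
  }
  threshold <- pmin(pmax(threshold, 0.1), spec$max_obstruction - 0.1)
  sensitivity <- spec$max_obstruction - threshold

  sdlog <- ifelse(is_fnd, spec$slope_sdlog_fnd, spec$slope_sdlog_hc)
  slope <- rlnorm(n, spec$slope_meanlog, sdlog)
  alpha <- .alpha_from_threshold(threshold, slope, lapse = spec$lapse)

  v <- rnorm(n, ifelse(is_fnd, spec$v_mean_fnd, spec$v_mean_hc), spec$v_sd)
  a <- pmax(rnorm(n, ifelse(is_fnd, spec$a_mean_fnd, spec$a_mean_hc),
                  spec$a_sd), 0.5)
  t0 <- pmin(pmax(rnorm(n, spec$t_mean, spec$t_sd), 0.12), 0.8)

  # SDQ-20 from group mean + coupling to true sensitivity; residual SD keeps
  # the marginal SD, so implied r = slope * sd_sens / sd_sdq exactly
  sdq_mean <- ifelse(is_fnd, spec$sdq_mean_fnd, spec$sdq_mean_hc)
  sdq_sd <- ifelse(is_fnd, spec$sdq_sd_fnd, spec$sdq_sd_hc)
  b <- ifelse(is_fnd, spec$sdq_slope_fnd, spec$sdq_slope_hc)
  sens_mean <- spec$max_obstruction - thr_mean
  resid_sd <- sqrt(sdq_sd^2 - (b * thr_sd)^2)
  sdq <- sdq_mean + b * (sensitivity - sens_mean) + rnorm(n, 0, resid_sd)
  sdq <- pmin(pmax(round(sdq), 20), 100)  # SDQ-20 instrument range

  q <- function(m_hc, s_hc, m_fnd, s_fnd, lo, hi, digits = 0) {
    x <- rnorm(n, ifelse(is_fnd, m_fnd, m_hc), ifelse(is_fnd, s_fnd, s_hc))
    pmin(pmax(round(x, digits), lo), hi)
  }
  # discomfort ratings: FND shift = d * common SD (SD 22 on a 0-100 scale)
  rating <- function(d) q(25, 22, 25 + d * 22, 22, 0, 100)

  tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group,
    threshold_true = threshold,
    sensitivity_true = sensitivity,
    alpha_true = alpha,
    slope_true = slope,
    lapse = spec$lapse,
    v_true = v, a_true = a, t_true = t0,
    conf_coupling = spec$confidence_coupling,
    conf_noise = spec$confidence_noise,
    conf_intercept = spec$confidence_intercept,
    sdq20 = sdq,
    maia_total = q(24.1, 4.5, 19.9, 6.3, 0, 40, 1),
    ias = q(87, 10, 79, 13, 21, 105),
    bdi = q(5.5, 5.5, 16.5, 10, 0, 63),
    stai_t = q(37.5, 9, 46, 11, 20, 80),
    ctq = q(36, 9, 49, 18, 25, 125),
    medication = runif(n) < ifelse(is_fnd, spec$medication_prev_fnd,
                                   spec$medication_prev_hc),
    bmi = q(23.3, 2.8, 25.2, 4.2, 15, 50, 1),
    breathlessness = rating(0.65),
    unpleasantness = rating(0.48),
    dizziness = rating(0.45),
    asthma = rating(0.45)
  )
}

#' Simulate one trial response of a latent subject
#'
#' In `"lognormal"` mode correctness is a Bernoulli draw with probability
#' given by the subject's Weibull psychometric function
#' ([weibull_p_correct()] — the single source of truth shared with the
#' fitter) and the response time is a fast lognormal; use this mode for
#' psychometric and staircase studies. In `"ddm"` mode choice and RT are
#' drawn jointly from the subject's drift-diffusion process, correctness
#' being the boundary hit — accuracy is then `plogis(v a)`, independent of
#' the stimulus level, and carries the drift-rate group structure that the
#' hierarchical diffusion fit is meant to recover.
#'
#' Confidence in both modes is a monotone (logistic) function of the
#' trial's internal evidence magnitude plus noise, scaled to 0-100:
#' evidence is `N(qnorm(p), 1)` conditioned on its sign matching the
#' trial's correctness, so confidence carries information about accuracy
#' in proportion to the coupling strength.
#'
#' @param subject One row of a [generate_cohort()] tibble (data frame or
#'   list).
#' @param stimulus_level Obstruction level in `[0, 17]`.
#' @param mode `"ddm"` or `"lognormal"` response-time generation.
#' @return A list: `correct`, `confidence` (integer 0-100), `rt` (seconds).
#'   Uses the current RNG stream.
#' @export
simulate_response <- function(subject, stimulus_level, mode = c("ddm", "lognormal")) {
  mode <- match.arg(mode)
  s <- as.list(subject)

  if (mode == "ddm") {
    # choice and RT drawn jointly from the subject's diffusion process;
    # correctness is the boundary hit, so accuracy is plogis(v * a) and
    # carries the drift-rate structure directly
    sim <- .simulate_ddm_cpp(1L, s$v_true, s$a_true, s$t_true, 1e-3)
    correct <- sim$upper[1]
    rt <- min(max(sim$rt[1], 0.16), 5.99)
    p <- plogis(s$v_true * s$a_true)
  } else {
    p <- weibull_p_correct(stimulus_level, s$alpha_true, s$slope_true,
                           guess = 0.5, lapse = s$lapse)
    correct <- runif(1) < p
    rt <- min(max(rlnorm(1, log(0.9), 0.35), 0.16), 5.99)
  }
  p <- min(max(p, 1e-6), 1 - 1e-6)

  # evidence conditioned on sign(E) == correct (inverse-CDF draw)
  delta <- qnorm(p)
  u <- if (correct) runif(1, pnorm(-delta), 1) else runif(1, 0, pnorm(-delta))
  e <- delta + qnorm(u)
  latent <- s$conf_intercept + s$conf_coupling * abs(e) +
    rnorm(1, 0, s$conf_noise)
  confidence <- as.integer(round(100 * plogis(latent)))

  list(correct = correct, confidence = confidence, rt = rt)
}

#' Simulate a closed-loop staircase session for one subject
#'
#' Runs a full adaptive session: each trial's obstruction level is chosen
#' by the psi staircase from the subject's responses so far, the response
#' is simulated with [simulate_response()], and the staircase posterior is
#' updated. Trial and block indices and the randomised interval assignment
#' (obstruction on breath 1 or 2) are populated. Reproducible given
#' `seed`.
#'
#' @param subject One row of a [generate_cohort()] tibble.
#' @param cfg A [session_config()].
#' @param seed Optional integer seed.
#' @param mode RT generation mode, see [simulate_response()].
#' @param staircase Optional pre-initialised [init_psi()] state (a fresh
#'   default staircase is used when `NULL`).
#' @return A tibble of trial records (possibly empty); the final staircase
#'   state is attached as attribute `"psi_state"`.
#' @export
simulate_session <- function(subject, cfg = session_config(), seed = NULL,
                             mode = c("ddm", "lognormal"), staircase = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  s <- as.list(subject)
  n <- cfg$n_trials_total
  if (n == 0) {
    out <- tibble(
      subject_id = character(), group = character(), block = integer(),
      trial_index = integer(), stimulus_level = numeric(),
      stimulus_interval = integer(), response_interval = integer(),
      correct = logical(), confidence = integer(), rt = numeric(),
      deadline = numeric()
    )
    return(out)
  }
  state <- staircase %||%
    init_psi(stimuli = seq(0, cfg$max_obstruction, length.out = 61))

  block_sizes <- c(rep(ceiling(n / cfg$n_blocks), cfg$n_blocks - 1))
  block_sizes <- c(block_sizes, n - sum(block_sizes))
  block_sizes <- block_sizes[block_sizes > 0]
  block <- rep(seq_along(block_sizes), block_sizes)
  trial_index <- unlist(lapply(block_sizes, seq_len), use.names = FALSE)

  level <- rt <- numeric(n)
  corr <- logical(n)
  conf <- stim_int <- integer(n)
  for (i in seq_len(n)) {
    x <- select_stimulus(state)
    resp <- simulate_response(s, x, mode = mode)
    state <- update_posterior(state, x, resp$correct)
    level[i] <- x
    corr[i] <- resp$correct
    conf[i] <- resp$confidence
    rt[i] <- resp$rt
    stim_int[i] <- sample(c(1L, 2L), 1)
  }
  out <- tibble(
    subject_id = s$subject_id, group = s$group,
    block = block, trial_index = trial_index,
    stimulus_level = level,
    stimulus_interval = stim_int,
    response_interval = ifelse(corr, stim_int, 3L - stim_int),
    correct = corr, confidence = conf, rt = rt,
    deadline = cfg$deadline_s
  )
  attr(out, "psi_state") <- state
  out
}

#' Simulate a full study: cohort plus closed-loop sessions
#'
#' Generates a latent cohort and one adaptive session per subject. The
#' global seed is expanded into independent per-subject substreams so that
#' individual sessions are reproducible in isolation.
#'
#' Pick the response mode for the layer under study: `"lognormal"`
#' (Weibull-governed accuracy) for psychometric, staircase and
#' group-statistics work; `"ddm"` (the default) for drift-diffusion
#' recovery, where accuracy is stimulus-independent and psychometric
#' thresholds are not meaningful — see [simulate_response()].
#'
#' @param spec A [cohort_spec()].
#' @param cfg A [session_config()].
#' @param seed Integer seed.
#' @param mode RT generation mode, see [simulate_response()].
#' @return A list with `trials` (all trial records), `subjects` (observed
#'   subject-level table: group, questionnaires, covariates), and `truth`
#'   (the latent cohort tibble).
#' @export
simulate_study <- function(spec = cohort_spec(), cfg = session_config(),
                           seed = 1, mode = c("ddm", "lognormal")) {
  mode <- match.arg(mode)
  truth <- generate_cohort(spec, seed = seed)
  set.seed(seed + 1L)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, nrow(truth))
  trials <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    simulate_session(truth[i, ], cfg, seed = sub_seeds[i], mode = mode)
  })
  subjects <- truth |>
    dplyr::select("subject_id", "group", "sdq20", "maia_total", "ias",
                  "bdi", "stai_t", "ctq", "medication", "bmi",
                  "breathlessness", "unpleasantness", "dizziness", "asthma")
  list(trials = trials, subjects = subjects, truth = truth)
}
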