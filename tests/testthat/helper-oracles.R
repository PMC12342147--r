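# Independent oracles and fixture builders used across the suite.

# Exhaustive grid-search maximiser of the Weibull Bernoulli log-likelihood.
grid_search_weibull_loglik <- function(level, correct,
                                       alphas = seq(2, 30, length.out = 120),
                                       betas = exp(seq(log(0.3), log(40),
                                                       length.out = 80)),
                                       lapses = seq(0, 0.1, by = 0.01),
                                       guess = 0.5) {
  best <- -Inf
  for (l in lapses) {
    for (b in betas) {
      p <- outer(level, alphas, function(x, a)
        guess + (1 - guess - l) * (1 - exp(-(x / a)^b)))
      p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
      ll <- colSums(log(p[correct, , drop = FALSE])) +
        colSums(log(1 - p[!correct, , drop = FALSE]))
      best <- max(best, max(ll))
    }
  }
  best
}

# Brute-force expected posterior entropy of a psi state, per candidate.
expected_entropy_oracle <- function(state) {
  post <- state$posterior
  vapply(seq_along(state$stimuli), function(c) {
    pc_node <- state$likelihood[c, ]
    p1 <- sum(pc_node * post)
    h <- 0
    for (outcome in c(TRUE, FALSE)) {
      like <- if (outcome) pc_node else 1 - pc_node
      w <- post * like
      pw <- sum(w)
      if (pw > 0) {
        q <- w / pw
        q <- q[q > 0]
        h <- h + pw * (-sum(q * log(q)))
      }
    }
    h
  }, numeric(1))
}

# Exact Mann-Whitney p value by full enumeration of group assignments
# (no ties, two-sided by doubling the smaller tail, as in the exact test).
mann_whitney_enumeration_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_obs <- sum(outer(x, y, ">"))
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(idx)
    sum(outer(pooled[idx], pooled[-idx], ">")))
  p_low <- mean(us <= u_obs)
  p_high <- mean(us >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# A small synthetic trial table for IO tests.
make_trial_table <- function(n = 10, subject_id = "S001", group = "HC",
                             seed = 42) {
  set.seed(seed)
  stim_int <- sample(c(1L, 2L), n, replace = TRUE)
  correct <- sample(c(TRUE, FALSE), n, replace = TRUE)
  tibble::tibble(
    subject_id = subject_id, group = group,
    block = rep(1L, n), trial_index = seq_len(n),
    stimulus_level = round(runif(n, 0, 17), 2),
    stimulus_interval = stim_int,
    response_interval = ifelse(correct, stim_int, 3L - stim_int),
    correct = correct,
    confidence = sample(0:100, n, replace = TRUE),
    rt = round(runif(n, 0.3, 3), 3),
    deadline = 6
  )
}

# Simulate a Weibull observer at given levels (no staircase).
simulate_weibull_trials <- function(n, alpha, beta, lapse = 0.02,
                                    levels = NULL, seed = 1) {
  set.seed(seed)
  x <- levels %||% runif(n, 0, 17)
  p <- weibull_p_correct(x, alpha, beta, guess = 0.5, lapse = lapse)
  list(level = x, correct = runif(n) < p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
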