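test_that("cohort generation is deterministic with exact group sizes", {
  co1 <- generate_cohort(seed = 4)
  co2 <- generate_cohort(seed = 4)
  expect_equal(co1, co2)
  expect_equal(sum(co1$group == "FND"), 43)
  expect_equal(sum(co1$group == "HC"), 48)
  expect_true(all(co1$threshold_true > 0 & co1$threshold_true < 17))
  expect_equal(co1$sensitivity_true, 17 - co1$threshold_true)
  # derived Weibull scale puts the 75% point at the drawn threshold
  thr_back <- threshold_at(p = 0.75, alpha = co1$alpha_true[1],
                           beta = co1$slope_true[1], lapse = co1$lapse[1])
  expect_equal(thr_back, co1$threshold_true[1], tolerance = 1e-9)
})

test_that("a null group effect yields a near-zero threshold effect size", {
  spec <- cohort_spec(n_fnd = 10000, n_hc = 10000,
                      threshold_mean_fnd = 13.5, threshold_sd_fnd = 1.3,
                      threshold_mean_hc = 13.5, threshold_sd_hc = 1.3)
  co <- generate_cohort(spec, seed = 9)
  d <- cohens_d(co$threshold_true[co$group == "FND"],
                co$threshold_true[co$group == "HC"])
  expect_lt(abs(d), 0.05)
})

test_that("default spec reproduces the configured sensitivity effect size", {
  ds <- vapply(1:200, function(s) {
    co <- generate_cohort(seed = s)
    cohens_d(co$sensitivity_true[co$group == "HC"],
             co$sensitivity_true[co$group == "FND"])
  }, numeric(1))
  expect_gte(mean(ds), 0.37)
  expect_lte(mean(ds), 0.57)
})

test_that("SDQ-sensitivity coupling holds in FND and is absent in HC", {
  rs <- vapply(1:60, function(s) {
    co <- generate_cohort(seed = s)
    fnd <- co[co$group == "FND", ]
    hc <- co[co$group == "HC", ]
    c(cor(fnd$sdq20, fnd$sensitivity_true), cor(hc$sdq20, hc$sensitivity_true))
  }, numeric(2))
  expect_gte(mean(rs[1, ]), -0.55)
  expect_lte(mean(rs[1, ]), -0.20)
  expect_lt(abs(mean(rs[2, ])), 0.15)
  # an infeasible coupling (implied |r| >= 1) is a configuration error
  expect_error(cohort_spec(sdq_slope_fnd = -9, sdq_sd_fnd = 10),
               class = "rrst_config_error")
})

test_that("response generation respects chance, asymptote and independence", {
  co <- generate_cohort(seed = 3)
  s <- co[1, ]
  set.seed(50)
  # zero signal: accuracy at chance
  acc0 <- mean(vapply(1:2000, function(i)
    simulate_response(s, 0, mode = "lognormal")$correct, logical(1)))
  expect_lt(abs(acc0 - 0.5), 0.035)
  # saturating stimulus, steep slope, no lapse: accuracy near 1
  s2 <- s
  s2$alpha_true <- 8; s2$slope_true <- 30; s2$lapse <- 0
  acc1 <- mean(vapply(1:500, function(i)
    simulate_response(s2, 17, mode = "lognormal")$correct, logical(1)))
  expect_gt(acc1, 0.99)
  # zero confidence coupling: AUROC2 indistinguishable from 0.5
  s3 <- s
  s3$conf_coupling <- 0
  resp <- purrr::map_dfr(1:10000, function(i)
    tibble::as_tibble(simulate_response(s3, 12, mode = "lognormal")))
  expect_lt(abs(auroc2_pairwise_oracle(resp$confidence, resp$correct) - 0.5),
            0.02)
  expect_true(all(resp$confidence >= 0 & resp$confidence <= 100))
})

test_that("sessions have the configured shape, balance and determinism", {
  co <- generate_cohort(seed = 6)
  cfg <- session_config()
  tr <- simulate_session(co[2, ], cfg, seed = 77, mode = "lognormal")
  expect_equal(nrow(tr), 50)
  expect_equal(as.numeric(table(tr$block)), c(17, 17, 16))
  expect_equal(max(tr$trial_index), 17)
  expect_true(all(tr$stimulus_level >= 0 & tr$stimulus_level <= 17))
  # interval assignment is consistent with correctness
  expect_equal(tr$correct, tr$stimulus_interval == tr$response_interval)
  # interval balance within binomial fluctuation (4 Sd)
  n1 <- sum(tr$stimulus_interval == 1)
  expect_lt(abs(n1 - 25), 4 * sqrt(50 * 0.25))
  # determinism and the empty session
  tr2 <- simulate_session(co[2, ], cfg, seed = 77, mode = "lognormal")
  expect_equal(tr, tr2, ignore_attr = TRUE)
  tr0 <- simulate_session(co[2, ], session_config(n_trials_total = 0),
                          seed = 1)
  expect_equal(nrow(tr0), 0)
})

test_that("simulate-then-fit recovers the generating curve (shared evaluator)", {
  co <- generate_cohort(seed = 8)
  # pick a mid-range subject so the curve is identifiable within the device
  s <- co[which.min(abs(co$threshold_true - 13)), ]
  set.seed(60)
  lev <- runif(8000, 0, 17)
  corr <- vapply(seq_along(lev), function(i)
    simulate_response(s, lev[i], mode = "lognormal")$correct, logical(1))
  fit <- fit_weibull_mle(level = lev, correct = corr, lapse = s$lapse)
  expect_equal(fit$alpha, s$alpha_true, tolerance = 0.25 / s$alpha_true)
  expect_equal(fit$threshold75, s$threshold_true, tolerance = 0.3)
})

test_that("ddm response mode ties RTs to the subject's diffusion parameters", {
  co <- generate_cohort(seed = 13)
  s <- co[1, ]
  set.seed(70)
  resp <- purrr::map_dfr(1:400, function(i)
    tibble::as_tibble(simulate_response(s, 10, mode = "ddm")))
  expect_true(all(resp$rt > s$t_true))
  # mean decision time in the right ballpark of the closed-form expectation
  edt <- (s$a_true / (2 * s$v_true)) * tanh(s$v_true * s$a_true / 2)
  expect_lt(abs(mean(resp$rt) - (s$t_true + edt)), 0.35)
})

test_that("study simulation writes coherent trial and subject tables", {
  spec <- cohort_spec(n_fnd = 3, n_hc = 3)
  study <- simulate_study(spec, session_config(n_trials_total = 25),
                          seed = 21, mode = "lognormal")
  expect_equal(nrow(study$trials), 6 * 25)
  expect_equal(nrow(study$subjects), 6)
  expect_equal(nrow(study$truth), 6)
  expect_true(all(c("sdq20", "maia_total", "medication") %in%
                    names(study$subjects)))
  # validates against the trial-record contract
  expect_silent(validate_trials(study$trials,
                                session_config(n_trials_total = 25)))
})
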