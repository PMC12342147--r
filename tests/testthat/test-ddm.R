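test_that("simulated choice fractions match the closed-form absorption law", {
  # zero drift from the midpoint: both boundaries equally likely
  s0 <- simulate_ddm(ddm_params(0, 1.5, 0.3), 10000, seed = 1)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(s0$correct) - 0.5), 3 * se)
  # with drift: P(correct) = plogis(v * a)
  s1 <- simulate_ddm(ddm_params(0.9, 1.8, 0.3), 10000, seed = 2)
  p <- ddm_p_correct(0.9, 1.8)
  expect_lt(abs(mean(s1$correct) - p), 4 * sqrt(p * (1 - p) / 10000))
  # every RT strictly exceeds the non-decision time
  expect_true(all(s1$rt > 0.3))
  expect_error(ddm_params(1, -1, 0.3), class = "rrst_argument_error")
  expect_error(simulate_ddm(ddm_params(1, 1, 0.2), 10, dt = 0.01),
               class = "rrst_argument_error")
})

test_that("first-passage density is normalised and zero at the offset", {
  par <- ddm_params(0.8, 1.6, 0.25)
  f <- function(t) wiener_fpt_density(t, "upper", par) +
    wiener_fpt_density(t, "lower", par)
  total <- integrate(Vectorize(f), 0.25, 60, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-4)
  expect_equal(wiener_fpt_density(0.25, "upper", par), 0)
  expect_equal(wiener_fpt_density(0.1, "lower", par), 0)
  expect_true(all(wiener_fpt_density(seq(0.26, 5, by = 0.01), "upper", par) >= 0))
})

test_that("density integrals match simulated boundary fractions and histogram", {
  par <- ddm_params(0.7, 1.5, 0.3)
  sim <- simulate_ddm(par, 100000, seed = 7)
  # upper-boundary mass
  p_upper <- integrate(Vectorize(function(t) wiener_fpt_density(t, "upper", par)),
                       0.3, 60, rel.tol = 1e-9)$value
  expect_equal(p_upper, mean(sim$correct), tolerance = 0.01)
  # histogram of correct RTs against the density integrated over each bin
  # (the density rises steeply just after t0, so bin masses are compared,
  # not midpoint values), both normalised over the same truncated window
  rts <- sim$rt[sim$correct]
  br <- seq(0.3, 3, by = 0.1)
  h <- hist(rts[rts < 3], breaks = br, plot = FALSE)
  fup <- Vectorize(function(t) wiener_fpt_density(t, "upper", par))
  bin_mass <- vapply(seq_len(length(br) - 1), function(i)
    integrate(fup, br[i], br[i + 1], rel.tol = 1e-8)$value, numeric(1))
  dens_pred <- (bin_mass / sum(bin_mass)) / diff(br)
  # sup-norm discrepancy below the binning + MC tolerance
  expect_lt(max(abs(h$density - dens_pred)), 0.08)
})

test_that("EZ moment inversion recovers simulation parameters within 5%", {
  par <- ddm_params(0.8, 1.8, 0.3)
  sim <- simulate_ddm(par, 200000, seed = 11)
  rc <- sim$rt[sim$correct]
  ez <- ez_diffusion(mean(sim$correct), mean(rc), var(rc), n = nrow(sim))
  expect_equal(ez$v, par$v, tolerance = 0.05)
  expect_equal(ez$a, par$a, tolerance = 0.05)
  expect_equal(ez$t0, par$t0, tolerance = 0.05)
})

test_that("EZ edge cases: direction, symmetry, chance-level correction", {
  expect_gt(ez_diffusion(0.8, 0.7, 0.05)$v, 0)
  expect_lt(ez_diffusion(0.2, 0.7, 0.05)$v, 0)
  hi <- ez_diffusion(0.75, 0.7, 0.05)
  lo <- ez_diffusion(0.25, 0.7, 0.05)
  expect_equal(hi$v, -lo$v, tolerance = 1e-12)
  # exactly at chance: the documented edge correction applies, v finite
  mid <- ez_diffusion(0.5, 0.7, 0.05, n = 100)
  expect_true(is.finite(mid$v))
  expect_gt(mid$v, 0)
  expect_error(ez_diffusion(0.7, 0.7, 0), class = "rrst_argument_error")
})

test_that("posterior_prob_greater counts strict exceedances", {
  expect_equal(posterior_prob_greater(2:11, 1:10), 1)
  expect_equal(posterior_prob_greater(1:10, 1:10), 0)
  # interleaved hand-counted vectors
  a <- c(5, 1, 4, 2, 9, 3, 8, 0, 7, 6)
  b <- c(4, 2, 5, 1, 8, 4, 9, 1, 6, 5)
  expect_equal(posterior_prob_greater(a, b), mean(a > b))
  expect_error(posterior_prob_greater(numeric(0), numeric(0)),
               class = "rrst_argument_error")
  expect_error(posterior_prob_greater(1:3, 1:4), class = "rrst_argument_error")
})

test_that("hierarchical fit returns a coherent, reproducible object", {
  set.seed(30)
  mk <- function(vs, as_, id0, grp) {
    purrr::map_dfr(seq_along(vs), function(i) {
      sim <- simulate_ddm(ddm_params(vs[i], as_[i], 0.3), 60)
      tibble::tibble(subject_id = sprintf("%s%02d", id0, i), group = grp,
                     rt = sim$rt, correct = sim$correct)
    })
  }
  trials <- dplyr::bind_rows(
    mk(rnorm(6, 0.9, 0.2), rnorm(6, 1.6, 0.15), "F", "FND"),
    mk(rnorm(6, 0.9, 0.2), rnorm(6, 1.6, 0.15), "H", "HC")
  )
  fit <- fit_hierarchical_ddm(trials, model_spec = c("v", "a"),
                              n_samples = 300, burn_in = 150, seed = 5)
  expect_s3_class(fit, "hddm_fit")
  expect_equal(nrow(fit$chains), 300)
  expect_setequal(
    setdiff(colnames(fit$chains), "deviance"),
    c("mu_v_FND", "mu_v_HC", "mu_a_FND", "mu_a_HC", "mu_t",
      "sd_v", "sd_a", "sd_t")
  )
  expect_equal(nrow(fit$subject_summary), 12)
  expect_true(all(fit$diagnostics$ratio >= 0))
  # deterministic given the seed
  fit2 <- fit_hierarchical_ddm(trials, model_spec = c("v", "a"),
                               n_samples = 300, burn_in = 150, seed = 5)
  expect_equal(fit$chains, fit2$chains)
  expect_equal(fit$dic, fit2$dic)
  # DIC comparison of a fit with itself is a tie; shared-t contrast errors
  cmp <- compare_models(fit, fit2)
  expect_equal(cmp$delta_dic, c(0, 0))
  expect_error(group_contrast(fit, "t"), class = "rrst_argument_error")
})

test_that("identical populations give exchangeable group contrasts", {
  # P(g1 > g2) tracks the realised finite-sample difference, so under a
  # null population it must scatter on both sides of 0.5 across replicate
  # cohorts rather than pile up at one extreme
  pgs <- vapply(1:6, function(rep) {
    set.seed(400 + rep)
    trials <- purrr::map_dfr(1:12, function(i) {
      s <- simulate_ddm(ddm_params(rnorm(1, 0.9, 0.25), rnorm(1, 1.6, 0.15),
                                   runif(1, 0.25, 0.35)), 50)
      tibble::tibble(subject_id = sprintf("S%02d", i),
                     group = rep(c("HC", "FND"), each = 6)[i],
                     rt = s$rt, correct = s$correct)
    })
    fit <- fit_hierarchical_ddm(trials, model_spec = "v", n_samples = 250,
                                burn_in = 150, seed = rep, min_trials = 30)
    group_contrast(fit, "v")$p_greater
  }, numeric(1))
  expect_gt(max(pgs), 0.2)
  expect_lt(min(pgs), 0.8)
  expect_gt(mean(pgs > 0.5 - 1e-9), 0)  # not uniformly favouring FND
  expect_lt(mean(pgs), 0.95)
  expect_gt(mean(pgs), 0.05)
})

test_that("model comparison refuses fits on different data", {
  set.seed(31)
  mk <- function(seed) {
    set.seed(seed)
    purrr::map_dfr(1:4, function(i) {
      sim <- simulate_ddm(ddm_params(0.8, 1.5, 0.3), 40)
      tibble::tibble(subject_id = sprintf("S%d", i),
                     group = rep(c("FND", "HC"), 2)[i],
                     rt = sim$rt, correct = sim$correct)
    })
  }
  f1 <- fit_hierarchical_ddm(mk(1), model_spec = "v", n_samples = 50,
                             burn_in = 50, seed = 1, min_trials = 30)
  f2 <- fit_hierarchical_ddm(mk(2), model_spec = "v", n_samples = 50,
                             burn_in = 50, seed = 1, min_trials = 30)
  expect_error(compare_models(f1, f2), class = "rrst_argument_error")
})

test_that("RT trimming and missing-RT subjects are handled and logged", {
  set.seed(32)
  sim <- simulate_ddm(ddm_params(0.9, 1.6, 0.3), 80)
  trials <- tibble::tibble(subject_id = "A", group = "FND",
                           rt = sim$rt, correct = sim$correct)
  trials$rt[1:3] <- c(0.05, 6, NA)  # contaminants and a missing RT
  more <- purrr::map_dfr(1:3, function(i) {
    s <- simulate_ddm(ddm_params(0.9, 1.6, 0.3), 80)
    tibble::tibble(subject_id = paste0("B", i), group = "HC",
                   rt = s$rt, correct = s$correct)
  })
  # one subject with all RTs missing is dropped from the DDM only
  ghost <- tibble::tibble(subject_id = "G", group = "HC",
                          rt = NA_real_, correct = TRUE)[rep(1, 40), ]
  expect_message(
    fit <- fit_hierarchical_ddm(dplyr::bind_rows(trials, more, ghost),
                                model_spec = "v", n_samples = 80,
                                burn_in = 60, seed = 2),
    "dropped 1 subject"
  )
  expect_false("G" %in% fit$subject_summary$subject_id)
  expect_equal(fit$subject_summary$n_trials[fit$subject_summary$subject_id == "A"],
               77L)
})
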