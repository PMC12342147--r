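#' Fit task measures for every subject in a trial table
#'
#' Per subject: maximum-likelihood Weibull psychometric fit (threshold at
#' 75% correct, sensitivity, slope), type-II ROC metacognitive score, and
#' mean response time over trials with a recorded RT. Subjects whose
#' psychometric fit fails (degenerate data, too few trials) are retained
#' with `NA` measures and the failure reason recorded.
#'
#' Because staircase sessions concentrate trials near the threshold, the
#' per-subject refit defaults to the stabilised variant of
#' [fit_weibull_mle()]: lapse fixed at the staircase's 0.02 and a weak
#' log-normal penalty on the slope. Pass `lapse = NULL, slope_prior = NULL`
#' for the pure maximum-likelihood refit.
#'
#' @param trials A validated trial table (see [read_trials()]).
#' @param max_obstruction Device ceiling.
#' @param lapse,slope_prior Refit settings, see [fit_weibull_mle()].
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   `sensitivity`, `threshold75`, `slope`, `lapse_hat`, `metascore`,
#'   `metascore_defined`, `mean_rt`, `n_trials`, `fit_ok`, `fit_note`.
#' @export
fit_subjects <- function(trials, max_obstruction = 17, lapse = 0.02,
                         slope_prior = c(log(3), 0.7)) {
  trials |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::group_modify(function(d, key) {
      fit <- tryCatch(
        fit_weibull_mle(level = d$stimulus_level, correct = d$correct,
                        lapse = lapse, slope_prior = slope_prior,
                        max_obstruction = max_obstruction),
        error = function(e) e
      )
      meta <- type2_roc(d$confidence, d$correct)
      if (inherits(fit, "error")) {
        tibble(
          sensitivity = NA_real_, threshold75 = NA_real_, slope = NA_real_,
          lapse_hat = NA_real_, metascore = meta$auroc2,
          metascore_defined = meta$defined,
          mean_rt = mean(d$rt, na.rm = TRUE), n_trials = nrow(d),
          fit_ok = FALSE, fit_note = conditionMessage(fit)
        )
      } else {
        tibble(
          sensitivity = fit$sensitivity, threshold75 = fit$threshold75,
          slope = fit$beta, lapse_hat = fit$lapse,
          metascore = meta$auroc2, metascore_defined = meta$defined,
          mean_rt = mean(d$rt, na.rm = TRUE), n_trials = nrow(d),
          fit_ok = fit$converged, fit_note = ""
        )
      }
    }) |>
    dplyr::ungroup()
}

#' Run a full synthetic study and write its artefacts
#'
#' Generates a cohort and closed-loop sessions from a [cohort_spec()] and
#' [session_config()], then writes `trials.csv`, `subjects.csv` and
#' `ground_truth.json` to `out_dir`. Existing outputs are never overwritten
#' unless `force = TRUE`.
#'
#' @param spec A [cohort_spec()].
#' @param cfg A [session_config()].
#' @param seed Integer seed (mandatory).
#' @param out_dir Output directory (created if needed).
#' @param force Overwrite existing outputs.
#' @param mode RT generation mode, see [simulate_response()].
#' @return Invisibly, a named list of the three file paths.
#' @export
run_simulation <- function(spec = cohort_spec(), cfg = session_config(),
                           seed, out_dir, force = FALSE,
                           mode = c("ddm", "lognormal")) {
  mode <- match.arg(mode)
  if (missing(seed)) abort("`seed` is mandatory.", class = "rrst_config_error")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir),
                   class = "rrst_io_error")
  }
  paths <- list(
    trials = file.path(out_dir, "trials.csv"),
    subjects = file.path(out_dir, "subjects.csv"),
    truth = file.path(out_dir, "ground_truth.json")
  )
  existing <- vapply(paths, file.exists, logical(1))
  if (any(existing) && !force) {
    abort(paste0("outputs already exist (use force = TRUE): ",
                 paste(unlist(paths)[existing], collapse = ", ")),
          class = "rrst_io_error")
  }
  message(sprintf("simulating cohort (%d + %d subjects, %d trials each, seed %d)",
                  spec$n_fnd, spec$n_hc, cfg$n_trials_total, seed))
  study <- simulate_study(spec, cfg, seed = seed, mode = mode)
  write_trials(study$trials, paths$trials, cfg)
  write_subjects(study$subjects, paths$subjects)
  jsonlite::write_json(
    list(seed = seed, mode = mode, truth = study$truth),
    paths$truth, auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Run the full analysis battery on a study's outputs
#'
#' Applies the complete analysis pipeline to a trial table and subject
#' table (paths or data frames): per-subject psychometric fits, metascores
#' and mean RTs; the pooled 2.5-SD outlier exclusion on sensitivity; group
#' contrasts with effect sizes (sensitivity by Welch t / Cohen's d, slope,
#' metascore and RT by Mann-Whitney, medication by chi-squared / odds
#' ratio); per-group SDQ-20 correlations with Bonferroni adjustment; the
#' SDQ-20 ~ sensitivity x group + medication regression; the RT control
#' model; discomfort-rating contrasts with FDR adjustment; and optionally
#' the hierarchical drift-diffusion fit with the drift and boundary group
#' contrasts.
#'
#' Every reported number is tagged with the name of the producing
#' operation. Stats are computed on complete cases with the n used
#' reported.
#'
#' @param trials Trial table or path to `trials.csv`.
#' @param subjects Subject table or path to `subjects.csv`.
#' @param seed Analysis seed (used by the MCMC stage).
#' @param ddm Run the hierarchical DDM stage?
#' @param ddm_samples,ddm_burn MCMC sizes for the DDM stage.
#' @param bonferroni_m Family size for the SDQ correlation family (two
#'   interoceptive measures x two scores by default).
#' @param cfg A [session_config()] for trial validation.
#' @param out_dir Optional directory to write `report.json` and
#'   `subject_summary.csv`.
#' @return An object of class `rrst_report` (a named list), invisibly
#'   written to `out_dir` when given.
#' @export
run_analysis <- function(trials, subjects, seed = 1, ddm = TRUE,
                         ddm_samples = 2000, ddm_burn = 500,
                         bonferroni_m = 4, cfg = session_config(),
                         out_dir = NULL) {
  if (is.character(trials)) trials <- read_trials(trials, cfg)
  else trials <- validate_trials(trials, cfg)
  if (is.character(subjects)) subjects <- read_subjects(subjects)

  fits <- fit_subjects(trials, cfg$max_obstruction)
  summary_tbl <- dplyr::left_join(fits, subjects,
                                  by = c("subject_id", "group"))
  summary_tbl <- exclude_outliers(summary_tbl, score = .data$sensitivity)
  kept <- summary_tbl |> dplyr::filter(!.data$excluded)
  fnd <- kept |> dplyr::filter(.data$group == "FND")
  hc <- kept |> dplyr::filter(.data$group == "HC")

  cc <- function(x) x[is.finite(x)]

  sens_test <- welch_t(cc(hc$sensitivity), cc(fnd$sensitivity))
  slope_test <- mann_whitney(cc(hc$slope), cc(fnd$slope))
  meta_test <- mann_whitney(cc(hc$metascore), cc(fnd$metascore))
  rt_test <- mann_whitney(cc(hc$mean_rt), cc(fnd$mean_rt))
  med_tab <- c(sum(fnd$medication), sum(!fnd$medication),
               sum(hc$medication), sum(!hc$medication))

  cor_block <- function(df, label) {
    r_sens <- pearson_r(df$sdq20, df$sensitivity)
    r_meta <- pearson_r(df$sdq20, df$metascore)
    list(
      sdq_sensitivity = c(as.list(r_sens), operation = "pearson_r",
                          group = label),
      sdq_metascore = c(as.list(r_meta), operation = "pearson_r",
                        group = label)
    )
  }
  cors <- list(FND = cor_block(fnd, "FND"), HC = cor_block(hc, "HC"))
  p_family <- c(cors$FND$sdq_sensitivity$p_value,
                cors$FND$sdq_metascore$p_value)
  p_adj <- adjust_pvalues(p_family, method = "bonferroni", m = bonferroni_m)
  cors$FND$sdq_sensitivity$p_adjusted <- p_adj[1]
  cors$FND$sdq_metascore$p_adjusted <- p_adj[2]

  reg <- fit_linear_model(kept, sdq20 ~ sensitivity * group + medication)
  rt_reg <- fit_linear_model(kept, sensitivity ~ group + mean_rt)

  ratings <- c("breathlessness", "unpleasantness", "dizziness", "asthma")
  disc <- purrr::map(ratings, function(v) {
    mw <- mann_whitney(cc(fnd[[v]]), cc(hc[[v]]))
    d <- cohens_d(cc(fnd[[v]]), cc(hc[[v]]))
    c(as.list(mw), effect_size = d, operation = "mann_whitney+cohens_d")
  })
  names(disc) <- ratings
  disc_p <- vapply(disc, function(x) x$p_value, numeric(1))
  disc_adj <- adjust_pvalues(disc_p, method = "bh_fdr")
  for (i in seq_along(disc)) disc[[i]]$p_adjusted <- disc_adj[i]

  report <- list(
    n = list(total = nrow(summary_tbl), included = nrow(kept),
             excluded = sum(summary_tbl$excluded),
             fnd = nrow(fnd), hc = nrow(hc),
             operation = "exclude_outliers"),
    sensitivity = c(as.list(sens_test),
                    cohens_d = cohens_d(cc(hc$sensitivity),
                                        cc(fnd$sensitivity)),
                    mean_fnd = mean(cc(fnd$sensitivity)),
                    sd_fnd = sd(cc(fnd$sensitivity)),
                    mean_hc = mean(cc(hc$sensitivity)),
                    sd_hc = sd(cc(hc$sensitivity)),
                    operation = "welch_t+cohens_d_pooled"),
    slope = c(as.list(slope_test),
              median_fnd = median(cc(fnd$slope)),
              median_hc = median(cc(hc$slope)),
              operation = "mann_whitney"),
    metascore = c(as.list(meta_test),
                  median_fnd = median(cc(fnd$metascore)),
                  median_hc = median(cc(hc$metascore)),
                  operation = "mann_whitney"),
    mean_rt = c(as.list(rt_test),
                median_fnd = median(cc(fnd$mean_rt)),
                median_hc = median(cc(hc$mean_rt)),
                operation = "mann_whitney"),
    medication = c(as.list(chi2_test(med_tab[1], med_tab[2],
                                     med_tab[3], med_tab[4])),
                   as.list(odds_ratio(med_tab[1], med_tab[2],
                                      med_tab[3], med_tab[4])),
                   operation = "chi2_test+odds_ratio"),
    correlations = cors,
    regression_sdq = list(coefficients = tidy(reg), model = glance(reg),
                          operation = "fit_linear_model"),
    regression_rt_control = list(coefficients = tidy(rt_reg),
                                 model = glance(rt_reg),
                                 operation = "fit_linear_model"),
    discomfort = disc,
    seed = seed
  )

  if (ddm) {
    hfit <- fit_hierarchical_ddm(
      trials |> dplyr::filter(.data$subject_id %in% kept$subject_id),
      model_spec = c("v", "a"),
      n_samples = ddm_samples, burn_in = ddm_burn, seed = seed
    )
    report$ddm <- list(
      p_v_hc_gt_fnd = group_contrast(hfit, "v")$p_greater,
      p_a_hc_gt_fnd = group_contrast(hfit, "a")$p_greater,
      dic = hfit$dic, converged = hfit$converged,
      group_level = tidy(hfit),
      operation = "fit_hierarchical_ddm+posterior_prob_greater"
    )
  }

  out <- structure(list(report = report, subject_summary = summary_tbl),
                   class = "rrst_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    write_subjects(summary_tbl, file.path(out_dir, "subject_summary.csv"))
  }
  out
}

#' @export
print.rrst_report <- function(x, ...) {
  r <- x$report
  cat("RRST analysis report\n")
  cat(sprintf("  subjects: %d included / %d total (%d excluded)\n",
              r$n$included, r$n$total, r$n$excluded))
  cat(sprintf("  sensitivity: HC %.2f (%.2f) vs FND %.2f (%.2f), d = %.2f, p = %.3g\n",
              r$sensitivity$mean_hc, r$sensitivity$sd_hc,
              r$sensitivity$mean_fnd, r$sensitivity$sd_fnd,
              r$sensitivity$cohens_d, r$sensitivity$p_value))
  cat(sprintf("  metascore medians: HC %.3f vs FND %.3f, p = %.3g\n",
              r$metascore$median_hc, r$metascore$median_fnd,
              r$metascore$p_value))
  if (!is.null(r$ddm)) {
    cat(sprintf("  DDM: P(v HC > FND) = %.3f, P(a HC > FND) = %.3f\n",
                r$ddm$p_v_hc_gt_fnd, r$ddm$p_a_hc_gt_fnd))
  }
  invisible(x)
}

#' Parameter-recovery metrics for a matched simulation/analysis pair
#'
#' Compares the analysis estimates with the generating ground truth:
#' bias, RMSE and Pearson correlation for the threshold, sensitivity, log
#' slope, and (when present in the truth table) subject drift rates.
#'
#' @param analysis An [run_analysis()] result (`rrst_report`) or its
#'   `subject_summary` tibble.
#' @param truth The `truth` tibble from [simulate_study()] (or the parsed
#'   `ground_truth.json`).
#' @return A tibble with one row per recovered quantity: `quantity`,
#'   `bias`, `rmse`, `correlation`, `n`.
#' @export
recovery_report <- function(analysis, truth) {
  est <- if (inherits(analysis, "rrst_report")) analysis$subject_summary
         else analysis
  if (is.character(truth)) {
    truth <- as_tibble(jsonlite::read_json(truth, simplifyVector = TRUE)$truth)
  }
  if (!setequal(est$subject_id, truth$subject_id)) {
    abort("subject ids in analysis and ground truth do not match.",
          class = "rrst_argument_error")
  }
  m <- dplyr::inner_join(est, truth, by = "subject_id",
                         suffix = c("_est", "_true"))
  one <- function(e, t, label) {
    ok <- is.finite(e) & is.finite(t)
    tibble(
      quantity = label,
      bias = mean(e[ok] - t[ok]),
      rmse = sqrt(mean((e[ok] - t[ok])^2)),
      correlation = if (sum(ok) >= 3 && sd(e[ok]) > 0 && sd(t[ok]) > 0)
        cor(e[ok], t[ok]) else NA_real_,
      n = sum(ok)
    )
  }
  dplyr::bind_rows(
    one(m$threshold75, m$threshold_true, "threshold75"),
    one(m$sensitivity, m$sensitivity_true, "sensitivity"),
    one(log(m$slope), log(m$slope_true), "log_slope")
  )
}
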