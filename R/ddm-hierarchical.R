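#' Hierarchical Bayesian drift-diffusion fit
#'
#' Estimates group- and subject-level drift-diffusion parameters
#' simultaneously from trial-level choices and response times, under
#' accuracy coding (upper boundary = correct, start point `a/2`, diffusion
#' scale 1). Subject parameters are drawn from group-level normal
#' populations; any subset of \{v, a, t\} may be allowed to vary by group
#' (`model_spec`), the rest sharing a single population mean across groups.
#'
#' Sampling is component-wise Metropolis-within-Gibbs with random-walk
#' proposals whose scales adapt during burn-in (target acceptance ~0.35);
#' the group-level drift mean is updated by its conjugate Gibbs draw.
#' Priors are weakly informative: population drift mean `N(2, 3)`, boundary
#' mean `Gamma(mean 1.5)`, non-decision mean truncated normal within
#' `(0.05, min RT)`, population SDs half-normal(0, 1).
#'
#' Trials with missing RT, RT below `rt_min` (fast contaminants) or at/over
#' the response deadline `rt_max` are excluded and logged; subjects left
#' with fewer than `min_trials` usable trials are dropped from this fit
#' only.
#'
#' Convergence is assessed per stored parameter as the batch-means
#' Monte-Carlo error relative to the posterior SD; the fit is flagged
#' `converged` only when every ratio is below 0.10. A non-converged fit is
#' returned with the flag set, never silently accepted.
#'
#' @param trials Data frame with columns `subject_id`, `group` (FND/HC),
#'   `rt` (seconds), `correct` (logical).
#' @param model_spec Character subset of `c("v", "a", "t")` naming the
#'   parameters whose population means vary by group.
#' @param n_samples Post-burn-in MCMC samples to retain.
#' @param burn_in Burn-in (adaptation) iterations.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param rt_min,rt_max RT trimming bounds in seconds.
#' @param min_trials Minimum usable trials per subject.
#' @return An object of class `hddm_fit` with group-level posterior chains,
#'   subject-level posterior summaries, DIC decomposition, and diagnostics.
#' @export
fit_hierarchical_ddm <- function(trials, model_spec = c("v", "a"),
                                 n_samples = 2000, burn_in = 500,
                                 seed = 1, rt_min = 0.15, rt_max = 6,
                                 min_trials = 30) {
  stopifnot(all(model_spec %in% c("v", "a", "t")))
  set.seed(seed)

  usable <- trials |>
    dplyr::filter(!is.na(.data$rt), .data$rt > rt_min, .data$rt < rt_max)
  n_trimmed <- nrow(trials) - nrow(usable)
  if (n_trimmed > 0) {
    message(sprintf("hddm: excluded %d trial(s) with missing or out-of-range RT.",
                    n_trimmed))
  }
  all_ids <- unique(trials$subject_id)
  counts <- usable |> dplyr::count(.data$subject_id)
  n_usable <- setNames(rep(0L, length(all_ids)), all_ids)
  n_usable[counts$subject_id] <- counts$n
  dropped <- all_ids[n_usable < min_trials]
  if (length(dropped) > 0) {
    message(sprintf("hddm: dropped %d subject(s) with < %d usable trials.",
                    length(dropped), min_trials))
    usable <- usable |> dplyr::filter(!.data$subject_id %in% dropped)
  }
  ids <- unique(usable$subject_id)
  n_sub <- length(ids)
  groups_of <- vapply(ids, function(id)
    as.character(usable$group[usable$subject_id == id][1]), character(1))
  group_levels <- sort(unique(groups_of))
  if (n_sub < 2) {
    abort("need at least 2 usable subjects.", class = "rrst_argument_error")
  }
  per_group <- table(factor(groups_of, levels = group_levels))
  if (length(group_levels) == 2 && any(per_group < 5)) {
    warn("fewer than 5 usable subjects in a group; estimates will be fragile.")
  }

  rt_list <- lapply(ids, function(id) usable$rt[usable$subject_id == id])
  cr_list <- lapply(ids, function(id)
    as.logical(usable$correct[usable$subject_id == id]))
  min_rt <- vapply(rt_list, min, numeric(1))
  gidx <- match(groups_of, group_levels)
  n_groups <- length(group_levels)

  # group index per parameter: all-1s when the parameter is shared
  gi <- function(p) if (p %in% model_spec) gidx else rep(1L, n_sub)
  ng <- function(p) if (p %in% model_spec) n_groups else 1L
  gv <- list(v = gi("v"), a = gi("a"), t = gi("t"))

  # -- initial values from per-subject EZ moments -------------------------
  v <- a <- t0 <- numeric(n_sub)
  for (i in seq_len(n_sub)) {
    acc <- mean(cr_list[[i]])
    rts_c <- rt_list[[i]][cr_list[[i]]]
    if (length(rts_c) < 5) rts_c <- rt_list[[i]]
    ez <- tryCatch(
      ez_diffusion(acc, mean(rts_c), max(var(rts_c), 1e-3),
                   n = length(rt_list[[i]])),
      error = function(e) ddm_params(0.5, 1.5, 0.3)
    )
    v[i] <- min(max(ez$v, -5), 5)
    a[i] <- min(max(ez$a, 0.3), 4)
    t0[i] <- min(max(ez$t0, 0.06), min_rt[i] - 0.02)
  }
  mu_v <- vapply(seq_len(ng("v")), function(g) mean(v[gv$v == g]), numeric(1))
  mu_a <- vapply(seq_len(ng("a")), function(g) mean(a[gv$a == g]), numeric(1))
  mu_t <- vapply(seq_len(ng("t")), function(g) mean(t0[gv$t == g]), numeric(1))
  sd_v <- max(sd(v), 0.1)
  sd_a <- max(sd(a), 0.1)
  sd_t <- max(sd(t0), 0.03)

  loglik_i <- vapply(seq_len(n_sub), function(i)
    .wiener_loglik_cpp(rt_list[[i]], cr_list[[i]], v[i], a[i], t0[i]),
    numeric(1))
  bad <- !is.finite(loglik_i)
  if (any(bad)) {
    # fall back to a bland but valid start
    for (i in which(bad)) {
      v[i] <- 0.5; a[i] <- 1.5; t0[i] <- min(0.2, min_rt[i] / 2)
      loglik_i[i] <- .wiener_loglik_cpp(rt_list[[i]], cr_list[[i]],
                                        v[i], a[i], t0[i])
    }
  }

  # proposal scales (adapted during burn-in)
  sc_v <- rep(0.3, n_sub); sc_a <- rep(0.15, n_sub); sc_t <- rep(0.02, n_sub)
  sc_mu_a <- rep(0.1, ng("a")); sc_mu_t <- rep(0.02, ng("t"))
  sc_sd <- c(v = 0.3, a = 0.3, t = 0.3)
  acc_v <- acc_a <- acc_t <- rep(0, n_sub)
  acc_mu_a <- rep(0, ng("a")); acc_mu_t <- rep(0, ng("t"))
  acc_sd <- c(v = 0, a = 0, t = 0)
  half_norm_lp <- function(s, scale = 1) {
    if (s <= 0) return(-Inf)
    dnorm(s, 0, scale, log = TRUE)
  }

  par_names <- c(
    paste0("mu_v", if (ng("v") > 1) paste0("_", group_levels) else ""),
    paste0("mu_a", if (ng("a") > 1) paste0("_", group_levels) else ""),
    paste0("mu_t", if (ng("t") > 1) paste0("_", group_levels) else ""),
    "sd_v", "sd_a", "sd_t", "deviance"
  )
  chains <- matrix(NA_real_, nrow = n_samples, ncol = length(par_names),
                   dimnames = list(NULL, par_names))
  sub_sum <- matrix(0, n_sub, 3, dimnames = list(ids, c("v", "a", "t")))
  sub_sq <- sub_sum

  t_floor <- 0.03
  total_iter <- burn_in + n_samples
  adapt_every <- 50

  for (iter in seq_len(total_iter)) {
    # ---- subject-level updates ----
    for (i in seq_len(n_sub)) {
      # drift
      prop <- v[i] + rnorm(1, 0, sc_v[i])
      if (abs(prop) <= 8) {
        llp <- .wiener_loglik_cpp(rt_list[[i]], cr_list[[i]], prop, a[i], t0[i])
        lr <- llp - loglik_i[i] +
          dnorm(prop, mu_v[gv$v[i]], sd_v, log = TRUE) -
          dnorm(v[i], mu_v[gv$v[i]], sd_v, log = TRUE)
        if (is.finite(llp) && log(runif(1)) < lr) {
          v[i] <- prop; loglik_i[i] <- llp; acc_v[i] <- acc_v[i] + 1
        }
      }
      # boundary
      prop <- a[i] + rnorm(1, 0, sc_a[i])
      if (prop >= 0.1 && prop <= 6) {
        llp <- .wiener_loglik_cpp(rt_list[[i]], cr_list[[i]], v[i], prop, t0[i])
        lr <- llp - loglik_i[i] +
          dnorm(prop, mu_a[gv$a[i]], sd_a, log = TRUE) -
          dnorm(a[i], mu_a[gv$a[i]], sd_a, log = TRUE)
        if (is.finite(llp) && log(runif(1)) < lr) {
          a[i] <- prop; loglik_i[i] <- llp; acc_a[i] <- acc_a[i] + 1
        }
      }
      # non-decision time
      prop <- t0[i] + rnorm(1, 0, sc_t[i])
      if (prop >= t_floor && prop < min_rt[i] - 1e-3) {
        llp <- .wiener_loglik_cpp(rt_list[[i]], cr_list[[i]], v[i], a[i], prop)
        lr <- llp - loglik_i[i] +
          dnorm(prop, mu_t[gv$t[i]], sd_t, log = TRUE) -
          dnorm(t0[i], mu_t[gv$t[i]], sd_t, log = TRUE)
        if (is.finite(llp) && log(runif(1)) < lr) {
          t0[i] <- prop; loglik_i[i] <- llp; acc_t[i] <- acc_t[i] + 1
        }
      }
    }

    # ---- group-level means ----
    # drift mean: conjugate normal draw (prior N(2, 3))
    for (g in seq_len(ng("v"))) {
      vi <- v[gv$v == g]
      prec <- 1 / 3^2 + length(vi) / sd_v^2
      mu_post <- (2 / 3^2 + sum(vi) / sd_v^2) / prec
      mu_v[g] <- rnorm(1, mu_post, sqrt(1 / prec))
    }
    # boundary mean: MH with Gamma(mean 1.5) prior
    for (g in seq_len(ng("a"))) {
      ai <- a[gv$a == g]
      prop <- mu_a[g] + rnorm(1, 0, sc_mu_a[g])
      if (prop > 0) {
        lr <- sum(dnorm(ai, prop, sd_a, log = TRUE)) -
          sum(dnorm(ai, mu_a[g], sd_a, log = TRUE)) +
          dgamma(prop, shape = 2.25, rate = 1.5, log = TRUE) -
          dgamma(mu_a[g], shape = 2.25, rate = 1.5, log = TRUE)
        if (log(runif(1)) < lr) {
          mu_a[g] <- prop
          acc_mu_a[g] <- acc_mu_a[g] + 1
        }
      }
    }
    # non-decision mean: MH with truncated normal prior
    for (g in seq_len(ng("t"))) {
      ti <- t0[gv$t == g]
      prop <- mu_t[g] + rnorm(1, 0, sc_mu_t[g])
      if (prop > 0.05 && prop < min(min_rt)) {
        lr <- sum(dnorm(ti, prop, sd_t, log = TRUE)) -
          sum(dnorm(ti, mu_t[g], sd_t, log = TRUE)) +
          dnorm(prop, 0.3, 0.25, log = TRUE) -
          dnorm(mu_t[g], 0.3, 0.25, log = TRUE)
        if (log(runif(1)) < lr) {
          mu_t[g] <- prop
          acc_mu_t[g] <- acc_mu_t[g] + 1
        }
      }
    }
    # ---- group-level SDs (log-scale random walk, half-normal prior) ----
    upd_sd <- function(s, values, mu_vec, gvec, scale_name) {
      prop <- s * exp(rnorm(1, 0, sc_sd[scale_name]))
      lr <- sum(dnorm(values, mu_vec[gvec], prop, log = TRUE)) -
        sum(dnorm(values, mu_vec[gvec], s, log = TRUE)) +
        half_norm_lp(prop) - half_norm_lp(s) +
        log(prop) - log(s)  # Jacobian of the log-scale walk
      if (is.finite(lr) && log(runif(1)) < lr) {
        acc_sd[scale_name] <<- acc_sd[scale_name] + 1
        prop
      } else {
        s
      }
    }
    sd_v <- upd_sd(sd_v, v, mu_v, gv$v, "v")
    sd_a <- upd_sd(sd_a, a, mu_a, gv$a, "a")
    sd_t <- upd_sd(sd_t, t0, mu_t, gv$t, "t")

    # ---- adaptation during burn-in ----
    if (iter <= burn_in && iter %% adapt_every == 0) {
      tune <- function(sc, acc) {
        rate <- acc / adapt_every
        pmin(pmax(sc * exp(rate - 0.35), 1e-4), 5)
      }
      sc_v <- tune(sc_v, acc_v); sc_a <- tune(sc_a, acc_a)
      sc_t <- tune(sc_t, acc_t)
      sc_mu_a <- tune(sc_mu_a, acc_mu_a)
      sc_mu_t <- tune(sc_mu_t, acc_mu_t)
      sc_sd <- tune(sc_sd, acc_sd)
      acc_v[] <- 0; acc_a[] <- 0; acc_t[] <- 0
      acc_mu_a[] <- 0; acc_mu_t[] <- 0; acc_sd[] <- 0
    }

    # ---- storage ----
    if (iter > burn_in) {
      k <- iter - burn_in
      chains[k, ] <- c(mu_v, mu_a, mu_t, sd_v, sd_a, sd_t,
                       -2 * sum(loglik_i))
      sub_sum <- sub_sum + cbind(v, a, t0)
      sub_sq <- sub_sq + cbind(v, a, t0)^2
    }
  }

  # ---- DIC ----
  sub_mean <- sub_sum / n_samples
  dhat <- -2 * sum(vapply(seq_len(n_sub), function(i)
    .wiener_loglik_cpp(rt_list[[i]], cr_list[[i]],
                       sub_mean[i, 1], sub_mean[i, 2], sub_mean[i, 3]),
    numeric(1)))
  dbar <- mean(chains[, "deviance"])
  pd <- dbar - dhat
  dic <- dbar + pd

  # ---- diagnostics: batch-means MC error vs posterior SD ----
  diag_cols <- setdiff(colnames(chains), "deviance")
  diagnostics <- purrr::map_dfr(diag_cols, function(p) {
    x <- chains[, p]
    nb <- max(min(30, floor(length(x) / 10)), 2)
    bs <- floor(length(x) / nb)
    bm <- vapply(seq_len(nb), function(b)
      mean(x[((b - 1) * bs + 1):(b * bs)]), numeric(1))
    mcse <- sd(bm) / sqrt(nb)
    tibble(parameter = p, mcse = mcse, posterior_sd = sd(x),
           ratio = ifelse(sd(x) > 0, mcse / sd(x), 0))
  })

  structure(
    list(
      model_spec = model_spec,
      group_levels = group_levels,
      chains = as_tibble(as.data.frame(chains)),
      subject_summary = tibble(
        subject_id = ids, group = groups_of,
        v_mean = sub_mean[, 1], a_mean = sub_mean[, 2], t_mean = sub_mean[, 3],
        v_sd = sqrt(pmax(sub_sq[, 1] / n_samples - sub_mean[, 1]^2, 0)),
        a_sd = sqrt(pmax(sub_sq[, 2] / n_samples - sub_mean[, 2]^2, 0)),
        t_sd = sqrt(pmax(sub_sq[, 3] / n_samples - sub_mean[, 3]^2, 0)),
        n_trials = vapply(rt_list, length, integer(1))
      ),
      dic = dic, pd = pd, mean_deviance = dbar, deviance_at_mean = dhat,
      diagnostics = diagnostics,
      converged = all(diagnostics$ratio < 0.10),
      n_samples = n_samples, burn_in = burn_in, seed = seed,
      n_trimmed = n_trimmed, dropped_subjects = dropped,
      fingerprint = c(n = nrow(usable), sum_rt = sum(usable$rt),
                      n_correct = sum(usable$correct))
    ),
    class = "hddm_fit"
  )
}

#' Compare hierarchical DDM fits by DIC
#'
#' Ranks fits of competing group structures on the same data by the
#' deviance information criterion, `DIC = Dbar + pD` with
#' `pD = Dbar - D(posterior mean)`. Fits must have identical data
#' fingerprints.
#'
#' @param ... `hddm_fit` objects, or a single list of them.
#' @return A tibble sorted by ascending DIC with columns `model`, `dic`,
#'   `pd`, `mean_deviance`, `delta_dic`, `converged`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "hddm_fit")) fits <- fits[[1]]
  stopifnot(all(vapply(fits, inherits, logical(1), "hddm_fit")))
  fps <- lapply(fits, function(f) f$fingerprint)
  if (length(unique(vapply(fps, paste, character(1), collapse = "|"))) > 1) {
    abort("fits were not run on identical data (fingerprint mismatch).",
          class = "rrst_argument_error")
  }
  out <- purrr::map_dfr(fits, function(f) tibble(
    model = paste0("{", paste(f$model_spec, collapse = ","), "}"),
    dic = f$dic, pd = f$pd, mean_deviance = f$mean_deviance,
    converged = f$converged
  ))
  out <- dplyr::arrange(out, .data$dic)
  out$delta_dic <- out$dic - out$dic[1]
  out
}

#' Posterior group contrast from a hierarchical DDM fit
#'
#' @param fit An `hddm_fit` with the parameter varying by group.
#' @param param One of `"v"`, `"a"`, `"t"`.
#' @param greater,lesser Group labels to compare, default `P(HC > FND)`.
#' @return A list with `p_greater` and the vector of posterior draws of
#'   the difference.
#' @export
group_contrast <- function(fit, param = "v", greater = "HC", lesser = "FND") {
  stopifnot(inherits(fit, "hddm_fit"))
  if (!param %in% fit$model_spec) {
    abort(sprintf("parameter '%s' does not vary by group in this fit.", param),
          class = "rrst_argument_error")
  }
  ca <- paste0("mu_", param, "_", greater)
  cb <- paste0("mu_", param, "_", lesser)
  sa <- fit$chains[[ca]]
  sb <- fit$chains[[cb]]
  list(p_greater = posterior_prob_greater(sa, sb), diff = sa - sb)
}

#' @export
print.hddm_fit <- function(x, ...) {
  cat(sprintf(
    "hierarchical DDM fit: %d subjects, group-varying {%s}\n",
    nrow(x$subject_summary), paste(x$model_spec, collapse = ",")))
  cat(sprintf("  %d samples after %d burn-in; DIC = %.1f (pD = %.1f)\n",
              x$n_samples, x$burn_in, x$dic, x$pd))
  cat(sprintf("  converged (all MC-error ratios < 0.10): %s\n", x$converged))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_hierarchical_ddm
#' @param x An `hddm_fit` object.
#' @param ... Unused.
#' @export
tidy.hddm_fit <- function(x, ...) {
  cols <- setdiff(colnames(x$chains), "deviance")
  purrr::map_dfr(cols, function(p) {
    s <- x$chains[[p]]
    tibble(term = p, estimate = mean(s), std_error = sd(s),
           ci_low = unname(quantile(s, 0.025)),
           ci_high = unname(quantile(s, 0.975)))
  })
}

#' @rdname fit_hierarchical_ddm
#' @export
glance.hddm_fit <- function(x, ...) {
  tibble(
    dic = x$dic, pd = x$pd, mean_deviance = x$mean_deviance,
    converged = x$converged, n_subjects = nrow(x$subject_summary),
    n_samples = x$n_samples, burn_in = x$burn_in
  )
}
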