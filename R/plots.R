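#' Plot a fitted psychometric function
#'
#' Fitted Weibull curve over the stimulus range with the observed
#' proportion correct in stimulus-level bins (point size = trials per
#' bin) and the 75%-correct threshold marked.
#'
#' @param object A `weibull_fit`.
#' @param n_bins Number of stimulus bins for the empirical points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.weibull_fit <- function(object, n_bins = 8, ...) {
  xmax <- max(object$max_obstruction, max(object$data$stimulus_level))
  curve <- tibble(
    x = seq(0, xmax, length.out = 200),
    p = weibull_p_correct(seq(0, xmax, length.out = 200), object$alpha,
                          object$beta, object$guess, object$lapse)
  )
  pts <- object$data |>
    dplyr::mutate(bin = cut(.data$stimulus_level, n_bins)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(x = mean(.data$stimulus_level),
                     p = mean(.data$correct), n = dplyr::n(),
                     .groups = "drop")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$p)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(data = pts, ggplot2::aes(size = .data$n),
                        alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$threshold75, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0.75, linetype = 3) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "obstruction level", y = "P(correct)",
                  size = "trials",
                  title = sprintf("Weibull fit: threshold = %.2f, slope = %.2f",
                                  object$threshold75, object$beta)) +
    ggplot2::theme_minimal()
}

#' Plot a type-II ROC curve
#'
#' @param object A `metacog_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metacog_result <- function(object, ...) {
  ggplot2::ggplot(object$roc_points,
                  ggplot2::aes(x = .data$fa, y = .data$hit)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "type-II false-alarm rate", y = "type-II hit rate",
      title = if (object$defined)
        sprintf("type-II ROC, AUROC2 = %.3f", object$auroc2)
      else "type-II ROC (undefined)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a psi-staircase posterior
#'
#' Heatmap of the joint (threshold, slope) posterior with the stimulus
#' track overlaid on the margin.
#'
#' @param object A `psi_staircase`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psi_staircase <- function(object, ...) {
  df <- tibble(alpha = object$nodes$alpha, beta = object$nodes$beta,
               mass = object$posterior)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$beta,
                                   fill = .data$mass)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "threshold (alpha)", y = "slope (beta)",
                  fill = "posterior",
                  title = sprintf("psi posterior after %d trials",
                                  length(object$history$stimulus_level))) +
    ggplot2::theme_minimal()
}

#' Plot group-level drift-diffusion posteriors
#'
#' Posterior densities of the group-level means of every group-varying
#' parameter.
#'
#' @param object An `hddm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hddm_fit <- function(object, ...) {
  cols <- grep("^mu_[vat]_", colnames(object$chains), value = TRUE)
  if (length(cols) == 0) cols <- grep("^mu_", colnames(object$chains),
                                      value = TRUE)
  long <- object$chains |>
    dplyr::select(dplyr::all_of(cols)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "parameter",
                        values_to = "draw") |>
    tidyr::separate(.data$parameter, into = c("mu", "param", "group"),
                    sep = "_", fill = "right") |>
    dplyr::mutate(group = .data$group %||% "all")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$draw, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::facet_wrap(~ .data$param, scales = "free") +
    ggplot2::labs(x = "posterior draw", y = "density",
                  title = "group-level DDM posteriors") +
    ggplot2::theme_minimal()
}

#' Group comparison panel for a fitted cohort
#'
#' Box/jitter panels of sensitivity, slope (log scale), metascore and mean
#' RT per group from a subject summary table.
#'
#' @param subject_summary A [fit_subjects()] / [run_analysis()] subject
#'   table.
#' @return A ggplot object.
#' @export
plot_group_measures <- function(subject_summary) {
  long <- subject_summary |>
    dplyr::transmute(.data$group, sensitivity = .data$sensitivity,
                     log_slope = log(.data$slope),
                     metascore = .data$metascore, mean_rt = .data$mean_rt) |>
    tidyr::pivot_longer(-"group", names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(~ .data$measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
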