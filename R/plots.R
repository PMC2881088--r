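#' @describeIn significance_connectivity_diagnostic scatter of marginal Cox
#'   coefficient against intramodular connectivity with a linear fit and a
#'   loess smooth.
#' @param object The object to plot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.sig_conn_diagnostic <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$intramodular_connectivity,
                               y = .data$marginal_coefficient)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$module)),
                        alpha = 0.6, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "blue", linewidth = 0.6) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.6) +
    ggplot2::labs(x = "Intramodular connectivity",
                  y = "Marginal Cox coefficient",
                  colour = "Module",
                  title = sprintf("Marginal significance vs connectivity (r = %.3f)",
                                  object$correlation)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_path coefficient trajectories of the selected genes along
#'   the checkpointed iteration path.
#' @param object A `tgdr_fit`.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.tgdr_fit <- function(object, ...) {
  sel <- which(object$beta != 0)
  if (length(sel) == 0L) sel <- seq_len(min(5L, length(object$beta)))
  path <- object$path$beta[sel, , drop = FALSE]
  df <- tibble::tibble(
    gene = rep(names(object$beta)[sel], times = ncol(path)),
    k = rep(object$path$k, each = length(sel)),
    beta = as.vector(path)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$beta,
                                   group = .data$gene, colour = .data$gene)) +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::guides(colour = if (length(sel) > 15L) "none" else "legend") +
    ggplot2::labs(x = "Iteration k", y = "Coefficient",
                  title = sprintf("%s path (tau1 = %g, tau2 = %g)",
                                  object$method, object$tau1, object$tau2)) +
    ggplot2::theme_minimal()
}

#' @describeIn loo_predictive_evaluation Kaplan-Meier curves of the
#'   median-dichotomized predicted risk groups.
#' @param object An `evaluation_report`.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.evaluation_report <- function(object, ...) {
  sf <- survival::survfit(survival::Surv(object$time, object$status) ~
                            object$risk_group)
  groups <- sub("^object\\$risk_group=", "", rep(names(sf$strata), sf$strata))
  df <- tibble::tibble(time = sf$time, surv = sf$surv, group = groups)
  # step-function anchors at time zero
  df0 <- tibble::tibble(time = 0, surv = 1, group = unique(groups))
  ggplot2::ggplot(dplyr::bind_rows(df0, df),
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = "Risk group",
                  title = sprintf("Predicted risk groups (logrank = %.2f, p = %.3g)",
                                  object$logrank_statistic, object$logrank_pvalue)) +
    ggplot2::theme_minimal()
}

#' Scale-free topology fit across candidate powers
#'
#' Plots the log-log linearity (R squared) of the connectivity distribution
#' for each candidate soft power, the criterion behind [pick_soft_power()].
#'
#' @param S Similarity matrix from [pearson_similarity()].
#' @param candidates Candidate powers.
#' @param r2_target Target shown as a horizontal reference line.
#' @return A ggplot object.
#' @export
plot_scale_free_fit <- function(S, candidates = 1:10, r2_target = 0.8) {
  b <- pick_soft_power(S, candidates, r2_target = r2_target)
  tab <- attr(b, "fit_table")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$power, y = .data$r_squared)) +
    ggplot2::geom_hline(yintercept = r2_target, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Soft power b", y = expression(R^2),
                  title = "Scale-free topology criterion") +
    ggplot2::theme_minimal()
}
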