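#' Two-sample logrank statistic
#'
#' The standard chi-square form: at each distinct event time the observed
#' deaths in group 1 are compared with their hypergeometric expectation given
#' the risk-set sizes, and (O - E)^2 / V is referred to a chi-square
#' distribution with 1 degree of freedom. Under the null of identical
#' survival in the two groups the statistic is approximately chi-square(1).
#'
#' @param time,status Survival outcome vectors.
#' @param group Binary group membership (two nonempty levels).
#' @return List with `statistic` and `p_value`.
#' @export
logrank_statistic <- function(time, status, group) {
  stopifnot(length(time) == length(status), length(time) == length(group))
  lev <- unique(group)
  if (length(lev) != 2L) stop("exactly two nonempty groups are required", call. = FALSE)
  if (sum(status) < 1L) stop("at least one event required", call. = FALSE)
  g1 <- group == lev[1L]
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[status == 1]))) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & g1)
    d_t <- sum(time == t & status == 1)
    d1_t <- sum(time == t & status == 1 & g1)
    O <- O + d1_t
    E <- E + d_t * n1_t / n_t
    if (n_t > 1L) {
      V <- V + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

# split scores at their median: scores above go to the high-risk group,
# scores at or below (incl. ties at the median, stable order) to low-risk
median_risk_groups <- function(scores) {
  if (diff(range(scores)) == 0) {
    stop("degenerate predictive scores (all equal); cannot form risk groups",
         call. = FALSE)
  }
  ifelse(scores > median(scores), "high", "low")
}

# one leave-one-out pass shared by the predictive evaluation and the
# occurrence index: refit (with inner CV tuning) on each n-1 subset
loo_refit_all <- function(design, conn, grid, K_max, cv_folds, seed, dnu,
                          stride, restrict_f2, method = "network",
                          progress = FALSE) {
  n <- nrow(design$X)
  d <- ncol(design$X)
  if (n < 20L) stop("leave-one-out evaluation needs at least 20 subjects", call. = FALSE)
  scores <- numeric(n)
  selected <- matrix(FALSE, d, n, dimnames = list(design$gene_ids, design$sample_ids))
  tunings <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    sub <- new_cox_design(design$X[keep, , drop = FALSE], design$time[keep],
                          design$status[keep], design$gene_ids,
                          design$sample_ids[keep])
    # deterministic per-subject reseeding of the inner CV folds
    fit <- select_markers(sub, conn, grid = grid, method = method,
                          K_max = K_max, cv_folds = cv_folds,
                          seed = seed + i, dnu = dnu, stride = stride,
                          restrict_f2 = restrict_f2)
    scores[i] <- drop(design$X[i, , drop = FALSE] %*% fit$beta)
    selected[, i] <- fit$beta != 0
    tunings[[i]] <- glance(fit)
    if (progress) message("leave-one-out refit ", i, "/", n, " done")
  }
  list(scores = scores, selected = selected,
       tunings = dplyr::bind_rows(tunings))
}

#' Leave-one-out predictive evaluation
#'
#' The prediction protocol: each subject is held out in turn, the selection
#' procedure (inner cross-validated tuning plus regularized fit) is rerun on
#' the remaining n - 1 subjects, and the held-out subject receives the risk
#' score beta' X_i. The n scores are dichotomized at their median into
#' low/high risk groups and the group survival difference is measured by the
#' logrank statistic; under the null of no predictive power it is
#' chi-square(1) distributed. Per-gene occurrence indexes (fraction of the n
#' refits selecting the gene) are returned from the same refits.
#'
#' @inheritParams cross_validate
#' @param method `"network"` or `"tgdr"` (see [select_markers()]).
#' @param progress Emit a message per refit.
#' @return An `evaluation_report`: per-sample scores and risk groups, the
#'   logrank statistic and p-value, per-gene occurrence indexes, and the
#'   tunings chosen inside each refit.
#' @export
loo_predictive_evaluation <- function(design, conn, grid = default_tuning_grid(),
                                      K_max = 2000L, cv_folds = 5L, seed = 1L,
                                      dnu = 1e-3, stride = 20L,
                                      restrict_f2 = FALSE,
                                      method = c("network", "tgdr"),
                                      progress = FALSE) {
  method <- match.arg(method)
  ref <- loo_refit_all(design, conn, grid, K_max, cv_folds, seed, dnu,
                       stride, restrict_f2, method, progress)
  group <- median_risk_groups(ref$scores)
  lr <- logrank_statistic(design$time, design$status, group)
  structure(
    list(sample_ids = design$sample_ids,
         predictive_scores = ref$scores,
         risk_group = group,
         time = design$time, status = design$status,
         logrank_statistic = lr$statistic,
         logrank_pvalue = lr$p_value,
         occurrence_index = rowMeans(ref$selected),
         selected = ref$selected,
         tunings = ref$tunings,
         method = method),
    class = "evaluation_report"
  )
}

#' Per-gene occurrence index
#'
#' Reproducibility of each gene's selection: the gene selection procedure is
#' rerun on every leave-one-out subset and, for each gene, the fraction c/n
#' of the n refits in which it is selected is reported. Reliably identified
#' markers have occurrence indexes near 1.
#'
#' @inheritParams loo_predictive_evaluation
#' @param report Optionally, an existing `evaluation_report` from
#'   [loo_predictive_evaluation()] whose refits are reused.
#' @return Named per-gene vector of values in {0, 1/n, ..., 1}.
#' @export
occurrence_index <- function(design, conn, grid = default_tuning_grid(),
                             K_max = 2000L, cv_folds = 5L, seed = 1L,
                             dnu = 1e-3, stride = 20L, restrict_f2 = FALSE,
                             method = c("network", "tgdr"), report = NULL,
                             progress = FALSE) {
  if (!is.null(report)) {
    stopifnot(inherits(report, "evaluation_report"))
    return(report$occurrence_index)
  }
  method <- match.arg(method)
  ref <- loo_refit_all(design, conn, grid, K_max, cv_folds, seed, dnu,
                       stride, restrict_f2, method, progress)
  rowMeans(ref$selected)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Leave-one-out predictive evaluation (", x$method, ")\n",
      "  n = ", length(x$predictive_scores), ", events = ", sum(x$status), "\n",
      "  logrank statistic = ", format(x$logrank_statistic, digits = 4),
      " (p = ", format(x$logrank_pvalue, digits = 3), ")\n",
      "  genes with occurrence index >= 0.5: ",
      sum(x$occurrence_index >= 0.5), "\n", sep = "")
  invisible(x)
}

#' @describeIn loo_predictive_evaluation per-sample tibble (`type =
#'   "scores"`) or per-gene occurrence tibble (`type = "occurrence"`).
#' @param x An `evaluation_report`.
#' @param type Which table to return.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.evaluation_report <- function(x, type = c("scores", "occurrence"), ...) {
  type <- match.arg(type)
  if (type == "scores") {
    tibble::tibble(sample = x$sample_ids, score = x$predictive_scores,
                   risk_group = x$risk_group, time = x$time, status = x$status)
  } else {
    tibble::tibble(gene = names(x$occurrence_index),
                   occurrence_index = unname(x$occurrence_index))
  }
}

#' @describeIn loo_predictive_evaluation one-row summary with the logrank
#'   statistic and p-value.
#' @exportS3Method generics::glance
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n = length(x$predictive_scores),
    n_events = sum(x$status),
    logrank_statistic = x$logrank_statistic,
    logrank_pvalue = x$logrank_pvalue,
    median_occurrence_selected = median(x$occurrence_index[x$occurrence_index > 0.5]),
    n_ever_selected = sum(x$occurrence_index > 0)
  )
}

#' Marginal significance versus intramodular connectivity
#'
#' The diagnostic relating each gene's marginal Cox coefficient (single-gene
#' model, see [marginal_coefficient()]) to its intramodular connectivity.
#' Across many expression studies these are positively correlated, which is
#' the empirical motivation for steering selection toward hub genes.
#'
#' @param expr Standardized genes x samples matrix.
#' @param surv Survival tibble.
#' @param network A `coexpression_network` built on the same genes.
#' @return A `sig_conn_diagnostic`: list with `correlation` (Pearson, between
#'   marginal coefficient and intramodular connectivity) and `table`, the
#'   per-gene pair tibble. [autoplot()] draws the scatter.
#' @export
significance_connectivity_diagnostic <- function(expr, surv, network) {
  stopifnot(inherits(network, "coexpression_network"))
  al <- align_samples(expr, surv)
  expr <- al$expr; surv <- al$surv
  if (!identical(rownames(expr), network$gene_ids)) {
    stop("network and expression matrix cover different genes", call. = FALSE)
  }
  coefs <- vapply(seq_len(nrow(expr)), function(g) {
    marginal_coefficient(expr[g, ], surv$time, surv$status)
  }, 0)
  kin <- unname(network$intramodular_connectivity)
  if (var(coefs) == 0 || var(kin) == 0) {
    stop("zero variance in marginal coefficients or connectivity; correlation undefined",
         call. = FALSE)
  }
  tab <- tibble::tibble(gene = rownames(expr),
                        marginal_coefficient = coefs,
                        intramodular_connectivity = kin,
                        module = as.integer(network$modules))
  structure(list(correlation = cor(coefs, kin), table = tab),
            class = "sig_conn_diagnostic")
}

#' @export
print.sig_conn_diagnostic <- function(x, ...) {
  cat("Marginal significance vs intramodular connectivity\n",
      "  genes: ", nrow(x$table), "\n",
      "  Pearson correlation: ", format(x$correlation, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' @describeIn significance_connectivity_diagnostic the per-gene pair table.
#' @param x A `sig_conn_diagnostic`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.sig_conn_diagnostic <- function(x, ...) x$table

#' Write the evaluation report tables as TSV plus a text summary
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named vector of written paths, invisibly.
#' @export
write_evaluation_report <- function(report, dir, prefix = "evaluation") {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    scores = file.path(dir, paste0(prefix, "_scores.tsv")),
    occurrence = file.path(dir, paste0(prefix, "_occurrence.tsv")),
    summary = file.path(dir, paste0(prefix, "_summary.txt"))
  )
  sc <- tidy(report, type = "scores")
  sc$score <- signif(sc$score, 6L)
  write.table(sc, paths["scores"], sep = "\t", quote = FALSE, row.names = FALSE)
  oc <- tidy(report, type = "occurrence")
  oc$occurrence_index <- signif(oc$occurrence_index, 6L)
  write.table(oc, paths["occurrence"], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(
    paste0("method: ", report$method),
    paste0("n: ", length(report$predictive_scores)),
    paste0("events: ", sum(report$status)),
    paste0("logrank_statistic: ", signif(report$logrank_statistic, 6L)),
    paste0("logrank_pvalue: ", signif(report$logrank_pvalue, 6L))
  ), paths["summary"])
  invisible(paths)
}
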