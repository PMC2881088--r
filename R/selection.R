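#' Gradient thresholding vector
#'
#' The first-level mask of the thresholded gradient update: component j is 1
#' when |g_j| >= tau1 * max_i |g_i| and 0 otherwise. tau1 = 0 keeps every
#' gene, tau1 = 1 keeps only the maximal-gradient gene(s). An all-zero
#' gradient yields an all-zero mask.
#'
#' @param g Gradient vector.
#' @param tau1 Threshold in \[0, 1\].
#' @return Binary (0/1) vector of the same length.
#' @export
gradient_threshold_vector <- function(g, tau1) {
  stopifnot(tau1 >= 0, tau1 <= 1, all(is.finite(g)))
  gmax <- max(abs(g))
  if (gmax == 0) return(numeric(length(g)))
  as.numeric(abs(g) >= tau1 * gmax)
}

#' Connectivity thresholding vector
#'
#' The second-level mask: component j is 1 when conn_j >= tau2 * max_i
#' conn_i. tau2 = 0 disables the connectivity level entirely (all ones),
#' recovering plain TGDR; tau2 = 1 keeps only the most connected gene(s).
#'
#' @param conn Nonnegative connectivity vector (typically intramodular
#'   connectivity from [build_network()]).
#' @param tau2 Threshold in \[0, 1\].
#' @return Binary (0/1) vector of the same length.
#' @export
connectivity_threshold_vector <- function(conn, tau2) {
  stopifnot(tau2 >= 0, tau2 <= 1, all(conn >= 0))
  if (tau2 == 0) return(rep(1, length(conn)))
  cmax <- max(conn)
  if (cmax == 0) {
    warning("all connectivities are zero; connectivity threshold selects nothing",
            call. = FALSE)
    return(numeric(length(conn)))
  }
  as.numeric(conn >= tau2 * cmax)
}

#' Rescale intramodular connectivity to \[0, 1\] within each module
#'
#' Optional preprocessing for the connectivity threshold: dividing by the
#' module maximum makes hub status comparable across modules of different
#' size and density.
#'
#' @param conn Intramodular connectivity vector.
#' @param modules Integer module labels aligned with `conn` (0 = unassigned).
#' @return Rescaled vector; unassigned genes keep 0.
#' @export
scale_connectivity_by_module <- function(conn, modules) {
  stopifnot(length(conn) == length(modules))
  out <- conn
  for (m in setdiff(unique(modules), 0L)) {
    idx <- modules == m
    mx <- max(conn[idx])
    if (mx > 0) out[idx] <- conn[idx] / mx
  }
  out
}

#' Fit the network-guided thresholded gradient path
#'
#' The core selection algorithm. Starting from beta = 0, each of `K`
#' iterations computes the Cox partial-likelihood gradient, masks it by the
#' gradient threshold (tau1, [gradient_threshold_vector()]) and the
#' connectivity threshold (tau2, [connectivity_threshold_vector()]), and
#' takes a step of size `dnu` along the masked gradient. Only genes passing
#' both thresholds are ever updated, so the final nonzero set is the selected
#' marker set. `tau2 = 0` is exactly plain TGDR (see [fit_tgdr()]).
#'
#' @param design A [cox_design()] with standardized expression.
#' @param conn Per-gene connectivity (intramodular connectivity from
#'   [build_network()]); ignored when `tau2 = 0`.
#' @param tau1,tau2 Thresholds in \[0, 1\].
#' @param K Number of iterations (tuned by [cross_validate()]).
#' @param dnu Step size increment (default 1e-3).
#' @param stride Checkpoint spacing for the recorded path (default 20).
#' @param restrict_f2 Take the connectivity maximum over the genes passing
#'   the gradient threshold instead of all genes (default FALSE).
#' @return A `tgdr_fit`: coefficients, selected genes, the checkpointed path
#'   and the final log partial likelihood. Use [tidy()] / [glance()].
#' @export
fit_path <- function(design, conn, tau1, tau2, K, dnu = 1e-3, stride = 20L,
                     restrict_f2 = FALSE) {
  stopifnot(inherits(design, "cox_design"))
  d <- ncol(design$X)
  if (length(conn) != d) stop("connectivity must have one value per gene", call. = FALSE)
  stopifnot(tau1 >= 0, tau1 <= 1, tau2 >= 0, tau2 <= 1, dnu > 0, K >= 0)
  res <- tgdr_path_engine(design$X, design$time, design$status,
                          as.numeric(conn), seq_len(nrow(design$X)) - 1L,
                          tau1, tau2, dnu, as.integer(K), as.integer(stride),
                          restrict_f2, TRUE, FALSE)
  beta <- setNames(res$beta, design$gene_ids)
  structure(
    list(beta = beta,
         selected = design$gene_ids[beta != 0],
         k_used = as.integer(K),
         tau1 = tau1, tau2 = tau2, dnu = dnu, stride = as.integer(stride),
         restrict_f2 = restrict_f2,
         conn = setNames(as.numeric(conn), design$gene_ids),
         path = list(k = res$k, beta = res$betas, loglik = res$loglik_train),
         loglik = res$loglik_train[length(res$loglik_train)],
         n_samples = nrow(design$X), n_events = sum(design$status),
         method = if (tau2 > 0) "network-tgdr" else "tgdr"),
    class = "tgdr_fit"
  )
}

#' Fit plain TGDR (threshold gradient descent regularization)
#'
#' The connectivity-free special case of [fit_path()]: the connectivity mask
#' is forced to all ones, so selection is driven by the gradient threshold
#' alone and every gene is treated as exchangeable.
#'
#' @inheritParams fit_path
#' @return A `tgdr_fit`.
#' @export
fit_tgdr <- function(design, tau1, K, dnu = 1e-3, stride = 20L) {
  fit_path(design, conn = numeric(ncol(design$X)), tau1 = tau1, tau2 = 0,
           K = K, dnu = dnu, stride = stride)
}

#' @export
print.tgdr_fit <- function(x, ...) {
  cat(if (x$method == "network-tgdr") "Network-guided TGDR fit" else "TGDR fit",
      "\n  tau1 = ", x$tau1, ", tau2 = ", x$tau2, ", K = ", x$k_used,
      ", dnu = ", x$dnu,
      "\n  selected genes: ", length(x$selected), " of ", length(x$beta),
      "\n  log partial likelihood: ", format(x$loglik, digits = 6), "\n",
      sep = "")
  invisible(x)
}

#' @describeIn fit_path per-gene tibble (gene, beta, selected, connectivity).
#' @param x A `tgdr_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.tgdr_fit <- function(x, ...) {
  tibble::tibble(
    gene = names(x$beta),
    beta = unname(x$beta),
    selected = unname(x$beta != 0),
    connectivity = unname(x$conn)
  )
}

#' @describeIn fit_path one-row fit summary.
#' @exportS3Method generics::glance
#' @export
glance.tgdr_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, tau1 = x$tau1, tau2 = x$tau2, k = x$k_used,
    dnu = x$dnu, n_selected = length(x$selected),
    loglik = x$loglik, n_samples = x$n_samples, n_events = x$n_events
  )
}

#' Write the fit table (gene, beta, selected, connectivity context) as TSV
#' @param fit A `tgdr_fit`.
#' @param path Output path.
#' @param network Optional `coexpression_network` for module /
#'   whole-network-connectivity columns.
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(fit, path, network = NULL) {
  tab <- tidy(fit)
  if (!is.null(network)) {
    tab <- dplyr::left_join(tab, tidy(network), by = "gene",
                            suffix = c("", "_network"))
  }
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], signif, digits = 6L)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default tuning grid for the two thresholds
#' @param tau1,tau2 Candidate values for each threshold.
#' @return Tibble with columns `tau1`, `tau2` (all combinations).
#' @export
default_tuning_grid <- function(tau1 = c(0, 0.25, 0.5, 0.75, 0.9, 1),
                                tau2 = c(0, 0.25, 0.5, 0.75, 0.9, 1)) {
  tidyr_expand <- expand.grid(tau2 = tau2, tau1 = tau1)  # tau1 varies slowest
  tibble::tibble(tau1 = tidyr_expand$tau1, tau2 = tidyr_expand$tau2)
}

# stratified fold assignment: within each event-status stratum samples are
# shuffled and dealt round-robin, so every fold sees events
make_folds <- function(status, cv_folds, seed) {
  n <- length(status)
  folds <- integer(n)
  with_seed(seed, {
    for (s in unique(status)) {
      idx <- which(status == s)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(cv_folds), length(idx))
    }
  })
  folds
}

#' Cross-validated tuning of the thresholds and iteration count
#'
#' V-fold cross-validation over a (tau1, tau2) grid with K evaluated on a
#' stride grid up to `K_max`. The score is the cross-validated partial
#' likelihood in the Verweij-van Houwelingen form,
#' CV(k, tau1, tau2) = sum over folds of \[ R_all(beta_(-f)) -
#' R_(-f)(beta_(-f)) \], i.e. the part of the full-data likelihood earned by
#' the held-out subjects. Folds are stratified by event status. Score ties
#' prefer the sparser model: larger tau1, then larger tau2, then smaller K.
#'
#' @inheritParams fit_path
#' @param grid Tibble/data frame with columns `tau1`, `tau2`
#'   (default [default_tuning_grid()]).
#' @param K_max Largest iteration count considered (default 2000).
#' @param cv_folds Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @return A `selection_config`: list with the chosen `tau1`, `tau2`, `K`,
#'   the winning `cv_score`, and `cv_table`, a tibble of every
#'   (tau1, tau2, k, score) evaluated.
#' @export
cross_validate <- function(design, conn, grid = default_tuning_grid(),
                           K_max = 2000L, cv_folds = 5L, seed = 1L,
                           dnu = 1e-3, stride = 20L, restrict_f2 = FALSE) {
  stopifnot(inherits(design, "cox_design"), cv_folds >= 2L)
  grid <- tibble::as_tibble(grid)
  stopifnot(all(c("tau1", "tau2") %in% names(grid)), nrow(grid) >= 1L)
  n <- nrow(design$X)
  folds <- make_folds(design$status, cv_folds, seed)
  for (f in seq_len(cv_folds)) {
    if (sum(design$status[folds != f]) < 1L) {
      stop("training fold ", f, " has no events; use fewer folds", call. = FALSE)
    }
  }
  pieces <- vector("list", nrow(grid))
  for (gidx in seq_len(nrow(grid))) {
    t1 <- grid$tau1[gidx]; t2 <- grid$tau2[gidx]
    score <- NULL; ks <- NULL
    for (f in seq_len(cv_folds)) {
      train <- which(folds != f) - 1L
      res <- tgdr_path_engine(design$X, design$time, design$status,
                              as.numeric(conn), train, t1, t2, dnu,
                              as.integer(K_max), as.integer(stride),
                              restrict_f2, FALSE, TRUE)
      contrib <- res$loglik_full - res$loglik_train
      score <- if (is.null(score)) contrib else score + contrib
      ks <- res$k
    }
    pieces[[gidx]] <- tibble::tibble(tau1 = t1, tau2 = t2, k = ks, score = score)
  }
  cv_table <- dplyr::bind_rows(pieces)
  ord <- order(-cv_table$score, -cv_table$tau1, -cv_table$tau2, cv_table$k)
  best <- cv_table[ord[1L], ]
  structure(
    list(tau1 = best$tau1, tau2 = best$tau2, K = as.integer(best$k),
         cv_score = best$score, cv_table = cv_table,
         cv_folds = as.integer(cv_folds), seed = as.integer(seed),
         dnu = dnu, stride = as.integer(stride), K_max = as.integer(K_max),
         restrict_f2 = restrict_f2),
    class = "selection_config"
  )
}

#' @export
print.selection_config <- function(x, ...) {
  cat("Cross-validated tuning (", x$cv_folds, "-fold, seed ", x$seed, ")\n",
      "  tau1 = ", x$tau1, ", tau2 = ", x$tau2, ", K = ", x$K,
      " (CV score ", format(x$cv_score, digits = 6), ")\n", sep = "")
  invisible(x)
}

#' Tune and fit in one call
#'
#' Convenience wrapper: [cross_validate()] followed by a final [fit_path()]
#' at the chosen tuning on the full data. `method = "tgdr"` restricts the
#' grid to tau2 = 0 (plain TGDR).
#'
#' @inheritParams cross_validate
#' @param method `"network"` (dual thresholds) or `"tgdr"`.
#' @return A `tgdr_fit` with the `selection_config` attached as `$tuning`.
#' @export
select_markers <- function(design, conn, grid = default_tuning_grid(),
                           method = c("network", "tgdr"), K_max = 2000L,
                           cv_folds = 5L, seed = 1L, dnu = 1e-3, stride = 20L,
                           restrict_f2 = FALSE) {
  method <- match.arg(method)
  grid <- tibble::as_tibble(grid)
  if (method == "tgdr") {
    grid <- dplyr::distinct(dplyr::mutate(grid, tau2 = 0))
  }
  cfg <- cross_validate(design, conn, grid = grid, K_max = K_max,
                        cv_folds = cv_folds, seed = seed, dnu = dnu,
                        stride = stride, restrict_f2 = restrict_f2)
  fit <- fit_path(design, conn, tau1 = cfg$tau1, tau2 = cfg$tau2, K = cfg$K,
                  dnu = dnu, stride = stride, restrict_f2 = restrict_f2)
  fit$tuning <- cfg
  fit
}
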