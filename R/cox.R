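#' Assemble a Cox design from expression and survival data
#'
#' Pairs a (standardized) genes x samples expression matrix with survival
#' outcomes, precomputing the time ordering and risk-set structure used by
#' the partial likelihood. Risk sets are r_i = {k : Y_k >= Y_i}, so subjects
#' censored exactly at an event time remain at risk for that event; ties are
#' handled by the Breslow convention throughout.
#'
#' @param expr Genes x samples matrix.
#' @param surv Survival tibble (`sample`, `time`, `status`); matched to the
#'   expression columns by sample id.
#' @return A `cox_design`: list with `X` (samples x genes), `time`, `status`,
#'   `gene_ids`, `sample_ids`.
#' @export
cox_design <- function(expr, surv) {
  al <- align_samples(expr, surv)
  if (sum(al$surv$status) < 1) stop("at least one observed event is required", call. = FALSE)
  structure(
    list(X = t(al$expr), time = al$surv$time, status = as.integer(al$surv$status),
         gene_ids = rownames(al$expr), sample_ids = al$surv$sample),
    class = "cox_design"
  )
}

# design straight from vectors, for internal reuse (e.g. CV folds)
new_cox_design <- function(X, time, status, gene_ids = colnames(X),
                           sample_ids = rownames(X)) {
  structure(list(X = X, time = time, status = as.integer(status),
                 gene_ids = gene_ids, sample_ids = sample_ids),
            class = "cox_design")
}

#' @export
print.cox_design <- function(x, ...) {
  cat("Cox design: ", length(x$time), " samples x ", ncol(x$X), " genes, ",
      sum(x$status), " events\n", sep = "")
  invisible(x)
}

# risk-set sums S0_i = sum_{k: Y_k >= Y_i} w_k for every subject i, with
# w = exp(eta - max(eta)); returns list(S0, shift) on the original order
risk_set_sums <- function(eta, time) {
  shift <- max(eta)
  w <- exp(eta - shift)
  ord <- order(time, decreasing = TRUE)
  # cumulative sums down the sorted order, with tie blocks flushed together
  ts <- time[ord]
  cs <- cumsum(w[ord])
  # position of the last index sharing each sorted time
  last <- cummax_rev(ts)
  S0_sorted <- cs[last]
  S0 <- numeric(length(eta))
  S0[ord] <- S0_sorted
  list(S0 = S0, shift = shift, w = w)
}

# for a descending-sorted time vector, index of the last entry tied with each
cummax_rev <- function(ts) {
  n <- length(ts)
  idx <- seq_len(n)
  # entries tied with a later (smaller index? no: later position) equal time
  # share the furthest position with that time
  last <- idx
  if (n >= 2L) {
    for (i in (n - 1L):1L) if (ts[i] == ts[i + 1L]) last[i] <- last[i + 1L]
  }
  last
}

#' Cox log-partial likelihood
#'
#' R_n(beta) = sum over events i of \[ beta'X_i - log sum_{k in r_i}
#' exp(beta'X_k) \], with Breslow handling of tied event times and
#' log-sum-exp stabilization of every risk-set sum.
#'
#' @param beta Coefficient vector, one per gene.
#' @param design A [cox_design()].
#' @return The scalar log-partial likelihood (0 when there are no events).
#' @export
cox_loglik <- function(beta, design) {
  stopifnot(inherits(design, "cox_design"), length(beta) == ncol(design$X))
  if (sum(design$status) == 0L) return(0)
  eta <- drop(design$X %*% beta)
  rs <- risk_set_sums(eta, design$time)
  ev <- design$status == 1L
  sum(eta[ev] - (log(rs$S0[ev]) + rs$shift))
}

#' Gradient of the Cox log-partial likelihood
#'
#' g_j = sum over events i of \[ X_ij - (sum_{k in r_i} X_kj e^{beta'X_k}) /
#' (sum_{k in r_i} e^{beta'X_k}) \]: each event contributes the difference
#' between the subject's expression and the risk-set weighted mean.
#'
#' @inheritParams cox_loglik
#' @return Gradient vector, one component per gene.
#' @export
cox_gradient <- function(beta, design) {
  stopifnot(inherits(design, "cox_design"), length(beta) == ncol(design$X))
  d <- ncol(design$X)
  if (sum(design$status) == 0L) return(numeric(d))
  X <- design$X
  eta <- drop(X %*% beta)
  rs <- risk_set_sums(eta, design$time)
  ord <- order(design$time, decreasing = TRUE)
  last <- cummax_rev(design$time[ord])
  # S1_i (vector per gene): cumulative sums of w_k X_k down the sorted order
  WX <- X[ord, , drop = FALSE] * rs$w[ord]
  S1_sorted <- apply(WX, 2L, cumsum)[last, , drop = FALSE]
  S1 <- matrix(0, nrow(X), d)
  S1[ord, ] <- S1_sorted
  ev <- design$status == 1L
  colSums(X[ev, , drop = FALSE] - S1[ev, , drop = FALSE] / rs$S0[ev])
}

#' Marginal Cox regression coefficient of a single gene
#'
#' Fits the one-covariate Cox model by Newton-Raphson on the partial
#' likelihood (Breslow ties), the "marginal gene significance" used in the
#' significance-versus-connectivity diagnostic. Under monotone likelihood
#' (perfect risk separation) the estimate diverges; it is capped at
#' `cap` with a warning.
#'
#' @param x Expression of one gene across samples.
#' @param time,status Survival outcome vectors.
#' @param tol Convergence tolerance on the Newton step (default 1e-8).
#' @param max_iter Iteration cap (default 50).
#' @param cap Absolute bound on the estimate (default 20).
#' @return The estimated coefficient (scalar).
#' @export
marginal_coefficient <- function(x, time, status, tol = 1e-8, max_iter = 50L,
                                 cap = 20) {
  stopifnot(length(x) == length(time), length(time) == length(status))
  if (var(x) == 0) stop("gene has zero variance; marginal coefficient undefined", call. = FALSE)
  if (sum(status) < 1) stop("at least one event required", call. = FALSE)
  design <- new_cox_design(matrix(x, ncol = 1L), time, status,
                           gene_ids = "g", sample_ids = as.character(seq_along(x)))
  beta <- 0
  for (it in seq_len(max_iter)) {
    g <- cox_gradient(beta, design)
    h <- cox_hessian_1d(beta, design)
    if (h >= -1e-12) {
      # flat likelihood with a live gradient: monotone in beta (separation)
      if (abs(g) > 1e-3) {
        warning("monotone partial likelihood; estimate capped at ",
                sign(g) * cap, call. = FALSE)
        return(sign(g) * cap)
      }
      break
    }
    step <- -g / h
    # damp absurd steps from near-flat curvature
    if (abs(step) > 5) step <- sign(step) * 5
    beta <- beta + step
    if (abs(beta) > cap) {
      warning("monotone partial likelihood; estimate capped at ", sign(beta) * cap,
              call. = FALSE)
      return(sign(beta) * cap)
    }
    if (abs(step) < tol) break
  }
  unname(beta)
}

# second derivative of the 1-covariate log-partial likelihood
cox_hessian_1d <- function(beta, design) {
  X <- design$X
  eta <- drop(X %*% beta)
  rs <- risk_set_sums(eta, design$time)
  ord <- order(design$time, decreasing = TRUE)
  last <- cummax_rev(design$time[ord])
  x <- drop(X)
  wx <- (x * rs$w)[ord]
  wxx <- (x^2 * rs$w)[ord]
  S1 <- cumsum(wx)[last]; S2 <- cumsum(wxx)[last]
  n <- length(x)
  S1f <- numeric(n); S2f <- numeric(n)
  S1f[ord] <- S1; S2f[ord] <- S2
  ev <- design$status == 1L
  -sum(S2f[ev] / rs$S0[ev] - (S1f[ev] / rs$S0[ev])^2)
}
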