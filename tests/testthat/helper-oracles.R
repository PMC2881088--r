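# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own vectorized/compiled code
# paths: plain loops and closed forms only.

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# O(d^3) topological overlap dissimilarity by explicit triple loop
tom_brute <- function(A) {
  diag(A) <- 0
  d <- nrow(A)
  C <- sapply(seq_len(d), function(k) sum(A[k, -k]))
  D <- matrix(0, d, d)
  for (k in seq_len(d)) {
    for (j in seq_len(d)) {
      if (k == j) next
      l <- 0
      for (u in seq_len(d)) if (u != k && u != j) l <- l + A[k, u] * A[u, j]
      denom <- min(C[k], C[j]) + 1 - A[k, j]
      D[k, j] <- if (denom <= 0) 1 else 1 - (l + A[k, j]) / denom
    }
  }
  D
}

# Cox log partial likelihood by direct evaluation of the defining sum
loglik_brute <- function(beta, X, time, status) {
  eta <- as.vector(X %*% beta)
  ll <- 0
  for (i in seq_along(time)) {
    if (status[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + eta[i] - log(sum(exp(eta[risk])))
    }
  }
  ll
}

# single-covariate partial likelihood maximised by grid search
marginal_grid_oracle <- function(x, time, status, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  vals <- vapply(grid, function(b) loglik_brute(b, matrix(x, ncol = 1), time, status), 0)
  grid[which.max(vals)]
}

# two-sample logrank by the per-event-time O/E/V hand formula
logrank_brute <- function(time, status, group) {
  lev <- unique(group)
  g1 <- group == lev[1]
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[status == 1]))) {
    n_t <- sum(time >= t); n1 <- sum(time >= t & g1)
    d_t <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & g1)
    O <- O + d1; E <- E + d_t * n1 / n_t
    if (n_t > 1) V <- V + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
  }
  (O - E)^2 / V
}

# small reproducible survival dataset with controllable signal
toy_survival_data <- function(n = 40, d = 10, seed = 42, beta = NULL,
                              censor = 0.25) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  eta <- if (is.null(beta)) rep(0, n) else as.vector(X %*% beta)
  T_ev <- rexp(n, rate = exp(eta))
  C <- quantile(T_ev, 1 - censor) * runif(n, 0.5, 1.5)
  list(X = X, time = pmin(T_ev, C), status = as.integer(T_ev <= C))
}

# wrap a plain matrix + outcome vectors into the package's design object
design_from <- function(X, time, status) {
  genes <- paste0("g", seq_len(ncol(X)))
  samples <- paste0("s", seq_len(nrow(X)))
  dimnames(X) <- list(samples, genes)
  expr <- t(X)
  surv <- tibble::tibble(sample = samples, time = time, status = status)
  cox_design(expr, surv)
}
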