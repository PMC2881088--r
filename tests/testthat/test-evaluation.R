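test_that("logrank statistic matches hand formula, survdiff, and its invariances", {
  # single death time, two per group: explicit O - E and variance
  time <- c(1, 2, 2, 3); status <- c(1L, 0L, 0L, 0L)
  group <- c("a", "a", "b", "b")
  lr <- logrank_statistic(time, status, group)
  # at t = 1: n = 4, n1 = 2, d = 1, d1 = 1 -> E = 0.5, V = 1*(1/2)*(1/2)*(3/3)
  expect_equal(lr$statistic, (1 - 0.5)^2 / 0.25, tolerance = 1e-12)
  expect_equal(lr$p_value, pchisq(1, 1, lower.tail = FALSE))

  # identical multisets interleaved across groups: statistic 0
  t2 <- rep(c(1, 2, 3, 4), each = 2); s2 <- rep(c(1L, 0L, 1L, 1L), each = 2)
  g2 <- rep(c("a", "b"), 4)
  expect_equal(logrank_statistic(t2, s2, g2)$statistic, 0, tolerance = 1e-12)

  # general data: agrees with survdiff and the brute-force oracle
  set.seed(51)
  n <- 60
  tt <- rexp(n); ss <- rbinom(n, 1, 0.7); gg <- rbinom(n, 1, 0.5)
  if (length(unique(gg)) == 1) gg[1] <- 1 - gg[1]
  mine <- logrank_statistic(tt, ss, gg)
  sd_fit <- survival::survdiff(survival::Surv(tt, ss) ~ gg)
  expect_equal(mine$statistic, unname(sd_fit$chisq), tolerance = 1e-8)
  expect_equal(mine$statistic, logrank_brute(tt, ss, gg), tolerance = 1e-10)

  # invariant under group relabeling
  expect_equal(logrank_statistic(tt, ss, 1 - gg)$statistic, mine$statistic,
               tolerance = 1e-12)

  expect_error(logrank_statistic(tt, ss, rep(1, n)), "two nonempty groups")
})

test_that("median dichotomization balances groups and respects monotone transforms", {
  set.seed(52)
  for (n in c(24, 25)) {
    scores <- rnorm(n)
    grp <- netcox:::median_risk_groups(scores)
    expect_equal(sort(as.vector(table(grp))), sort(c(floor(n / 2), ceiling(n / 2))))
    # strictly monotone transform leaves the split unchanged
    expect_identical(netcox:::median_risk_groups(exp(scores)), grp)
    tt <- rexp(n); ss <- rbinom(n, 1, 0.8); ss[1] <- 1L
    expect_equal(logrank_statistic(tt, ss, grp)$statistic,
                 logrank_statistic(tt, ss, netcox:::median_risk_groups(2 * scores + 1))$statistic,
                 tolerance = 1e-12)
  }
  expect_error(netcox:::median_risk_groups(rep(1, 10)), "degenerate")
})

loo_fixture <- function(seed = 53, n = 24L) {
  sc <- simulation_scenario(
    n_samples = n, module_sizes = c(15L, 15L), background_genes = 10L,
    hub_fraction = 0.2, within_module_cor = 0.6, hub_cor = 0.85,
    true_effects = c(M1_hub1 = 1, M1_hub2 = 1, M2_hub1 = -1),
    seed = seed)
  sim <- simulate_dataset(sc)
  expr <- standardize_expression(sim$expr)
  net <- build_network(expr, power = 6, min_module_size = 10L)
  list(design = cox_design(expr, sim$surv), net = net, sim = sim)
}

test_that("leave-one-out evaluation scores, dichotomizes, and indexes occurrences", {
  # deliberately small: n = 24, tiny grid, short paths (the full-scale
  # protocol is exercised by the acceptance suite)
  fx <- loo_fixture()
  grid <- tibble::tibble(tau1 = c(0.5, 0.5), tau2 = c(0, 0.75))
  rep <- loo_predictive_evaluation(fx$design, fx$net$intramodular_connectivity,
                                   grid = grid, K_max = 100, cv_folds = 3,
                                   seed = 7, stride = 20)
  n <- nrow(fx$design$X)
  expect_length(rep$predictive_scores, n)
  expect_equal(sort(as.vector(table(rep$risk_group))), c(n / 2, n / 2))
  expect_gte(rep$logrank_statistic, 0)
  expect_true(rep$logrank_pvalue > 0 && rep$logrank_pvalue <= 1)

  # score definitional check: held-out score = refit coefficients . expression
  i <- 1L
  keep <- setdiff(seq_len(n), i)
  sub <- netcox:::new_cox_design(fx$design$X[keep, , drop = FALSE],
                                 fx$design$time[keep], fx$design$status[keep],
                                 fx$design$gene_ids, fx$design$sample_ids[keep])
  refit <- select_markers(sub, fx$net$intramodular_connectivity, grid = grid,
                          K_max = 100, cv_folds = 3, seed = 7 + i, stride = 20)
  expect_equal(rep$predictive_scores[i],
               drop(fx$design$X[i, ] %*% refit$beta), tolerance = 1e-12)

  # occurrence indexes live on the {0, 1/n, ..., 1} lattice and match the
  # recorded selections
  oc <- occurrence_index(report = rep)
  expect_true(all(oc >= 0 & oc <= 1))
  expect_true(all(abs(oc * n - round(oc * n)) < 1e-12))
  expect_equal(unname(oc), unname(rowMeans(rep$selected)))

  # writers emit the declared tables
  outdir <- tempfile()
  paths <- write_evaluation_report(rep, outdir)
  expect_true(all(file.exists(paths)))
  sc_tab <- read.delim(paths["scores"])
  expect_equal(nrow(sc_tab), n)
  expect_true(all(c("sample", "score", "risk_group") %in% names(sc_tab)))
})

test_that("strong planted signal yields high occurrence for the true genes", {
  fx <- loo_fixture(seed = 54, n = 26L)
  grid <- tibble::tibble(tau1 = 0.5, tau2 = 0.75)
  oc <- occurrence_index(fx$design, fx$net$intramodular_connectivity,
                         grid = grid, K_max = 200, cv_folds = 3, seed = 11)
  truth <- fx$sim$truth$gene[fx$sim$truth$beta_true != 0]
  nulls <- setdiff(names(oc), truth)
  expect_gte(median(oc[truth]), median(oc[nulls]))
  expect_gte(median(oc[truth]), 0.8)
})

test_that("significance-connectivity diagnostic computes the pair correlation", {
  fx <- loo_fixture(seed = 55, n = 40L)
  expr <- t(fx$design$X)
  surv <- tibble::tibble(sample = fx$design$sample_ids,
                         time = fx$design$time, status = fx$design$status)
  diag_res <- significance_connectivity_diagnostic(expr, surv, fx$net)
  tab <- tidy(diag_res)
  expect_equal(nrow(tab), nrow(expr))
  expect_equal(diag_res$correlation,
               cor(tab$marginal_coefficient, tab$intramodular_connectivity))
  expect_true(abs(diag_res$correlation) <= 1)

  # constant connectivity makes the correlation undefined
  fake_net <- fx$net
  fake_net$intramodular_connectivity[] <- 2
  expect_error(significance_connectivity_diagnostic(expr, surv, fake_net),
               "zero variance")
})
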