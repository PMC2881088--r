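test_that("thresholding vectors implement the relative-maximum rule", {
  g <- c(0.1, 0.5, 1.0)
  expect_equal(gradient_threshold_vector(g, 0.4), c(0, 1, 1))
  expect_equal(gradient_threshold_vector(g, 0), c(1, 1, 1))
  expect_equal(gradient_threshold_vector(g, 1), c(0, 0, 1))
  expect_equal(gradient_threshold_vector(c(-2, 2, 1), 1), c(1, 1, 0))  # |.| ties kept
  expect_equal(gradient_threshold_vector(rep(0, 4), 0.5), rep(0, 4))

  conn <- c(2, 5, 10)
  expect_equal(connectivity_threshold_vector(conn, 0.4), c(0, 1, 1))
  expect_equal(connectivity_threshold_vector(conn, 0), c(1, 1, 1))
  expect_equal(connectivity_threshold_vector(conn, 1), c(0, 0, 1))
  expect_warning(z <- connectivity_threshold_vector(rep(0, 3), 0.5), "zero")
  expect_equal(z, rep(0, 3))
})

test_that("connectivity rescaling normalizes within modules only", {
  conn <- c(4, 2, 10, 5, 0)
  modules <- c(1L, 1L, 2L, 2L, 0L)
  expect_equal(scale_connectivity_by_module(conn, modules), c(1, 0.5, 1, 0.5, 0))
})

make_fit_fixture <- function(seed = 41, n = 60, d = 30) {
  sc <- simulation_scenario(
    n_samples = n, module_sizes = c(15L, 15L), background_genes = d - 30L,
    hub_fraction = 0.2, within_module_cor = 0.6, hub_cor = 0.85,
    true_effects = c(M1_hub1 = 0.8, M1_hub2 = 0.8, M2_hub1 = -0.8),
    seed = seed)
  sim <- simulate_dataset(sc)
  expr <- standardize_expression(sim$expr)
  net <- build_network(expr, power = 6, min_module_size = 10L)
  list(design = cox_design(expr, sim$surv), net = net, sim = sim)
}

test_that("the path starts empty, increases the likelihood, and records checkpoints", {
  fx <- make_fit_fixture()
  conn <- fx$net$intramodular_connectivity

  f0 <- fit_path(fx$design, conn, tau1 = 0.5, tau2 = 0.5, K = 0)
  expect_equal(unname(f0$beta), rep(0, 30))
  expect_equal(length(f0$selected), 0L)

  fit <- fit_path(fx$design, conn, tau1 = 0.5, tau2 = 0.5, K = 300)
  # likelihood along the recorded path is nondecreasing and beats beta = 0
  ll <- fit$path$loglik
  expect_true(all(diff(ll) >= -1e-12))
  expect_gte(fit$loglik, cox_loglik(rep(0, 30), fx$design))
  # recorded likelihoods match independent re-evaluation of the stored betas
  ll_re <- apply(fit$path$beta, 2, cox_loglik, design = fx$design)
  expect_equal(ll, ll_re, tolerance = 1e-8)
  expect_equal(fit$path$k, seq(0, 300, by = 20))
  # selected set is exactly the nonzero support
  expect_setequal(fit$selected, names(fit$beta)[fit$beta != 0])
})

test_that("tau2 = 0 reproduces plain TGDR bit for bit", {
  fx <- make_fit_fixture(seed = 42)
  conn <- fx$net$intramodular_connectivity
  for (tau1 in c(0, 0.5, 1)) {
    a <- fit_path(fx$design, conn, tau1 = tau1, tau2 = 0, K = 200)
    b <- fit_tgdr(fx$design, tau1 = tau1, K = 200)
    expect_identical(a$beta, b$beta)
    expect_identical(a$path$beta, b$path$beta)
  }
})

test_that("unthresholded TGDR approaches the unpenalized partial-likelihood maximizer", {
  # tiny well-conditioned problem: tau1 = 0 gradient ascent must converge to
  # the same optimum as survival's Newton solver
  dat <- toy_survival_data(n = 100, d = 3, seed = 43, beta = c(0.6, -0.4, 0))
  design <- design_from(dat$X, dat$time, dat$status)
  fit <- fit_tgdr(design, tau1 = 0, K = 20000, stride = 2000)
  cph <- survival::coxph(survival::Surv(dat$time, dat$status) ~ dat$X,
                         ties = "breslow")
  expect_equal(unname(fit$beta), unname(coef(cph)), tolerance = 1e-2)
})

test_that("selection is monotone in the thresholds and in K", {
  fx <- make_fit_fixture(seed = 44)
  conn <- fx$net$intramodular_connectivity
  taus <- c(0, 0.25, 0.5, 0.75, 0.9, 1)
  K <- 200
  counts <- matrix(NA_integer_, length(taus), length(taus))
  for (i in seq_along(taus)) for (j in seq_along(taus)) {
    counts[i, j] <- length(fit_path(fx$design, conn, taus[i], taus[j], K)$selected)
  }
  expect_true(all(apply(counts, 2, diff) <= 0))  # tau1 up, selection down
  expect_true(all(apply(counts, 1, diff) <= 0))  # tau2 up, selection down
  # K up at fixed thresholds: nonzero support only grows along one path
  fit <- fit_path(fx$design, conn, 0.5, 0.5, K = 400)
  n_sel <- apply(fit$path$beta != 0, 2, sum)
  expect_true(all(diff(n_sel) >= 0))
})

test_that("cross-validation returns the only candidate, is deterministic, and stays sparse on noise", {
  fx <- make_fit_fixture(seed = 45)
  conn <- fx$net$intramodular_connectivity

  # single grid point, single evaluable k
  cfg1 <- cross_validate(fx$design, conn, grid = tibble::tibble(tau1 = 0.5, tau2 = 0.5),
                         K_max = 20, cv_folds = 3, seed = 9, stride = 20)
  expect_equal(cfg1$tau1, 0.5); expect_equal(cfg1$tau2, 0.5)
  expect_true(cfg1$K %in% c(0L, 20L))

  cfg2 <- cross_validate(fx$design, conn, grid = default_tuning_grid(
    tau1 = c(0.5, 0.9), tau2 = c(0, 0.5)), K_max = 100, cv_folds = 3, seed = 9)
  cfg3 <- cross_validate(fx$design, conn, grid = default_tuning_grid(
    tau1 = c(0.5, 0.9), tau2 = c(0, 0.5)), K_max = 100, cv_folds = 3, seed = 9)
  expect_identical(cfg2[c("tau1", "tau2", "K", "cv_score")],
                   cfg3[c("tau1", "tau2", "K", "cv_score")])

  # pure noise (no survival signal): CV-selected models stay sparse on
  # average (5-fold CV as in the full protocol; d scaled down for speed)
  sel_frac <- vapply(1:10, function(s) {
    sc <- simulation_scenario(n_samples = 100L, module_sizes = c(40L, 40L),
                              background_genes = 40L, seed = 400L + s)
    sim <- simulate_dataset(sc)
    expr <- standardize_expression(sim$expr)
    net <- build_network(expr, power = 6, min_module_size = 10L)
    des <- cox_design(expr, sim$surv)
    fit <- select_markers(des, net$intramodular_connectivity,
                          grid = default_tuning_grid(tau1 = c(0, 0.5, 0.9),
                                                     tau2 = c(0, 0.5, 0.9)),
                          K_max = 600, cv_folds = 5, seed = s)
    length(fit$selected) / length(fit$beta)
  }, 0)
  expect_lte(mean(sel_frac), 0.05)
})

test_that("the connectivity threshold steers selection toward hubs", {
  # two genes with comparable marginal association but different intramodular
  # connectivity: a hub and an isolated background twin carrying the same
  # true effect
  hub_rate <- 0; bg_rate <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    sc <- simulation_scenario(
      n_samples = 80L, module_sizes = 40L, background_genes = 40L,
      hub_fraction = 0.05, within_module_cor = 0.5, hub_cor = 0.8,
      true_effects = c(M1_hub1 = 0.7, BG_g1 = 0.7), seed = 500L + s)
    sim <- simulate_dataset(sc)
    expr <- standardize_expression(sim$expr)
    net <- build_network(expr, power = 6, min_module_size = 10L)
    des <- cox_design(expr, sim$surv)
    fit <- fit_path(des, net$intramodular_connectivity, tau1 = 0.5, tau2 = 0.5,
                    K = 300)
    hub_rate <- hub_rate + ("M1_hub1" %in% fit$selected)
    bg_rate <- bg_rate + ("BG_g1" %in% fit$selected)
  }
  # with tau2 > 0 the low-connectivity twin can never be picked ahead of hubs
  expect_gte(hub_rate, bg_rate)
  expect_gte(hub_rate / n_seeds, 0.5)
})
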