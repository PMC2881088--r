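test_that("similarity is |Pearson correlation| and matches a direct computation", {
  set.seed(21)
  expr <- matrix(rnorm(3 * 4), 3, 4,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  S <- pearson_similarity(expr)
  expect_equal(diag(S), setNames(rep(1, 3), rownames(expr)))
  # brute-force Pearson formula per pair
  for (k in 1:3) for (j in 1:3) {
    x <- expr[k, ]; y <- expr[j, ]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(S[k, j], abs(r), tolerance = 1e-12)
  }
  # exact anticorrelation maps to similarity 1
  expr2 <- rbind(expr, g4 = -expr[1, ])
  expect_equal(pearson_similarity(expr2)["g1", "g4"], 1)

  expect_error(pearson_similarity(rbind(expr, flat = rep(1, 4))), "zero-variance")
  expect_error(pearson_similarity(expr[, 1:2]), "3 samples")
})

test_that("soft power adjacency is the elementwise power with zero diagonal", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  A <- soft_power_adjacency(S, 6)
  expect_equal(A[1, 2], 0.5^6)
  expect_equal(diag(A), c(0, 0))
  expect_equal(soft_power_adjacency(S, 1)[1, 2], 0.5)  # b = 1 identity
  S1 <- matrix(1, 3, 3)
  expect_equal(soft_power_adjacency(S1, 8.5)[1, 2], 1)  # fixed point
  expect_error(soft_power_adjacency(S, 0), "positive")
})

test_that("connectivity equals off-diagonal row sums (brute-force oracle)", {
  set.seed(22)
  A <- matrix(runif(25), 5, 5); A <- (A + t(A)) / 2; diag(A) <- 0
  C <- node_connectivity(A)
  for (k in 1:5) {
    acc <- 0
    for (j in 1:5) if (j != k) acc <- acc + A[k, j]
    expect_equal(unname(C[k]), acc, tolerance = 1e-14)
  }
  expect_equal(unname(node_connectivity(diag(5) * 0)), rep(0, 5))
  ones <- matrix(1, 6, 6)
  expect_equal(unname(node_connectivity(ones)), rep(5, 6))  # complete graph
})

test_that("TOM dissimilarity matches the triple-loop oracle and its closed cases", {
  set.seed(23)
  A <- matrix(runif(16, 0, 0.9), 4, 4); A <- (A + t(A)) / 2; diag(A) <- 0
  D <- tom_dissimilarity(A)
  expect_equal(D, tom_brute(A), tolerance = 1e-12)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 4))

  # identical unit-connected twins: omega = 1, d = 0
  At <- matrix(1, 4, 4); diag(At) <- 0
  expect_equal(tom_dissimilarity(At)[1, 2], 0, tolerance = 1e-12)

  # disconnected pair with no shared neighbours: omega = 0, d = 1
  Ad <- matrix(0, 4, 4)
  Ad[1, 3] <- Ad[3, 1] <- 1   # gene 1 connects only to 3
  Ad[2, 4] <- Ad[4, 2] <- 1   # gene 2 connects only to 4
  expect_equal(tom_dissimilarity(Ad)[1, 2], 1)
})

test_that("module detection recovers planted correlation blocks deterministically", {
  sc <- simulation_scenario(n_samples = 100L, module_sizes = c(50L, 50L),
                            background_genes = 0L, within_module_cor = 0.64,
                            hub_cor = 0.64, hub_fraction = 0, censor_target = 0,
                            seed = 24L)
  expr <- generate_expression(sc)
  net <- build_network(expr, power = 6, min_module_size = 20L)
  truth <- rep(1:2, each = 50)
  expect_gte(adjusted_rand(net$modules, truth), 0.9)
  expect_equal(length(setdiff(unique(net$modules), 0L)), 2L)

  D <- net$tom
  expect_identical(detect_modules(D), detect_modules(D))  # deterministic
  expect_equal(unname(detect_modules(D, min_module_size = 101L)),
               rep(0L, 100))  # cutoff beyond gene count
})

test_that("intramodular connectivity restricts sums to the module (masked oracle)", {
  set.seed(25)
  A <- matrix(runif(36, 0, 0.5), 6, 6); A <- (A + t(A)) / 2; diag(A) <- 0
  labels <- c(1L, 1L, 1L, 2L, 2L, 0L)
  kin <- intramodular_connectivity(A, labels)
  for (k in 1:6) {
    acc <- 0
    if (labels[k] > 0) {
      for (j in 1:6) if (j != k && labels[j] == labels[k]) acc <- acc + A[k, j]
    }
    expect_equal(unname(kin[k]), acc, tolerance = 1e-14)
  }
  expect_equal(unname(kin[6]), 0)  # unassigned
  # single-gene module has an empty sum
  expect_equal(unname(intramodular_connectivity(A, c(1L, 2L, 2L, 2L, 2L, 2L))[1]), 0)
  # one module spanning everything reproduces whole-network connectivity
  expect_equal(intramodular_connectivity(A, rep(1L, 6)), node_connectivity(A))
  # never exceeds whole-network connectivity
  expect_true(all(kin <= node_connectivity(A) + 1e-12))
})

test_that("scale-free criterion picks a qualifying power and falls back to 6", {
  # single candidate with trivial target
  set.seed(26)
  sc <- simulation_scenario(n_samples = 60L, module_sizes = c(40L, 40L),
                            background_genes = 20L, seed = 26L)
  S <- pearson_similarity(generate_expression(sc))
  expect_equal(as.numeric(pick_soft_power(S, candidates = 6, r2_target = 0)), 6)

  # planted approximate power-law connectivity: verify the log-log fit of the
  # returned candidate independently (fallback warning is asserted below)
  b <- suppressWarnings(pick_soft_power(S, candidates = c(2, 4, 6, 8), r2_target = 0.5))
  tab <- attr(b, "fit_table")
  k <- node_connectivity(soft_power_adjacency(S, as.numeric(b)))
  bins <- cut(k, 10, include.lowest = TRUE)
  freq <- as.numeric(table(bins)); kmean <- tapply(k, bins, mean)
  keep <- freq > 0 & !is.na(kmean) & kmean > 0
  refit <- summary(lm(log10(freq[keep]) ~ log10(kmean[keep])))$r.squared
  expect_equal(tab$r_squared[tab$power == as.numeric(b)], refit, tolerance = 1e-10)

  # unreachable target: conventional fallback with a warning
  expect_warning(b6 <- pick_soft_power(S, candidates = c(2, 4), r2_target = 0.999999),
                 "falling back")
  expect_equal(as.numeric(b6), 6)
})
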