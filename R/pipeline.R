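#' Assemble an end-to-end run configuration
#'
#' Collects every tunable of the pipeline — preprocessing, network
#' construction, selection tuning, evaluation toggles — with the package
#' defaults filled in, so a run is fully described by one object and its
#' seed. The configuration is written verbatim into the output manifest.
#'
#' @param expression,survival Paths to the tab-delimited expression and
#'   survival inputs (dialects of [read_expression()] / [read_survival()]).
#' @param out_dir Output directory.
#' @param impute_k KNN imputation neighbours (default 10).
#' @param prescreen_m Genes kept by the variance prescreen (default 2000).
#' @param standardize Standardize genes to zero median / unit variance.
#' @param power Soft power, or NULL to choose by the scale-free criterion.
#' @param power_candidates,r2_target Scale-free selection controls.
#' @param min_module_size,cut_height Module detection controls.
#' @param grid Tuning grid (tibble with tau1, tau2).
#' @param K_max,cv_folds,dnu,stride,restrict_f2 Selection controls, see
#'   [cross_validate()].
#' @param loo_prediction,occurrence,diagnostic Evaluation toggles: the
#'   leave-one-out predictive logrank evaluation (with occurrence indexes)
#'   and the significance-vs-connectivity diagnostic.
#' @param seed Integer master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(expression, survival, out_dir,
                       impute_k = 10L, prescreen_m = 2000L, standardize = TRUE,
                       power = NULL, power_candidates = 1:10, r2_target = 0.8,
                       min_module_size = 20L, cut_height = 0.99,
                       grid = default_tuning_grid(), K_max = 2000L,
                       cv_folds = 5L, dnu = 1e-3, stride = 20L,
                       restrict_f2 = FALSE,
                       loo_prediction = FALSE, occurrence = FALSE,
                       diagnostic = TRUE, seed = 1L) {
  structure(
    list(expression = expression, survival = survival, out_dir = out_dir,
         impute_k = as.integer(impute_k), prescreen_m = as.integer(prescreen_m),
         standardize = isTRUE(standardize),
         power = power, power_candidates = power_candidates,
         r2_target = r2_target, min_module_size = as.integer(min_module_size),
         cut_height = cut_height,
         grid = tibble::as_tibble(grid), K_max = as.integer(K_max),
         cv_folds = as.integer(cv_folds), dnu = dnu,
         stride = as.integer(stride), restrict_f2 = isTRUE(restrict_f2),
         loo_prediction = isTRUE(loo_prediction),
         occurrence = isTRUE(occurrence), diagnostic = isTRUE(diagnostic),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

config_manifest <- function(config, extra = list()) {
  m <- unclass(config)
  m$grid <- as.data.frame(m$grid)
  c(m, extra)
}

load_and_preprocess <- function(config) {
  for (p in c(config$expression, config$survival)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  expr <- read_expression(config$expression)
  surv <- read_survival(config$survival)
  if (anyNA(expr)) expr <- knn_impute(expr, k = config$impute_k)
  expr <- prescreen_by_variance(expr, m = config$prescreen_m)
  if (config$standardize) expr <- standardize_expression(expr)
  align_samples(expr, surv)
}

#' Run the full fitting pipeline
#'
#' preprocess (impute, prescreen, standardize) -> network construction ->
#' cross-validated tuning and final fits for both the network-guided method
#' and plain TGDR -> tables and a JSON manifest recording every setting and
#' the seed. Reruns with the same config and seed reproduce the outputs
#' byte-for-byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the network, both fits, and the written
#'   file paths.
#' @export
run_fit <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dat <- load_and_preprocess(config)
  message("netcox: preprocessed ", nrow(dat$expr), " genes x ",
          ncol(dat$expr), " samples")
  net <- build_network(dat$expr, power = config$power,
                       candidates = config$power_candidates,
                       r2_target = config$r2_target,
                       min_module_size = config$min_module_size,
                       cut_height = config$cut_height)
  message("netcox: network built (b = ", net$power, ", ",
          length(setdiff(unique(net$modules), 0L)), " modules)")
  design <- cox_design(dat$expr, dat$surv)
  conn <- net$intramodular_connectivity
  fit_net <- select_markers(design, conn, grid = config$grid,
                            method = "network", K_max = config$K_max,
                            cv_folds = config$cv_folds, seed = config$seed,
                            dnu = config$dnu, stride = config$stride,
                            restrict_f2 = config$restrict_f2)
  fit_plain <- select_markers(design, conn, grid = config$grid,
                              method = "tgdr", K_max = config$K_max,
                              cv_folds = config$cv_folds, seed = config$seed,
                              dnu = config$dnu, stride = config$stride)
  message("netcox: selected ", length(fit_net$selected), " genes (network), ",
          length(fit_plain$selected), " genes (TGDR)")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    modules = file.path(config$out_dir, "module_table.tsv"),
    fit_network = file.path(config$out_dir, "fit_network.tsv"),
    fit_tgdr = file.path(config$out_dir, "fit_tgdr.tsv"),
    tunings = file.path(config$out_dir, "tunings.tsv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  write_module_table(net, paths["modules"])
  write_fit_table(fit_net, paths["fit_network"], network = net)
  write_fit_table(fit_plain, paths["fit_tgdr"], network = net)
  tun <- dplyr::bind_rows(glance(fit_net), glance(fit_plain))
  write.table(as.data.frame(tun), paths["tunings"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  out <- list()
  if (config$diagnostic) {
    diag <- significance_connectivity_diagnostic(dat$expr, dat$surv, net)
    dpath <- file.path(config$out_dir, "significance_connectivity.tsv")
    dtab <- tidy(diag)
    dtab$marginal_coefficient <- signif(dtab$marginal_coefficient, 6L)
    dtab$intramodular_connectivity <- signif(dtab$intramodular_connectivity, 6L)
    write.table(dtab, dpath, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, diagnostic = dpath)
    out$diagnostic <- diag
  }
  manifest <- config_manifest(config, list(
    n_genes = nrow(dat$expr), n_samples = ncol(dat$expr),
    chosen_power = net$power,
    tuning_network = as.data.frame(glance(fit_net)),
    tuning_tgdr = as.data.frame(glance(fit_plain)),
    outputs = as.list(paths)
  ))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(c(list(network = net, fit_network = fit_net,
                   fit_tgdr = fit_plain, paths = paths), out))
}

#' Run the leave-one-out evaluation pipeline
#'
#' Preprocesses and rebuilds the network like [run_fit()], then runs the
#' leave-one-out predictive evaluation (scores, median-dichotomized risk
#' groups, logrank test) and writes the per-sample score table, per-gene
#' occurrence indexes and a text summary. Controlled by the
#' `loo_prediction` / `occurrence` toggles of the config; with both FALSE no
#' evaluation files are written.
#'
#' @param config A [run_config()].
#' @param method `"network"` or `"tgdr"`.
#' @return Invisibly, the `evaluation_report` (or NULL if disabled).
#' @export
run_evaluate <- function(config, method = c("network", "tgdr")) {
  stopifnot(inherits(config, "run_config"))
  method <- match.arg(method)
  if (!config$loo_prediction && !config$occurrence) {
    message("netcox: evaluation disabled in config; nothing to do")
    return(invisible(NULL))
  }
  dat <- load_and_preprocess(config)
  net <- build_network(dat$expr, power = config$power,
                       candidates = config$power_candidates,
                       r2_target = config$r2_target,
                       min_module_size = config$min_module_size,
                       cut_height = config$cut_height)
  design <- cox_design(dat$expr, dat$surv)
  report <- loo_predictive_evaluation(
    design, net$intramodular_connectivity, grid = config$grid,
    K_max = config$K_max, cv_folds = config$cv_folds, seed = config$seed,
    dnu = config$dnu, stride = config$stride,
    restrict_f2 = config$restrict_f2, method = method)
  message("netcox: LOO logrank = ", signif(report$logrank_statistic, 4),
          " (p = ", signif(report$logrank_pvalue, 3), ")")
  write_evaluation_report(report, config$out_dir,
                          prefix = paste0("evaluation_", method))
  invisible(report)
}

#' Simulate a benchmark dataset to disk
#'
#' Writes a named [default_benchmark_scenarios()] dataset (or a custom
#' scenario) in the expression/survival TSV dialects the pipeline reads.
#'
#' @param out_dir Output directory.
#' @param scenario A [simulation_scenario()] or the name of a benchmark
#'   scenario.
#' @param seed Seed stored into the scenario (overrides its own).
#' @return Named vector of written paths (expression, survival, truth),
#'   invisibly.
#' @export
run_simulate <- function(out_dir, scenario = "hub_signal", seed = 1L) {
  if (is.character(scenario)) {
    all <- default_benchmark_scenarios(seed = seed)
    if (!scenario %in% names(all)) {
      stop("unknown scenario '", scenario, "'; available: ",
           paste(names(all), collapse = ", "), call. = FALSE)
    }
    scenario <- all[[scenario]]
  }
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  sim <- simulate_dataset(scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(out_dir, "expression.tsv"),
             survival = file.path(out_dir, "survival.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_expression(sim$expr, paths["expression"])
  write_survival(sim$surv, paths["survival"])
  write.table(as.data.frame(sim$truth), paths["truth"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
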