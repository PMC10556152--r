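# Timeseries I/O, fit reports and the command-line driver.

#' Read a uniformly sampled timeseries from delimited text
#'
#' Expects a header row, a first column of times and one column per state;
#' comma or tab separated (sniffed from the first line).
#'
#' @param path file path
#' @return a `wendy_series`
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(df) < 2) stop("expected a time column plus at least one state column")
  if (any(is.na(df)))
    stop("missing value at row ", which(rowSums(is.na(df)) > 0)[1])
  wendy_series(df[[1]], as.matrix(df[, -1, drop = FALSE]), is_noisy = TRUE,
               rms = NULL)
}

#' Write a timeseries as delimited text (time column + state columns)
#'
#' @param ts a `wendy_series`
#' @param path output path
#' @param sep field separator
#' @export
write_timeseries <- function(ts, path, sep = ",") {
  df <- data.frame(t = sprintf("%.17g", ts$t))
  for (i in seq_len(ncol(ts$U)))
    df[[paste0("u", i)]] <- sprintf("%.17g", ts$U[, i])
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Turn a `wendy_fit` into a report list (JSON-ready)
#'
#' @param fit a `wendy_fit`
#' @param config optional resolved configuration to embed for provenance
#' @export
fit_report <- function(fit, config = NULL) {
  sm <- fit$system$slot_map
  params <- data.frame(
    slot = seq_len(fit$model$p),
    state = sm$state,
    feature = vapply(sm$feature, function(j) fit$model$features[[j]]$label,
                     character(1)),
    estimate = fit$w_hat,
    ols_estimate = fit$w_ols)
  if (!is.null(fit$uncertainty)) {
    params$std_err <- fit$uncertainty$se
    params$ci_lower <- fit$uncertainty$ci[, 1]
    params$ci_upper <- fit$uncertainty$ci[, 2]
  }
  rep <- list(
    package_version = as.character(utils::packageVersion("wendyr")),
    model = fit$model$name,
    parameters = params,
    sigma2_hat = fit$sigma2_hat,
    n_iterations = fit$irls$n_iter,
    stop_reason = fit$irls$stop_reason,
    sw_pvalues = fit$irls$sw_pvalues[!is.na(fit$irls$sw_pvalues)],
    min_radius = fit$radius$min_radius,
    K = fit$basis$K)
  if (!is.null(fit$uncertainty))
    rep$correlation <- fit$uncertainty$correlation
  if (!is.null(config)) rep$config <- config
  rep
}

default_config <- function() {
  list(eta = 9, s = 3, alpha = 1e-10, tau_fp = 1e-6, tau_sw = 1e-4,
       n0 = 10, max_its = 100, multipliers = c(1, 2, 4, 8),
       conf_level = 0.05, seed = 1)
}

validate_config <- function(cfg) {
  if (cfg$s <= 2 || cfg$s >= 4) stop("config: s must lie in (2, 4)")
  if (cfg$eta <= 0) stop("config: eta must be positive")
  if (cfg$alpha < 0 || cfg$alpha > 1) stop("config: alpha must lie in [0, 1]")
  if (cfg$conf_level <= 0 || cfg$conf_level >= 1)
    stop("config: conf_level must lie in (0, 1)")
  if (cfg$max_its < 1 || cfg$n0 < 0) stop("config: invalid iteration controls")
  cfg
}

#' Command-line driver
#'
#' Modes: `fit` (estimate parameters of a named model from a delimited
#' timeseries file), `benchmark` (noise-by-resolution trial sweep on a
#' built-in model) and `diagnose` (radius and singular-value diagnostics for
#' a dataset). Artifacts (JSON report, delimited tables) are written under
#' `output_dir`; inputs are never modified. A thin executable wrapper lives
#' in `inst/cli/wendy.R`.
#'
#' @param args character vector of command-line arguments, e.g.
#'   `c("fit", "--data", "series.csv", "--model", "logistic")`
#' @return exit status (0 on success), invisibly
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) < 1)
      stop("usage: wendy <fit|benchmark|diagnose> [options]")
    mode <- args[1]
    opts <- parse_cli_options(args[-1])
    cfg <- utils::modifyList(default_config(), opts[names(opts) %in%
                                                   names(default_config())])
    cfg <- validate_config(cfg)
    outdir <- if (!is.null(opts$output_dir)) opts$output_dir else "."
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    switch(mode,
      fit = cli_fit(opts, cfg, outdir),
      benchmark = cli_benchmark(opts, cfg, outdir),
      diagnose = cli_diagnose(opts, cfg, outdir),
      stop("unknown mode '", mode, "'; use fit, benchmark or diagnose"))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1
  numeric_keys <- c("eta", "s", "alpha", "tau_fp", "tau_sw", "n0", "max_its",
                    "conf_level", "seed", "sigma_nr", "n_points", "n_trials")
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!startsWith(args[i], "--") || i == length(args))
      stop("malformed option near '", args[i], "'")
    val <- args[i + 1]
    if (key %in% numeric_keys) val <- as.numeric(val)
    opts[[key]] <- val
    i <- i + 2
  }
  opts
}

cli_fit <- function(opts, cfg, outdir) {
  if (is.null(opts$data)) stop("fit mode needs --data <file>")
  if (is.null(opts$model)) stop("fit mode needs --model <name>")
  ts <- read_timeseries(opts$data)
  model <- get_model(opts$model)
  fit <- wendy_fit(ts, model, eta = cfg$eta, s = cfg$s, alpha = cfg$alpha,
                   tau_fp = cfg$tau_fp, tau_sw = cfg$tau_sw, n0 = cfg$n0,
                   max_its = cfg$max_its, conf_level = cfg$conf_level)
  rep <- fit_report(fit, config = cfg)
  jsonlite::write_json(rep, file.path(outdir, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(rep$parameters, file.path(outdir, "fit_parameters.csv"),
                   row.names = FALSE)
  message(sprintf("fit: min_radius = %d, K = %d, %d iterations, stop = %s",
                  fit$radius$min_radius, fit$basis$K, fit$irls$n_iter,
                  fit$irls$stop_reason))
  print(fit)
}

cli_benchmark <- function(opts, cfg, outdir) {
  if (is.null(opts$model)) stop("benchmark mode needs --model <name>")
  model <- get_model(opts$model)
  snr <- if (!is.null(opts$sigma_nr)) opts$sigma_nr else 0.1
  np <- if (!is.null(opts$n_points)) opts$n_points else 128
  nt <- if (!is.null(opts$n_trials)) opts$n_trials else 10
  trials <- run_trials(model, snr, np, nt, base_seed = cfg$seed)
  utils::write.csv(trials, file.path(outdir, "benchmark_trials.csv"),
                   row.names = FALSE)
  summ <- summarize_trials(trials)
  utils::write.csv(summ, file.path(outdir, "benchmark_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(config = cfg, summary = summ),
                       file.path(outdir, "benchmark_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("benchmark: ", nrow(trials), " rows written")
}

cli_diagnose <- function(opts, cfg, outdir) {
  if (is.null(opts$data)) stop("diagnose mode needs --data <file>")
  ts <- read_timeseries(opts$data)
  rad <- select_min_radius(ts$U, ts$t, s = cfg$s, eta = cfg$eta)
  basis <- orthonormal_basis(ts$t, rad$min_radius,
                             multipliers = cfg$multipliers, eta = cfg$eta)
  utils::write.csv(data.frame(radius = rad$candidate_radii,
                              ehat_rms = rad$ehat_rms),
                   file.path(outdir, "radius_diagnostics.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(index = seq_along(basis$singular_values),
                              singular_value = basis$singular_values),
                   file.path(outdir, "singular_values.csv"),
                   row.names = FALSE)
  message(sprintf("diagnose: min_radius = %d, K = %d", rad$min_radius,
                  basis$K))
}
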