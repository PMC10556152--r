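# Synthetic data: high-fidelity RK45 solves of the benchmark models, dyadic
# subsampling, additive Gaussian noise scaled to the trajectory rms, and the
# E2 / E_FS error metrics with a noise-by-resolution trial runner.

#' Construct a `wendy_series` from a uniform grid and state matrix
#'
#' @param t strictly increasing uniform time grid
#' @param U (M+1) x d state matrix (vector allowed)
#' @param is_noisy whether the series carries measurement noise
#' @param rms root-mean-square of vec(U) of the underlying noiseless series,
#'   if known (filled automatically for noiseless series)
#' @export
wendy_series <- function(t, U, is_noisy = FALSE, rms = NULL) {
  if (is.null(dim(U))) U <- matrix(U, ncol = 1)
  U <- as.matrix(U)
  if (length(t) != nrow(U)) stop("grid and state matrix sizes differ")
  if (length(t) < 2) stop("a timeseries needs at least 2 points")
  dts <- diff(t)
  if (any(dts <= 0)) stop("time grid must be strictly increasing")
  if (diff(range(dts)) > 1e-12 * max(abs(dts)) + 1e-300 &&
      diff(range(dts)) > 1e-6 * mean(dts))
    stop("non-uniform time grid (relative spread ",
         signif(diff(range(dts)) / mean(dts), 3),
         "); only uniformly sampled series are supported")
  if (any(!is.finite(U))) stop("state matrix contains non-finite values")
  if (is.null(rms) && !is_noisy) rms <- sqrt(mean(U^2))
  structure(list(t = as.numeric(t), U = unname(U), dt = mean(dts),
                 is_noisy = is_noisy, rms = rms),
            class = "wendy_series")
}

#' @export
print.wendy_series <- function(x, ...) {
  cat(sprintf("<wendy_series> %d points x %d states, dt = %.4g, t in [%g, %g]%s\n",
              length(x$t), ncol(x$U), x$dt, x$t[1], x$t[length(x$t)],
              if (x$is_noisy) " (noisy)" else ""))
  invisible(x)
}

#' Simulate the noiseless reference trajectory of a model
#'
#' Adaptive RK45 (Dormand-Prince) solve at absolute/relative tolerance 1e-12,
#' evaluated on `n_points` equally spaced times spanning [0, T].
#'
#' @param model a `wendy_model`
#' @param n_points number of sample points including t = 0
#' @param w parameter vector (defaults to the model's reference values)
#' @param tol solver absolute and relative tolerance
#' @return a noiseless `wendy_series` with its `rms` field populated
#' @export
simulate_truth <- function(model, n_points, w = model$w_ref, tol = 1e-12) {
  if (n_points < 2) stop("n_points must be at least 2")
  times <- seq(0, model$T_final, length.out = n_points)
  rhs <- if (!is.null(model$rhs))
    function(t, y, parms) list(model$rhs(y, parms))
  else
    function(t, y, parms) list(rhs_eval(model, parms, y))
  sol <- suppressWarnings(
    deSolve::ode(y = model$u0, times = times, func = rhs, parms = w,
                 method = "ode45", rtol = tol, atol = tol))
  U <- unname(sol[, -1, drop = FALSE])
  if (nrow(U) < n_points || any(!is.finite(U))) {
    bad <- if (nrow(U) < n_points) times[nrow(U) + 1] else
      times[which(!is.finite(rowSums(U)))[1]]
    stop("integration of model '", model$name, "' failed near t = ",
         signif(bad, 6))
  }
  wendy_series(times, U, is_noisy = FALSE)
}

#' Noise specification scaled to the trajectory root-mean-square
#'
#' @param sigma_nr noise ratio; the noise standard deviation is
#'   sigma_nr * rms of the noiseless trajectory, so sigma_nr is
#'   interpretable as the relative error between true and noisy data
#' @param seed integer RNG seed for reproducibility
#' @export
noise_spec <- function(sigma_nr, seed) {
  if (sigma_nr < 0) stop("sigma_nr must be nonnegative")
  list(sigma_nr = sigma_nr, seed = as.integer(seed))
}

#' Add i.i.d. Gaussian measurement noise to a noiseless series
#'
#' @param ts a noiseless `wendy_series`
#' @param spec a [noise_spec()]
#' @return a noisy `wendy_series` (same grid); `sigma_nr = 0` returns the
#'   input values unchanged
#' @export
corrupt <- function(ts, spec) {
  if (isTRUE(ts$is_noisy)) stop("series is already noisy")
  sigma <- spec$sigma_nr * ts$rms
  if (sigma == 0) return(ts)
  set.seed(spec$seed)
  E <- matrix(stats::rnorm(length(ts$U), sd = sigma), nrow(ts$U), ncol(ts$U))
  out <- wendy_series(ts$t, ts$U + E, is_noisy = TRUE, rms = ts$rms)
  out$sigma <- sigma
  out
}

#' Keep every `factor`-th sample of a series (dyadic coarsening)
#'
#' @param ts a `wendy_series`
#' @param factor subsampling stride; a power of two unless `strict = FALSE`
#' @param strict enforce the power-of-two convention of the benchmark
#'   protocol
#' @export
subsample_series <- function(ts, factor, strict = TRUE) {
  factor <- as.integer(factor)
  if (factor < 1) stop("subsampling factor must be a positive integer")
  if (strict && bitwAnd(factor, factor - 1L) != 0L)
    stop("subsampling factor must be a power of two")
  if (factor == 1L) return(ts)
  idx <- seq(1, length(ts$t), by = factor)
  out <- wendy_series(ts$t[idx], ts$U[idx, , drop = FALSE],
                      is_noisy = ts$is_noisy, rms = ts$rms)
  out$sigma <- ts$sigma
  out
}

#' Parameter and forward-simulation error metrics
#'
#' E2 is the relative l2 error of the parameter vector. E_FS re-simulates
#' the model from the exact initial condition with the estimated parameters
#' on the same grid (RK45 at tolerance 1e-12) and reports the relative l2
#' error of the trajectory; if that solve blows up, E_FS is `Inf`.
#'
#' @param w_hat estimated parameter vector
#' @param model a `wendy_model` (supplies `w_ref` and `u0`)
#' @param t_grid grid on which to compare trajectories (needed for E_FS)
#' @param truth optional noiseless `wendy_series` on `t_grid` (recomputed
#'   if missing)
#' @param compute_efs set `FALSE` to skip the forward solve
#' @return list with `E2` and `EFS`
#' @export
error_metrics <- function(w_hat, model, t_grid = NULL, truth = NULL,
                          compute_efs = TRUE) {
  if (length(w_hat) != model$p)
    stop("w_hat has ", length(w_hat), " entries; expected ", model$p)
  E2 <- sqrt(sum((w_hat - model$w_ref)^2)) / sqrt(sum(model$w_ref^2))
  EFS <- NA_real_
  if (compute_efs) {
    if (is.null(t_grid)) stop("E_FS needs the comparison grid")
    if (is.null(truth)) truth <- simulate_truth(model, length(t_grid))
    sim <- tryCatch(simulate_truth(model, length(t_grid), w = w_hat),
                    error = function(e) NULL)
    EFS <- if (is.null(sim)) Inf else
      sqrt(sum((truth$U - sim$U)^2)) / sqrt(sum(truth$U^2))
  }
  list(E2 = E2, EFS = EFS)
}

fine_points_for <- function(model) if (model$name == "logistic") 512L else 1024L

#' Run repeated noise trials of the OLS and reweighted estimators
#'
#' Reproduces the benchmark protocol: a high-fidelity reference solve on the
#' model's fine grid (512 points for logistic growth, 1024 otherwise), per
#' trial corruption with i.i.d. Gaussian noise of standard deviation
#' sigma_nr * rms (seed = base_seed + trial, common random numbers across
#' cells), dyadic subsampling to each requested resolution, and a paired
#' weak-form OLS / reweighted fit with E2 and E_FS recorded for both.
#'
#' @param model a `wendy_model`
#' @param sigma_nr_list noise ratios to sweep
#' @param n_points_list resolutions to sweep (must divide the fine grid by
#'   powers of two)
#' @param n_trials trials per cell
#' @param base_seed integer; trial seeds are `base_seed + trial`
#' @param compute_efs `TRUE` (forward solves for both methods), `"wendy"`
#'   (skip the OLS forward solve), or `FALSE` (no forward solves)
#' @param fine_points override the fine-grid size
#' @param ... further arguments passed to [wendy_fit()]
#' @return data.frame with columns model, sigma_nr, n_points, trial, method,
#'   E2, EFS; failed trials are dropped with a warning (attribute
#'   `n_failed` records the count)
#' @export
run_trials <- function(model, sigma_nr_list, n_points_list, n_trials,
                       base_seed = 0, compute_efs = TRUE,
                       fine_points = fine_points_for(model), ...) {
  if (n_trials < 1) stop("n_trials must be at least 1")
  fine <- simulate_truth(model, fine_points)
  truths <- list()
  for (np in n_points_list) {
    fac <- fine_points / np
    if (fac != floor(fac) || bitwAnd(as.integer(fac), as.integer(fac) - 1L) != 0L)
      stop("n_points = ", np, " is not a dyadic subsample of the ",
           fine_points, "-point fine grid")
    truths[[as.character(np)]] <- subsample_series(fine, fac)
  }
  rows <- list()
  n_failed <- 0L
  for (snr in sigma_nr_list) {
    for (np in n_points_list) {
      truth <- truths[[as.character(np)]]
      for (trial in seq_len(n_trials)) {
        noisy_fine <- corrupt(fine, noise_spec(snr, base_seed + trial))
        noisy <- subsample_series(noisy_fine, fine_points / np)
        res <- tryCatch({
          fit <- wendy_fit(noisy, model, ...)
          m_w <- error_metrics(fit$w_hat, model, truth$t, truth,
                               !identical(compute_efs, FALSE))
          m_o <- error_metrics(fit$w_ols, model, truth$t, truth,
                               isTRUE(compute_efs))
          list(
            data.frame(model = model$name, sigma_nr = snr, n_points = np,
                       trial = trial, method = "ols",
                       E2 = m_o$E2, EFS = m_o$EFS),
            data.frame(model = model$name, sigma_nr = snr, n_points = np,
                       trial = trial, method = "wendy",
                       E2 = m_w$E2, EFS = m_w$EFS))
        }, error = function(e) {
          warning("trial ", trial, " (sigma_nr = ", snr, ", n_points = ", np,
                  ") failed: ", conditionMessage(e), call. = FALSE)
          NULL
        })
        if (is.null(res)) n_failed <- n_failed + 1L else
          rows <- c(rows, res)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- n_failed
  out
}

#' Aggregate trial results into per-cell summaries
#'
#' Computes, per (sigma_nr, n_points) cell, the mean and median of E2 and
#' E_FS for each method and the median per-trial percentage drop in E2 from
#' OLS to the reweighted estimate, 100 * (E2_ols - E2_wendy) / E2_ols.
#'
#' @param trials output of [run_trials()]
#' @return data.frame, one row per cell
#' @export
summarize_trials <- function(trials) {
  cells <- unique(trials[, c("model", "sigma_nr", "n_points")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- trials[trials$sigma_nr == cells$sigma_nr[i] &
                   trials$n_points == cells$n_points[i] &
                   trials$model == cells$model[i], ]
    w <- cell[cell$method == "wendy", ]
    o <- cell[cell$method == "ols", ]
    o <- o[match(w$trial, o$trial), ]
    drop_pct <- 100 * (o$E2 - w$E2) / o$E2
    data.frame(model = cells$model[i], sigma_nr = cells$sigma_nr[i],
               n_points = cells$n_points[i], n_trials = nrow(w),
               mean_E2_wendy = mean(w$E2), median_E2_wendy = median(w$E2),
               mean_E2_ols = mean(o$E2), median_E2_ols = median(o$E2),
               mean_EFS_wendy = mean(w$EFS), median_EFS_wendy = median(w$EFS),
               mean_EFS_ols = mean(o$EFS), median_EFS_ols = median(o$EFS),
               median_drop_E2_pct = median(drop_pct))
  })
  do.call(rbind, out)
}
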