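# Ordinary least squares, the iteratively reweighted (errors-in-variables)
# estimator, noise-variance estimation and parameter uncertainty.

#' Ordinary least squares solution of the weak-form system
#'
#' @param ws a `wendy_system`
#' @return the minimizer of ||G w - b||_2
#' @export
ols_solve <- function(ws) {
  unname(qr.coef(qr(ws$G), ws$b))
}

# Finite-difference weights (Fornberg's recursion) for derivatives 0..m at
# point z from nodes x; returns length(x) x (m+1) matrix.
fornberg_weights <- function(z, x, m) {
  n <- length(x)
  C <- matrix(0, n, m + 1)
  C[1, 1] <- 1
  c1 <- 1
  c4 <- x[1] - z
  for (i in 2:n) {
    mn <- min(i - 1, m)
    c2 <- 1
    c5 <- c4
    c4 <- x[i] - z
    for (j in 1:(i - 1)) {
      c3 <- x[i] - x[j]
      c2 <- c2 * c3
      if (j == i - 1) {
        if (mn >= 1) for (k in mn:1)
          C[i, k + 1] <- c1 * (k * C[i - 1, k] - c5 * C[i - 1, k + 1]) / c2
        C[i, 1] <- -c1 * c5 * C[i - 1, 1] / c2
      }
      if (mn >= 1) for (k in mn:1)
        C[j, k + 1] <- (c4 * C[j, k + 1] - k * C[j, k]) / c3
      C[j, 1] <- c4 * C[j, 1] / c3
    }
    c1 <- c2
  }
  C
}

#' High-order noise filter (centered order-6 difference over 15 points)
#'
#' The weights of the 6th derivative on a 15-point centered stencil
#' annihilate polynomials up to degree 5 exactly; normalized to unit 2-norm
#' they pass white noise through with unchanged variance.
#'
#' @return length-15 weight vector with unit 2-norm
#' @export
noise_filter <- function() {
  w <- fornberg_weights(0, -7:7, 6)[, 7]
  w / sqrt(sum(w^2))
}

#' Estimate the measurement noise variance from the data
#'
#' Convolves each state column with the unit-norm high-order filter of
#' [noise_filter()] (valid part only) and returns the mean of the squared
#' filtered entries. Smooth trends locally well approximated by degree-5
#' polynomials are annihilated, leaving the white-noise variance.
#'
#' @param data a `wendy_series` or list with element `U` (at least 15 rows)
#' @return estimated variance sigma^2
#' @export
estimate_sigma2 <- function(data) {
  U <- data$U
  if (is.null(dim(U))) U <- matrix(U, ncol = 1)
  if (nrow(U) < 15)
    stop("noise-variance estimation needs at least 15 timepoints; got ",
         nrow(U))
  f <- noise_filter()
  valid <- 8:(nrow(U) - 7)
  tot <- 0
  for (i in seq_len(ncol(U))) {
    v <- stats::filter(U[, i], f, method = "convolution", sides = 2)[valid]
    tot <- tot + sum(v^2)
  }
  tot / (length(valid) * ncol(U))
}

sw_pvalue <- function(r) {
  n <- length(r)
  if (n < 3) return(1)
  if (n > 5000) r <- r[seq(1, n, length.out = 5000)]
  if (stats::sd(r) == 0) return(1)
  stats::shapiro.test(r)$p.value
}

#' Iteratively reweighted least squares for the errors-in-variables problem
#'
#' Starts from the ordinary least squares solution and alternates between
#' (i) linearizing the residual's noise dependence at the current iterate to
#' obtain the covariance C = (1 - alpha) L L^T + alpha I and (ii) solving
#' the C-weighted least squares via the lower Cholesky factor applied to G
#' and b. Iteration continues while all three hold: the relative step
#' exceeds `tau_fp`, fewer than `max_its` iterations have run, and (after a
#' burn-in of `n0` iterations) the Shapiro-Wilk p-value of the weighted
#' residual exceeds `tau_sw`. When the normality clause breaks, the iterate
#' with the highest Shapiro-Wilk p-value seen is returned, since later
#' iterates can drift once the first-order statistical model stops holding.
#'
#' @param ws a `wendy_system`
#' @param builder function(w) returning the output of [build_L()] at w;
#'   defaults to `build_L` on `ws` with relaxation `alpha`
#' @param alpha covariance relaxation weight (default 1e-10)
#' @param tau_fp fixed-point tolerance on the relative step (default 1e-6)
#' @param tau_sw Shapiro-Wilk p-value floor (default 1e-4)
#' @param n0 burn-in before normality is checked (default 10)
#' @param max_its iteration cap (default 100)
#' @return a `wendy_irls` list: `w_hat`, `w_iterates`, `n_iter`,
#'   `stop_reason` (fixed_point / max_iterations / normality_break),
#'   `sw_pvalues`, `C_hat`, `chol_hat`, `alpha`
#' @export
irls_fit <- function(ws, builder = NULL, alpha = 1e-10, tau_fp = 1e-6,
                     tau_sw = 1e-4, n0 = 10, max_its = 100) {
  if (is.null(builder)) builder <- function(w) build_L(ws, w, alpha = alpha)
  G <- ws$G
  b <- ws$b
  w <- ols_solve(ws)
  iterates <- list(w)          # iterates[[n + 1]] = w^(n)
  pvals <- NA_real_
  stop_reason <- "max_iterations"
  n <- 0L
  repeat {
    fc <- builder(w)
    Gt <- forwardsolve(fc$chol, G)
    bt <- forwardsolve(fc$chol, b)
    wn <- unname(qr.coef(qr(Gt), bt))
    r <- drop(Gt %*% wn - bt)
    n <- n + 1L
    iterates[[n + 1L]] <- wn
    p <- if (n < n0) NA_real_ else if (n == n0) 1 else sw_pvalue(r)
    pvals[n + 1L] <- p
    denom <- sqrt(sum(w^2))
    step <- sqrt(sum((wn - w)^2)) / if (denom > 0) denom else 1
    if (!is.na(p) && p <= tau_sw) {
      stop_reason <- "normality_break"
      meas <- which(!is.na(pvals))
      meas <- meas[meas != n0 + 1L]   # drop the burn-in placeholder p = 1
      best <- if (length(meas)) meas[which.max(pvals[meas])] else n0 + 1L
      w <- iterates[[best]]
      break
    }
    w <- wn
    if (step <= tau_fp) {
      stop_reason <- "fixed_point"
      break
    }
    if (n >= max_its) {
      stop_reason <- "max_iterations"
      break
    }
  }
  fc <- builder(w)
  structure(list(w_hat = w, w_iterates = iterates, n_iter = n,
                 stop_reason = stop_reason, sw_pvalues = pvals,
                 C_hat = fc$C, chol_hat = fc$chol, alpha = fc$alpha),
            class = "wendy_irls")
}

#' Parameter covariance and confidence intervals
#'
#' Computes the sandwich covariance
#' S = sigma2_hat * (G^T G)^{-1} G^T C_hat G (G^T G)^{-1}
#' and per-parameter half-widths d_i(c) = sqrt(S_ii) * z_{1 - c/2}, the
#' (1 - c) normal interval around each estimate. The correlation matrix
#' (S scaled to unit diagonal) is also returned.
#'
#' @param ws a `wendy_system`
#' @param fit a `wendy_irls` result (supplies `C_hat`)
#' @param sigma2_hat estimated measurement variance, e.g. from
#'   [estimate_sigma2()]
#' @param conf_level the tail mass c in (0, 1); c = 0.05 gives 95% intervals
#' @return list with `S`, `se`, `half_width`, `ci` (p x 2 matrix),
#'   `correlation`, `conf_level`, `sigma2_hat`
#' @export
parameter_uncertainty <- function(ws, fit, sigma2_hat, conf_level = 0.05) {
  if (conf_level <= 0 || conf_level >= 1)
    stop("conf_level must lie strictly between 0 and 1")
  G <- ws$G
  GtG <- crossprod(G)
  A <- solve(GtG, t(G))                  # (G^T G)^{-1} G^T
  S <- sigma2_hat * (A %*% fit$C_hat %*% t(A))
  S <- (S + t(S)) / 2
  se <- sqrt(pmax(diag(S), 0))
  z <- stats::qnorm(1 - conf_level / 2)
  hw <- se * z
  ci <- cbind(lower = fit$w_hat - hw, upper = fit$w_hat + hw)
  corr <- S / tcrossprod(ifelse(se > 0, se, 1))
  list(S = S, se = se, half_width = hw, ci = ci, correlation = corr,
       conf_level = conf_level, sigma2_hat = sigma2_hat)
}

#' Fit a linear-in-parameters ODE model to a noisy timeseries
#'
#' End-to-end pipeline: estimate the noise variance, select the minimum
#' test-function radius from the data, build the orthonormal multiscale
#' basis, assemble the weak-form system, run the reweighted estimator and
#' compute parameter uncertainty. The weak-form OLS estimate is kept for
#' comparison.
#'
#' @param data a `wendy_series` or list with uniform grid `t` and state
#'   matrix `U`
#' @param model a `wendy_model`
#' @param eta bump shape parameter (default 9)
#' @param s aliasing coarsening factor in (2, 4) (default 3)
#' @param multipliers basis scale multipliers (default 1, 2, 4, 8)
#' @param alpha covariance relaxation (default 1e-10)
#' @param tau_fp,tau_sw,n0,max_its stopping controls, see [irls_fit()]
#' @param conf_level confidence tail mass c (default 0.05)
#' @return a `wendy_fit` object: estimates, OLS baseline, uncertainty,
#'   diagnostics (`min_radius`, `K`, iterations, stop reason)
#' @export
wendy_fit <- function(data, model, eta = 9, s = 3,
                      multipliers = c(1, 2, 4, 8), alpha = 1e-10,
                      tau_fp = 1e-6, tau_sw = 1e-4, n0 = 10, max_its = 100,
                      conf_level = 0.05) {
  U <- as_state_matrix(data$U, model$d)
  t_grid <- data$t
  sigma2_hat <- if (nrow(U) >= 15) estimate_sigma2(list(U = U)) else NA_real_
  rad <- select_min_radius(U, t_grid, s = s, eta = eta)
  basis <- orthonormal_basis(t_grid, rad$min_radius,
                             multipliers = multipliers, eta = eta)
  ws <- assemble_weak_system(basis, model, list(t = t_grid, U = U))
  w_ols <- ols_solve(ws)
  fit <- irls_fit(ws, alpha = alpha, tau_fp = tau_fp, tau_sw = tau_sw,
                  n0 = n0, max_its = max_its)
  unc <- if (is.finite(sigma2_hat))
    parameter_uncertainty(ws, fit, sigma2_hat, conf_level) else NULL
  structure(list(w_hat = fit$w_hat, w_ols = w_ols, model = model,
                 uncertainty = unc, sigma2_hat = sigma2_hat,
                 irls = fit, system = ws, basis = basis, radius = rad),
            class = "wendy_fit")
}

#' @export
print.wendy_fit <- function(x, ...) {
  cat(sprintf("<wendy_fit> model %s: %d parameters, K = %d test functions (min radius %d)\n",
              x$model$name, x$model$p, x$basis$K, x$radius$min_radius))
  cat(sprintf("  %d reweighting iterations, stopped on %s\n",
              x$irls$n_iter, x$irls$stop_reason))
  tab <- data.frame(slot = seq_len(x$model$p),
                    state = x$system$slot_map$state,
                    feature = vapply(x$system$slot_map$feature,
                                     function(j) x$model$features[[j]]$label,
                                     character(1)),
                    estimate = signif(x$w_hat, 6))
  if (!is.null(x$uncertainty)) {
    tab$std_err <- signif(x$uncertainty$se, 4)
    tab$ci_lower <- signif(x$uncertainty$ci[, 1], 5)
    tab$ci_upper <- signif(x$uncertainty$ci[, 2], 5)
  }
  print(tab, row.names = FALSE)
  if (is.finite(x$sigma2_hat))
    cat(sprintf("  estimated noise sd: %.4g\n", sqrt(x$sigma2_hat)))
  invisible(x)
}
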