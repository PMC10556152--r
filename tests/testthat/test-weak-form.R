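test_that("constant-feature rows reduce to trapezoid integrals of phi", {
  const_model <- wendy_model("const", features = list(feature_monomial(0)),
                             terms = list(1L), w_ref = 2, u0 = 0.5,
                             T_final = 1)
  t_grid <- seq(0, 1, length.out = 65)
  U <- matrix(sin(t_grid) + 2, ncol = 1)
  basis <- orthonormal_basis(t_grid, 4)
  ws <- assemble_weak_system(basis, const_model, list(t = t_grid, U = U))
  dt <- t_grid[2] - t_grid[1]
  quad <- rep(dt, 65); quad[c(1, 65)] <- dt / 2
  expect_equal(drop(ws$G), drop(basis$phi %*% quad))
})

test_that("weak residual at the true parameters is pure quadrature error", {
  m <- get_model("logistic")
  res_at <- function(n, r) {
    ts <- fx_truth("logistic", n)
    basis <- orthonormal_basis(ts$t, r)
    ws <- assemble_weak_system(basis, m, ts)
    sqrt(mean(weak_residual(ws, m$w_ref)^2))
  }
  # doubling the resolution at fixed radius fraction shrinks the error
  e_coarse <- res_at(128, 6)
  e_fine <- res_at(256, 12)
  expect_lt(e_fine, e_coarse)
})

test_that("rank deficiencies are reported against the solvability conditions", {
  m <- get_model("logistic")
  ts <- fx_noisy("logistic", 512, 8, 0.1, 3)
  basis <- orthonormal_basis(ts$t, 5)
  dup <- basis
  dup$phi[2, ] <- dup$phi[1, ]
  dup$dphi[2, ] <- dup$dphi[1, ]
  expect_error(assemble_weak_system(dup, m, ts), "rank\\(phi\\) < K")
  # constant data make u and u^2 collinear (feature rank failure)
  flatU <- matrix(1, length(ts$t), 1)
  flat <- list(t = ts$t, U = flatU)
  basis2 <- orthonormal_basis(ts$t, 5)
  expect_error(assemble_weak_system(basis2, m, flat), "state 1")
})

test_that("residual is linear and orthogonal to G at the LS solution", {
  m <- get_model("lotka_volterra")
  ts <- fx_noisy("lotka_volterra", 1024, 8, 0.1, 5)
  basis <- orthonormal_basis(ts$t, 5)
  ws <- assemble_weak_system(basis, m, ts)
  w0 <- ols_solve(ws)
  expect_lt(max(abs(crossprod(ws$G, weak_residual(ws, w0)))), 1e-10)
  delta <- stats::rnorm(length(w0), sd = 0.1)
  expect_equal(weak_residual(ws, w0 + delta) - weak_residual(ws, w0),
               drop(ws$G %*% delta), tolerance = 1e-12)
  expect_error(weak_residual(ws, c(w0, 1)), "length")
})

test_that("L reduces to hand expansions in the linear and w = 0 cases", {
  lin_model <- wendy_model("lin", features = list(feature_monomial(1)),
                           terms = list(1L), w_ref = -0.5, u0 = 1,
                           T_final = 2)
  t_grid <- seq(0, 2, length.out = 65)
  U <- matrix(exp(-0.5 * t_grid), ncol = 1)
  basis <- orthonormal_basis(t_grid, 4)
  ws <- assemble_weak_system(basis, lin_model, list(t = t_grid, U = U))
  w <- -0.37
  fc <- build_L(ws, w)
  expect_equal(fc$L, w * ws$phi_q + ws$dphi_q, tolerance = 1e-12)
  fc0 <- build_L(ws, 0)
  expect_equal(fc0$L, ws$dphi_q, tolerance = 1e-12)
})

test_that("L matches the finite-difference residual Jacobian quadratically", {
  set.seed(61)
  m <- get_model("lotka_volterra")
  ts <- fx_noisy("lotka_volterra", 1024, 16, 0.1, 6)
  basis <- orthonormal_basis(ts$t, 4)
  ws <- assemble_weak_system(basis, m, ts)
  w <- m$w_ref
  fc <- build_L(ws, w)
  E <- matrix(stats::rnorm(length(ts$U)), nrow(ts$U))
  rel_err <- vapply(c(2e-2, 1e-2, 5e-3), function(h) {
    ws2 <- assemble_weak_system(basis, m, list(t = ts$t, U = ts$U + h * E))
    dr <- weak_residual(ws2, w) - weak_residual(ws, w)
    lin <- h * drop(fc$L %*% as.vector(E))
    sqrt(sum((dr - lin)^2)) / sqrt(sum(lin^2))
  }, numeric(1))
  # remainder is second order: halving the perturbation halves the relative
  # error of the first-order model
  expect_lt(rel_err[2] / rel_err[1], 0.6)
  expect_lt(rel_err[3] / rel_err[2], 0.6)
  # covariance factor reproduces C
  expect_equal(fc$chol %*% t(fc$chol), fc$C, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(isSymmetric(fc$C, tol = 1e-12))
})

test_that("uniform quadrature rescaling leaves the weighted solution fixed", {
  m <- get_model("logistic")
  ts <- fx_noisy("logistic", 512, 8, 0.2, 9)
  basis <- orthonormal_basis(ts$t, 5)
  ws <- assemble_weak_system(basis, m, ts)
  scale_ws <- function(ws, cc) {
    ws$G <- cc * ws$G; ws$b <- cc * ws$b
    ws$phi_q <- cc * ws$phi_q; ws$dphi_q <- cc * ws$dphi_q
    ws$quad <- cc * ws$quad
    ws
  }
  ws2 <- scale_ws(ws, 3.7)
  f1 <- irls_fit(ws, n0 = 10)
  f2 <- irls_fit(ws2, n0 = 10)
  expect_equal(f1$w_hat, f2$w_hat, tolerance = 1e-6)
  fc1 <- build_L(ws, m$w_ref)
  fc2 <- build_L(ws2, m$w_ref)
  expect_equal(fc2$L, 3.7 * fc1$L, tolerance = 1e-12)
})

test_that("covariance weighting restores residual normality at w_star", {
  # raw weak-form residuals at the truth are non-Gaussian because the noisy
  # features enter G; the C^(-1/2) weighting whitens them
  m <- get_model("lotka_volterra")
  n_seeds <- 12
  sw_weighted <- sw_raw <- numeric(n_seeds)
  pooled <- NULL
  for (s in seq_len(n_seeds)) {
    ts <- fx_noisy("lotka_volterra", 1024, 4, 0.2, 100 + s)
    rad <- select_min_radius(ts$U, ts$t)
    basis <- orthonormal_basis(ts$t, rad$min_radius)
    ws <- assemble_weak_system(basis, m, ts)
    r_raw <- weak_residual(ws, m$w_ref)
    fc <- build_L(ws, m$w_ref)
    r_w <- forwardsolve(fc$chol, r_raw)
    sw_raw[s] <- stats::shapiro.test(r_raw)$p.value
    sw_weighted[s] <- stats::shapiro.test(r_w)$p.value
    pooled <- c(pooled, r_raw / stats::sd(r_raw))
  }
  # weighted residuals look Gaussian trial by trial
  expect_gte(mean(sw_weighted > 1e-3), 0.9)
  # raw residuals are distinctly non-Gaussian: decisive once pooled, and
  # visibly worse than the weighted ones per trial
  if (length(pooled) > 5000) pooled <- pooled[seq(1, length(pooled),
                                                  length.out = 5000)]
  expect_lt(stats::shapiro.test(pooled)$p.value, 1e-8)
  expect_lt(stats::median(sw_raw), stats::median(sw_weighted) / 100)
})
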