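test_that("bump profiles are compact, symmetric and unit norm", {
  for (m_t in c(1, 3, 8, 20)) {
    b <- bump_profile(m_t, dt = 0.05)
    v <- b$values
    expect_length(v, 2 * m_t + 1)
    expect_identical(v[1], 0)
    expect_identical(v[2 * m_t + 1], 0)
    expect_equal(v, rev(v))
    expect_equal(sum(v^2), 1, tolerance = 1e-14)
  }
  expect_error(bump_profile(0, 0.1), "at least 1")
})

test_that("aliasing estimator matches a direct single-mode DFT oracle", {
  M <- 96
  t_grid <- seq(0, 3, length.out = M + 1)
  u <- sin(2 * pi * t_grid / 3) + 0.3 * cos(4 * pi * t_grid / 3)
  s <- 3
  q <- floor(M / s)
  T_len <- 3
  dt <- t_grid[2] - t_grid[1]
  for (m_t in c(4, 9)) {
    psi <- bump_profile(m_t, dt)$values
    centers <- (m_t + 1):(M + 1 - m_t)
    oracle <- vapply(centers, function(cc) {
      prod <- numeric(M + 1)
      prod[(cc - m_t):(cc + m_t)] <- psi * u[(cc - m_t):(cc + m_t)]
      # truncated aliasing sum over modes n = -1, +1 of the coarsened grid
      F <- function(n) (dt / sqrt(T_len)) *
        sum(prod[1:M] * exp(-2i * pi * n * q * (0:(M - 1)) / M))
      Re((2i * pi / sqrt(T_len)) * (q * F(1) - q * F(-1)))
    }, numeric(1))
    got <- wendyr:::ehat_int_signed(matrix(u, ncol = 1), m_t, q, M, T_len, 9)
    expect_equal(drop(got), oracle, tolerance = 1e-12)
    # aggregate equals the mean over translates of summed squares
    expect_equal(ehat_rms(u, t_grid, m_t, s = s), mean(oracle^2),
                 tolerance = 1e-12)
  }
  expect_error(ehat_rms(u, t_grid, 4, s = 5), "\\(2, 4\\)")
  expect_error(ehat_rms(u, t_grid, 60), "does not fit")
})

test_that("estimator decays spectrally fast on constant data", {
  # constant data have zero true quadrature error; the single-mode estimate
  # inherits only the bump's own Fourier tail, which collapses with radius
  t_grid <- seq(0, 2, length.out = 65)
  vals <- vapply(c(8, 16, 24), function(r) ehat_rms(rep(2.5, 65), t_grid, r),
                 numeric(1))
  expect_true(all(diff(log(vals)) < -5))
  expect_lt(vals[3], 1e-10)
})

test_that("aliasing estimator is unbiased with variance within its bound", {
  set.seed(31)
  M <- 128
  T_len <- 4
  t_grid <- seq(0, T_len, length.out = M + 1)
  u_star <- exp(sin(2 * pi * t_grid / T_len))
  sigma <- 0.2
  m_t <- 7
  q <- floor(M / 3)
  clean <- wendyr:::ehat_int_signed(matrix(u_star, ncol = 1), m_t, q, M,
                                    T_len, 9)
  n_mc <- 400
  samples <- replicate(n_mc, {
    noisy <- u_star + stats::rnorm(M + 1, sd = sigma)
    wendyr:::ehat_int_signed(matrix(noisy, ncol = 1), m_t, q, M, T_len, 9)[, 1]
  })
  mc_mean <- rowMeans(samples)
  mc_sd <- apply(samples, 1, stats::sd)
  # unbiasedness: Monte-Carlo mean within ~4 standard errors, per translate
  expect_true(all(abs(mc_mean - clean[, 1]) < 4.5 * mc_sd / sqrt(n_mc)))
  # variance bound sigma^2 (4 pi q / M)^2, checked at 3x for sampling slack
  bound <- sigma^2 * (4 * pi * q / M)^2
  expect_true(all(mc_sd^2 < 3 * bound))
})

test_that("estimated error bounds the true quadrature error for small radii", {
  m <- get_model("logistic")
  ts <- fx_truth("logistic", 512)
  M <- length(ts$t) - 1
  dt <- ts$dt
  q <- floor(M / 3)
  u <- ts$U[, 1]
  udot <- m$rhs(u, m$w_ref)
  for (m_t in c(3, 5, 8)) {
    psi <- bump_profile(m_t, dt)$values
    dpsi <- fx_bump_deriv(m_t, dt)
    centers <- seq(m_t + 1, M + 1 - m_t, by = 7)
    e_true <- vapply(centers, function(cc) {
      idx <- (cc - m_t):(cc + m_t)
      phi <- dphi <- numeric(M + 1)
      phi[idx] <- psi
      dphi[idx] <- dpsi
      sum((phi[1:M] * udot[1:M] + dphi[1:M] * u[1:M]) * dt)
    }, numeric(1))
    e_hat <- wendyr:::ehat_int_signed(matrix(u, ncol = 1), m_t, q, M,
                                      M * dt, 9)[centers - m_t, 1]
    expect_true(mean(abs(e_true) <= abs(e_hat) * (1 + 1e-6)) > 0.9)
  }
})

test_that("two-segment changepoint matches exhaustive search", {
  # exact kink is recovered
  y <- c(seq(10, 2, by = -2), rep(2, 6))   # kink at index 5
  expect_equal(changepoint_index(y), 5)
  # a globally linear series falls back to the first interior index
  expect_equal(changepoint_index(seq(1, 10)), 2)
  expect_error(changepoint_index(c(1, 2, 3)), "at least 4")
  # random series against a brute-force lm-based oracle
  set.seed(41)
  for (rep in 1:10) {
    y <- cumsum(stats::rnorm(15))
    n <- length(y)
    x <- seq_len(n)
    tot <- vapply(2:(n - 1), function(k) {
      f1 <- stats::lm.fit(cbind(1, x[1:k]), y[1:k])
      f2 <- stats::lm.fit(cbind(1, x[k:n]), y[k:n])
      sum(f1$residuals^2) + sum(f2$residuals^2)
    }, numeric(1))
    expect_equal(changepoint_index(y), (2:(n - 1))[which.min(tot)])
  }
})

test_that("minimum radius tracks the noise level", {
  ts <- fx_truth("logistic", 512)
  lo <- corrupt(ts, noise_spec(1e-6, 7))
  hi <- corrupt(ts, noise_spec(1e-1, 7))
  r_lo <- select_min_radius(lo$U, lo$t)$min_radius
  r_hi <- select_min_radius(hi$U, hi$t)$min_radius
  # cleaner data demand more accurate integration, hence a larger radius
  expect_gt(r_lo, r_hi)
  # degenerate flat profile defaults to the first candidate
  flat <- select_min_radius(rep(0, 65), seq(0, 1, length.out = 65),
                            candidate_radii = c(2, 4, 8, 12))
  expect_equal(flat$min_radius, 2)
  expect_error(select_min_radius(lo$U, lo$t, candidate_radii = c(2, 4, 8)),
               "at least 4")
})

test_that("orthonormal basis has orthonormal, boundary-vanishing rows", {
  t_grid <- seq(0, 5, length.out = 129)
  basis <- orthonormal_basis(t_grid, 5)
  expect_gte(basis$K, 1)
  P <- basis$phi %*% t(basis$phi)
  expect_lt(max(abs(P - diag(basis$K))), 1e-10)
  expect_true(all(abs(basis$phi[, 1]) < 1e-12))
  expect_true(all(abs(basis$phi[, 129]) < 1e-12))
  # scales that cannot fit are dropped but the base scale survives
  small <- orthonormal_basis(seq(0, 1, length.out = 33), 8)
  expect_true(all(small$radii <= 15))
  expect_error(orthonormal_basis(seq(0, 1, length.out = 17), 10),
               "smaller")
})

test_that("spectral derivatives match high-order finite differences", {
  t_grid <- seq(0, 5, length.out = 257)
  dt <- t_grid[2] - t_grid[1]
  basis <- orthonormal_basis(t_grid, 8)
  # 4th-order central difference on interior points
  w4 <- c(1, -8, 0, 8, -1) / (12 * dt)
  for (k in seq_len(min(basis$K, 4))) {
    row <- basis$phi[k, ]
    fd <- stats::filter(row, rev(w4), method = "convolution", sides = 2)
    interior <- 3:(length(row) - 2)
    expect_equal(basis$dphi[k, interior], fd[interior],
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("refining the grid does not worsen the aliasing estimate", {
  f <- function(t) exp(sin(2 * pi * t / 4)) - 1
  a_phys <- 0.5
  v1 <- ehat_rms(f(seq(0, 4, length.out = 257)),
                 seq(0, 4, length.out = 257), round(a_phys / (4 / 256)))
  v2 <- ehat_rms(f(seq(0, 4, length.out = 513)),
                 seq(0, 4, length.out = 513), round(a_phys / (4 / 512)))
  expect_lte(v2, v1)
})
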