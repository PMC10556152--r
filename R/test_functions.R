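# Data-adaptive test functions: C-infinity bump profiles, minimum-radius
# selection via a Fourier aliasing estimate of the quadrature error, and an
# orthonormal multiscale basis obtained from the SVD of stacked convolution
# matrices.

#' Sample a compactly supported C-infinity bump test function
#'
#' The profile is psi(t; a) = C exp(-eta / [1 - (t/a)^2]_+) with half-support
#' a = m_t * dt, sampled on its 2*m_t + 1 support points and normalized to
#' unit discrete l2 norm. It vanishes identically at the support endpoints,
#' so integration by parts on [0, T] carries no boundary terms.
#'
#' @param m_t integer support radius in grid steps (>= 1)
#' @param dt grid step
#' @param eta shape parameter (default 9; estimates are insensitive over a
#'   wide range)
#' @return list with `values` (length 2*m_t+1), `radius`, `a`, `eta`
#' @export
bump_profile <- function(m_t, dt = 1, eta = 9) {
  if (m_t < 1) stop("bump radius m_t must be at least 1")
  if (dt <= 0 || eta <= 0) stop("dt and eta must be positive")
  x <- (-m_t):m_t / m_t          # t/a on the support grid
  v <- numeric(2 * m_t + 1)
  inside <- abs(x) < 1
  v[inside] <- exp(-eta / (1 - x[inside]^2))
  v <- v / sqrt(sum(v^2))
  list(values = v, radius = as.integer(m_t), a = m_t * dt, eta = eta)
}

#' Aliasing-based estimate of the weak-form integration error
#'
#' Translates of the radius-`m_t` bump are placed at every grid index where
#' the support fits. For each translate and each state the single DFT mode
#' floor(M/s) of the pointwise product phi_k * U^(i) yields the estimate
#' -(4 pi floor(M/s) / sqrt(T)) Im{F_hat}; the returned scalar is the mean
#' over translates of the summed squared estimates (all states).
#'
#' The estimator is computable from noisy data, is unbiased for its
#' noiseless value, and has variance insensitive to the radius, so its
#' log flattens once quadrature error drops below the noise floor.
#'
#' @param U (M+1) x d data matrix (vector allowed for d = 1)
#' @param t_grid uniform time grid of length M+1
#' @param m_t bump radius in grid steps
#' @param s coarsening factor, 2 < s < 4 (default 3)
#' @param eta bump shape parameter
#' @return mean over translates of the summed squared per-state estimates
#' @export
ehat_rms <- function(U, t_grid, m_t, s = 3, eta = 9) {
  if (s <= 2 || s >= 4) stop("coarsening factor s must lie in (2, 4)")
  if (is.null(dim(U))) U <- matrix(U, ncol = 1)
  M <- length(t_grid) - 1
  if (2 * m_t + 1 > M + 1) stop("bump support (radius ", m_t,
                                ") does not fit a grid of ", M + 1, " points")
  dt <- t_grid[2] - t_grid[1]
  T_len <- M * dt
  q <- floor(M / s)
  e2 <- ehat_int_sq(U, m_t, q, M, T_len, eta)
  mean(rowSums(e2))
}

# Signed aliasing estimates: K x d matrix, K = M+1-2*m_t translates.
ehat_int_signed <- function(U, m_t, q, M, T_len, eta) {
  psi <- bump_profile(m_t, T_len / M, eta)$values
  Mp1 <- M + 1
  ph <- 2 * pi * q * (0:M) / M
  valid <- (m_t + 1):(Mp1 - m_t)
  out <- matrix(0, length(valid), ncol(U))
  for (i in seq_len(ncol(U))) {
    x <- U[, i]
    # Im{ sum_m psi(m - c) x_m e^{-i ph_m} } over centers c via moving sums;
    # psi is symmetric so filter() convolution equals correlation.
    im <- stats::filter(-x * sin(ph), psi, method = "convolution", sides = 2)
    imF <- (T_len / M / sqrt(T_len)) * im[valid]
    out[, i] <- -(4 * pi * q / sqrt(T_len)) * imF
  }
  out
}

ehat_int_sq <- function(U, m_t, q, M, T_len, eta) {
  ehat_int_signed(U, m_t, q, M, T_len, eta)^2
}

#' Two-segment least-squares changepoint of a scalar series
#'
#' Fits one line to y[1..k] and another to y[k..n] (the split point is shared)
#' and returns the interior k minimizing the total sum of squared errors;
#' ties break toward smaller k. This deterministic O(n) rule locates the knee
#' between two roughly linear regimes.
#'
#' @param y numeric series of length >= 4
#' @return the split index k in 2..(n-1)
#' @export
changepoint_index <- function(y) {
  n <- length(y)
  if (n < 4) stop("changepoint needs at least 4 points")
  x <- seq_len(n)
  # zero-padded prefix sums for O(1) line-fit SSE on any window
  cy <- c(0, cumsum(y)); cyy <- c(0, cumsum(y^2)); cxy <- c(0, cumsum(x * y))
  cx <- c(0, cumsum(x)); cxx <- c(0, cumsum(x^2))
  seg_sse <- function(a, b) {
    m <- b - a + 1
    Sy <- cy[b + 1] - cy[a]
    Syy <- cyy[b + 1] - cyy[a]
    Sxy <- cxy[b + 1] - cxy[a]
    Sx <- cx[b + 1] - cx[a]
    Sxx <- cxx[b + 1] - cxx[a]
    vxx <- Sxx - Sx^2 / m
    vxy <- Sxy - Sx * Sy / m
    vyy <- Syy - Sy^2 / m
    sse <- vyy - ifelse(vxx > 0, vxy^2 / vxx, 0)
    pmax(sse, 0)
  }
  ks <- 2:(n - 1)
  tot <- seg_sse(rep(1L, length(ks)), ks) + seg_sse(ks, rep(n, length(ks)))
  ks[which.min(tot)]
}

#' Select the minimum usable test-function radius from data
#'
#' Computes the aliasing error estimate over candidate radii and returns the
#' radius at the changepoint of its log: below the changepoint the estimate
#' is dominated by quadrature error, above it by measurement noise, so radii
#' at or beyond the changepoint integrate accurately relative to the noise.
#' Cleaner data push the changepoint (and hence the minimum radius) to the
#' right.
#'
#' @inheritParams ehat_rms
#' @param candidate_radii strictly increasing integer radii (>= 4 of them);
#'   default ~25 log-spaced integers between 2 and floor((M-1)/4)
#' @return list with `candidate_radii`, `ehat_rms`, `min_radius`, `s`
#' @export
select_min_radius <- function(U, t_grid, s = 3, candidate_radii = NULL,
                              eta = 9) {
  M <- length(t_grid) - 1
  if (is.null(candidate_radii)) candidate_radii <- default_radii(M)
  candidate_radii <- as.integer(candidate_radii)
  if (length(candidate_radii) < 4)
    stop("need at least 4 candidate radii for changepoint detection")
  if (is.unsorted(candidate_radii, strictly = TRUE))
    stop("candidate radii must be strictly increasing")
  if (2 * max(candidate_radii) + 1 > M + 1)
    stop("largest candidate radius does not fit the grid")
  e <- vapply(candidate_radii, function(r) ehat_rms(U, t_grid, r, s, eta),
              numeric(1))
  if (diff(range(e)) == 0) {
    k <- 1L  # no quadrature-error regime to cut away
  } else {
    k <- changepoint_index(log(pmax(e, .Machine$double.xmin)))
  }
  list(candidate_radii = candidate_radii, ehat_rms = e,
       min_radius = candidate_radii[k], s = s)
}

default_radii <- function(M) {
  hi <- max(floor((M - 1) / 4), 3)
  unique(round(exp(seq(log(2), log(hi), length.out = 25))))
}

#' Orthonormal multiscale test-function basis
#'
#' Stacks the convolution matrices of the bump at radii
#' `multipliers * min_radius` (scales whose radius exceeds floor((M-1)/2)
#' grid steps are dropped; the base scale is always kept), takes the SVD,
#' truncates at the changepoint of the cumulative singular-value sum, and
#' returns the leading right singular vectors as the test-function matrix
#' `phi` together with its spectral time derivative `dphi`.
#'
#' Rows of `phi` are orthonormal and vanish at both ends of the grid, so
#' Fourier differentiation (periodic extension with period T + dt, Nyquist
#' mode zeroed on even lengths) is spectrally accurate.
#'
#' @param t_grid uniform time grid (length M+1)
#' @param min_radius base radius in grid steps
#' @param multipliers scale multipliers (default 1, 2, 4, 8)
#' @param eta bump shape parameter
#' @return list with `phi` (K x (M+1)), `dphi`, `K`, `radii`,
#'   `singular_values`
#' @export
orthonormal_basis <- function(t_grid, min_radius, multipliers = c(1, 2, 4, 8),
                              eta = 9) {
  Mp1 <- length(t_grid)
  M <- Mp1 - 1
  dt <- t_grid[2] - t_grid[1]
  if (min_radius < 1) stop("min_radius must be at least 1")
  radii <- unique(as.integer(multipliers) * as.integer(min_radius))
  keep <- radii <= floor((M - 1) / 2) & (Mp1 - 2 * radii) >= 1
  if (!keep[1])
    stop("no test-function scale fits a grid of ", Mp1,
         " points with base radius ", min_radius,
         "; use a smaller radius or more data")
  radii <- radii[keep]
  blocks <- lapply(radii, function(r) {
    psi <- bump_profile(r, dt, eta)$values
    nk <- Mp1 - 2 * r
    B <- matrix(0, nk, Mp1)
    for (k in seq_len(nk)) B[k, k:(k + 2 * r)] <- psi
    B
  })
  Psi <- do.call(rbind, blocks)
  sv <- svd(Psi)
  r_eff <- sum(sv$d > max(dim(Psi)) * .Machine$double.eps * sv$d[1])
  K <- if (r_eff < 4) r_eff else min(changepoint_index(cumsum(sv$d[seq_len(r_eff)])), r_eff)
  K <- max(K, 1L)
  phi <- t(sv$v[, seq_len(K), drop = FALSE])
  dphi <- t(apply(phi, 1, spectral_derivative, dt = dt))
  if (K == 1) dphi <- matrix(dphi, 1, Mp1)
  list(phi = phi, dphi = dphi, K = K, radii = radii,
       singular_values = sv$d, t_grid = t_grid)
}

#' Spectral (Fourier) derivative of a periodic sample vector
#'
#' Treats `v` as one period of a smooth periodic function sampled at n points
#' with spacing `dt` (period n * dt); the Nyquist mode is zeroed for even n.
#'
#' @param v sample vector
#' @param dt grid spacing
#' @export
spectral_derivative <- function(v, dt) {
  n <- length(v)
  P <- n * dt
  idx <- 0:(n - 1)
  k <- ifelse(idx > n / 2, idx - n, idx)
  if (n %% 2 == 0) k[idx == n / 2] <- 0
  Re(stats::fft(stats::fft(v) * (2i * pi * k / P), inverse = TRUE)) / n
}
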