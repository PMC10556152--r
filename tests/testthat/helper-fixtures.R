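# Shared simulation cache so expensive reference solves run once per session.
.fx <- new.env(parent = emptyenv())

fx_truth <- function(name, n_points) {
  key <- paste0(name, "_", n_points)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- simulate_truth(get_model(name), n_points)
  .fx[[key]]
}

fx_noisy <- function(name, n_fine, factor, sigma_nr, seed) {
  subsample_series(corrupt(fx_truth(name, n_fine), noise_spec(sigma_nr, seed)),
                   factor)
}

# Analytic derivative of the unit-l2 bump profile (for quadrature oracles).
fx_bump_deriv <- function(m_t, dt, eta = 9) {
  x <- (-m_t):m_t / m_t
  a <- m_t * dt
  v <- numeric(2 * m_t + 1)
  inside <- abs(x) < 1
  v[inside] <- exp(-eta / (1 - x[inside]^2))
  nrm <- sqrt(sum(v^2))
  dv <- numeric(2 * m_t + 1)
  dv[inside] <- v[inside] * (-2 * eta * x[inside] / (1 - x[inside]^2)^2) / a
  dv / nrm
}

fine_points_for_test <- function(name) if (name == "logistic") 512L else 1024L
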