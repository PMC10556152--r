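# Weak-form linear system: G w = b up to residual, with trapezoidal
# quadrature folded into the test-function matrices, plus the first-order
# errors-in-variables matrix L mapping measurement noise to residual
# perturbations.

#' Assemble the weak-form regression system
#'
#' For each state i with active features, the block of G is
#' (phi Q) Theta_i(U) restricted to the active features of that state, and
#' the block of b is -(dphi Q) U[, i], where Q is the diagonal trapezoid
#' weight matrix (dt everywhere, dt/2 at the two endpoints). States share no
#' columns, so G is block diagonal along the parameter slots.
#'
#' @param basis output of [orthonormal_basis()]
#' @param model a `wendy_model`
#' @param data a `wendy_series` (see [simulate_truth()]) or list with
#'   elements `t` and `U`
#' @return a `wendy_system`: list with `G`, `b`, `quad`, `phi_q`, `dphi_q`,
#'   `slot_map`, `K`, `model`, `data`
#' @export
assemble_weak_system <- function(basis, model, data) {
  U <- as_state_matrix(data$U, model$d)
  t_grid <- data$t
  Mp1 <- length(t_grid)
  if (ncol(basis$phi) != Mp1)
    stop("basis grid length (", ncol(basis$phi),
         ") does not match the data (", Mp1, " points)")
  dt <- t_grid[2] - t_grid[1]
  quad <- rep(dt, Mp1)
  quad[c(1, Mp1)] <- dt / 2
  phi_q <- sweep(basis$phi, 2, quad, "*")
  dphi_q <- sweep(basis$dphi, 2, quad, "*")
  Th <- features_matrix(model, U)
  K <- nrow(phi_q)
  sv_phi <- svd(basis$phi, nu = 0, nv = 0)$d
  if (sum(sv_phi > max(dim(basis$phi)) * .Machine$double.eps * sv_phi[1]) < K)
    stop("weak-form system is singular: test-function rows are not ",
         "linearly independent (rank(phi) < K)")
  active_states <- which(lengths(model$terms) > 0)
  G <- matrix(0, K * length(active_states), model$p)
  b <- numeric(K * length(active_states))
  col0 <- 0L
  for (bi in seq_along(active_states)) {
    i <- active_states[bi]
    js <- model$terms[[i]]
    rows <- (bi - 1L) * K + seq_len(K)
    G[rows, col0 + seq_along(js)] <- phi_q %*% Th[, js, drop = FALSE]
    b[rows] <- -drop(dphi_q %*% U[, i])
    col0 <- col0 + length(js)
  }
  rk <- qr(G)$rank
  if (rk < model$p) {
    notes <- character(0)
    for (i in active_states) {
      if (qr(Th[, model$terms[[i]], drop = FALSE])$rank < length(model$terms[[i]]))
        notes <- c(notes, sprintf(
          "features of state %d are linearly dependent along the trajectory (rank(Theta_%d) < J_%d)", i, i, i))
    }
    if (K < max(lengths(model$terms)))
      notes <- c(notes, "fewer test functions than features (K < J)")
    if (length(notes) == 0)
      notes <- "G is numerically rank deficient"
    stop("weak-form system is singular (rank ", rk, " < ", model$p, "): ",
         paste(notes, collapse = "; "))
  }
  structure(list(G = G, b = b, quad = quad, phi_q = phi_q, dphi_q = dphi_q,
                 slot_map = model$slot_map, K = K,
                 active_states = active_states,
                 model = model, data = list(t = t_grid, U = U)),
            class = "wendy_system")
}

#' Weak-form residual r(U, w) = G w - b
#'
#' @param ws a `wendy_system`
#' @param w parameter vector
#' @export
weak_residual <- function(ws, w) {
  if (length(w) != ncol(ws$G))
    stop("parameter vector has length ", length(w), "; expected ", ncol(ws$G))
  drop(ws$G %*% w - ws$b)
}

#' First-order noise-to-residual map L and regularized covariance factor
#'
#' L is the Jacobian of the weak-form residual with respect to the vectorized
#' measurement noise (states stacked column-wise): the feature-gradient term
#' contracts the per-state coefficients against the quadrature-weighted phi
#' rows, and the derivative term adds the quadrature-weighted dphi block on
#' each state's own noise column. The commutation of noise indices is applied
#' as direct index bookkeeping; no permutation matrix is formed.
#'
#' The residual covariance (up to sigma^2) is regularized as
#' C = (1 - alpha) L L^T + alpha I and returned with its lower Cholesky
#' factor; if factorization fails, alpha is increased by a factor of 100
#' once before aborting.
#'
#' @param ws a `wendy_system`
#' @param w parameter vector at which to linearize
#' @param alpha covariance relaxation weight in [0, 1] (default 1e-10;
#'   alpha = 1 reduces the weighted solve to ordinary least squares)
#' @return list with `L`, `C`, `chol` (lower triangular), `alpha`
#' @export
build_L <- function(ws, w, alpha = 1e-10) {
  model <- ws$model
  if (length(w) != model$p)
    stop("parameter vector has length ", length(w), "; expected ", model$p)
  U <- ws$data$U
  Mp1 <- nrow(U)
  d <- model$d
  K <- ws$K
  grads <- feature_jacobian(model, U)
  nb <- length(ws$active_states)
  L <- matrix(0, K * nb, Mp1 * d)
  col_idx <- function(cc) (cc - 1L) * Mp1 + seq_len(Mp1)
  slot0 <- 0L
  for (bi in seq_len(nb)) {
    i <- ws$active_states[bi]
    js <- model$terms[[i]]
    wi <- w[slot0 + seq_along(js)]
    rows <- (bi - 1L) * K + seq_len(K)
    for (cc in seq_len(d)) {
      Dic <- numeric(Mp1)
      for (jj in seq_along(js)) {
        gcol <- grads[[js[jj]]][, cc]
        if (wi[jj] != 0 && any(gcol != 0)) Dic <- Dic + wi[jj] * gcol
      }
      blk <- NULL
      if (any(Dic != 0)) blk <- sweep(ws$phi_q, 2, Dic, "*")
      if (cc == i) blk <- if (is.null(blk)) ws$dphi_q else blk + ws$dphi_q
      if (!is.null(blk)) L[rows, col_idx(cc)] <- blk
    }
    slot0 <- slot0 + length(js)
  }
  covariance_factor(L, alpha)
}

covariance_factor <- function(L, alpha) {
  make_C <- function(a) {
    C <- (1 - a) * tcrossprod(L)
    diag(C) <- diag(C) + a
    C
  }
  C <- make_C(alpha)
  ch <- tryCatch(t(chol(C)), error = function(e) NULL)
  if (is.null(ch)) {
    alpha <- alpha * 100
    C <- make_C(alpha)
    ch <- tryCatch(t(chol(C)), error = function(e)
      stop("covariance factorization failed even after relaxing alpha to ",
           alpha, "; increase alpha"))
  }
  list(L = L, C = C, chol = ch, alpha = alpha)
}
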