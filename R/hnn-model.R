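# The 4-neuron memristive Hopfield neural network under electromagnetic
# radiation.  State (x, y, z, u) are the membrane voltages of neurons 1-4
# and w is the magnetic flux through the membrane of neuron 2; the
# radiation-induced current k*y*(a + b*w) feeds back on neuron 2 only.

#' Synaptic weight matrix of the 4-neuron Hopfield network
#'
#' The fixed 4x4 weight matrix of the model.  Rows are the receiving
#' neurons; entry `W[i, j]` multiplies `tanh` of neuron `j`'s voltage in the
#' equation of neuron `i`.
#'
#' @return A 4x4 numeric matrix.
#' @export
hnn_weights <- function() {
  matrix(c(2.5, 1.5,  0, -4.5,
           0,   2.2,  2,  0,
           2.3, -1.5, 0,  4,
           4,   1.3,  0,  0.6),
         nrow = 4, byrow = TRUE)
}

#' Parameters of the memristive Hopfield network
#'
#' @param a,b Electromagnetic-radiation parameters (memductance offset and
#'   flux slope of the coupling memristor), dimensionless.
#' @param k Feedback strength of the radiation-induced current.
#' @param p Flux gain from the membrane potential of neuron 2.
#' @param g Flux leakage rate.
#' @param W Synaptic weight matrix; defaults to [hnn_weights()] and may be
#'   overridden for generalised topologies.
#' @return An object of class `hnn_params`.
#' @export
hnn_params <- function(a = 0.78, b = 0.1, k = 0.1, p = 0.3, g = 0.8,
                       W = hnn_weights()) {
  W <- as.matrix(W)
  vals <- c(a = a, b = b, k = k, p = p, g = g)
  if (!all(is.finite(vals)) || !all(is.finite(W)))
    stop("all parameters must be finite", call. = FALSE)
  if (!identical(dim(W), c(4L, 4L)))
    stop("'W' must be a 4x4 matrix", call. = FALSE)
  structure(list(a = a, b = b, k = k, p = p, g = g, W = W),
            class = "hnn_params")
}

#' @export
print.hnn_params <- function(x, ...) {
  cat(sprintf("HNN parameters: a = %g, b = %g, k = %g, p = %g, g = %g\n",
              x$a, x$b, x$k, x$p, x$g))
  invisible(x)
}

#' Vector field of the memristive Hopfield network
#'
#' The five right-hand sides of the model: neurons 1-4 follow
#' \eqn{-x_i + \sum_j W_{ij}\tanh(x_j)} with the radiation current
#' \eqn{k y (a + b \omega)} added to neuron 2, and the flux obeys
#' \eqn{p y - g \omega}.  The origin is an equilibrium for every parameter
#' set, since every term vanishes there.
#'
#' @param state Numeric 5-vector `(x, y, z, u, w)`.
#' @param params An [hnn_params()].
#' @return Numeric 5-vector.
#' @export
hnn_vector_field <- function(state, params = hnn_params()) {
  stopifnot(length(state) == 5L, inherits(params, "hnn_params"))
  th <- tanh(state[1:4])
  f <- c(drop(params$W %*% th) - state[1:4], 0)
  f[2] <- f[2] + params$k * state[2] * (params$a + params$b * state[5])
  f[5] <- params$p * state[2] - params$g * state[5]
  f
}

#' Linear/nonlinear decomposition of the memristive Hopfield network
#'
#' Splits the model into the form the series integrator consumes: a linear
#' matrix with diagonal `(-1, k*a - 1, -1, -1, -g)` and flux coupling `p` at
#' entry (5, 2); a nonlinear part holding every `tanh` term of the weight
#' matrix plus the bilinear radiation term `k*b*w*y`; and a zero constant
#' vector.  The recomposition equals [hnn_vector_field()] at every state.
#'
#' @param params An [hnn_params()].
#' @param order Fractional order `q` in (0, 1].
#' @return A [caputo_system()] (also of class `hnn_system`) carrying the
#'   parameters in `$params`.
#' @export
hnn_decomposition <- function(params = hnn_params(), order = 0.478) {
  stopifnot(inherits(params, "hnn_params"))
  L <- diag(c(-1, params$k * params$a - 1, -1, -1, -params$g))
  L[5, 2] <- params$p
  terms <- list()
  for (i in 1:4)
    for (j in 1:4)
      if (params$W[i, j] != 0)
        terms[[length(terms) + 1L]] <-
          list(row = i, type = "tanh", arg = j, coef = params$W[i, j])
  if (params$k * params$b != 0)
    terms[[length(terms) + 1L]] <-
      list(row = 2L, type = "prod", args = c(5L, 2L),
           coef = params$k * params$b)
  sys <- caputo_system(L, terms, order = order)
  sys$params <- params
  class(sys) <- c("hnn_system", class(sys))
  sys
}

#' Construct the memristive Hopfield system
#'
#' Convenience wrapper around [hnn_params()] and [hnn_decomposition()].
#'
#' @inheritParams hnn_params
#' @param order Fractional order `q` in (0, 1].
#' @return An `hnn_system` (a [caputo_system()] with parameters attached).
#' @examples
#' sys <- hnn_system(order = 0.478)
#' adm_step(sys, c(1, 1, -1, 0, 0), h = 1e-3)
#' @export
hnn_system <- function(a = 0.78, b = 0.1, k = 0.1, p = 0.3, g = 0.8,
                       order = 0.478, W = hnn_weights()) {
  hnn_decomposition(hnn_params(a = a, b = b, k = k, p = p, g = g, W = W),
                    order = order)
}

#' @export
print.hnn_system <- function(x, ...) {
  cat(sprintf("Memristive Hopfield network (Caputo order q = %g)\n", x$order))
  cat(sprintf("  a = %g, b = %g, k = %g, p = %g, g = %g\n", x$params$a,
              x$params$b, x$params$k, x$params$p, x$params$g))
  invisible(x)
}

#' Simulate a Caputo system from an initial state
#'
#' `simulate` method dispatching to the Adomian series integrator; `nsim` is
#' the number of integration steps.  The pipeline is fully deterministic, so
#' `seed` is ignored.
#'
#' @param object A [caputo_system()].
#' @param nsim Number of steps.
#' @param seed Ignored (deterministic integrator).
#' @param state0 Initial state.
#' @param h Step size.
#' @param M Series truncation order.
#' @param n_discard Transient marker passed to [adm_integrate()].
#' @param ... Unused.
#' @return An `adm_trajectory`.
#' @export
simulate.caputo_system <- function(object, nsim = 1000L, seed = NULL,
                                   state0 = NULL, h = 1e-3, M = 3L,
                                   n_discard = 0L, ...) {
  if (is.null(state0))
    state0 <- if (object$dimension == 5L) c(1, 1, -1, 0, 0)
              else numeric(object$dimension)
  adm_integrate(object, state0, h = h, n_steps = nsim, M = M,
                n_discard = n_discard)
}

#' Jacobian of the memristive Hopfield network
#'
#' Analytic Jacobian of [hnn_vector_field()] at a state, with
#' \eqn{\mathrm{sech}^2(v)} computed as \eqn{1 - \tanh^2(v)} (never
#' negative).  At the origin the flux column has `-g` as its only nonzero
#' entry, so `-g` is an exact eigenvalue there.
#'
#' @inheritParams hnn_vector_field
#' @return A 5x5 numeric matrix.
#' @export
hnn_jacobian <- function(state, params = hnn_params()) {
  stopifnot(length(state) == 5L, inherits(params, "hnn_params"))
  s2 <- 1 - tanh(state[1:4])^2
  J <- matrix(0, 5, 5)
  J[1:4, 1:4] <- params$W * rep(s2, each = 4)
  diag(J)[1:4] <- diag(J)[1:4] - 1
  J[2, 2] <- J[2, 2] + params$k * (params$a + params$b * state[5])
  J[2, 5] <- params$b * params$k * state[2]
  J[5, 2] <- params$p
  J[5, 5] <- -params$g
  J
}
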