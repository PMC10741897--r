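# Generic Adomian-decomposition integrator for Caputo systems.
#
# A Caputo system D^q x = L x + N(x) + g with 0 < q <= 1 is advanced over a
# step h by a truncated generalized power series in t^q.  Internally all
# series are stored as "plain" coefficients a_i = c_i / Gamma(i q + 1) so
# that t^(iq) * t^(jq) = t^((i+j)q) multiplies exactly; the classical
# Adomian coefficients c_i are recovered by multiplying back the Gamma
# factors.  With the initial state constant in time, the formal power-series
# recursion is term-for-term identical to the Adomian recursion
# x_i = J^q L x_{i-1} + J^q A_{i-1}.

#' Power-rule Gamma factor of the fractional series recursion
#'
#' Returns \eqn{\Gamma(iq+1)/\Gamma((i+1)q+1)}, the factor that maps the
#' order-\eqn{i} series coefficient of the vector field to the
#' order-\eqn{i+1} coefficient of the state under the Riemann--Liouville
#' \eqn{q}-integral of a power function.  Evaluated through `lgamma` so that
#' large orders do not overflow.
#'
#' @param i Non-negative integer series order.
#' @param q Fractional order in (0, 1].
#' @return A numeric scalar (vectorised over `i`).
#' @examples
#' gamma_ratio(0, 1)    # 1
#' gamma_ratio(1, 1)    # 1/2
#' gamma_ratio(1, 0.478)
#' @export
gamma_ratio <- function(i, q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q > 1)
    stop("'q' must be a finite fractional order in (0, 1]", call. = FALSE)
  if (any(i < 0) || any(i != floor(i)))
    stop("'i' must be a non-negative integer", call. = FALSE)
  exp(lgamma(i * q + 1) - lgamma((i + 1) * q + 1))
}

#' Truncated fractional power series of a state component
#'
#' A `tau_series` holds the coefficients `c_0..c_M` of the local expansion
#' \eqn{x(h) = \sum_i c_i h^{iq} / \Gamma(iq+1)} of one state component over
#' a step of a Caputo system of order `q`.
#'
#' @param coeffs Numeric vector of coefficients `c_0..c_M` (Gamma-scaled
#'   convention).
#' @param order Fractional order in (0, 1].
#' @return An object of class `tau_series`.
#' @seealso [tau_value()], [series_product()], [series_tanh()]
#' @export
tau_series <- function(coeffs, order) {
  if (!is.numeric(coeffs) || length(coeffs) < 1L || !all(is.finite(coeffs)))
    stop("'coeffs' must be a non-empty finite numeric vector", call. = FALSE)
  if (!is.numeric(order) || length(order) != 1L || !is.finite(order) ||
      order <= 0 || order > 1)
    stop("'order' must be in (0, 1]", call. = FALSE)
  structure(list(coeffs = as.numeric(coeffs), order = order,
                 M = length(coeffs) - 1L),
            class = "tau_series")
}

#' @export
print.tau_series <- function(x, ...) {
  cat(sprintf("Fractional power series in t^q (q = %g, truncation order %d)\n",
              x$order, x$M))
  cat("coefficients c_i (value = sum c_i h^(iq)/Gamma(iq+1)):\n")
  print(x$coeffs, ...)
  invisible(x)
}

# plain coefficients a_i = c_i / Gamma(i q + 1)
tau_plain <- function(ts) ts$coeffs / gamma((0:ts$M) * ts$order + 1)

tau_from_plain <- function(a, order)
  tau_series(a * gamma((seq_along(a) - 1L) * order + 1), order)

#' Evaluate a truncated fractional power series at a local time
#'
#' @param ts A [tau_series()].
#' @param h Local time (elapsed time since the expansion point), `h >= 0`.
#' @return The series value \eqn{\sum_i c_i h^{iq}/\Gamma(iq+1)}.
#' @export
tau_value <- function(ts, h) {
  stopifnot(inherits(ts, "tau_series"), h >= 0)
  sum(tau_plain(ts) * h^((0:ts$M) * ts$order))
}

#' Truncated Cauchy product of two fractional power series
#'
#' Multiplies two series that share the same fractional order.  The product
#' is computed on the plain-coefficient representation, where powers of
#' \eqn{t^q} multiply exactly, and is exact (in exact arithmetic) up to the
#' requested truncation order.
#'
#' @param u,v [tau_series()] objects with identical `order`.
#' @param M Truncation order of the product; defaults to the smaller input
#'   order.
#' @return A [tau_series()] of truncation order `M`.
#' @export
series_product <- function(u, v, M = min(u$M, v$M)) {
  stopifnot(inherits(u, "tau_series"), inherits(v, "tau_series"))
  if (u$order != v$order)
    stop("series orders differ; products are only defined for a shared q",
         call. = FALSE)
  if (M > min(u$M, v$M))
    stop("'M' exceeds the available truncation order", call. = FALSE)
  a <- tau_plain(u)
  b <- tau_plain(v)
  tau_from_plain(.series_product_cpp(a, b, as.integer(M)), u$order)
}

#' Formal composition of tanh with a fractional power series
#'
#' Computes the series of `tanh(u)` up to order `M` by the derivative
#' recursion \eqn{w' = (1 - w^2) u'} on plain coefficients, seeded with
#' `tanh` of the constant term.  This realises the Adomian polynomials of
#' the tanh activation: the order-\eqn{i} coefficient equals
#' \eqn{(1/i!)\, d^i/d\lambda^i \tanh(\sum_k \lambda^k a_k)} at
#' \eqn{\lambda = 0}.
#'
#' @param u A [tau_series()].
#' @param M Truncation order of the result (`M <= u$M`).
#' @return A [tau_series()] for `tanh(u)`.
#' @export
series_tanh <- function(u, M = u$M) {
  stopifnot(inherits(u, "tau_series"))
  if (M > u$M) stop("'M' exceeds the available truncation order", call. = FALSE)
  a <- tau_plain(u)
  tau_from_plain(.series_tanh_cpp(a, as.integer(M)), u$order)
}

#' Specify a Caputo fractional-order system for the series integrator
#'
#' A system \eqn{D^q x = L x + N(x) + g} is described by its linear matrix,
#' a list of scalar nonlinear primitives, a constant vector, and the
#' fractional order.  The nonlinearity is restricted to a fixed basis the
#' series engine can propagate exactly: `tanh` of a component and products
#' of two components.
#'
#' @param linear An `n x n` numeric matrix (the linear part `L`).
#' @param terms List of nonlinear terms.  Each term is a list with entries
#'   `row` (target equation), `coef`, and either `type = "tanh"` with `arg`
#'   (component index) or `type = "prod"` with `args` (two component
#'   indices).
#' @param constant Numeric `n`-vector `g` (defaults to zero).
#' @param order Fractional order `q` in (0, 1].
#' @return An object of class `caputo_system`.
#' @examples
#' # scalar D^q x = x
#' sys <- caputo_system(matrix(1), list(), order = 0.5)
#' adm_step(sys, 1, h = 0.01, M = 6)
#' @export
caputo_system <- function(linear, terms = list(), constant = NULL, order = 1) {
  linear <- as.matrix(linear)
  n <- nrow(linear)
  if (ncol(linear) != n || !all(is.finite(linear)))
    stop("'linear' must be a finite square matrix", call. = FALSE)
  if (is.null(constant)) constant <- numeric(n)
  if (length(constant) != n || !all(is.finite(constant)))
    stop("'constant' must be a finite vector matching the dimension",
         call. = FALSE)
  if (!is.numeric(order) || length(order) != 1L || !is.finite(order) ||
      order <= 0 || order > 1)
    stop("'order' must be in (0, 1]", call. = FALSE)
  tm <- matrix(0, nrow = length(terms), ncol = 5,
               dimnames = list(NULL, c("row", "type", "i", "j", "coef")))
  for (k in seq_along(terms)) {
    t <- terms[[k]]
    if (is.null(t$row) || is.null(t$type) || is.null(t$coef))
      stop("each nonlinear term needs 'row', 'type' and 'coef'", call. = FALSE)
    if (t$row < 1 || t$row > n) stop("term 'row' out of range", call. = FALSE)
    if (t$type == "tanh") {
      if (is.null(t$arg) || t$arg < 1 || t$arg > n)
        stop("tanh term needs a component index 'arg'", call. = FALSE)
      tm[k, ] <- c(t$row, 1, t$arg, 0, t$coef)
    } else if (t$type == "prod") {
      if (is.null(t$args) || length(t$args) != 2L ||
          any(t$args < 1) || any(t$args > n))
        stop("prod term needs two component indices 'args'", call. = FALSE)
      tm[k, ] <- c(t$row, 2, t$args[1], t$args[2], t$coef)
    } else stop(sprintf("unsupported nonlinear primitive '%s'", t$type),
                call. = FALSE)
  }
  structure(list(dimension = n, linear = linear, terms = terms,
                 terms_matrix = tm, constant = as.numeric(constant),
                 order = order),
            class = "caputo_system")
}

#' @export
print.caputo_system <- function(x, ...) {
  cat(sprintf("Caputo fractional-order system: dimension %d, order q = %g\n",
              x$dimension, x$order))
  cat(sprintf("  nonlinear terms: %d (%s)\n", length(x$terms),
              if (length(x$terms)) paste(unique(vapply(x$terms, `[[`, "", "type")),
                                         collapse = ", ") else "none"))
  invisible(x)
}

#' Evaluate the full vector field of a Caputo system
#'
#' Computes `L x + N(x) + g` at a state; this is the right-hand side the
#' series integrator expands, and the order-1 series coefficients returned
#' by [adm_coefficients()] equal it exactly at the expansion point.
#'
#' @param sys A [caputo_system()].
#' @param state Numeric state vector.
#' @return Numeric vector of the same length.
#' @export
vector_field <- function(sys, state) {
  stopifnot(inherits(sys, "caputo_system"),
            length(state) == sys$dimension)
  f <- drop(sys$linear %*% state) + sys$constant
  tm <- sys$terms_matrix
  for (k in seq_len(nrow(tm))) {
    v <- if (tm[k, "type"] == 1) tanh(state[tm[k, "i"]])
         else state[tm[k, "i"]] * state[tm[k, "j"]]
    f[tm[k, "row"]] <- f[tm[k, "row"]] + tm[k, "coef"] * v
  }
  f
}

#' Adomian series coefficients of the local expansion at a state
#'
#' Runs the Adomian recursion at `state0` and returns, per component, the
#' truncated expansion of the solution over the next step as a
#' [tau_series()].  The order-1 coefficients equal the vector field at
#' `state0`; a state at an equilibrium therefore yields all higher
#' coefficients zero.
#'
#' @param sys A [caputo_system()].
#' @param state0 Expansion state.
#' @param M Truncation order (number of terms minus one), `M >= 1`.
#' @return A list of `tau_series`, one per component.
#' @export
adm_coefficients <- function(sys, state0, M = 3L) {
  stopifnot(inherits(sys, "caputo_system"),
            length(state0) == sys$dimension)
  if (M < 1) stop("'M' must be at least 1", call. = FALSE)
  A <- .adm_coefficients_cpp(sys$linear, sys$terms_matrix, sys$constant,
                             sys$order, as.numeric(state0), as.integer(M))
  lapply(seq_len(sys$dimension),
         function(c) tau_from_plain(A[c, ], sys$order))
}

#' Advance a Caputo system by one Adomian series step
#'
#' Each component is advanced by \eqn{\sum_{i=0}^{M} c_i h^{iq}/\Gamma(iq+1)}
#' with coefficients expanded at the current state.  `M = 1` is the two-term
#' reduced scheme used for hardware emulation.
#'
#' @inheritParams adm_coefficients
#' @param state Current state vector.
#' @param h Step size, `h > 0`.
#' @return The advanced state vector.
#' @export
adm_step <- function(sys, state, h, M = 3L) {
  stopifnot(inherits(sys, "caputo_system"),
            length(state) == sys$dimension, h > 0, M >= 1)
  drop(.adm_step_cpp(sys$linear, sys$terms_matrix, sys$constant, sys$order,
                     as.numeric(state), h, as.integer(M)))
}

#' Integrate a Caputo system by repeated Adomian series steps
#'
#' Iterates [adm_step()] with the series coefficients recomputed from the
#' current state at every step.  A state with any component exceeding 1e6 in
#' magnitude (or non-finite) aborts the run; the divergence index is
#' recorded on the returned trajectory.
#'
#' @inheritParams adm_step
#' @param state0 Initial state.
#' @param n_steps Number of steps (`>= 1`).
#' @param n_discard Number of initial samples marked as transient (used by
#'   downstream peak/attractor analysis; all samples are recorded).
#' @return An object of class `adm_trajectory` with fields `states`
#'   (`(n_steps+1) x n` matrix), `t`, `h`, `order`, `M`, `n_discard` and
#'   `diverged_at` (`NA` if the run completed).
#' @export
adm_integrate <- function(sys, state0, h, n_steps, M = 3L, n_discard = 0L) {
  stopifnot(inherits(sys, "caputo_system"),
            length(state0) == sys$dimension, h > 0, n_steps >= 1, M >= 1,
            n_discard >= 0)
  res <- .adm_integrate_cpp(sys$linear, sys$terms_matrix, sys$constant,
                            sys$order, as.numeric(state0), h,
                            as.integer(n_steps), as.integer(M))
  states <- res$states
  colnames(states) <- state_names(sys$dimension)
  structure(list(states = states, t = (0:n_steps) * h, h = h,
                 order = sys$order, M = as.integer(M),
                 n_discard = as.integer(n_discard),
                 diverged_at = if (res$diverged_at > 0) res$diverged_at else NA),
            class = "adm_trajectory")
}

state_names <- function(n) {
  if (n == 5L) c("x", "y", "z", "u", "w") else paste0("x", seq_len(n))
}

#' @export
print.adm_trajectory <- function(x, ...) {
  cat(sprintf("ADM trajectory: %d steps, h = %g, q = %g, M = %d\n",
              nrow(x$states) - 1L, x$h, x$order, x$M))
  if (!is.na(x$diverged_at))
    cat(sprintf("  diverged at step %d (|state| > 1e6)\n", x$diverged_at))
  if (x$n_discard > 0)
    cat(sprintf("  first %d samples marked transient\n", x$n_discard))
  cat("final state:\n")
  print(x$states[nrow(x$states), ], ...)
  invisible(x)
}

#' @export
as.data.frame.adm_trajectory <- function(x, ...) {
  data.frame(t = x$t, x$states, ...)
}

#' Phase-portrait plot of a trajectory
#'
#' @param x An `adm_trajectory`.
#' @param planes Two component indices (or names) to plot against each other.
#' @param discard Drop the transient samples before plotting (default TRUE).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.adm_trajectory <- function(x, planes = c(2L, 3L), discard = TRUE, ...) {
  s <- x$states
  if (discard && x$n_discard > 0) s <- s[-seq_len(x$n_discard), , drop = FALSE]
  graphics::plot(s[, planes[1]], s[, planes[2]], type = "l",
                 xlab = colnames(s)[planes[1]] %||% "c1",
                 ylab = colnames(s)[planes[2]] %||% "c2", ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# post-transient samples of one component
post_transient <- function(traj, component) {
  s <- traj$states[, component]
  if (traj$n_discard > 0) s <- s[-seq_len(traj$n_discard)]
  s
}
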