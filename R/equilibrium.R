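# Equilibrium location and fractional-order stability of the memristive
# Hopfield network.  The 5-d equilibrium system is reduced to two residuals
# H1(x, y), H2(x, y): the flux gives w = p*y/g, and (z, u) solve their own
# two equations for given (x, y) (a contraction-like 2-d Newton, vectorised
# over the whole search grid).  Sign-change cells of (H1, H2) seed a damped
# Newton polish on the full 5-d system.

#' Locate equilibria of the memristive Hopfield network
#'
#' Scans the (x, y) plane for simultaneous sign changes of the two reduced
#' equilibrium residuals, then polishes each candidate with a damped Newton
#' iteration on the full 5-d system using the analytic Jacobian, and
#' deduplicates the polished roots.  With the default parameters the model
#' has a single equilibrium at the origin.
#'
#' @param params An [hnn_params()].
#' @param xlim,ylim Search ranges for the membrane voltages of neurons 1
#'   and 2.  `tanh` saturation confines equilibria to a few units.
#' @param n_grid Grid resolution per axis.
#' @param tol Newton polish tolerance on the max-norm residual.
#' @param dedupe Radius below which two polished roots are merged.
#' @return A matrix with one equilibrium per row (0 rows if none found, with
#'   a warning).
#' @export
find_equilibria <- function(params = hnn_params(), xlim = c(-5, 5),
                            ylim = c(-5, 5), n_grid = 400L, tol = 1e-12,
                            dedupe = 1e-6) {
  stopifnot(inherits(params, "hnn_params"))
  xs <- seq(xlim[1], xlim[2], length.out = n_grid)
  ys <- seq(ylim[1], ylim[2], length.out = n_grid)
  X <- matrix(xs, n_grid, n_grid)
  Y <- matrix(ys, n_grid, n_grid, byrow = TRUE)
  red <- reduced_residuals(X, Y, params)
  cand <- sign_change_cells(red$H1, red$H2)
  roots <- list()
  for (idx in seq_len(nrow(cand))) {
    i <- cand[idx, 1]; j <- cand[idx, 2]
    x0 <- (xs[i] + xs[i + 1]) / 2
    y0 <- (ys[j] + ys[j + 1]) / 2
    start <- c(x0, y0, red$z[i, j], red$u[i, j], params$p * y0 / params$g)
    root <- newton_polish(start, params, tol)
    if (!is.null(root)) roots[[length(roots) + 1L]] <- root
  }
  if (!length(roots)) {
    warning("no sign-change cell found on the search grid; returning none")
    return(matrix(numeric(0), ncol = 5,
                  dimnames = list(NULL, state_names(5))))
  }
  eq <- do.call(rbind, roots)
  keep <- rep(TRUE, nrow(eq))
  for (i in seq_len(nrow(eq)))
    if (keep[i] && i < nrow(eq))
      for (j in (i + 1):nrow(eq))
        if (keep[j] && max(abs(eq[i, ] - eq[j, ])) < dedupe) keep[j] <- FALSE
  eq <- eq[keep, , drop = FALSE]
  colnames(eq) <- state_names(5)
  eq
}

# Given grids of (x, y): solve the (z, u) equilibrium subsystem by a
# vectorised 2-d Newton, and return the residuals of the remaining two
# equations.  w is eliminated as p*y/g.
reduced_residuals <- function(X, Y, params) {
  W <- params$W
  tx <- tanh(X); ty <- tanh(Y)
  z <- W[3, 1] * tx + W[3, 2] * ty # start from the tanh-free part
  u <- W[4, 1] * tx + W[4, 2] * ty
  for (it in 1:80) {
    tz <- tanh(z); tu <- tanh(u)
    F1 <- -z + W[3, 1] * tx + W[3, 2] * ty + W[3, 3] * tz + W[3, 4] * tu
    F2 <- -u + W[4, 1] * tx + W[4, 2] * ty + W[4, 3] * tz + W[4, 4] * tu
    s2z <- 1 - tz^2; s2u <- 1 - tu^2
    J11 <- -1 + W[3, 3] * s2z; J12 <- W[3, 4] * s2u
    J21 <- W[4, 3] * s2z;      J22 <- -1 + W[4, 4] * s2u
    det <- J11 * J22 - J12 * J21
    z <- z - (J22 * F1 - J12 * F2) / det
    u <- u - (-J21 * F1 + J11 * F2) / det
    if (max(abs(F1), abs(F2)) < 1e-13) break
  }
  Wm <- params$p * Y / params$g
  tz <- tanh(z); tu <- tanh(u)
  H1 <- -X + W[1, 1] * tx + W[1, 2] * ty + W[1, 3] * tz + W[1, 4] * tu
  H2 <- -Y + W[2, 1] * tx + W[2, 2] * ty + W[2, 3] * tz + W[2, 4] * tu +
    params$k * Y * (params$a + params$b * Wm)
  list(H1 = H1, H2 = H2, z = z, u = u)
}

# grid cells whose four corners change sign in both residuals
sign_change_cells <- function(H1, H2) {
  n <- nrow(H1)
  ch <- function(H) {
    lo <- pmin(H[-n, -n], H[-1, -n], H[-n, -1], H[-1, -1])
    hi <- pmax(H[-n, -n], H[-1, -n], H[-n, -1], H[-1, -1])
    lo <= 0 & hi >= 0
  }
  which(ch(H1) & ch(H2), arr.ind = TRUE)
}

newton_polish <- function(start, params, tol, max_iter = 100L) {
  s <- start
  f <- hnn_vector_field(s, params)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) return(s)
    J <- hnn_jacobian(s, params)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat { # damping: halve until the residual shrinks
      s_new <- s - lambda * step
      f_new <- hnn_vector_field(s_new, params)
      if (max(abs(f_new)) < max(abs(f)) || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    s <- s_new; f <- f_new
  }
  if (max(abs(f)) < 1e-8) s else NULL
}

#' Characteristic polynomial by the Faddeev--LeVerrier recursion
#'
#' Coefficients of \eqn{\det(\lambda I - J)} in monic, descending-power
#' order.  The \eqn{\lambda^{n-1}} coefficient equals `-trace(J)` exactly.
#'
#' @param J A square numeric matrix.
#' @return Numeric vector of length `n + 1`, leading coefficient 1.
#' @export
characteristic_polynomial <- function(J) {
  J <- as.matrix(J)
  n <- nrow(J)
  stopifnot(ncol(J) == n)
  coefs <- numeric(n + 1)
  coefs[1] <- 1
  Mk <- J
  for (k in seq_len(n)) {
    ck <- -sum(diag(Mk)) / k
    coefs[k + 1] <- ck
    if (k < n) Mk <- J %*% (Mk + ck * diag(n))
  }
  coefs
}

#' Fractional-order stability of an equilibrium
#'
#' A Caputo system of order `q` is stable at an equilibrium when every
#' Jacobian eigenvalue satisfies \eqn{|\arg(\lambda)| > q\pi/2}.  The
#' critical order is the largest `q` (clamped to (0, 1]) at which that still
#' holds: \eqn{q^* = (2/\pi)\min_i |\arg(\lambda_i)|}.
#'
#' @param eigenvalues Complex (or numeric) eigenvalues of the Jacobian.
#' @param q Fractional order in (0, 1].
#' @return List with `stable` (logical; `NA` when marginal), `critical_order`,
#'   and `marginal` (TRUE when an eigenvalue sits at zero).
#' @export
fractional_stability <- function(eigenvalues, q) {
  stopifnot(q > 0, q <= 1)
  marginal <- any(Mod(eigenvalues) < 1e-12)
  min_arg <- min(abs(Arg(eigenvalues)))
  crit <- min(max(2 / pi * min_arg, .Machine$double.eps), 1)
  list(stable = if (marginal) NA else min_arg > q * pi / 2,
       critical_order = crit, marginal = marginal)
}

#' Equilibrium and stability report for the memristive Hopfield network
#'
#' Locates the equilibria, and for each one computes the Jacobian, its
#' monic characteristic polynomial, the eigenvalues and the fractional
#' stability verdict at the requested order.
#'
#' @inheritParams find_equilibria
#' @param order Fractional order at which stability is judged.
#' @param ... Passed to [find_equilibria()].
#' @return An object of class `equilibrium_report`.
#' @export
equilibrium_report <- function(params = hnn_params(), order = 0.478, ...) {
  eq <- find_equilibria(params, ...)
  per <- lapply(seq_len(nrow(eq)), function(i) {
    J <- hnn_jacobian(eq[i, ], params)
    ev <- eigen(J, only.values = TRUE)$values
    st <- fractional_stability(ev, order)
    list(equilibrium = eq[i, ], char_poly = characteristic_polynomial(J),
         eigenvalues = ev, stable = st$stable,
         critical_order = st$critical_order, marginal = st$marginal)
  })
  structure(list(equilibria = eq, details = per, order = order,
                 params = params),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("Equilibrium report (q = %g): %d equilibrium point(s)\n",
              x$order, nrow(x$equilibria)))
  for (d in x$details) {
    cat("  at (", paste(formatC(d$equilibrium, format = "g"), collapse = ", "),
        ")\n", sep = "")
    cat("    eigenvalues: ",
        paste(format(d$eigenvalues, digits = 5), collapse = ", "), "\n",
        sep = "")
    cat(sprintf("    stable at q = %g: %s (critical order %.4f)\n",
                x$order, format(d$stable), d$critical_order))
  }
  invisible(x)
}
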