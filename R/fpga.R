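# Two-term reduced-step scheme and fixed-point datapath emulation.  The
# hardware implementation keeps only the first two series terms x0 and x1;
# accuracy is recovered by shrinking the step, and the discarded
# second-order term is audited along the trajectory.

#' One two-term (reduced) series step of the memristive Hopfield network
#'
#' Closed-form update `state + f(state) * h^q / Gamma(q + 1)`, where `f` is
#' the vector field: the first-order series coefficient equals the field at
#' the expansion point, so this is exactly [adm_step()] with `M = 1`.
#'
#' @param state Numeric 5-vector.
#' @param params An [hnn_params()].
#' @param q Fractional order in (0, 1].
#' @param h Step size.
#' @return The advanced 5-vector.
#' @examples
#' two_term_step(c(1, 1, -1, 0, 0), hnn_params(), q = 0.478, h = 1e-6)
#' @export
two_term_step <- function(state, params = hnn_params(), q = 0.478, h) {
  stopifnot(h > 0, q > 0, q <= 1)
  state + hnn_vector_field(state, params) * h^q / gamma(q + 1)
}

#' Signed fixed-point number format
#'
#' @param word_bits Total word width (including sign), at most 64.
#' @param frac_bits Fractional bits, `0 < frac_bits < word_bits`.
#' @param rounding `"round"` (round to nearest) or `"truncate"`.
#' @return An object of class `fixed_point_format`.
#' @export
fixed_point_format <- function(word_bits = 32L, frac_bits = 26L,
                               rounding = c("round", "truncate")) {
  rounding <- match.arg(rounding)
  if (!(frac_bits > 0 && frac_bits < word_bits && word_bits <= 64))
    stop("need 0 < frac_bits < word_bits <= 64", call. = FALSE)
  structure(list(word_bits = as.integer(word_bits),
                 frac_bits = as.integer(frac_bits), rounding = rounding,
                 scale = 2^frac_bits,
                 max = 2^(word_bits - 1 - frac_bits) - 2^(-frac_bits)),
            class = "fixed_point_format")
}

#' @export
print.fixed_point_format <- function(x, ...) {
  cat(sprintf("signed fixed point %d.%d (%s), range +/- %g\n",
              x$word_bits - x$frac_bits, x$frac_bits, x$rounding, x$max))
  invisible(x)
}

# package-local saturation counter for the current emulated step
.fp_env <- new.env(parent = emptyenv())
.fp_env$saturations <- 0L

#' Quantise values to a fixed-point format
#'
#' Rounds (or truncates) to the format's grid and saturates at the
#' representable range.
#'
#' @param x Numeric vector.
#' @param fmt A [fixed_point_format()].
#' @return Quantised values.
#' @export
fp_quantize <- function(x, fmt) {
  y <- x * fmt$scale
  y <- if (fmt$rounding == "round") round(y) else trunc(y)
  y <- y / fmt$scale
  over <- abs(y) > fmt$max
  if (any(over)) {
    .fp_env$saturations <- .fp_env$saturations + sum(over)
    y[over] <- sign(y[over]) * fmt$max
  }
  y
}

# 1024-entry tanh lookup table on [-4, 4] with linear interpolation,
# saturating outside; table entries are stored at the format's precision.
fp_tanh_lut <- function(fmt) {
  key <- sprintf("lut_%d_%d_%s", fmt$word_bits, fmt$frac_bits, fmt$rounding)
  lut <- .fp_env[[key]]
  if (is.null(lut)) {
    grid <- seq(-4, 4, length.out = 1024L)
    lut <- list(grid = grid, values = fp_quantize(tanh(grid), fmt),
                step = grid[2] - grid[1])
    .fp_env[[key]] <- lut
  }
  lut
}

fp_tanh <- function(x, fmt) {
  lut <- fp_tanh_lut(fmt)
  x <- pmin(pmax(x, -4), 4)
  i <- pmin(floor((x + 4) / lut$step) + 1, 1023L)
  frac <- (x - lut$grid[i]) / lut$step
  fp_quantize(lut$values[i] + frac * (lut$values[i + 1] - lut$values[i]), fmt)
}

#' One two-term step emulated in fixed-point arithmetic
#'
#' Replays [two_term_step()] with every arithmetic result quantised to the
#' given format and `tanh` evaluated through a 1024-entry lookup table on
#' \[-4, 4\] with linear interpolation (saturating outside), emulating a
#' hardware datapath.  Overflow saturates; the count of saturation events is
#' attached as an attribute.
#'
#' @inheritParams two_term_step
#' @param fmt A [fixed_point_format()].
#' @return The advanced 5-vector with attribute `saturations`.
#' @export
fixed_point_step <- function(state, params = hnn_params(), q = 0.478, h,
                             fmt = fixed_point_format()) {
  stopifnot(inherits(fmt, "fixed_point_format"), h > 0)
  .fp_env$saturations <- 0L
  qz <- function(x) fp_quantize(x, fmt)
  s <- qz(state)
  th <- fp_tanh(s[1:4], fmt)
  W <- params$W
  f <- numeric(5)
  for (i in 1:4) {
    acc <- qz(-s[i])
    for (j in 1:4)
      if (W[i, j] != 0) acc <- qz(acc + qz(W[i, j] * th[j]))
    f[i] <- acc
  }
  # radiation feedback on neuron 2: k*y*(a + b*w)
  rad <- qz(qz(params$k * s[2]) * qz(params$a + qz(params$b * s[5])))
  f[2] <- qz(f[2] + rad)
  f[5] <- qz(qz(params$p * s[2]) - qz(params$g * s[5]))
  kq <- qz(h^q / gamma(q + 1))
  out <- qz(s + qz(f * kq))
  attr(out, "saturations") <- .fp_env$saturations
  out
}

#' Truncation audit of the two-term reduced-step scheme
#'
#' Runs the two-term trajectory and, at every step, also computes the first
#' discarded series term \eqn{c_2 h^{2q}/\Gamma(2q+1)}; returns the running
#' per-component maximum of its absolute value.  This bounds the local
#' truncation error of the hardware scheme along the actual orbit.
#'
#' @param params An [hnn_params()].
#' @param q Fractional order.
#' @param h Step size (the hardware regime uses 1e-6).
#' @param n_steps Number of iterations.
#' @param state0 Initial state.
#' @return List with `max_abs_second` (named 5-vector), `final_state`,
#'   `diverged_at` (`NA` when the run completed), `h`, `q`, `n_steps`.
#' @export
truncation_audit <- function(params = hnn_params(), q = 0.478, h = 1e-6,
                             n_steps = 1e6, state0 = c(1, 1, -1, 0, 0)) {
  stopifnot(inherits(params, "hnn_params"), h > 0, n_steps >= 1)
  sys <- hnn_decomposition(params, order = q)
  res <- .two_term_audit_cpp(sys$linear, sys$terms_matrix, sys$constant, q,
                             as.numeric(state0), h, as.numeric(n_steps))
  mx <- drop(res$max_abs_second)
  names(mx) <- state_names(5)
  fs <- drop(res$final_state)
  names(fs) <- state_names(5)
  list(max_abs_second = mx, final_state = fs,
       diverged_at = if (res$diverged_at > 0) res$diverged_at else NA,
       h = h, q = q, n_steps = n_steps)
}
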