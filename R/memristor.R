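# Flux-controlled memristor with linear memductance W(phi) = a + b*phi and a
# Caputo fractional flux balance D^alpha phi = p*v - g*phi, driven by a
# sinusoidal voltage.  Under such a drive the i-v loop is pinched at the
# origin structurally, since i = W(phi)*v vanishes wherever v does.

#' Memristor parameters
#'
#' @param a,b Memductance offset and slope: `W(phi) = a + b*phi`.
#' @param p Flux gain from the applied voltage.
#' @param g Flux leakage rate.
#' @param alpha Fractional order of the flux equation, in (0, 1].
#' @return An object of class `memristor_params`.
#' @export
memristor_params <- function(a = 0.01, b = 0.02, p = 0.3, g = 0.8,
                             alpha = 0.9) {
  vals <- c(a, b, p, g, alpha)
  if (!all(is.finite(vals))) stop("parameters must be finite", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]", call. = FALSE)
  structure(list(a = a, b = b, p = p, g = g, alpha = alpha),
            class = "memristor_params")
}

#' Sinusoidal drive voltage
#'
#' @param Am Voltage amplitude (`>= 0`).
#' @param F Angular drive frequency (`> 0`).
#' @param phase Phase offset in radians.
#' @return An object of class `drive_signal`.
#' @export
drive_signal <- function(Am, F, phase = 0) {
  if (Am < 0 || F <= 0) stop("need Am >= 0 and F > 0", call. = FALSE)
  structure(list(Am = Am, F = F, phase = phase), class = "drive_signal")
}

#' Memductance of the flux-controlled memristor
#'
#' @param phi Magnetic flux (vectorised).
#' @param params A [memristor_params()].
#' @return `a + b * phi`.
#' @export
memductance <- function(phi, params = memristor_params()) {
  params$a + params$b * phi
}

#' Simulate the driven memristor
#'
#' Integrates the scalar Caputo flux equation with the Adomian series
#' scheme, treating the drive voltage as frozen within each step (sampled at
#' the step start).  The current is `i = W(phi) * v` at every sample, so the
#' hysteresis loop is pinched at the origin to machine precision.
#'
#' @param params A [memristor_params()].
#' @param drive A [drive_signal()].
#' @param h Step size.
#' @param n_periods Number of drive periods to cover (used when `n_steps` is
#'   not given).
#' @param n_steps Number of steps; overrides `n_periods`.
#' @param M Series truncation order.
#' @param phi0 Initial flux.
#' @return A `data.frame` with columns `t`, `v`, `i`, `phi` and attributes
#'   `drive`, `params`, `h`; class `memristor_sim`.
#' @export
simulate_memristor <- function(params = memristor_params(), drive,
                               h = 1e-3, n_periods = 10, n_steps = NULL,
                               M = 3L, phi0 = 0) {
  stopifnot(inherits(params, "memristor_params"),
            inherits(drive, "drive_signal"), h > 0)
  if (is.null(n_steps))
    n_steps <- ceiling(n_periods * 2 * pi / (drive$F * h))
  al <- params$alpha
  tt <- (0:n_steps) * h
  v <- drive$Am * sin(drive$F * tt + drive$phase)
  # per-step linear recursion: a_0 = phi, a_1 = r_0 (p v - g phi),
  # a_{i+1} = r_i (-g) a_i; phi' = sum a_i h^(i alpha)
  r <- gamma_ratio(0:(M - 1), al)
  hp <- h^((1:M) * al)
  wts <- numeric(M) # phi' = phi + (p v - g phi) * sum(wts)
  acc <- 1
  for (i in 1:M) {
    acc <- acc * r[i] * if (i == 1) 1 else -params$g
    wts[i] <- acc * hp[i]
  }
  C <- sum(wts)
  phi <- numeric(n_steps + 1)
  phi[1] <- phi0
  guard <- 1e6
  diverged_at <- NA
  for (kk in seq_len(n_steps)) {
    phi[kk + 1] <- phi[kk] + (params$p * v[kk] - params$g * phi[kk]) * C
    if (!is.finite(phi[kk + 1]) || abs(phi[kk + 1]) > guard) {
      diverged_at <- kk
      phi[(kk + 1):(n_steps + 1)] <- NA
      break
    }
  }
  out <- data.frame(t = tt, v = v, i = memductance(phi, params) * v,
                    phi = phi)
  attr(out, "drive") <- drive
  attr(out, "params") <- params
  attr(out, "h") <- h
  attr(out, "diverged_at") <- diverged_at
  class(out) <- c("memristor_sim", "data.frame")
  out
}

#' Pinched-hysteresis diagnostics of a simulated memristor
#'
#' Computes the mean per-period shoelace area of the closed post-transient
#' (v, i) loop and a pinch flag: the loop counts as pinched when the largest
#' current magnitude observed at near-zero voltage (|v| < eps * Am) is below
#' `delta` times the overall current maximum.
#'
#' @param sim A `memristor_sim` from [simulate_memristor()].
#' @param n_discard Samples to drop as transient; defaults to the first 20%.
#' @param eps Relative voltage window defining "near zero".
#' @param delta Relative current threshold for the pinch flag.
#' @return A list with `loop_area`, `pinched`, and `n_periods` used.
#' @export
hysteresis_metrics <- function(sim, n_discard = NULL, eps = 1e-3,
                               delta = 1e-2) {
  stopifnot(inherits(sim, "memristor_sim"))
  drive <- attr(sim, "drive")
  h <- attr(sim, "h")
  if (is.null(n_discard)) n_discard <- floor(nrow(sim) * 0.2)
  v <- sim$v[-seq_len(n_discard)]
  i <- sim$i[-seq_len(n_discard)]
  per <- round(2 * pi / (drive$F * h)) # samples per drive period
  n_per <- floor(length(v) / per)
  if (n_per < 2)
    stop("post-transient samples must cover at least two drive periods",
         call. = FALSE)
  lobe <- function(vv, ii) { # shoelace area of one closed lobe
    vn <- c(vv[-1], vv[1]); in_ <- c(ii[-1], ii[1])
    0.5 * abs(sum(vv * in_ - vn * ii))
  }
  half <- per %/% 2
  areas <- vapply(seq_len(n_per), function(kk) {
    idx <- ((kk - 1) * per + 1):(kk * per)
    # the pinched loop is a figure-eight: its two lobes have opposite
    # orientation, so each half-period lobe is closed and measured alone
    lobe(v[idx[1:half]], i[idx[1:half]]) +
      lobe(v[idx[(half + 1):per]], i[idx[(half + 1):per]])
  }, numeric(1))
  imax <- max(abs(i))
  near0 <- abs(v) < eps * drive$Am
  pinched <- !any(near0) || max(abs(i[near0])) < delta * imax
  list(loop_area = mean(areas), pinched = pinched, n_periods = n_per)
}
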