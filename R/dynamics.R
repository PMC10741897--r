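# Lyapunov spectra, bifurcation scans and attractor classification for the
# fractional-order memristive Hopfield network.

#' Lyapunov spectrum via the tangent map of the series step
#'
#' Propagates an orthonormal frame through the central-difference Jacobian
#' of the M-term Adomian one-step map, re-orthonormalising with modified
#' Gram--Schmidt every step, and averages the log diagonal growth over the
#' post-transient steps divided by the step size.
#'
#' @param sys A [caputo_system()].
#' @param state0 Initial state; defaults to `(1, 1, -1, 0, 0)` for the
#'   5-dimensional network.
#' @param h Step size.
#' @param n_steps Total steps.
#' @param n_discard Transient steps excluded from the averages.
#' @param n_exp Number of exponents (`<=` dimension).
#' @param M Series truncation order.
#' @param delta Finite-difference perturbation of the step-map Jacobian.
#' @return Numeric vector of `n_exp` exponents, sorted descending, with
#'   attributes `n_used` and `diverged_at`.
#' @export
lyapunov_spectrum <- function(sys, state0 = NULL, h = 1e-3, n_steps = 2e5,
                              n_discard = 1e4, n_exp = 3L, M = 3L,
                              delta = 1e-7) {
  stopifnot(inherits(sys, "caputo_system"), n_exp <= sys$dimension,
            n_steps > n_discard)
  if (is.null(state0))
    state0 <- if (sys$dimension == 5L) c(1, 1, -1, 0, 0)
              else numeric(sys$dimension)
  res <- .lyapunov_cpp(sys$linear, sys$terms_matrix, sys$constant, sys$order,
                       as.numeric(state0), h, as.integer(n_steps),
                       as.integer(n_discard), as.integer(M),
                       as.integer(n_exp), delta)
  les <- sort(res$les, decreasing = TRUE)
  attr(les, "n_used") <- res$n_used
  attr(les, "diverged_at") <- if (res$diverged_at > 0) res$diverged_at else NA
  les
}

#' Strict local maxima of a sampled signal
#'
#' @param v Numeric vector.
#' @return Values of the strict interior local maxima (empty if none).
#' @export
find_peaks <- function(v) {
  m <- length(v)
  if (m < 3) return(numeric(0))
  mid <- v[2:(m - 1)]
  v[which(mid > v[1:(m - 2)] & mid > v[3:m]) + 1L]
}

# number of peak clusters under absolute tolerance tol
count_peak_clusters <- function(peaks, tol) {
  sp <- sort(peaks)
  1L + sum(diff(sp) > tol)
}

#' Classify an attractor from its peak set and Lyapunov exponents
#'
#' Peak values are clustered with an absolute tolerance (default 1e-3 of
#' the peak range).  A small cluster count with a non-positive leading
#' exponent is periodic; a leading exponent indistinguishable from zero with
#' a large, growing cluster count is quasi-periodic; a positive leading
#' exponent is chaotic.
#'
#' @param peaks Post-transient strict local maxima of one component.
#' @param les Lyapunov exponents (descending), or `NULL` when unavailable.
#' @param tol_cluster Absolute peak-clustering tolerance; default
#'   `1e-3 * diff(range(peaks))`.
#' @param tol_zero Threshold below which the leading exponent counts as
#'   zero (units of inverse time).
#' @param max_period Largest cluster count still reported as periodic.
#' @return A label: `"periodic-k"`, `"quasi-periodic"`, `"chaotic"`,
#'   `"aperiodic"` (no exponents available) or `"indeterminate"`.
#' @export
classify_attractor <- function(peaks, les = NULL, tol_cluster = NULL,
                               tol_zero = 0.05, max_period = 8L) {
  if (length(peaks) < 3) return("indeterminate")
  if (is.null(tol_cluster)) {
    rng <- diff(range(peaks))
    tol_cluster <- max(1e-3 * rng, 1e-9)
  }
  k <- count_peak_clusters(peaks, tol_cluster)
  if (is.null(les)) {
    return(if (k <= max_period) sprintf("periodic-%d", k) else "aperiodic")
  }
  le1 <- les[1]
  if (!is.finite(le1)) return("indeterminate")
  if (le1 > tol_zero) return("chaotic")
  if (k <= max_period) return(sprintf("periodic-%d", k))
  if (abs(le1) <= tol_zero) return("quasi-periodic")
  "indeterminate"
}

#' Bifurcation scan over the fractional order or the radiation parameter b
#'
#' For each sweep value the network is rebuilt, integrated from a cold
#' restart at the fixed initial state, and the post-transient strict local
#' maxima of the chosen component are recorded; optionally a Lyapunov
#' spectrum is attached and each value is classified.  Divergent runs are
#' labelled and the scan continues.
#'
#' @param params An [hnn_params()] (its `b` is overridden on a b-axis scan).
#' @param order Fractional order (overridden on a q-axis scan).
#' @param axis `"q"` or `"b"`.
#' @param values Sweep values (within (0, 1] for the q axis).
#' @param state0 Initial state for every run (cold restart).
#' @param h Step size.
#' @param n_steps Steps per run.
#' @param n_discard Transient cutoff; default the larger of 1e4 and 30% of
#'   `n_steps`.
#' @param component Component whose maxima are recorded (default `y`).
#' @param attach_les Attach a 3-exponent Lyapunov spectrum per value.
#' @param le_steps,le_discard Step counts for the attached spectra.
#' @param M Series truncation order.
#' @param tol_zero Zero threshold passed to [classify_attractor()].
#' @return An object of class `dynamics_report`.
#' @export
bifurcation_scan <- function(params = hnn_params(), order = 0.478,
                             axis = c("q", "b"), values,
                             state0 = c(1, 1, -1, 0, 0), h = 1e-3,
                             n_steps = 8e4, n_discard = NULL,
                             component = 2L, attach_les = TRUE,
                             le_steps = 4e4, le_discard = 1e4, M = 3L,
                             tol_zero = 0.05) {
  axis <- match.arg(axis)
  stopifnot(inherits(params, "hnn_params"), length(values) >= 1)
  if (axis == "q" && (any(values <= 0) || any(values > 1)))
    stop("q-axis sweep values must lie in (0, 1]", call. = FALSE)
  if (is.null(n_discard)) n_discard <- max(1e4, floor(0.3 * n_steps))
  nv <- length(values)
  peaks <- vector("list", nv)
  les <- if (attach_les) matrix(NA_real_, nv, 3) else NULL
  labels <- character(nv)
  for (iv in seq_len(nv)) {
    v <- values[iv]
    pv <- params
    ov <- order
    if (axis == "b") pv <- hnn_params(a = params$a, b = v, k = params$k,
                                      p = params$p, g = params$g, W = params$W)
    else ov <- v
    sys <- hnn_decomposition(pv, order = ov)
    traj <- adm_integrate(sys, state0, h = h, n_steps = n_steps, M = M,
                          n_discard = n_discard)
    if (!is.na(traj$diverged_at)) {
      labels[iv] <- "divergent"
      peaks[[iv]] <- numeric(0)
      next
    }
    pk <- find_peaks(post_transient(traj, component))
    peaks[[iv]] <- pk
    le <- NULL
    if (attach_les) {
      le <- lyapunov_spectrum(sys, state0 = state0, h = h,
                              n_steps = le_steps, n_discard = le_discard,
                              n_exp = 3L, M = M)
      les[iv, ] <- le
    }
    labels[iv] <- classify_attractor(pk, le, tol_zero = tol_zero)
  }
  structure(list(sweep_name = axis, sweep_values = values, peaks = peaks,
                 les = les, labels = labels,
                 counts = vapply(peaks, function(p) {
                   if (length(p) < 1) return(NA_integer_)
                   rng <- diff(range(p))
                   count_peak_clusters(p, max(1e-3 * rng, 1e-9))
                 }, integer(1)),
                 component = component, h = h, n_steps = n_steps,
                 n_discard = n_discard, params = params, order = order),
            class = "dynamics_report")
}

#' @export
print.dynamics_report <- function(x, ...) {
  cat(sprintf("Dynamics scan over %s: %d values in [%g, %g]\n", x$sweep_name,
              length(x$sweep_values), min(x$sweep_values),
              max(x$sweep_values)))
  tab <- table(x$labels)
  cat("labels: ", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Bifurcation diagram of a dynamics scan
#'
#' Plots every recorded post-transient peak value against its sweep value.
#'
#' @param x A `dynamics_report`.
#' @param pch,cex,... Passed to [graphics::plot()].
#' @export
plot.dynamics_report <- function(x, pch = ".", cex = 1, ...) {
  xs <- rep(x$sweep_values, lengths(x$peaks))
  ys <- unlist(x$peaks)
  graphics::plot(xs, ys, pch = pch, cex = cex, xlab = x$sweep_name,
                 ylab = sprintf("peaks of component %d", x$component), ...)
  invisible(x)
}

#' Detect a period-doubling cascade in a dynamics scan
#'
#' Searches a scan for the signature of a period-doubling route to chaos:
#' a regular window with `k` peak branches, followed (in sweep order) by
#' windows with about `2k` and `4k` branches, followed by a chaotic label.
#' A reverse cascade (chaos, 4k, 2k, k) is detected by scanning backwards.
#' Branch counts are compared with a small tolerance since nearly-merged
#' branches can fall inside the clustering tolerance.
#'
#' @param report A `dynamics_report` from [bifurcation_scan()], or a list
#'   with `counts` and `labels`.
#' @param direction `"forward"` (k, 2k, 4k, chaos with increasing sweep
#'   value) or `"reverse"`.
#' @param tol Function mapping an expected branch count to an allowed
#'   absolute deviation.
#' @return `TRUE` if the cascade pattern is present.
#' @export
detect_period_doubling <- function(report,
                                   direction = c("forward", "reverse"),
                                   tol = function(m) max(2, ceiling(0.12 * m))) {
  direction <- match.arg(direction)
  counts <- report$counts
  labels <- report$labels
  if (direction == "reverse") {
    counts <- rev(counts)
    labels <- rev(labels)
  }
  n <- length(counts)
  regular <- !(labels %in% c("chaotic", "divergent", "indeterminate")) &
    !is.na(counts)
  idx <- seq_len(n)
  for (i1 in which(regular)) {
    k <- counts[i1]
    for (i2 in which(regular & idx > i1 & abs(counts - 2 * k) <= tol(2 * k))) {
      for (i3 in which(regular & idx > i2 & abs(counts - 4 * k) <= tol(4 * k))) {
        if (i3 < n && any(labels[(i3 + 1):n] == "chaotic")) return(TRUE)
      }
    }
  }
  FALSE
}

#' Signed accumulation metric of a multi-scroll attractor
#'
#' The skew-robust location (median) of one component over the
#' post-transient trajectory.  For the multi-scroll regime the sign encodes
#' the end toward which the scrolls accumulate; a symmetric attractor gives
#' a value near zero relative to its extent.
#'
#' @param traj An `adm_trajectory`.
#' @param component Component index (default the flux, 5).
#' @return A signed scalar.
#' @export
scroll_direction_metric <- function(traj, component = 5L) {
  stopifnot(inherits(traj, "adm_trajectory"))
  s <- post_transient(traj, component)
  if (length(s) < 1e4)
    warning("fewer than 1e4 post-transient samples; metric may be noisy")
  median(s)
}
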