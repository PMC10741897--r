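---
title: "Methods: fractional-order memristive Hopfield network dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractional-order memristive Hopfield network dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The package simulates a four-neuron continuous Hopfield network in which
neuron 2 is exposed to electromagnetic radiation, modelled by a
flux-controlled memristor: the membrane flux `w` integrates the membrane
voltage `y` and feeds a current `k*y*(a + b*w)` back into neuron 2.  With
unit membrane capacitances and resistances and zero bias currents, the
five state equations are

    D^q x = -x + 2.5 tanh(x) + 1.5 tanh(y) - 4.5 tanh(u)
    D^q y = -y + 2.2 tanh(y) + 2 tanh(z) + k y (a + b w)
    D^q z = -z + 2.3 tanh(x) - 1.5 tanh(y) + 4 tanh(u)
    D^q u = -u + 4 tanh(x) + 1.3 tanh(y) + 0.6 tanh(u)
    D^q w = p y - g w

where `D^q` is the Caputo derivative of order `q` in (0, 1].  The synaptic
weights form the fixed matrix `hnn_weights()` (overridable for generalised
topologies).  `a` and `b` are the radiation parameters (memductance offset
and flux slope), `k` the feedback strength, `p` the flux gain and `g` the
flux leakage.  The reference regime, shipped as the preset
`"chaos-q0478"`, is `a = 0.78, b = 0.1, k = 0.1, p = 0.3, g = 0.8` with
`q = 0.478` and initial state `(1, 1, -1, 0, 0)`.

All state variables are dimensionless circuit quantities; time is in the
dimensionless units of the rescaled circuit, so Lyapunov exponents carry
units of inverse model time.

## The series integrator

The solver writes the system as `D^q x = L x + N(x) + g` (for the network:
`L` has diagonal `(-1, k a - 1, -1, -1, -g)` plus the flux coupling `p`,
`N` holds every `tanh` term and the bilinear term `k b w y`, and `g = 0`).
The solution over one step is expanded as a generalized power series in
`t^q`,

    x_c(h) = sum_{i=0}^{M} c_i h^{i q} / Gamma(i q + 1),

and the Adomian recursion maps the order-`i` series coefficient of the
vector field to the order-`i+1` coefficient of the state through the
power-rule factor `Gamma(iq+1)/Gamma((i+1)q+1)` (`gamma_ratio()`,
evaluated through `lgamma` so large orders cannot overflow).  Internally
the series are kept as *plain* coefficients `a_i = c_i / Gamma(iq+1)`, so
that products of powers multiply exactly and the Gamma bookkeeping for
products and compositions disappears.  Because the expansion state is
constant within a step, this formal power series is term-for-term the
Adomian decomposition: the order-`i` coefficient of `tanh(x(t))` equals the
`i`-th Adomian polynomial of `tanh`.  `tanh` series are propagated by the
derivative recursion `w' = (1 - w^2) u'`; products by the truncated Cauchy
convolution.  The test suite checks these coefficients against an
independent trigonometric-quadrature (Cauchy-integral) oracle for the
Taylor coefficients of `tanh` composed with random series.

Stepping restarts the expansion at every step.  This is the standard
practice for this model class and is what the package's hardware emulation
verifies, but it deliberately discards the memory kernel of the Caputo
operator: the scheme is *not* a full-history fractional solver, and no
predictor--corrector method is provided.  Two consequences worth knowing:

* in the limit `M = 1` the update `x + f(x) h^q / Gamma(q+1)` is an Euler
  map of the *integer-order* flow with effective step `h^q / Gamma(q+1)`;
* at `q = 1` the `M`-term step reduces exactly to degree-`M` Taylor
  stepping, which the tests verify against closed forms.

Defaults: truncation `M = 3` (four terms, matching the reference
analysis), `M = 1` for the hardware emulation mode, step `h = 0.001` for
dynamics work and `h = 1e-6` for the reduced two-term scheme.  A state
component exceeding `1e6` in magnitude aborts a run and records the
divergence index; scans label such runs `divergent` and continue.

## Equilibria and fractional stability

Setting the right-hand sides to zero, the flux gives `w = p y / g` and the
`(z, u)` pair solves its own two equations for given `(x, y)` (solved by a
vectorised damped Newton over the whole search grid).  The remaining two
residuals are scanned on a 400-point-per-axis grid over `[-5, 5]^2` (tanh
saturation confines equilibria to a few units); cells where both residuals
change sign seed a damped Newton polish on the full 5-d system with the
analytic Jacobian (tolerance `1e-12`, deduplication radius `1e-6`).  With
the default parameters the only equilibrium is the origin.

Stability at order `q` uses the fractional criterion: an equilibrium is
stable when every Jacobian eigenvalue satisfies `|arg(lambda)| > q*pi/2`;
the critical order is `(2/pi) min |arg(lambda)|`.  At the origin the flux
column of the Jacobian has `-g` as its only nonzero entry, so `-g` is an
exact eigenvalue — a structural fact the acceptance checks use.  The
recomputed origin spectrum at the reference parameters is
`(-0.8, 0.0291 ± 4.2608i, 0.6599 ± 0.8720i)`, giving a critical order of
0.588: the origin is *stable* at `q = 0.478` even though a chaotic
attractor coexists with it.  The package reports this as computed; it is a
hidden-attractor-like feature of the model, not an error.

## Lyapunov exponents

The method of record for the reference results does not specify its
exponent algorithm, so the package uses the standard tangent-map approach
of the fractional-chaos literature: propagate an orthonormal frame through
the Jacobian of the one-step series map (central differences, perturbation
`1e-7`), re-orthonormalise by modified Gram--Schmidt every step, and
average the log diagonal growth over post-transient steps divided by `h`.
Defaults: `h = 0.001`, `M = 3`, `2e5` steps after a `1e4`-step transient.
At the reference regime this yields exponents near `(4.04, -0.006, -15.9)`
— the (+, ~0, -) chaotic signature, with the leading exponent within a few
percent of the reference value 4.164; exponent magnitudes from tangent
methods are method-sensitive at roughly the 15% level, while the sign
pattern is robust.  The suite checks invariance (5%) under doubling the
run length and halving the perturbation.

## Bifurcation scans and attractor classification

Scans integrate each sweep value from a cold restart at `(1, 1, -1, 0, 0)`
(no state continuation — the reference analysis does not state any — so
bifurcation-point estimates can shift slightly), discard the larger of
`1e4` samples and 30% of the run as transient, and record the strict local
maxima of `y`, the component used in the reference portraits.  Peak values
are clustered with an absolute tolerance of `1e-3` of the peak range.

Classification follows the rule: leading exponent above `tol_zero = 0.05`
is `chaotic`; otherwise up to 8 clusters is `periodic-k`; otherwise a
leading exponent within `±tol_zero` of zero is `quasi-periodic`.  Two
conventions matter when reading the labels:

* **Branch multiplicity.**  A single fundamental loop of this attractor
  family crosses several maxima of `y` (five in the forward-doubling
  window near `q = 0.48`, seven near `q = 0.60`).  "Period-1 to period-2
  to period-4" therefore appears as branch counts `k -> 2k -> 4k`;
  `detect_period_doubling()` searches a scan for exactly this geometric
  pattern (with a small count tolerance, since nearly-merged branches can
  fall inside the clustering tolerance) followed — or preceded, for the
  reverse route — by a chaotic label.
* **The cluster cap.**  Period-doubled orbits with more than 8 branches
  (e.g. the 12- and 23-branch orbits inside the regular windows of the
  `b`-scan at `q = 0.5`) fall past the cap and are labelled
  `quasi-periodic` alongside genuine torus-like orbits such as the one at
  `q = 0.5906` (21 narrow bands, leading exponent indistinguishable from
  zero).  Both are regular, non-chaotic orbits; when the distinction
  matters, raise `max_period` or inspect the branch counts directly.  The
  acceptance suite accordingly checks the regular windows of the `b`-scan
  as "non-chaotic with a near-zero leading exponent" rather than by label
  prefix.

The multi-scroll regime (`p = 2.6, g = 2.5`, preset `"multiscroll"`) is
summarised by `scroll_direction_metric()`: the median of the flux over the
post-transient orbit.  The median was chosen over the mean as a
skew-robust location: the scrolls accumulate toward one end of the flux
axis, and the sign of the metric flips with the sign of `b` while its
magnitude is symmetric within a few percent.

## The memristor

The drive module integrates the scalar flux balance
`D^alpha phi = p v(t) - g phi` under `v = Am sin(F t)` with the same
series scheme, freezing the drive within each step (sampled at the step
start).  Freezing makes the scheme first-order in `h` regardless of `M`;
at the default `h = 1e-3` and ten drive periods this is accurate to a few
parts in a thousand, and the integer-order limit is checked against both
the closed-form sinusoidal steady state and a stiff-safe adaptive ODE
reference (at `h = 1e-5` for the tight comparison).  The current is
`i = (a + b phi) v` at every sample, so the loop is pinched at the origin
structurally.  Loop area is measured per drive period as the sum of the
two half-period lobe areas (the pinched loop is a figure-eight whose lobes
have opposite orientation, so a whole-period shoelace sum would cancel);
the first 20% of samples are discarded as transient.  Area decreases with
drive frequency and increases with amplitude, as expected from the
out-of-phase flux response `p Am F / (g^2 + F^2)` in the integer-order
limit.

## Two-term hardware emulation and the truncation audit

Hardware implementations keep only the first two series terms; accuracy is
recovered by shrinking the step to `h = 1e-6`.  `two_term_step()` is the
closed-form update `x + f(x) h^q / Gamma(q+1)` and agrees with the
`M = 1` series step to `1e-12`.  `truncation_audit()` runs the two-term
trajectory while recording the running maximum of the first discarded term
`|c_2| h^{2q} / Gamma(2q+1)` per component: at the reference regime over
`1e6` iterations the maxima are about
`(3.5e-5, 1.5e-5, 3.4e-5, 3.0e-5, 1.3e-6)`, inside the `1e-4` budget, and
they scale as `h^{2q}`.  Inside the multi-scroll window (e.g. `b = ±1.2`)
the audit also stays within budget.  At `b = ±1.6` — the boundary the
multi-scroll analysis itself excludes from its open interval — the
two-term map escapes: being an Euler map of the integer-order flow, it
follows that flow's finite-time blow-up once the quadratic radiation
feedback `k b w y` dominates, while the four-term map at `h = 0.001`
remains on the attractor.

`fixed_point_step()` replays the two-term update with every arithmetic
result quantised to a signed fixed-point format (default 32 bits with 26
fractional bits, covering the seven-decimal reference printout;
configurable), with `tanh` through a 1024-entry lookup table on `[-4, 4]`
with linear interpolation and saturation — a hardware-plausible datapath.
Overflow saturates and is counted.  Quantisation error shrinks
monotonically with word width; the interpolation error of the fixed-size
table (about `6e-6` near the origin) is shared by all formats, so
wide-format comparisons against a floating reference are made against a
reference that shares the lookup path when the quantisation noise itself
is the quantity of interest.

## Problem sizes and reproducibility

Every pipeline in the package is deterministic: identical configurations
produce byte-identical trajectories, labels and reports, and trajectory
CSVs serialise doubles with 17 significant digits so they round-trip
bit-exactly.  The analysis sizes used by the test and acceptance suites —
`2e5`-step exponent runs, 50-to-65-point scans with `8e4`-step
integrations and `4e4`-step attached spectra, `1e6`-step truncation audits
— were chosen as the smallest sizes at which the reported quantities are
stable at the tolerances quoted above; larger runs sharpen the estimates
but do not change any conclusion.

## Known limitations

* The restarted series scheme is memoryless; it is the method of record
  for this model family, not a reference-quality Caputo solver.  Long-run
  trajectories should be read as the dynamics of the restarted map.
* The drive is frozen per step in the memristor module (first-order
  sampling error); halve `h` rather than raising `M` for accuracy there.
* Exponent magnitudes inherit the method sensitivity of tangent-map
  estimators on non-smooth attractors; compare sign patterns and ratios
  across settings before reading small differences as dynamics.
* Cold-restart scans can shift bifurcation-point estimates by a grid step
  or two relative to continuation-style sweeps.
* One printed reference value (the fifth one-iteration component,
  `0.0045901`) disagrees with its own closed form by a factor of ten; the
  package reproduces the closed-form value `4.59e-4` and documents the
  discrepancy rather than matching the typo.
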