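# fohnn

Simulation and dynamic analysis of a four-neuron Hopfield neural network
under electromagnetic radiation, formulated as a Caputo fractional-order
system. The radiation acting on neuron 2 is modelled by a flux-controlled
memristor: the membrane flux ω integrates the membrane voltage y and feeds
the current k·y·(a + b·ω) back into the neuron. The five state equations
are

    D^q x = −x + 2.5 tanh(x) + 1.5 tanh(y) − 4.5 tanh(u)
    D^q y = −y + 2.2 tanh(y) + 2 tanh(z)   + k y (a + b ω)
    D^q z = −z + 2.3 tanh(x) − 1.5 tanh(y) + 4 tanh(u)
    D^q u = −u + 4 tanh(x)   + 1.3 tanh(y) + 0.6 tanh(u)
    D^q ω = p y − g ω

with D^q the Caputo derivative of order q ∈ (0, 1]. The package is aimed
at researchers in nonlinear neural dynamics and chaos-based engineering
who want a reproducible software counterpart of this model family:

* a generic Adomian-decomposition integrator for Caputo systems
  (`caputo_system()`, `adm_step()`, `adm_integrate()`), implemented as a
  generalized power series in t^q with exact Gamma bookkeeping;
* the memristive Hopfield model with its linear/nonlinear decomposition
  and analytic Jacobian (`hnn_system()`, `hnn_jacobian()`);
* equilibrium location and the fractional stability criterion
  |arg(λ)| > qπ/2 (`find_equilibria()`, `fractional_stability()`,
  `equilibrium_report()`);
* Lyapunov spectra, bifurcation scans, attractor classification and
  multi-scroll direction metrics (`lyapunov_spectrum()`,
  `bifurcation_scan()`, `classify_attractor()`,
  `scroll_direction_metric()`);
* the flux-controlled memristor with pinched-hysteresis diagnostics
  (`simulate_memristor()`, `hysteresis_metrics()`);
* a two-term reduced-step emulation of a fixed-point hardware datapath
  with truncation audits (`two_term_step()`, `fixed_point_step()`,
  `truncation_audit()`).

The integration cores are compiled (Rcpp); every pipeline is
deterministic. See `vignettes/fohnn-methods.Rmd` for the method details
and numerical conventions.

## Worked example

```r
library(fohnn)

# the chaotic reference regime: a=0.78, b=0.1, k=0.1, p=0.3, g=0.8, q=0.478
sys <- hnn_system(order = 0.478)

# one two-term (hardware-style) iteration from (1, 1, -1, 0, 0)
two_term_step(c(1, 1, -1, 0, 0), sys$params, q = 0.478, h = 1e-6)
#> [1]  1.0031310527  0.9988223515 -0.9975377329  0.0061759573  0.0004590141

# Lyapunov spectrum of the attractor (2e5 steps, 1e4-step transient)
lyapunov_spectrum(sys, h = 1e-3, n_steps = 2e5, n_discard = 1e4)
#> [1]   4.042412709  -0.005564695 -15.918625932

# equilibrium and fractional stability report
equilibrium_report(hnn_params(), order = 0.478)
#> Equilibrium report (q = 0.478): 1 equilibrium point(s)
#>   at (3.813e-21, -1.264e-20, 1.596e-20, -2.942e-21, -4.739e-21)
#>     eigenvalues:  0.02908+4.26078i,  0.02908-4.26078i,  0.65992+0.87205i,
#>                   0.65992-0.87205i, -0.80000+0.00000i
#>     stable at q = 0.478: TRUE (critical order 0.5876)
```

The two-term iteration reproduces the published hardware verification
values for the first four components; the fifth published value carries a
decimal-shift typo (its digits 4590 match the closed-form 4.590e-4). The
spectrum's (+, ≈0, −) pattern confirms chaos at q = 0.478, and the report
shows the model's single equilibrium at the origin — which the fractional
criterion declares stable at this order (critical order 0.588), a
coexistence the package reports as computed.

A thin command-line front end covers the same tasks:

```sh
exec/fohnn lyapunov   --preset chaos-q0478 --q 0.478
exec/fohnn bifurcation --preset chaos-q0478 --axis q --from 0.4 --to 1 --points 600 --out scan.json
exec/fohnn memristor  --Am 30 --F 5 --alpha 0.9 --out iv.csv
exec/fohnn verify-fpga --preset chaos-q0478 --format 32:26
```

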