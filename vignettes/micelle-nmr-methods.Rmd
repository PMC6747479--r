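---
title: "Models and methods: NMR analysis of peptide-micelle systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: NMR analysis of peptide-micelle systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(micellr)
```

micellr analyses the solution-state NMR observables that characterise a
transmembrane peptide inside a detergent micelle: translational diffusion
(PGSE), overall tumbling (15N relaxation), slow conformational exchange
(31P CPMG relaxation dispersion), and two sequence-level summaries
(chemical-shift perturbation and helical-wheel amphipathicity). Every
stage takes a tibble and returns a tibble or a small fitted object with
`tidy()`, `glance()` and `autoplot()` methods, and every stage has a
matching simulator with embedded ground truth so the full chain can be
validated without any experimental download.

## Translational diffusion

Echo attenuation in a pulsed-field-gradient spin-echo experiment follows
the Stejskal-Tanner law

$$I(G) = I_0\,\exp\!\big[-D\,(G\gamma\delta)^2(\Delta - \delta/3)\big],$$

with gradient strength $G$ (internally always T/m; the reader accepts
G/cm with an explicit unit header, 1 G/cm = 0.01 T/m), gyromagnetic
ratio $\gamma$ of the observed nucleus, gradient pulse length $\delta$
and diffusion time $\Delta$. `fit_st()` estimates $(I_0, D)$ by
nonlinear least squares in amplitude space — the measurement noise is
additive on amplitudes, so fitting the log would distort the error
model — with starting values from a log-linear regression and optional
inverse-variance weights when per-point errors are supplied. Both
parameters are optimised on the log scale, which enforces positivity
without constraints; standard errors are mapped back by the delta
method. $\Delta$ is never assumed: the conventional values for this
kind of sample (40 ms for 1H, 60 ms for 31P, 200 ms for 2H) are
documented but must be passed explicitly.

`invert_polydispersity()` exposes departures from single-component
behaviour by non-negative least squares of the amplitudes onto a
log-spaced grid of diffusion coefficients (default 64 points over 4
decades centred on the single-component fit), with a first-difference
Tikhonov penalty. The smoothing parameter, when not given, is chosen by
the discrepancy principle: the largest $\lambda$ whose reconstruction
residual stays at the noise floor (estimated from the single-component
residuals, or from supplied per-point errors). Two properties anchor the
implementation: a noiseless monodisperse input concentrates the weights
at the true coefficient within a grid step, and $\lambda \to \infty$
yields exactly uniform weights (the analytic limit of the
first-difference penalty, computed in closed form to avoid a terminally
ill-conditioned augmented system). A practical caveat encoded in the
tests: a component must attenuate measurably over the gradient range to
be distinguishable from baseline, so resolving a slow component may
require longer gradient pulses than the fast component alone would need.

The hydrodynamic radius follows from Stokes-Einstein,
$R_h = k_B T / (6\pi\eta D)$. The solvent viscosity is taken from a
reference table for pure water (5 K anchors, 273.15-373.15 K,
interpolated linearly in $\log\eta$ so the interpolant stays positive
and monotone) with a multiplicative heavy-water correction linear in the
D2O volume fraction (factor 1.23 at pure D2O). Users who have a
measured viscosity can pass it directly through `solvent_spec()`. No
shape-factor or obstruction corrections are applied: the radius is the
equivalent-sphere radius, and systematic growth of apparent $R_h$ with
the reporter nucleus' distance from the aggregate centre (2H or 31P
versus 1H) should be interpreted with that in mind.

## Relaxation rates

`fit_monoexp_decay()` fits $I(t) = I_0 e^{-Rt}$ (two parameters) and
`fit_inversion_recovery()` fits $I(t) = I_0(1 - A e^{-R_1 t})$ (three
parameters; $A \approx 2$ for ideal inversion). Both initialise from
deterministic closed forms (log-linear regression; first/last-point
heuristics), draw parameter covariance from the Jacobian at the
solution, and never iterate from random starts, so results are exactly
reproducible. Amplitudes that dip below zero in the noisy tail of a
strong decay are legitimate observations and are kept; only the
initialisation is restricted to positive points.

Lack of fit raises a `flagged` field rather than an error: reduced
chi-square above 3 when per-point errors are available, a residual runs
test at the 5% level otherwise. The flag is the mechanism by which a
bi-exponential decay — e.g. a peptide exchanging between micelles slowly
enough to split the relaxation — announces itself while still returning
the best single-exponential summary.

## Rotational correlation time

For an amide 15N under isotropic tumbling the dipolar + CSA expressions
are

$$R_1 = \tfrac{d^2}{4}\big[J(\omega_H-\omega_N) + 3J(\omega_N) +
6J(\omega_H+\omega_N)\big] + c^2 J(\omega_N),$$
$$R_2 = \tfrac{d^2}{8}\big[4J(0) + J(\omega_H-\omega_N) + 3J(\omega_N) +
6J(\omega_H) + 6J(\omega_H+\omega_N)\big] +
\tfrac{c^2}{6}\big[4J(0) + 3J(\omega_N)\big],$$

with $J(\omega) = \tfrac{2}{5}\tau_c/(1+\omega^2\tau_c^2)$,
$d = \mu_0\hbar\gamma_H\gamma_N/(4\pi r_{NH}^3)$ and
$c = \Delta\sigma\,\omega_N/\sqrt{3}$. Defaults $r_{NH} = 1.02$ Å and
$\Delta\sigma = -160$ ppm are the conventional amide values and are
overridable through `model_free_constants()`.

Keeping only the $J(0)$ and $J(\omega_N)$ terms gives
$R_2/R_1 = 7/6 + \tfrac{2}{3}\omega_N^2\tau_c^2$ and hence the closed
form used by `tauc_from_ratio()`:

$$\tau_c = \frac{\sqrt{6R_2/R_1 - 7}}{4\pi\nu_N}.$$

It requires $R_2/R_1 > 7/6$ and degrades gracefully to zero at that
boundary. `tauc_exact()` inverts the full expressions by bracketed root
finding on $[0.1, 100]$ ns; the two estimators agree within 5% across
the 4-25 ns range relevant to micelle-bound peptides, which is the
package's internal cross-validation of the approximation.

The static field enters only through $\nu_N$ and is a mandatory
argument — there is no default field anywhere in this module. The test
suite pins the convention by verifying that the published rate pairs for
both micelle types reproduce the published correlation times at the
600 MHz (14.1 T) field within their printed uncertainties; uncertainty
is propagated to first order from the rate standard errors and is linear
in them by construction.

## CPMG relaxation dispersion

### Forward models

`cr_r2eff()` implements the Carver-Richards closed form for two-site
exchange as a function of the $\pi$-$\pi$ pulse spacing $\tau_{cp}$ (see
the function documentation for the full expression). Two conventions are
fixed and documented prominently: $\Delta\omega$ is in angular units
(rad/s), and $\tau_{cp}$ is the $\pi$-$\pi$ spacing itself. Overflow of
the hyperbolic terms at extreme parameters is handled by a log-domain
branch, and the no-dispersion limits ($p_b = 0$, or
$\Delta\omega = 0$) are evaluated analytically.

`bm_r2eff()` is the numerical ground truth: it propagates the two-site
complex transverse magnetisation through the
$\pi/2_x - [\tau_{cp}/2 - \pi_y - \tau_{cp}/2]^n$ train using 2x2
matrix exponentials (closed form) for the free-precession/exchange
segments and complex conjugation for ideal $\pi_y$ pulses, starting from
equilibrium populations, and reports
$-\ln(|M(T)|/|M(0)|)/T$. The default total time $T = 0.2$ s is chosen
because the closed form describes the dominant (infinite-train) decay
mode: over short windows the minor exchange eigenmode has not yet died
away and contributes a transient of up to a few percent at the longest
spacings. The two models agree within 2% at all 17 schedule spacings
across the slow-exchange regime ($p_b \le 0.05$,
$k_{ex} \in [100, 1000]$ s$^{-1}$), which is asserted as a test. The
agreement validates the $\tau_{cp}$ timing convention rather than
assuming it.

The Carver-Richards curve is *not* strictly monotone in $\tau_{cp}$: it
carries genuine small oscillations with period $\approx 2\pi/\Delta\omega$
(about 1.2 ms for the measured parameter set). The tests therefore
assert the physically meaningful version of "dispersion flattens under
fast pulsing": the global minimum sits at the fastest pulsing and equals
the slow eigenvalue of the exchange-relaxation matrix, which is within
1% of the population-weighted average of the intrinsic rates here.

### Fitting and its identifiability limits

`fit_dispersion()` minimises weighted squared residuals of the closed
form over $(p_b, k_{ex}, \Delta\omega, R_{2a}, R_{2b})$ on the log
scale, inside the box $p_b \in (10^{-4}, 0.5)$,
$k_{ex} \in (1, 10^5)$ s$^{-1}$, $\Delta\omega \in (10, 10^5)$ rad/s,
rates in $(0.1, 200)$ s$^{-1}$, from a deterministic Latin-hypercube of
starting points (default 32, reproducible given `seed`). The best
converged result is returned with these rules: among starts whose
residual sums are statistically comparable to the lowest one, interior
solutions beat solutions pinned at a box bound (a minor-state rate
driven to the bound is a boundary artefact, not an estimate); the
selected solution is polished by restarting the optimiser until the step
stalls; and a fit that does not improve at all on a constant-$R_2$ model
is marked not converged, since a flat curve determines no exchange
parameter. Replicate spacings are independent observations throughout.

A single 17-point schedule truncated at $\tau_{cp} = 2$ ms does **not**
determine all five parameters. For the measured parameter regime
($k_{ex} \approx 253$ s$^{-1}$) the longest spacing is only about half
an exchange lifetime, and the model surface is flat along a valley in
which $p_b$ and $k_{ex}$ trade off (approximately preserving the
exchange contribution $p_b k_{ex}$) with small compensating shifts in
the intrinsic rates: fixing $k_{ex}$ at values between roughly 100 and
500 s$^{-1}$ reproduces the noiseless generating curve to better than
0.03 s$^{-1}$ RMS. Against measurement noise of 0.3 s$^{-1}$ this is
invisible, so no estimator can separate $p_b$ from $k_{ex}$ from such
data alone. What the data *do* pin down — and what the package's
recovery tests assert at the ensemble median — are $\Delta\omega$ (set
by the oscillation period of the curve), $R_{2a}$ (the fast-pulsing
plateau), and the product $p_b k_{ex}$. Separating the factors requires
additional information: a second static field, spacings well beyond the
exchange lifetime, or an independently measured exchange-free $R_{2b}$
(for a micelle system, the empty-micelle measurement) imposed as a
constraint. Interestingly, the numerical Bloch-McConnell observable over
a realistic finite relaxation window does discriminate along the valley
at the 1-2 s$^{-1}$ level — the degeneracy is a property of the
asymptotic closed form — which suggests fitting finite-window
simulations as another way out; the package keeps the conventional
closed-form fit as its estimator and surfaces the limitation instead of
hiding it.

`detect_exchange()` compares the flat model against the dispersion fit
with an F-test (4 numerator degrees of freedom). On flat 10-point
curves with 0.3 s$^{-1}$ noise the measured false-positive rate is
conservative (well below the nominal 5%), and the measured power on the
measured-parameter curves exceeds 95%; both are asserted over seeded
ensembles in the test suite.

## Synthetic data

The generators share one seeded Gaussian noise model with per-generator
sub-streams (derived by hashing the generator name with the seed), so a
single seed yields independent noise across stages and bit-identical
series on repetition. Acquisition schedules are shipped as named
presets: the ten- and eight-point 15N relaxation series, the ten-point
31P inversion recovery and nine-point 31P decay, the 17-spacing and
10-spacing CPMG schedules (duplicate spacings kept as independent rows),
and a 25-step gradient ramp up to the 0.6 T/m probe maximum. The
gradient pulse length defaults to 4 ms, a typical value for micelle
diffusion measurements, since no single value is canonical.

The simulators emulate additive, homoscedastic Gaussian amplitude noise
on ideal forward models. They do not emulate lineshape distortion,
baseline or phase errors, $B_1$ inhomogeneity and pulse miscalibration,
temperature drift, or correlated noise between points. Passing recovery
tests therefore demonstrates correctness of the estimators under the
stated error model, not robustness to every artefact of real spectra;
the goodness-of-fit flags and the polydispersity inversion are the
in-package tools for noticing when real data depart from the model.

## Sequence-level summaries

`csp()` reports signed per-residue shift differences
$\Delta\delta_i = \delta_{b,i} - \delta_{a,i}$ for one atom type
(negative = upfield in medium b), keeping residues missing from either
table explicitly marked rather than zero-filled; a combined
$\sqrt{\Delta\delta_H^2 + (\Delta\delta_N/5)^2}$ magnitude is available
but off by default since single-atom signed differences are what the
underlying comparison uses.

`helical_wheel()` places residue $i$ at $((i-1)\cdot 100°) \bmod 360°$
(3.6 residues per ideal α-helical turn, rotation configurable) and
classifies faces by a configurable hydrophobic set
(default A, C, F, I, L, M, V, W). `amphipathicity()` summarises face
segregation by the circular mean resultant length of the hydrophobic
residues' angles, with a heuristic threshold of 0.4 for the amphipathic
flag. A deliberate design point: for the transmembrane fragment this
package was exercised on, the sequence-only wheel is *not* amphipathic —
roughly two-thirds of the helix is hydrophobic, so the hydrophobic
resultant is near zero whichever window is chosen. Face segregation of
such a helix in a zwitterionic micelle is driven by its molecular
environment, and assigning faces from simulation-derived contact data is
outside this package's scope; the statistic is designed for sequences
whose periodicity itself is amphipathic, and the tests exercise it on a
designed example.

## Problem sizes and runtime choices

The test suite and the acceptance script use desk-scale ensembles chosen
to give stable medians while keeping a full run in minutes on one core:
50 replicates for the dispersion simulate-and-refit study (32 starts
each), 500/100 seeds for the detection size/power ensembles, 100-200
seeds for the diffusion and relaxation recovery studies, and 2000 seeds
for the law-of-large-numbers check on the generators. Determinism
everywhere comes from explicit seeds; no test depends on global RNG
state.

## Known limitations

- Two-site exchange only; no three-site or off-resonance ($R_{1\rho}$)
  models.
- Single-field analysis; the $p_b$/$k_{ex}$ degeneracy discussed above
  is the direct cost.
- Isotropic tumbling only: no anisotropic diffusion tensor, no
  Lipari-Szabo internal-motion parameters, and no separation of the
  exchange contribution from $R_2$ before the $\tau_c$ inversion — an
  exchange-broadened $R_2$ biases $\tau_c$ upward, which is exactly the
  regime flagged by the dispersion module.
- Stokes-Einstein assumes a sphere; apparent radii from off-centre
  reporter nuclei carry shape information the model does not represent.
- The viscosity table covers 273-373 K liquid water; other solvents
  must be supplied explicitly.
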