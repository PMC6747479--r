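# micellr

Quantitative NMR analysis of peptide–micelle systems in R.

Solution NMR is the workhorse for studying how a hydrophobic
transmembrane peptide sits inside a detergent micelle. A single sample
yields several complementary observables, each needing its own small
piece of quantitative analysis:

- **Translational diffusion** — pulsed-field-gradient spin-echo (PGSE)
  amplitudes decay as the Stejskal–Tanner law
  `I = I0·exp(−D(Gγδ)²(Δ−δ/3))`; the fitted coefficient `D` converts to
  a hydrodynamic radius via Stokes–Einstein `Rh = kB·T/(6πηD)`, sizing
  the peptide–micelle complex.
- **Overall tumbling** — 15N `R1` and `R2` relaxation rates, fitted from
  exponential series, invert to the rotational correlation time under
  the isotropic rigid-rotor model, `τc = √(6·R2/R1 − 7)/(4πνN)`.
- **Slow conformational exchange** — 31P CPMG relaxation dispersion
  `R2,eff(τcp)` is fitted with the Carver–Richards two-site exchange
  model (populations `pa`, `pb`, exchange rate `kex`, shift difference
  `Δω`, intrinsic rates `R2a`, `R2b`), cross-validated against a
  numerical Bloch–McConnell propagator, with an F-test for whether
  exchange is present at all.
- **Sequence summaries** — signed chemical-shift perturbations between
  two media and helical-wheel amphipathicity statistics.

Everything is tidyverse-native: data frames in, tibbles out, fitted
objects with `tidy()`, `glance()` and `autoplot()` methods. A
synthetic-data module generates every series type at realistic
acquisition schedules with known ground truth, so the entire chain is
testable end to end without experimental data.

## Worked example

```r
library(micellr)

# --- how big is the peptide-micelle complex? ---------------------------
echo <- sim_echo_series(i0 = 100, d = 8.2e-11, sigma = 1, seed = 1)
stf <- fit_st(echo, "1H", delta = 4e-3, big_delta = 40e-3)
stf
#> Stejskal-Tanner fit (1H)
#>   D_tr = 8.211e-11 +/- 1.3e-12 m^2/s
#>   I0   = 99.9 +/- 0.54
stokes_einstein_rh(stf$d_tr, solvent_spec(303))
#> Hydrodynamic radius: 33.8 Angstrom (D = 8.21e-11 m^2/s, T = 303.0 K, eta = 0.0008 Pa s)

# --- how fast does it tumble? ------------------------------------------
f <- field_spec(proton_frequency = 599.98e6)   # 14.1 T spectrometer
tauc_from_ratio(1.59, 10.01, f, r1_error = 0.08, r2_error = 0.81)
#> tau_c = 7.26 +/- 0.42 ns (ratio_approximation)

# --- is there slow exchange, and what does it look like? ---------------
truth <- exchange_params(p_b = 0.028, k_ex = 253, delta_omega = 5.2e3,
                         r2_a = 31.25, r2_b = 5.26)
curve <- sim_dispersion(truth, "cpmg_tm4_17", sigma = 0.3, seed = 1)
detect_exchange(curve, seed = 2)
#> Exchange detected: F = 353, p = 2.5e-12 (alpha = 0.05)

flat <- sim_dispersion(exchange_params(0, 0, 0, 12, 12),
                       "cpmg_empty_10", sigma = 0.3, seed = 2)
detect_exchange(flat, seed = 2)
#> Exchange not detected: F = 1.92, p = 0.246 (alpha = 0.05)

fit <- fit_dispersion(curve, n_starts = 32, seed = 1)
autoplot(fit)
```

Reading the numbers: the 33.8 Å radius is a typical detergent micelle
carrying a peptide; `τc` = 7.26 ns is the tumbling time of that complex
derived purely from the two relaxation rates (the quoted ±0.42 ns is
first-order propagation of the rate uncertainties); the dispersion
F-test cleanly separates a loaded micelle (strong exchange) from an
empty one (flat curve).

One caution that the package makes explicit rather than hiding: on a
single 17-point dispersion schedule, `p_b` and `k_ex` are individually
poorly determined — they trade off along a flat valley of the
Carver–Richards model, and only `Δω`, `R2a` and the product `p_b·k_ex`
are stable. See the methods vignette
(`vignettes/micelle-nmr-methods.Rmd`) for the full identifiability
analysis and what additional data resolve it.

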