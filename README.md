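# photodyn

Simulation and analysis of the **dynamical adaptation (DA) model** of
photoreceptor light response.

Cone photoreceptors adapt *dynamically*: the gain and the time scale of
their response to light both depend on the recent history of the input,
over the same few hundred milliseconds that the response itself lasts.
The DA model captures this with a feedforward first-order equation for
the response `R(t)` (the deviation of the membrane potential from its
dark resting value, in mV):

    tau_r dR/dt = alpha * y(t) - (1 + beta * z(t)) * R(t)

where `y = Ky * I` and `z = Kz * I` are two filtered copies of the light
intensity `I(t)` (photons/µm²/ms).  `Ky` is a unit-area gamma filter
`Ky(t) ∝ (t/τ_y)^n_y e^{-t/τ_y}`; `Kz = γ Ky + (1-γ) Ks` adds a slower,
delayed gamma component `Ks(n_z, τ_z)`.  The multiplicative `(1+βz)`
term divisively sets both the instantaneous gain, `α/(1+βz)`, and the
instantaneous time constant, `τ_r/(1+βz)` — so smaller gains come with
faster kinetics (the gain–bandwidth trade-off), incremental sensitivity
falls as `1/I_B` on bright backgrounds (the Weber–Fechner law), and the
flash response turns from monophasic to biphasic as the background
brightens.  Being feedforward, the equation has an exact closed-form
solution for any input, which the package evaluates alongside an
exponential-Euler integrator as a built-in cross-check.

The package is aimed at modellers and physiologists who want to

* simulate the model under flash, step, sinusoidal, Gaussian-flicker and
  naturalistic-surrogate stimuli (`simulate_da`, `simulate_da_exact`,
  the `make_*` generators);
* use its analytic limits: small-flash perturbation, bright-background
  algebraic form, linearised transfer function, Weber curve, and the
  Gaussian-flicker mean/flash-response statistics with their
  correlation-weighted kernel overlaps (`small_flash_response`,
  `bright_limit_flash_response`, `weber_sensitivity_curve`,
  `frequency_gain_curve`, `flicker_mean_response`,
  `flicker_flash_modulation`, `kernel_overlaps`);
* run the LN-cascade comparison pipeline used to detect dynamical
  adaptation in recorded data: reverse-correlation filter, cubic static
  nonlinearity, instantaneous gain, percentile-conditioned filters and
  circular-shift significance tests (`estimate_ln`,
  `instantaneous_gain_series`, `grouped_gain_analysis`,
  `circular_shift_pvalue`);
* fit the eight model parameters to stimulus/response traces and map
  the goodness-of-fit landscape (`fit_da_model`, `goodness_of_fit`,
  `sensitivity_scan`).

The four published parameter sets (salamander cone flicker fit; the
turtle-cone data sets BHL, B and DN) ship as JSON fixtures
(`da_preset("BHL")` etc.).

## Worked example

Flash responses in the dark with the BHL parameter set:

```r
library(photodyn)
p <- da_preset("BHL")
fam <- run_flash_family(p, photons = 41 * 2.1^seq(0, 16, by = 4),
                        dt = 0.1)$summary
fam
#>        photons     peak_mV  delay_ms  flat
#> 1      41.0000  -0.2846592 100.52250 FALSE
#> 2     797.3721  -4.7462076  96.66389 FALSE
#> 3   15507.3723 -22.2820610  66.28805 FALSE
#> 4  301588.9280 -26.5468892  42.64455 FALSE
#> 5 5865331.6300 -26.8555594  28.31412 FALSE
```

The peak hyperpolarisation grows with flash strength and saturates near
`alpha/beta = 25 mV`, while the peak delay keeps dropping even after the
amplitude has saturated — gain and kinetics co-vary.  A single absorbed
photon (1 photon/µm², `alpha = 2`) evokes a peak response of about
13 µV in these parameter sets:

```r
p$alpha <- 2
g <- time_grid(0, 0.1, 8000)
stim <- make_flash_stimulus(1, onset = 10, duration = 1, grid = g)
1000 * max(abs(simulate_da(stim, p)$response))
#> [1] 12.7476
```

A command-line wrapper is provided for shell use:

```sh
exec/photodyn stimulate --type flicker --mean 100 --contrast 0.35 \
    --seed 7 --duration 30000 --out stim.csv
exec/photodyn simulate --stim stim.csv --params salamander --out resp.csv
```

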