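---
title: "Model-free pyrolysis kinetics with thermokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-free pyrolysis kinetics with thermokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermokin)
```

## The model

Non-isothermal thermogravimetry (TGA) records the mass of a sample while it
is heated at a constant rate $\beta$ (K min$^{-1}$). For a single-step
solid-state decomposition the fractional conversion
$\alpha = (w_0 - w_t)/(w_0 - w_f)$ evolves as

$$\frac{d\alpha}{dT} \;=\; \frac{A}{\beta}\, f(\alpha)\,
  \exp\!\left(-\frac{E_a}{RT}\right),$$

where $E_a$ is the activation energy (J mol$^{-1}$), $A$ the
pre-exponential factor (min$^{-1}$), and $f(\alpha)$ the differential
mechanism function of the reaction model. The triplet
$(E_a, A, f(\alpha))$ fully specifies the kinetics. The temperature
integral of this equation has no closed form, which is why the package
integrates it numerically and why the classical model-free methods below
each linearise it with a different approximation.

`simulate_conversion()` integrates the rate law with `deSolve::lsoda`
(rtol $10^{-8}$, atol $10^{-12}$): the exponential term makes the problem
stiff near the onset, and an adaptive stiff-capable solver handles the
whole reaction-model catalogue (`F0.5/F1/F2/Fn`, Avrami `A2/A3`, diffusion
`D1–D3`, contracting geometry `R2/R3`) without step-size tuning. Because
several models are singular at $\alpha = 0$ (e.g. D1 with
$f = 1/2\alpha$), integration starts at $\alpha_0 = 10^{-10}$ and the
offset is subtracted so that $\alpha(T_{\text{start}})$ is exactly zero.
If $\alpha$ completes before the end of the program it is clamped at 1
with a warning; the returned $d\alpha/dT$ is evaluated from the rate-law
right-hand side at the solved $\alpha$, not by differencing the solution.

## What the synthetic generator emulates — and what it does not

The default scenario mirrors a pharmaceutical-powder pyrolysis study:
about 10 mg of sample, a dominant single decomposition stage between
roughly 490 and 780 K, and heating rates $\beta \in \{10, 20, 30, 40\}$
K min$^{-1}$. The generator defaults to the first-order model F1: the
governing mechanism of metformin decomposition is not established, and F1
is the conventional neutral choice for a dominant single stage.
Measurement imperfections are modelled as multiplicative Gaussian mass
noise (relative sd, typically $10^{-3}$–$2\times 10^{-3}$ for a modern
microbalance) plus an optional linear baseline drift per kelvin.

What it deliberately does **not** emulate: multi-step or parallel
reactions, heat- and mass-transfer gradients inside the sample bed,
buoyancy/baseline artefacts of real instruments, and moisture release.
Passing parameter-recovery tests on this generator therefore shows that
the estimation chain is correct *given* single-step Arrhenius kinetics;
it does not show that real thermograms satisfy those assumptions.

## From thermogram to activation energies

`compute_conversion()` applies the conversion definition over an analysis
window, restores monotonicity by a running-maximum clip of noise-induced
inversions (the largest clipped magnitude is kept in the `"clip"`
attribute), and differentiates with an order-2 Savitzky–Golay filter
(default window 11 points, odd, configurable). Friedman's method is the
noise-sensitive one — it uses the rate directly — and the 5% accuracy it
reaches at mid-conversions under 0.2% mass noise depends on this
smoothing; on noiseless data a window of 0 (plain central differences)
is less biased and is what the package's own exactness checks use.

`temperatures_at_conversions()` inverts each curve with shape-preserving
monotone piecewise-cubic interpolation (`splinefun(method = "monoH.FC")`),
which cannot overshoot between samples; rates are interpolated linearly.
The default conversion grid is $\alpha = 0.10$ to $0.80$ in steps of
$0.05$, the range over which single-stage kinetics are usually clean;
both ends of the decomposition are affected by secondary processes in
real data.

Four linearizations are fitted per conversion level by unweighted
ordinary least squares of the ordinate on $1/T$ across heating rates
($R^2 = 1 - SS_{res}/SS_{tot}$ on the transformed ordinate):

| method | ordinate | $E_a$ from slope |
|---|---|---|
| KAS | $\ln(\beta/T^2)$ | $-sR$ |
| FWO | $\ln\beta$ | $-sR/1.052$ |
| Starink | $\ln(\beta/T^{1.92})$ | $-sR/1.0037$ |
| Friedman | $\ln(\beta\, d\alpha/dT)$ | $-sR$ |

The FWO (Doyle) constants are fixed at 5.331 and 1.052 and the Starink
constants at 1.92 and 1.0037, the values conventional in this
literature. Friedman is implemented as a single per-conversion
regression; some descriptions mention a two-step fitting variant, but no
operational definition of it exists, so the plain OLS form is used and
documented here.

### A note on FWO bias

The Doyle linearisation assumes the local slope of the log temperature
integral is $-1.052$, which is accurate for $x = E_a/RT \gtrsim 30$. At
the conditions of the default scenario $x$ spans only about 20–24, where
the true slope is $\approx -(1 + 2/x) \approx -1.09$, so FWO
systematically overestimates $E_a$ by about 3.5% — a property of the
method itself, reproducible by direct quadrature of the temperature
integral with no simulation involved. KAS and Starink, whose
linearizations carry the $T^2$ (resp. $T^{1.92}$) factor, stay within
about 0.4% under the same conditions, and Friedman, which uses no
integral approximation at all, within 0.05%. This ordering is exactly
what the package's recovery tests assert.

## Kissinger analysis and activation thermodynamics

The DTG peak temperature $T_p$ shifts with heating rate as
$\ln(\beta/T_p^2) = -E_a/(R T_p) + \ln(AR/E_a)$; `kissinger_regression()`
fits this line and returns $E_a$ and $A = (E_a/R)\,e^{\text{intercept}}$.
For a first-order model the peak obeys the stationarity condition
$E_a \beta / (R T_p^2) = A \exp(-E_a/(R T_p))$, which
`predict_peak_temperature()` solves by bracketed root-finding (relative
tolerance $10^{-10}$) — this closed-loop consistency (simulate → find
peak → regress → recover $E_a$) is the package's strongest internal
check, accurate to 0.5%.

Per conversion, the frequency factor
$A = \beta E_a \exp(E_a/(R T_p)) / (R T_p^2)$ is evaluated at every
$(\beta, T_p)$ pair and combined as a geometric mean — the natural
average for a quantity entering the rate law exponentially; published
per-conversion $A$ values rarely state which pairing was used, and the
geometric mean is reproducible and symmetric. The activation
thermodynamics are

$$\Delta G = E_a + R T_p \ln\!\frac{k_B T_p}{h A},\qquad
  \Delta H = E_a - R T_\alpha,\qquad
  \Delta S = \frac{\Delta H - \Delta G}{T_m}.$$

Two conventions must be fixed because the field's papers rarely state
them:

* **Units of $A$ in $\Delta G$**: $k_B T / h$ has units s$^{-1}$, so $A$
  is converted from min$^{-1}$ to s$^{-1}$ (divide by 60) before the
  ratio. Published tables are not always consistent on this point, which
  shifts $\Delta G$ by $R T \ln 60 \approx 20$ kJ mol$^{-1}$; the package
  uses the dimensionally consistent convention.
* **$T_\alpha$ and $T_m$**: $\Delta H$ uses the mean over heating rates
  of $T(\alpha)$ (so $\Delta H$ varies with conversion, as published
  tables show), and $T_m$ defaults to the DTG peak at the lowest heating
  rate, exposed as an argument since sources do not define it separately
  from $T_p$.

The $\Delta H$ and $\Delta S$ identities hold to machine precision for
every emitted row by construction, and $\Delta G > 0$
(non-spontaneity) throughout the default scenario.

## Product yields

`compute_yields()` implements the standard three-phase balance from
apparatus weighings: liquid from the condenser train mass gains, char
from the reactor flask gain, and gas strictly by difference — in mass
*and* in percentage — so the yields close to exactly 100 wt%. Replicates
are summarised as mean ± sample sd.

## The ANN surrogate

`train_ann()` fits a feed-forward network with one hidden layer of
logistic units and a linear output, mapping (temperature, heating rate)
to fractional mass loss. Design choices:

* **Regularised least squares instead of evidence maximisation.** The
  Bayesian-regularisation trainer popular in MATLAB workflows is
  approximated by the penalised objective $SSE + \lambda\lVert w
  \rVert^2$ with $\lambda$ selected on the validation split from
  $\{10^{-4}, 10^{-3}, 10^{-2}\}$; only the MSE/correlation outcomes are
  comparable across implementations anyway.
* **One hidden layer of 4 neurons** is the default architecture; the
  training engine (`nnet`) supports exactly one hidden layer, and wider
  or narrower layers are a parameter.
* **Epochs** are warm-started BFGS segments (default 25 × 200
  iterations); the validation MSE is recorded after each and the weights
  of the best segment are kept (`best_epoch`). Long segments matter:
  restarting BFGS too frequently discards curvature information and
  stalls the fit.
* **Splitting** is random by row (60/20/20 train/test/validation, exact
  to one row of rounding) under the spec seed; rows, initial weights and
  hence the whole training trajectory are reproducible end to end.
* Predictions are clamped to $[0, 1]$; monotonicity in temperature is
  *not* enforced, and queries outside the training temperature range
  warn about extrapolation.

On the 840-row synthetic dataset (4 noiseless curves × 210 grid points)
the surrogate reaches a test-set correlation above 0.999; reproducing any
particular instrument study's exact MSE is out of scope since such data
are not deposited.

## Numerical choices and degenerate inputs

* OLS fits use the closed-form simple-regression formulas; designs with
  fewer than 3 distinct heating rates, or identical abscissae, raise
  errors rather than produce meaningless slopes.
* Conversion levels a truncated curve never reaches become `NA` cells
  (with a warning) and are dropped per level, with `n_points` recorded.
* DTG maxima on a window boundary are rejected — a boundary maximum means
  the window does not contain a peak.
* Ties in the DTG maximum break towards the lowest temperature.
* Problem sizes used by the package's own checks: temperature step 0.5 K
  (fine-grid oracles use 0.01–0.02 K), four heating rates, 15-point
  conversion grids — small enough to run interactively, large enough that
  interpolation error (< 0.05 K) is negligible against the 0.5–5%
  tolerances of the kinetic quantities.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  scenario = list(Ea = 105e3, A = 1e9, model = "F1", w0 = 10, wf = 1,
                  T_start = 450, T_end = 800, step = 0.5,
                  betas = c(10, 20, 30, 40)),
  ann = list(n_points = 210), seed = 1)
res <- run_pipeline(cfg)
res
```

## Known limitations

Single-step kinetics only — overlapping stages must be windowed out by
the user; no baseline or buoyancy correction for real instrument exports;
the isoconversional assumption (one $E_a(\alpha)$ common to all heating
rates) is inherited, not tested; FWO retains its low-$x$ bias by design,
since the conventional Doyle constants are part of the method's
definition.
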