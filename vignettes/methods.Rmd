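---
title: "Models and numerical methods behind picostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods behind picostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picostat)
```

`picostat` is a virtual instrument: a software model of a coin-sized
potentiostat built from an LMP91000-class analog front end driven by a
microcontroller DAC, together with synthetic electrochemical cells, so that
the entire measurement chain — excitation waveform, voltage quantization,
cell current, transimpedance readout, filtering, and peak analysis — can be
exercised and tested without hardware. This vignette documents the models,
their assumptions, the tunable parameters, and the numerical choices.

## 1. The dual-stage voltage reference

The front end's internal bias generator outputs a *fraction* of the voltage
at its VREF pin. The stock part exposes 14 fractions (0, 1, 2, 4, ..., 24 %,
`bias_ladder()`), so with VREF tied to a 3.3 V rail the coarsest adjacent
setpoints are 66 mV apart (`stock_resolution()`), 54 mV at the part's 2.7 V
minimum supply. Driving VREF from an n-bit DAC multiplies the two stages:
the achievable cell bias is

$$ V_\text{bias} = s \cdot f_j \cdot \frac{c\,V_\text{supply}}{2^n - 1},
\qquad s \in \{+1,-1\},\; f_j \in \text{ladder},\; c \in [0, 2^n-1]. $$

With a 10-bit DAC at 3.3 V the fixed-top-fraction spacing is
$0.24 \times 3.3/1023 \approx 0.77$ mV — the "~1 mV resolution" regime — and
the full range is exactly $\pm 0.24 \times 3.3 = \pm 0.792$ V.

**DAC transfer convention.** We use the divisor $2^n - 1$, under which the
full-scale code reaches the supply exactly; this is the transfer of the
SAMD21-class DACs this design uses, and it is the only convention under
which the advertised $\pm 0.792$ V range is exactly attainable. The
alternative $2^n$ convention is available via
`dac_spec(full_scale = "pow2")`. The often-quoted "3.3 mV" LSB is a rounded
statement ($3.3/1023 = 3.226$ mV).

**Quantization.** `quantize_bias()` supports two strategies.
`fixed_max_fraction` pins the ladder at its top tap and moves only the DAC
(constant spacing, monotone, what simple firmware does);
`exhaustive` searches all $2 \times 14 \times 1024$ (sign, fraction, code)
triples for the global minimum absolute error. Ties are broken
deterministically: smaller DAC-code change from the previous setting (less
glitch energy on the VREF pin), then smaller fraction, then positive sign.
The cell polarity mechanism of the physical part is not documented, so sign
is abstracted as an attribute of the setting.

## 2. Excitation waveforms

All four techniques produce a `waveform`: strictly increasing sampling
instants `times` (the end of each dwell), the ideal setpoint applied during
each dwell, and the indices at which current is recorded.

* **CV** (`generate_cv()`): triangular staircase from `v_start` toward
  `v_vertex1`, to `v_vertex2`, and back, `n_cycles` times; dwell =
  `step / scan_rate`. The initial sweep direction is toward `v_vertex1`, so
  direction is explicit in the parameter order. The staircase closes at
  `v_start` every cycle and meets the requested extrema exactly.
* **SWV** (`generate_swv()`): base staircase from `v_start` to `v_stop`;
  each period ($1/f$) holds base $+a$ for the first half and base $-a$ for
  the second, the pulse sign oriented along the sweep direction
  (`pulse_first = "against"` flips it). Samples are taken at the end of each
  half-cycle — the standard SWV convention — and
  `swv_difference_current()` returns $i_\text{fwd} - i_\text{rev}$ against
  the base potential.
* **NPV** (`generate_npv()`): pulses of growing amplitude from a holding
  potential, the k-th pulse at `v_base + k·step` (k = 0, 1, ...), lasting
  `pulse_width` out of every `pulse_period`; sampled at pulse end.
* **CA** (`generate_ca()`): one pre-step sample at the holding potential,
  then a step held for `duration`, sampled at `sample_rate`.

Spans that are not integer multiples of the step keep the requested
endpoint by appending a short final step, with a warning. A hardware-derived
scan-rate ceiling (0.23 V/s for the physical device) is a property of the
real instrument's timing, not of the model, so it is not enforced here.

`quantize_waveform()` maps every ideal setpoint through `quantize_bias()`;
for any in-range waveform the worst-case error is half the strategy's
setpoint spacing (checked against a brute-force oracle in the tests).

## 3. Synthetic cells

The package ships two cell models chosen to mirror the two chemistries such
an instrument is validated with: a freely diffusing reversible couple
(ferricyanide-like) and a surface-adsorbed reversible species
(methylene-blue aptamer-like).

### 3.1 Diffusing Nernstian couple

`simulate_diffusive()` solves 1-D semi-infinite diffusion,
$\partial_t c = D\,\partial_x^2 c$, by explicit finite differences with an
equilibrium (Nernstian) surface boundary:
$c_R(0) = C/(1+\theta)$, $\theta = \exp[nF(E - E^0)/RT]$. Both halves of
the couple share one diffusion coefficient, so the total concentration
profile stays uniform and only one species is tracked. The current is the
surface flux, $i = nFAD\,\partial_x c_R|_0$, anodic positive, evaluated
with a second-order one-sided gradient.

Numerics: the sub-step is the shortest dwell divided by `n_sub` (default
25); the spatial step follows from the stability cap
$\lambda = D\Delta t/\Delta x^2 \le 0.45$ (default; the explicit scheme
requires $\le 0.5$); the domain spans six diffusion lengths
$6\sqrt{DT_\text{total}}$ with a fixed-concentration outer boundary; the
march itself is a small C++ kernel. A resource guard raises a configuration
error instead of attempting an over-resolved march. `quiet_time` holds the
first setpoint before the sweep (an equilibration period, as on real
instruments) without reporting its currents.

**Staircase sampling point.** A staircase only reproduces the classical
linear-sweep response if the current is read part-way through each step:
end-of-step sampling under-reads the Randles–Ševčík peak by roughly 7 % at
1 mV steps (the deficit shrinks as $\sqrt{\Delta E}$). Following the
classical staircase-voltammetry equivalence result, the simulator reads the
faradaic current a quarter of the way into each dwell for CV
(`sample_point = 0.25`), which brings the peak within ~1.5 % of
Randles–Ševčík at 1 mV steps, and at the end of the interval (definitional)
for SWV, NPV and CA. Both the Randles–Ševčík and Cottrell limits are
asserted in the test suite at 5 %.

### 3.2 Adsorbed reversible species

For a surface-confined monolayer the oxidized fraction follows the Nernst
equation at each setpoint, $f = \theta/(1+\theta)$, and the reported
current is the faradaic charge passed during the dwell divided by its
duration: $i_k = nFA\Gamma_\text{eff}\,(f_k - f_{k-1})/\Delta t_k$ with
$\Gamma_\text{eff} = \Gamma \cdot \text{gain}$. This dwell-averaged
convention makes the instantaneous-equilibration model meaningful under
pulsed techniques. The ideal CV of this model peaks exactly at $E^0$ with
zero anodic/cathodic separation and height $n^2F^2vA\Gamma/4RT$ (asserted
at 2 % in the tests); the ~20 mV separation seen on real aptamer
electrodes is an instrumental/uncompensated-resistance effect that this
reversible model deliberately omits. Target binding of a signal-on aptamer
is modeled as a pure multiplicative gain on the electroactive coverage,
since what such experiments quantify is the percent signal change.

`add_background()` contributes double-layer charging ($C_{dl}\,dE/dt$,
averaged per dwell) and a constant offset.

### 3.3 Fixtures

`make_fixture()` builds seven deterministic datasets using the technique
parameterizations of the underlying experiments (CV 0 V start over
−0.2..+0.45 V at 50 mV/s; SWV at 31.25 Hz over −0.2..+0.5 V for the couple;
CV −0.04 V start over −0.45..−0.02 V, 7 cycles, and SWV at 62.5 Hz over
−0.03..−0.5 V for the aptamer; CA −0.2→+0.2 V, 40 s at 10 Hz; NPV
−0.2→+0.5 V, 10 mV/50 ms/200 ms). Cell constants the experiments do not
publish are documented plausible defaults, declared once in the fixtures
file: a 2 mm gold disc ($A = 0.0314$ cm²), $D = 7.6\times10^{-6}$ cm²/s,
5 mM couple concentration, $E^0 = 0.15$ V (midway between the observed
oxidation/reduction peaks), aptamer $E^0 = -0.345$ V (center of the
documented reduction window) and coverage $1.8\times10^{-12}$ mol/cm²,
calibrated once so the blank SWV peak sits at the ~1 µA scale of the real
sensor. The cocaine fixture scales the coverage by 1.44/1.04, the ratio of
the published bound/blank peak currents. Noise defaults are a 1.5 nA white
floor plus a 0.5 nA residual 60 Hz tone (fixtures emulate recordings made
*after* the feedback RC filter).

The ferricyanide CV fixture runs two cycles and is analyzed on the final
one: the first scan of a fresh cell is history-dependent, and the
tangent-baseline peak measure only becomes direction-symmetric on the
quasi-reproducible later cycles. Recording a conditioned scan is standard
electroanalytical practice.

What the fixtures deliberately do **not** emulate: electrode fouling,
oxygen interference, pH dependence, uncompensated resistance, aptamer
binding kinetics, or a quantitative dose–response. Passing tests therefore
demonstrate the correctness of the instrument model and analysis chain on
idealized reversible chemistry, not performance on real sensor data.

## 4. Readout model

`tia_output()` maps cell current to the amplifier output,
$v = z\,V_\text{ref} + iR_f$, clipped at the rails with a saturation flag
(clipping is a condition, not an error). The internal zero is a fraction
$z$ of VREF (default 0.5, configurable — the physical part's setting is not
documented in the design being modeled, only that the zero tracks VREF);
because VREF moves with the DAC, the zero moves with every setpoint, and
`current_from_output()` recovers the current by subtracting the zero the
firmware set and dividing by the feedback impedance — the exact inverse in
the unsaturated region. A multiplicative TIA `gain_error` (datasheet
tolerance up to ~5 %) is available and defaults to 1.

The feedback RC network is a first-order low-pass,
$f_c = 1/2\pi R C$ (`rc_cutoff()`); `lowpass_first_order()` realizes it on
sampled series with the step-invariant recurrence
$y_k = y_{k-1} + (1 - e^{-2\pi f_c/f_s})(x_k - y_{k-1})$, initialized at
the first sample (no startup transient, DC gain exactly 1). Its measured
tone attenuation matches $1/\sqrt{1+(f/f_c)^2}$ within 2 % across
$f/f_c \in [0.1, 20]$ in the tests. `add_noise()` adds white Gaussian
current noise and a 60 Hz line tone, reproducibly under a fixed seed.

## 5. The analyst

`fit_baseline()` implements the firmware's closed-form least-squares sums
for the tangent line $y = b_0 + b_1 x$ over the baseline window; the test
suite pins it against an independent normal-equations solve at $10^{-10}$
relative. `find_peak()` extrapolates the tangent under the peak window and
reports the maximal deviation, $i_p = \max_i s\,[y_i - (b_0 + b_1 x_i)]$
with $s = +1$ anodic, $s = -1$ cathodic (one sign-flip rule rather than
separate formulas). Cyclic inputs are first restricted to the final
full-span sweep in the relevant direction (forward for anodic, reverse for
cathodic); short closing stubs back to the start potential are excluded by
a 90 %-of-max-span filter. Region endpoints may be given in either order
and are normalized to lo < hi. No smoothing is applied before peak finding.

`default_regions()` carries the documented analysis windows: ferricyanide
oxidation baseline [−0.185, −0.03] V / peak [0.14, 0.30] V, reduction
baseline [0.30, 0.40] V / peak [0.03, 0.17] V, and the aptamer reduction
baseline [−0.20, −0.05] V / peak [−0.375, −0.315] V (vs. Ag/AgCl).

`noise_stats()` uses the *sample* standard deviation (n − 1 denominator;
pinned by a two-point test) and defines the limit of detection as exactly
$3\sigma$ — so a 1.5 nA floor implies a 4.5 nA LOD. `compare_voltammograms()`
interpolates the test trace linearly onto the reference grid over the
common potential support before computing the RMSE, and uses the reference
instrument's peak in the denominator of the percent error; percent-error
conventions differ between laboratories, and this package documents its
own rather than matching any particular published figure.
`signal_gain()` is the relative peak increase in percent.

## 6. Pipeline, formats, determinism

`run_pipeline()` chains waveform → exhaustive quantization → cell
simulation *on the achieved (quantized) potentials* → background → noise →
RC filter → TIA → current recovery → voltammogram → peak analysis, taking
a nested list or YAML file. Every random draw flows from the single config
seed through an RNG-state-preserving helper, so identical configs produce
identical reports. Voltammograms exchange as plain CSV
(`potential_V,current_A[,time_s]`, '#'-prefixed header lines for metadata,
17 significant digits) with a lossless read/write round trip; currents
labeled mA/µA/nA are converted to amperes on read. A thin command-line
wrapper (`exec/picostat`) exposes quantize / waveform / simulate / analyze /
noise / pipeline.

## 7. Problem sizes and known limitations

The bundled simulations are desk-scale by construction: the densest fixture
(two-cycle, 1 mV CV) marches ~65 k sub-steps over ~750 spatial nodes in
well under a second via the C++ kernel, and the full test suite runs in
tens of seconds. Known limitations: reversible (Nernstian) kinetics only —
no Butler–Volmer rate limitation; equal diffusion coefficients within the
couple; no uncompensated-resistance or instrumental peak-separation
emulation; linear interpolation in instrument comparison assumes monotone
potential grids (extract a sweep segment from cyclic data first); and the
readout ADC is not modeled (the TIA output is treated as read with full
precision).
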