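---
title: "Tray-level biomass sensing: models, corrections and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tray-level biomass sensing: models, corrections and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traymass)
```

## The measurement problem

Fresh biomass is the central state variable of crop monitoring and control in
controlled-environment agriculture, but the traditional way to obtain it —
harvesting and weighing — is destructive and slow. A cheap alternative is to
hang each multi-plant cultivation tray of a hydroponic vertical farm on four
strain-gauge load cells and weigh the tray continuously. The raw signal is
badly corrupted, though: low-cost cells drift with temperature, climate-control
actuators couple into the mounting through pressure and vibration, manual
interventions produce spikes, and broadband measurement noise dwarfs the
gram-scale growth increments of interest. `traymass` implements the full
conditioning chain that turns the four raw cell streams into a usable
per-plant biomass signal, plus a digital twin of the sensor physics so the
chain can be validated without hardware.

## Sensor model

Each cell is four strain gauges of nominal resistance $R$ in a Wheatstone
bridge with excitation $V_{in}$. The exact output is

$$V_{out} = \left(\frac{R+\Delta R_2}{(R+\Delta R_1)+(R+\Delta R_2)}
 - \frac{R+\Delta R_4}{(R+\Delta R_3)+(R+\Delta R_4)}\right) V_{in},$$

and for the symmetric small-deformation configuration
($\Delta R_2 = \Delta R_3 = \Delta R$, $\Delta R_1 = \Delta R_4 = -\Delta R$)
both half-bridge denominators equal $2R$ and the expression collapses exactly
to $V_{out} = (\Delta R / R)\, V_{in}$. `bridge_output_exact()` and
`bridge_output_linear()` implement both forms; the package warns when
$|\Delta R|/R > 0.05$, outside the regime where the cell is operated.
Span calibration (`fit_span()`) converts digitizer units to grams with a known
reference mass, and `tare()` removes the empty-tray baseline.

## Processing chain

Readings $S_i$ (grams, four cells), air temperature $T$ and binary actuator
states $u$ arrive on a uniform 15 s grid. The chain, in order:

1. **Hampel outlier rejection** per cell: a centered rolling window (150 s,
   i.e. 11 samples) computes median and scaled MAD; samples deviating by more
   than 3 scaled-MAD units are replaced by the window median and flagged.
   Windows are truncated at the series edges. The 3-unit threshold and the
   centered-window reading of the 150 s duration are package choices; the
   scale factor 1.4826 makes the MAD consistent for Gaussian noise.
2. **Temperature correction** per cell:
   $S_{T,i} = S_i - (c_T (T - T_0) + c_{T0})$, with $(c_T, c_{T0})$ fitted by
   OLS against $(T - T_0)$ on a recording under constant load
   (`fit_temperature_model()`). Linear compensation is sufficient for these
   cells; a nonlinear model is a possible extension hook. Note an
   identifiability constraint: under a constant load $L$ the regression
   intercept is $L + c_{T0}$, so $c_{T0}$ is recoverable only when $L$ is
   known — hence the `true_load` argument. When it is unknown only the drift
   slope is removed. The regressor is chamber air temperature; cell body
   temperature would track the drift more faithfully during fast transients,
   and the channel is configurable.
3. **Summation**: $M_T = \sum_{i=1}^4 S_{T,i}$.
4. **Actuator correction**: the coupling of an actuator with state $u$ is
   quantified by the Pearson correlation $\rho(M_T, u)$ and corrected by
   $M_u = M_T - \delta_{M,u}\, u$ with
   $\delta_{M,u} = \overline{M_T(u{=}1)} - \overline{M_T(u{=}0)}$.
   Samples within ±2 samples of an on/off edge are excluded from the means to
   avoid transient bias (a package choice). Because harvests or configuration
   changes can alter the coupling, $\delta$ is re-estimated on a rolling
   cadence (default 24 h, `reestimate_delta()`); windows in which the actuator
   never switches retain the previous estimate.
5. **Low-pass filtering**: an order-4 Butterworth filter with cutoff
   0.025 min⁻¹ (a 40 min time constant) removes the remaining measurement
   noise. Four 5 kg cells at ±0.02 % of full scale give ±1 g per cell and a
   worst-case ±4 g per tray; the cutoff is chosen so that tray changes above
   that accuracy limit are distinguishable from noise. The filter runs either
   zero-phase (forward–backward; default for offline reprocessing — the
   magnitude response is squared, so a sinusoid at the cutoff comes through at
   1/2 rather than $1/\sqrt2$) or causal (single pass, for streaming, with a
   group delay near DC of about $2/(2\pi f_c)$ minutes).

`run_pipeline()` applies the five stages and retains every intermediate
series ($M$, $M_T$, $M_u$, $M_f$).

### Numerical choices in the filter stage

`signal::filtfilt()` pads with zeros internally, which produces large edge
transients on signals that start or end far from zero. `lowpass()` therefore
centers the series on its first sample and extends both ends by odd
reflection (continuous in value and slope) before the forward–backward pass,
then trims. The pad length is $\lceil 10/W \rceil$ samples ($W$ the
normalized cutoff), long enough for the slowest pole's transient to decay
below the noise floor.

Gaps flagged in the sample mask are bridged by linear interpolation when
shorter than 5 min; at longer gaps the series is split and each segment
filtered independently; segments shorter than about three filter lengths
pass through unfiltered. A low-pass filter also assumes a slowly varying
signal, which a harvest violates: the trial runner passes the logged harvest
times as `breaks` so the filter is applied independently on each side of
every step instead of smearing ~650 g of removed mass into the surrounding
hour.

## From tray mass to per-plant biomass

The wet rockwool plug of each plant rides on the tray. At transplant the
seedling mass is negligible, so the average plug mass is
$m_{sub} = M_f(\text{start})/n_0$ (`init_substrate_mass()`). A plant ledger
records every removal; plants leave with their plugs, so at any time

$$m_{lc} = \frac{M_f - n\, m_{sub}}{n}$$

with $n$ the current count (`mass_per_plant()`). Root mass hangs submerged in
the nutrient solution and is essentially not carried by the tray, so $m_{lc}$
tracks shoot (wet leaf) mass.

Manual reference measurements weigh the whole plant with plug and basket from
a small sample of plants. Two factors map them to the sensor scale
(`compute_adjustment_factors()`): the leaf share of total plant mass
$c_{man} = \bar m_{leaf} / (\bar m_{leaf} + \bar m_{root})$ and the
sampling-bias ratio
$c_{sample} = (\bar m_{man} - m_{sub} - m_{basket}) / (\bar m_{leaf} + \bar m_{root})$,
giving the adjusted manual measurement
$\tilde m_{man} = (c_{man}/c_{sample}) (m_{man} - m_{sub} - m_{basket})$.
Baskets are treated as part of the tray tare but present in manual
measurements, which is why $m_{basket}$ appears only here.

Accuracy bookkeeping: `sensor_accuracy()` propagates the cell rating to the
tray (±4 g for four 5 kg cells at 0.02 %), and `per_plant_resolution()`
divides by the plant count — ±0.4 g at 10 plants, ±0.66 g at 6. This is the
floor on detectable per-plant change, not the expected error.
`harvest_error()` and `evaluate_regression()` quantify agreement with manual
references at harvest points and across a trial.

One bookkeeping subtlety: the per-plant formula divides $(M_f - n\,m_{sub})$
by the *current* $n$, which presumes both $M_f$ and $n$ reflect the tray
after any removal. The package reads the harvest-point value from a
configurable window (default 10 min) immediately *before* the event, with
the count in force at that moment, and resumes with the updated count after.

## The digital twin

No public recording of an instrumented tray exists, so validation runs
against `simulate_tray()`, which generates raw streams with exactly the
disturbance structure the pipeline must remove, plus ground truth. Per cell:

$$S_i(t) = \tfrac14 M_{true}(t) + c_{T,i}(T(t)-T_0) + c_{T0,i}
 + \tfrac14 \delta_{sim} u(t) + \varepsilon(t) + \text{spikes},$$

with $M_{true} = \text{tare} + n(t)(m_{sub} + m_{shoot}(t))$. Choices worth
stating:

* **Growth** is a logistic sigmoid per plant. The defaults — asymptote 84 g,
  rate 0.425 d⁻¹, midpoint day 21.6 — are solved so that the curve passes
  through ≈15 g at day 18 and ≈84 g at day 32, the per-plant masses observed
  at the two harvests of the reference validation trial; growth is slow early
  and fastest in the final week, as lettuce behaves.
* **Temperature** follows the 17 h photoperiod as a square wave (base 20 °C,
  the trial setpoint, +4 °C while the LEDs run) smoothed by a 30 min
  first-order lag. Per-cell drift coefficients default to the fitted values
  of the reference test trial (1.61, −1.41, 0.61, −1.88 g/°C), so the four
  cells drift in different directions, as real cells do.
* **Actuator**: a climate-control channel duty-cycling at 30 min period,
  shifting the tray reading by −4 g while active (the top of the observed
  0 to −4 g range), split equally across the four cells. Whether the
  physical coupling is equal per cell is unknown; since the pipeline only
  ever uses the summed tray mass, the split is immaterial downstream.
* **Noise and spikes**: 1 g Gaussian noise per cell; Poisson spike arrivals
  (default 10/day, ±200 g, one sample, one random cell) emulating manual
  handling and voltage glitches.
* **Roots** are tracked in the ground truth (at the 23 % mass share implied
  by a leaf fraction of 0.77) but never added to tray mass.
* All randomness flows from the mandatory `seed`; identical seeds give
  bit-identical series.

What the twin does **not** emulate: ADC/electronics noise spectra, mechanical
vibration resonances, multi-tray cross-talk, plant-to-plant growth variation,
water-content dynamics within a day, and drift of the temperature
coefficients over weeks. Passing the simulation suite therefore demonstrates
that the algorithms invert the disturbance model they assume — not that the
disturbance model captures every effect in a particular physical
installation, which is why the operating procedure re-fits the calibration at
the start of every trial.

## Validation setup and problem sizes

The test suite and the acceptance script exercise, among others:

* temperature-parameter recovery on one simulated day/night cycle
  (5,761 samples, 1 g noise) — slopes recover to a few percent;
* actuator decorrelation: $|\rho(M_u, u)| < 0.1$ after correcting with the
  estimated $\delta$ (from $|\rho| \approx 0.7$ before);
* Hampel equivalence against a brute-force rolling median/MAD reference on
  1,000 random series;
* a full 32-day validation-style trial at 15 s cadence (184,321 samples,
  20 → 10 plants at day 18): the per-plant error at each harvest epoch is
  held to the detection resolution at that epoch plus the ±0.2 g per-plant
  share that the ±4 g tray accuracy contributes through the substrate
  initialisation at $n_0 = 20$;
* linearity: a constant 72 g added to a steady simulated tray moves the
  filtered mass by 72 ± 4 g.

These sizes (one day for calibration fits, two days for step/decorrelation
checks, one full trial for end-to-end recovery) are chosen as the smallest
that exercise every mechanism at realistic cadence.

## Known limitations

* The fixed 0.025 min⁻¹ cutoff is tuned to the fast late growth phase; early
  in the trial, growth increments sit below the detection floor for hours at
  a time. An adaptive, growth-phase-dependent cutoff is an obvious extension.
* Unlogged step disturbances (masses added or removed without a ledger
  entry) are smeared by the filter; the pipeline corrects only what is
  logged or modelled.
* $c_{T0}$ and the true load are confounded under constant-load calibration;
  air temperature lags cell body temperature during fast transients.
* The delta contrast estimator is unbiased under a stationary mass; a strong
  growth trend within a re-estimation window adds a bias of order the
  within-window trend times the on/off phase asymmetry (about −1 g at peak
  growth with the default 24 h cadence and 30 min duty cycle), which stays
  inside the tray accuracy band.
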