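# traymass

Continuous, non-destructive plant biomass measurement for hydroponic
vertical farms, using four low-cost strain-gauge load cells under each
cultivation tray. `traymass` is for growers and phenotyping researchers who
want a clean per-plant fresh-biomass signal out of raw, disturbance-ridden
weight streams — and for anyone who needs to prototype or validate such a
sensor without hardware, via the included digital-twin simulator.

## What it computes

Raw per-cell readings `S_i` (grams, 15 s cadence), chamber temperature `T`
and binary actuator states `u` are turned into tray and per-plant mass by a
five-stage chain:

1. **Hampel outlier rejection** per cell (150 s centered window, 3
   scaled-MAD units) — removes spikes from manual handling and voltage
   glitches;
2. **temperature correction** per cell, `S_T = S − (c_T·(T − T₀) + c_T0)`,
   with the per-cell drift model fitted by OLS on a constant-load recording;
3. **summation** to tray mass `M_T = ΣS_T,i`;
4. **actuator correction** `M_u = M_T − δ_{M,u}·u`, where
   `δ_{M,u} = mean(M_T | u=1) − mean(M_T | u=0)` is found by correlation
   analysis and re-estimated on a rolling daily cadence;
5. **low-pass filtering** with an order-4 Butterworth filter, cutoff
   0.025 min⁻¹ (40 min time constant), zero-phase or causal.

Per-plant mass then follows from substrate and plant-count bookkeeping:
`m_lc = (M_f − n·m_sub)/n`, with `m_sub` initialised as the start-of-trial
tray mass per plant and `n` tracked through a harvest ledger. Four 5 kg
cells at ±0.02 % of full scale give ±4 g per tray, i.e. a detectable
per-plant change of ±0.4 g at 10 plants.

The simulator (`simulate_tray()`) generates raw streams with the same
disturbance structure — per-cell linear temperature drift over a diurnal
cycle, an additive shift while an actuator runs, Gaussian noise, sporadic
spikes, logistic per-plant growth, harvest steps — plus ground truth, all
deterministically from one seed.

## Worked example

Simulate a 32-day validation-style trial (20 lettuce plants, 10 removed at
day 18), calibrate on the first day/night cycle, process, and evaluate:

```r
library(traymass)
report <- run_trial(list(
  seed = 1,
  simulate = list(duration_days = 32, schedule = "validation"),
  calibration = list(t0 = 20, window_days = 1),
  ledger = list(n0 = 20)))
report
#> <run_report> 184321 samples @ 15 s, n0 = 20 -> n = 10
#>   m_sub = 50.13 g; final m_lc = 83.09 g (ref 83.00 g, err 0.09 g / 0.11%)
#>   actuator act_climate: rho -0.014 -> 0.000
report$metrics$harvests
#>             timestamp   m_lc_g reference_g abs_error_g rel_error_pct
#> 1 2026-01-19 06:00:00 14.90331    14.93334  0.03002699     0.2010735
round(unlist(report$metrics$regression), 4)
#>     slope intercept r_squared       mae      rmse         n
#>    0.9984    0.0001    1.0000    0.0359    0.0459   32.0000
```

Reading this: the wet substrate plug was initialised at 50.13 g/plant (true
value 50 g); at the mid-trial harvest the sensor read 14.90 g per plant
against a true 14.93 g, and at the end of the trial 83.09 g against 83.00 g —
both well inside the ±0.4 g per-plant detection resolution. Daily sensor
readings regress on ground truth with slope ≈ 1 and R² ≈ 1.

A command-line front end wrapping the same functions (subcommands
`simulate`, `calibrate`, `process`, `evaluate`, `run-trial`) is installed at
`system.file("cli", "traymass.R", package = "traymass")`.

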