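# eitcpr

Lung-ventilation analysis from electrical impedance tomography (EIT)
recorded **during cardiopulmonary resuscitation** — for researchers studying
ventilation under mechanical chest compressions and head-up (trunk-elevated)
CPR, where the impedance signal is dominated by a compression artifact that
must be removed before any respiratory quantity can be measured.

The package implements the complete chain:

* **Artifact filtering** — zero-phase order-4 Butterworth low-pass with the
  cutoff at the geometric mean of the respiratory 3rd harmonic and the
  compression fundamental (0.92 Hz for 10 breaths/min vs a 102/min piston
  device): >40 dB at the artifact, unity gain and zero phase shift in the
  respiratory band.
* **Breath segmentation** on the summed lung-pixel signal: minima are
  inspiration onsets, maxima end-inspiration; VT_EIT is the cycle rise and
  EELI the cycle minimum (reported relative to a pre-compression baseline,
  as EIT is a relative measurement).
* **EIT indexes** per breath and per 60-s epoch: VT_EIT,
  anterior-to-posterior ratio, pendelluft (summed negative pixel tidal
  changes, as a negative %VT_EIT), regional ventilation delay
  (time to 40% of pixel excursion, % inflation time) and its SD (SDRVD),
  global inhomogeneity index GII = Σ|DI − median DI| / ΣDI, and
  EELI/VT_EIT averaged over the last three breaths of an epoch.
* **Respiratory mechanics** from 200-Hz flow/Paw/Pes under volume-controlled
  ventilation: breath-by-breath C_rs = VT/ΔPaw, C_cw = VT/ΔPes,
  C_lung = VT/Δ(Paw−Pes), with 1/C_rs = 1/C_lung + 1/C_cw, plus
  before/after-compression compliance changes with 95% CIs.
* **Statistics** — random-intercept mixed models (flat inclination as
  reference), paired before/after contrasts, median (Q1, Q3) summaries.
* **A synthetic-data generator** that emulates the measurement situation
  (waveform morphology, artifact spectrum, EELI drift, anterior-dominant
  and antiphase pixels, inflation delays, the 5-sequence × 3-inclination
  protocol) with full ground truth, so every stage is verified by
  parameter recovery.

## Worked example

Simulate a recording with a 60-s compression bout, then recover the
injected indexes:

```r
library(eitcpr)

sim <- simulate_eit_recording(subject_params(),
                              cc = compression_settings(windows = cbind(30, 90)),
                              duration_s = 96, seed = 1)
sim$truth
#> Ground truth: VT 2473.5 a.u., pendelluft -8.0 %VT, A/P 1.83, GII 0.570, SDRVD 1.98 %
#>   EELI drift 2968.2 a.u. (tau 10.0 s) -> EELI/VT -1.20 during compressions

compute_index_set(sim$recording,
                  epochs = data.frame(label = "during-CC", inclination = 0,
                                      start_s = 30, end_s = 90))
#>       label inclination n_breaths vt_eit_au ap_ratio pendelluft_pct_vt
#> 1 during-CC           0         9      2539     1.82              -7.9
#>   eeli_over_vt sdrvd_pct_insp_time  gii
#> 1        -1.19                1.96 0.57
```

Reading the row: nine breaths were segmented inside the compression window
after filtering; the tidal impedance (2539 a.u.) matches the injected
2473 a.u. within the filter's ~3% amplitude bound; 7.9% of the net tidal
change moved in antiphase (pendelluft); ventilation is anterior-dominant
(A/P 1.82); and the end-expiratory level has fallen by 1.19 tidal volumes
relative to the pre-compression baseline — exactly the injected drift.

Breath-by-breath mechanics from a simulated pressure/flow recording
(injected C_lung 50, C_cw 100 ml/cmH2O):

```r
cm <- compliance(simulate_pressure_flow(subject_params(), n_breaths = 3, seed = 1))
cm[cm$valid, c("vt_ml", "c_rs_ml_cmH2O", "c_lung_ml_cmH2O", "c_cw_ml_cmH2O")]
#>   vt_ml c_rs_ml_cmH2O c_lung_ml_cmH2O c_cw_ml_cmH2O
#> 1   408         33.33              50           100
```

The full protocol (subjects × 5 sequences × flat/18°/35°) runs through
`run_simulation_study(run_config(...), out_dir)`, which writes the index
table, mechanics tables, compliance-change table and mixed-model fits; a
thin command-line front end lives in `inst/cli/eitcpr.R`
(`simulate` / `analyze` / `validate`).

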