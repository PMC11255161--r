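# rltdosim

Internal dosimetry for ¹⁷⁷Lu radioligand therapy (e.g. ¹⁷⁷Lu-PSMA ligands
in metastatic castration-resistant prostate cancer), with tools to evaluate
how much of the full multi-time-point protocol can be simplified without
losing accuracy.

Serial post-therapy imaging gives, for each source region (kidneys, parotid
and submandibular glands, tumor lesions), a time–activity curve (TAC). The
**reference method** follows the MIRD formalism:

1. fit each TAC with a monoexponential `A₀·exp(−λ_eff·t)` or an uptake
   biexponential `A₀·(exp(−λ_eff·t) − exp(−λ_up·t))`; where no exponential
   describes the data, integrate trapezoidally with a monoexponential tail
   fitted to the last 2–3 points;
2. integrate analytically to infinity for the time-integrated activity
   (TIA = `A₀/λ_eff`, respectively `A₀(1/λ_eff − 1/λ_up)`), the total
   number of decays in the region;
3. convert TIA to absorbed dose with a sphere-model self-dose factor
   `S(m) = 3.6·10⁹ · E_e / m` (complete local absorption of electron
   emissions; optional tabulated photon term), and normalize by the
   injected activity (mGy/MBq).

Three **simplified estimators** are implemented for later treatment
cycles: SM1 rescales the cycle-1 fitted TAC through a single measured time
point; SM2 extrapolates dose from injected activity using cycle 1
(`D_i = D₁/A₁ · A_i`); SM3 uses the mean normalized dose of cycles 1–2.
Agreement with the reference is quantified by Bland–Altman percent bias
with 1.96·SD limits of agreement and by RMSE.

Because clinical TACs are patient data, the package ships a
**synthetic-cohort generator** that emulates the study population such
analyses are performed on: 16 patients × 4 cycles, ~6.2 GBq per cycle,
imaging at 2/24/48 h plus a variable last time point (72–168 h, mean
130 h), organ and lesion kinetics drawn around published per-cycle
normalized-dose and effective-half-life targets, declining tumor uptake
with lesion dropout (90/87/79/67 analyzable lesions), and multiplicative
measurement noise. The generator inverts its dose targets into true
kinetics, so the whole pipeline can be validated by parameter recovery.

## Worked example

```r
library(rltdosim)
library(dplyr)

cohort <- generate_cohort(cohort_config(seed = 42))
cohort
#> <rlt_cohort> 16 patients x 4 cycles, 138 regions (90 lesions), 2060 measurements

rm_rec <- run_reference_dosimetry(cohort)
dose_summary(rm_rec) |> filter(kind == "kidney")
#>   method kind   cycle     n norm_dose_mean norm_dose_sd ...
#> 1 RM     kidney     1    16          0.690        0.271
#> 2 RM     kidney     2    16          0.694        0.200
#> 3 RM     kidney     3    16          0.670        0.213
#> 4 RM     kidney     4    16          0.629        0.213
```

Per-cycle kidney normalized doses scatter around ~0.7 mGy/MBq — the level
the generator is calibrated to. Compare the single-time-point method at
48 h against the reference over cycles 2–4:

```r
sm1 <- run_simplified(cohort, rm_rec, method = "SM1", tp = "48h")
bland_altman(comparison_pairs(sm1, rm_rec, cycles = 2:4) |> filter(kind == "kidney"))
#> <ba_result> n = 48: bias -1.13% +/- 15.4 (LoA -16.6 to 14.3), RMSE 0.05476
```

A near-zero bias with ±15% limits of agreement: single-time-point imaging
at 48 h tracks the full protocol closely for kidneys. Cumulated totals
flag patients approaching organ-at-risk limits (28 Gy kidneys, 35 Gy
salivary glands):

```r
cumulate_doses(rm_rec, n_cycles = 4) |> filter(kind == "kidney") |> arrange(desc(total_Gy)) |> head(3)
#>   patient_id  total_Gy  flag_limit
#> 1 P03             29.9  kidney_28_40Gy
#> 2 P08             21.0  <NA>
#> 3 P13             20.5  <NA>
```

`autoplot(cohort)`, `autoplot(bland_altman(...))` and
`plot_dose_by_cycle()` give the standard diagnostic figures;
`tidy()`/`glance()` methods return fits and agreement results as tibbles.
File-level commands (`dosim_simulate()`, `dosim_run()`, `dosim_compare()`)
and a thin CLI wrapper (`inst/cli/rltdosim`) cover scripted use with CSV,
JSON and YAML interchange.

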