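# dcerrm — reference-region pharmacokinetic analysis of DCE-MRI

Quantitative dynamic contrast-enhanced MRI (DCE-MRI) without an arterial
input function. The package is written for preclinical and
musculoskeletal studies — its motivating use case is tracking microvessel
proliferation in an injured growth plate of a small-animal model — where
no adequate artery lies in the field of view and manual bolus injection
makes population input functions unreliable.

## The model

Tissue uptake follows the two-parameter Tofts model,

```
Ct(T) = Ktrans ∫₀ᵀ Cp(t) · exp(−(Ktrans/ve)(T−t)) dt ,
```

with the transfer coefficient `Ktrans` (min⁻¹) and the extravascular
extracellular volume fraction `ve`. Instead of measuring the plasma input
`Cp`, the reference-region model (RRM) eliminates it between the tissue
of interest (TOI) and a reference region (RR) — skeletal muscle with
fixed literature kinetics `Ktrans,RR = 0.045 min⁻¹`, `ve,RR = 0.08`:

```
R1,TOI(T) = R·[R1,RR(T) − R10,RR]
          + R·[Ktrans,RR/ve,RR − Ktrans,TOI/ve,TOI]
              · ∫₀ᵀ [R1,RR(t) − R10,RR]·exp(−(Ktrans,TOI/ve,TOI)(T−t)) dt
          + R10,TOI ,          R = Ktrans,TOI / Ktrans,RR .
```

Relaxation-rate curves `R1(t) = 1/T1(t)` come from a
proton-density-referenced FLASH T1 inversion (single 100 ms/5° reference
scan against the 8.09 ms/30° dynamic series), and `fit_rrm()` identifies
`(Ktrans,TOI, ve,TOI)` by bounded Levenberg–Marquardt least squares.
Rayleigh-corrected SNR estimation (`snr()`, σ_corr = σ_Rayleigh/0.655),
volume orchestration (`run_fit()`), longitudinal Welch + Bonferroni
statistics (`cohort_report()`) and a ground-truthed synthetic phantom and
cohort generator round out the pipeline. See the vignette
(`vignettes/reference-region-dce.Rmd`) for the full account of models,
numerical choices and validation scope.

## Worked example

Simulate one noisy measurement at the default study conditions (40
frames every 13.32 s, 3 baseline frames, muscle baseline SNR 80), then
run the full chain — T1 inversion, baseline R10, RRM fit — on it:

```r
library(dcerrm)
muscle   <- tissue_kinetics(ktrans = 0.045, ve = 0.08)
protocol <- acquisition_protocol()

ds <- simulate_roi_curves(kinetics_toi = tissue_kinetics(0.2, 0.3),
                          target_snr = 80, n_rr_voxels = 64, seed = 7)
r1_toi <- signal_to_r1(ds$s_ref_toi, ds$s_toi, protocol)
r1_rr  <- signal_to_r1(ds$s_ref_rr,  ds$s_rr,  protocol)
fit <- fit_rrm(r1_toi, r1_rr,
               r10_toi = estimate_r10(r1_toi, 3),
               r10_rr  = estimate_r10(r1_rr, 3),
               kinetics_rr = muscle)
fit
#> Reference-region model fit
#>   Ktrans = 0.1977 /min   ve = 0.3001   (R = 4.393)
#>   RMS residual = 0.0137 /s, converged = TRUE (4 iterations)
```

The true values were `Ktrans = 0.2 min⁻¹`, `ve = 0.3`: at SNR 80 the
AIF-free fit lands within ~1 %. `R` is the enhancement-amplitude ratio
relative to muscle. The same analysis on a digital phantom volume,
voxelwise against the ROI-mean muscle curve:

```r
ph <- simulate_phantom(phantom_spec(grid = c(16, 16, 2),
        rr_box  = list(x = c(3, 6),   y = c(3, 14), z = c(1, 2)),
        toi_box = list(x = c(11, 14), y = c(3, 14), z = c(1, 2)),
        target_snr = 80, seed = 1))
run_fit(ph$reference, ph$dynamic, ph$mask, ph$protocol)
#> Reference-region pipeline fit (voxelwise mode)
#>   tissue label 2: 96 voxels, 96 fitted (0% flagged)
#>   Ktrans 0.2006 [0.1996, 0.2019] /min   ve 0.3001 [0.2992, 0.3011]
```

The bracketed numbers are the 25th/75th percentile over converged,
unflagged voxels. Longitudinal statistics on a simulated 5-animal cohort
(days 1–82, implanted day-42 peak) flag the day pairs whose Ktrans
difference survives Bonferroni correction over all 21 pairs, e.g.:

```r
rep <- cohort_report(fit_cohort(simulate_cohort(cohort_spec(seed = 1))))
#>   ktrans: 21 pairwise comparisons, 15 significant
#>     ...
#>     day14 vs day42: adj p = 0.006906 (p<0.01)
#>   ve: 21 pairwise comparisons, 0 significant
```

A thin command-line front end (`inst/cli/dcerrm.R`) exposes `simulate`,
`t1map`, `fit`, `snr` and `cohort-stats` subcommands over the same
functions.

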