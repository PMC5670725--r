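# itvrange

Internal-target-volume (ITV) delineation strategies for stereotactic body
radiotherapy (SBRT) of lung lesions, evaluated as a function of tumor motion
range on a fully digital respiratory phantom.

## The problem

A lung tumor moves with respiration. The benchmark ("gold standard", GS) way
to capture that motion for treatment planning is to contour the gross tumor
volume (GTV) on all ten respiratory phases of a 4DCT scan and take the
Boolean union as the ITV. Because ten-phase contouring is slow, clinics use
single-image alternatives:

* **FB** — contour the free-breathing helical scan, then add a conventional
  anisotropic margin (5 mm axial, 10 mm superior–inferior);
* **FB-Aug** — union of the FB contour with the maximum-inhale (phase 0%)
  and maximum-exhale (phase 50%) contours;
* **AIP / MIP** — contour the average- or maximum-intensity projection of
  the ten phases.

All 4DCT-based ITVs receive an isotropic 5 mm planning margin to form the
planning target volume (PTV). Two statistics compare a strategy `x` to the
gold standard:

* the PTV ratio `R_x = PTV_x / PTV_GS` (volume only), and
* the Dice similarity coefficient
  `DSC = 2 |V_GS ∩ V_x| / (|V_GS| + |V_x|)` (volume *and* position), with
  DSC > 0.700 conventionally called good agreement.

`itvrange` provides:

* a digital respiratory phantom (1.5 cm radius high-contrast sphere in
  low-density lung, sinusoidal superior–inferior motion, 4 s period) with a
  4DCT acquisition model: ten phase bins with residual intra-bin motion,
  MIP/AIP projections, and a free-breathing helical scan model that
  reproduces interplay artifacts;
* threshold-based GTV segmentation, Boolean ITV construction, and
  physical-space ellipsoidal margin expansion (Rcpp);
* the overlap metrics, an analytic capsule (swept-sphere) oracle, and a
  study driver that sweeps motion ranges 1–4 cm;
* a packaged 17-patient lung SBRT cohort table (motion vector, gold-standard
  PTV volume, and per-strategy R and DSC) with its summary statistics.

## Worked example

One phantom range (±1.0 cm amplitude, i.e. a 2 cm motion range) through the
whole pipeline:

```r
library(itvrange)
sw <- run_phantom_sweep(amplitudes = 1.0)
round(sw$summary[, 1:11], 3)
#>   range_cm ptv_gs_cc ptv_fb_cc  r_fb dsc_fb r_fbaug dsc_fbaug r_aip dsc_aip r_mip dsc_mip
#> 1        2    59.654    43.511 0.729  0.806   0.984     0.992 0.573   0.729     1       1
```

The ten-phase gold-standard PTV measures 59.7 cc (the analytic swept-sphere
oracle `capsule_volume(2, 2)` gives 58.6 cc). The MIP strategy recovers the
phase union exactly under threshold segmentation (R = 1.00, DSC = 1.00);
FB-Aug stays within 2% of the benchmark (DSC 0.992); the free-breathing scan
under-covers the moving target (median over 8 scan start phases: R = 0.73,
DSC = 0.81), and AIP retains only positions occupied most of the cycle
(R = 0.57). Columns `*_mean` (not shown) carry the start-phase means for the
FB strategies.

The clinical cohort statistics:

```r
rec <- load_clinical_table()
sm  <- summarize_clinical(rec, "FB_AUG")
sprintf("FB-Aug: DSC %.3f +/- %.3f, R %.2f +/- %.2f, window %d%%",
        sm$mean_dsc, sm$sd_dsc, sm$mean_r, sm$sd_r,
        acceptance_window(rec, "FB_AUG"))
#> "FB-Aug: DSC 0.881 +/- 0.056, R 1.03 +/- 0.10, window 82%"
```

i.e. across the 17 patients the augmented free-breathing strategy agrees
best with the ten-phase benchmark (mean DSC 0.881) and lands inside the
±10% PTV-ratio window for 82% of cases.

A command-line front end covering the sweep, the clinical summaries, and
NIfTI export of simulated volumes is installed at
`system.file("cli", "itvrange", package = "itvrange")`.

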