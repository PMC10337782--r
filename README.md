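# renalpet

Estimation of split and absolute renal function from routine **static
somatostatin-receptor PET** (⁶⁸Ga-DOTATATE) — the imaging patients with
advanced neuroendocrine tumors already receive before peptide receptor
radionuclide therapy (PRRT). Impaired single-kidney function raises the
risk of nephrotoxicity under PRRT, but unilateral dysfunction compensated
by the contralateral kidney is invisible to serum markers; the standard
test, ⁹⁹ᵐTc-MAG3 renal scintigraphy, costs the patient an extra
examination. This package implements, with full ground-truth testability,
a PET-only alternative and the apparatus needed to validate it: digital
phantoms, a cohort simulator, the clinical reference arm, and the
comparison statistics.

## The method

The tracer-avid renal parenchyma is segmented inside a per-kidney VOI by a
dual SUV-threshold isocontour, keeping voxels with

> 5 ≤ SUV ≤ 15

(the lower bound removes background, the upper bound removes radioactive
urine in the renal pelvic caliceal system). From the segmented parenchyma
with SUVmean *U* and volume *V* (ml), per kidney:

- **ACI** (Accumulation Index) = *V / U*  [ml]
- **TKA** (Total Kidney Accumulation) = *U · V*  [ml·SUV]
- **bpcTKA** = (*U* − *U*₍blood₎) · *V*, with *U*₍blood₎ the SUVmean of a
  ≥ 5 ml cylindric VOI in the descending aorta
- **Split renal function** (left) = 100 · left / (left + right), applied
  to ACI (primary) and, for comparison, to SUVmean, TKA and volume
- **MTV** = *U*₍tumor₎ · *V*₍tumor₎ and **%ID** = 100 · MTV / (1000 ·
  weight[kg]), the tumor-sink quantities

The reference arm provides the 2009 CKD-EPI eGFR (race-free by default),
CKD G-staging, and side-separated tubular extraction rate
(TER · split / 100).

## Worked example

```r
library(renalpet)

# a noiseless digital phantom: two ellipsoid-shell kidneys (SUV 8)
# around SUV-20 urine cores, aorta at blood SUV 2.5, background 1
ph  <- build_phantom(default_phantom_spec(psf_fwhm = 0, noise_sd = 0))
rep <- run_patient(ph$volume, ph$vois)

rep$indices$left$parenchymal_volume_ml   # 165.952  (analytic truth 164.93)
rep$indices$left$suv_mean                # 8
rep$indices$left$aci                     # 20.744   (ml)
rep$blood_pool$suv_mean                  # 2.5
rep$split$ACI$split_left_pct             # 50
```

The recovered parenchymal volume is within 0.7 % of the analytic
ellipsoid-shell volume, the urine core is fully excluded, and the
symmetric phantom splits exactly 50:50.

The analysis workflow lives under `analysis/` (run from the repository
root, outputs under `results/`):

- `01_phantom_recovery.R` — segmentation recovery under PSF blur and noise
- `02_estimator_comparison.R` — ACI vs SUVmean/TKA/volume split
  estimators on 100 calibrated synthetic cohorts, plus Bland–Altman
  agreement (ACI ranks first, mean r ≈ 0.90 against true split)
- `03_cohort_reference.R` — summaries of the packaged 25-patient cohort
  table (GFR 79.4 ± 20.9 ml/min/1.73 m², 13 M / 12 F, CKD stage 2 n = 14,
  stage 3 n = 4; %ID 6.3 ± 9.0 %)

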