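# bpequant

Quantification of **background parenchymal enhancement (BPE)** on bilateral
breast DCE-MRI, with and without **N4 bias-field correction**, for imaging
researchers who measure BPE as a treatment-response marker and need to know
how much coil-sensitivity inhomogeneity moves their numbers.

BPE is the contrast uptake of normal fibroglandular tissue (FGT). Given a
pre-contrast volume S0 and an early post-contrast volume S1, the package
runs two parallel arms of one automated pipeline:

1. **Whole-breast masking** — Otsu-based foreground extraction on the
   smoothed pre-contrast volume, restricted anterior to the detected chest
   wall, split into left/right breasts;
2. **Bias-field correction** (corrected arm only) — a from-scratch N4
   implementation: iterative log-domain histogram sharpening by Wiener
   deconvolution with a Gaussian of FWHM 0.15, voxel remapping to the
   sharpened conditional expectation, and multiresolution tensor cubic
   B-spline smoothing of the residual, estimated strictly within the
   breast mask;
3. **FGT segmentation** — fuzzy c-means on the contralateral breast's
   intensities (6 clusters, 20 iterations, fuzziness m = 2), keeping the
   two highest-intensity clusters as FGT;
4. **BPE measurement** — the mean percent enhancement

   PE = (S1 − S0) / S0 × 100 %

   over the *half-stack* mask (the FGT mask restricted to the central 50 %
   of FGT-bearing axial slices).

Per exam the two arms are compared by Sørensen–Dice overlap, voxel-count
and BPE differences; cohorts are summarised with Hodges–Lehmann
pseudo-medians, Wilcoxon signed-rank tests and (for blinded reader
assessments) Cohen's weighted kappa. ΔBPE between treatment timepoints can
be fed to a bootstrap out-of-sample AUC analysis of pathologic complete
response with an L2-penalised single-predictor logistic model.

Because real trial MRI cannot ship with a package, a **phantom generator**
produces bilateral-breast exams with known ground truth (tissue masks,
injected bias field, true enhancement), so every stage is testable end to
end.

## Worked example

```r
library(bpequant)

spec <- phantom_spec(bias_amplitude = 1.5, seed = 42)  # 1.5x bias field
ph   <- generate_phantom(spec)                          # S0, S1 + ground truth
res  <- run_exam(ph$s0, ph$s1, tumor_side = "left",
                 run_config(write_overlays = FALSE))

res$uncorrected$bpe; res$corrected$bpe; res$record$dice
```

prints, with the field-recovery check added:

```
uncorrected:     voxel count   3788, BPE 29.95%
bias-corrected:  voxel count   3788, BPE 29.95%
Dice(uncorrected, corrected) = 1.000
field recovery: cor(log estimated, log true) = 0.985
```

The phantom enhances its FGT by exactly 30 %, and both arms recover it to
0.05 percentage points; the estimated log bias field correlates 0.985 with
the injected one inside the breast mask. With this phantom's tissue
contrast the 1.5× field does not flip any cluster assignments, so the two
half-stack masks coincide (Dice 1.0) — the corrected arm's value lies in
repairing the exams where inhomogeneity does corrupt the clustering, which
the test suite exercises at higher amplitudes.

Paired cohort differences use the signed-rank machinery:

```r
hodges_lehmann(c(0.8, 0.5, 0.9, 0.4, 0.7, 0.6, 0.3, 0.9))
#> <paired_summary n=8> pseudo-median 0.65 [0.4, 0.85], p = 0.01415 (normal-approximation)
```

A thin command-line wrapper is installed at `inst/cli/bpequant`
(`bpequant phantom | breastmask | n4 | bpe | run`).

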