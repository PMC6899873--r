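# radstab

Stability analysis of MRI radiomic features on simulated brain phantoms.

## The problem

Radiomic features — quantitative shape, intensity and texture
descriptors extracted from medical images — are candidate imaging
biomarkers, but in MRI their values drift with the acquisition protocol:
repetition and echo time (TR/TE), voxel size (pixel spacing PS and slice
thickness ST), random noise, and the scanner's smooth intensity
non-uniformity (INU, "bias field"). Multi-centre and retrospective
studies mix protocols, so features that are not robust to these factors
are unusable. `radstab` is for researchers who need to (a) quantify
per-feature robustness under each acquisition factor, (b) measure how
much standard preprocessing repairs it, and (c) select a feature panel
that survives protocol variation.

Because a physical test–retest experiment confounds everything at once,
`radstab` works on a digital multi-tissue head phantom imaged with a
closed-form spin-echo model, so each factor can be varied in isolation
with everything else held fixed.

## What it computes

* **Simulation** — a seeded, brain-like 3D label phantom (10 tissues with
  editable T1/T2/PD and per-tissue texture), spin-echo contrast
  `S = PD (1 − e^(−TR/T1)) e^(−TE/T2)`, Rician noise (percent of the
  brightest tissue's signal per quadrature channel), three smooth
  multiplicative INU field patterns (40% ⇒ field in [0.8, 1.2]), and
  voxel-size degradation (slice-axis partial-volume averaging +
  trilinear resampling). Five study designs: a TR×TE grid (42 T1w / 48
  T2w images), an ST×PS grid (28), ten 9%-noise replicates, 3 INU fields
  + 1 reference, and 50 random-parameter draws.
* **Features** — 107 three-dimensional radiomic features per ROI:
  14 shape/size, 18 first-order, and 75 textural over GLCM, GLRLM,
  GLSZM, NGTDM and GLDM matrices, with fixed-bin-number discretization
  (32 bins). Texture counting and mesh geometry run in C++; every
  feature is verified against an independent brute-force oracle in the
  test suite.
* **Statistics** — per-feature ICC(A,1) (absolute agreement, two-way
  ANOVA without replication) across the (ROI × condition) matrix:

  `ICC(A,1) = (MSR − MSE) / (MSR + (k−1) MSE + (k/n)(MSC − MSE))`

  Wilcoxon signed-rank comparisons of ICC before vs after the matched
  preprocessing (Z-score for TR/TE, 1 mm isotropic resampling for voxel
  size, 3×3×3 σ=0.5 Gaussian for noise, bias-field correction for INU);
  stable-set selection (ICC > 0.75 in all four analyses, shape features
  judged on the voxel-size analysis); Jaccard similarity of the T1w and
  T2w stable sets; and confirmation of the stable set on the
  random-parameter images.

## Worked example

```r
library(radstab)

cfg <- run_config(modalities = c("T1w", "T2w"), analyses = 1:5,
                  phantom_size = 64, phantom_seed = 1, scenario_seed = 2)
report <- run_full_study(cfg)
print(report)
```

which prints (elided):

```
<stability_report>
  T1w: 32 stable features; 30 confirmed (93.75%)
  T2w: 30 stable features; 26 confirmed (86.67%)
  Jaccard(T1w, T2w) = 0.88
  T1w analysis1 FOS: median ICC change +0.0816 [0.0492-0.0947], P = 0.000481
  T1w analysis2 SS: median ICC change +0.00239 [2.23e-06-0.0597], P = 0.0681
  T1w analysis2 textural: median ICC change +0.202 [0.0278-0.41], P = 2.57e-08
  T1w analysis3 textural: median ICC change +0.0586 [0.00346-0.0864], P = 5.13e-08
  T1w analysis4 FOS: median ICC change +0.0309 [0.00156-0.132], P = 0.000214
  T1w analysis4 textural: median ICC change +0.178 [0.103-0.308], P = 5.4e-14
  T2w analysis1 FOS: median ICC change +0.0318 [0.00379-0.0631], P = 0.00147
  ...
```

Reading this: each modality gets a stable feature set (ICC > 0.75 in all
four single-factor analyses of the preprocessed images); the Jaccard
index measures how much the T1w and T2w panels agree; the confirmed
percentage is the fraction of the stable set that stays above threshold
when all parameters vary at once (analysis 5); the per-analysis lines
give the median ICC change under the matched preprocessing with its
interquartile range and signed-rank P — e.g. Z-score normalization
raises first-order ICC under TR/TE variation, while isotropic resampling
raises shape and texture ICC under voxel-size variation.

A thin command-line wrapper is installed as `exec/radstab`
(`radstab full-study --modalities T1w,T2w --out-dir results`), and
volumes/masks can be exchanged as NIfTI-1 via `read_volume()` /
`write_volume()` for user-supplied data.

## Documentation

The methods vignette (`vignettes/radiomic-stability.Rmd`) describes the
simulation model and its assumptions, the feature definitions and their
numerical conventions, the statistics, and what the synthetic study can
and cannot say about real data.
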