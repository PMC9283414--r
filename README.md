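# rapidvol

Quantitative comparison of rapid, reduced-field-of-view T1-weighted brain
scans against standard high-resolution acquisitions.

Ultra-fast multicontrast MR sequences deliver a T1-weighted contrast in
about a minute, but with lower signal-to-noise and a truncated axial field
of view (FoV). `rapidvol` is for imaging methodologists who want to test
whether tissue-volume and brain-age measures survive the switch to such a
sequence. It implements, as reusable and heavily tested functions, the full
statistical pipeline of that comparison:

- **Volumetrics** — global tissue volumes by voxel summation; a voxel
  inclusion mask (≥ 0.001 mm³ of tissue in ≥ 95% of participants, with
  `count ≥ ceiling(0.95 n)`); voxel-wise cross-sequence correlation maps;
  exact FoV reduction via an explicit mask.
- **Associations** — Spearman *r*<sub>s</sub> with the t-approximation
  p-value, Pearson *r*², and a *paired* bootstrap test for differences in
  association strength: the same resampled participants are applied to every
  contrast in each of 10,000 replicates, and the percentile CI95 of each
  pairwise difference is inspected for zero.
- **Reliability** — ICC(3,1), the two-way consistency intraclass correlation
  for single measurements, ICC = (MS_B − MS_E)/(MS_B + (k−1) MS_E), with
  F-based confidence intervals; scalar or voxel-wise.
- **Brain-age evaluation** — the median absolute error (MAE) of predicted
  against chronological age; the null benchmark of predicting one constant
  (40.6 y) for everyone; the null/model error ratio; and the leave-one-out
  regression correction that removes a systematic prediction offset by
  regressing the standard-sequence prediction on the rapid-sequence one in
  each fold.
- **Mechanism demonstration** — a small Gaussian-process age model over
  volumetric features (global volumes + octant GM sums) showing that FoV
  truncation alone produces a systematic brain-age offset, and that the LOO
  regression removes it.
- **Synthetic cohort generator** — paired "segmented" tissue-volume maps
  (GM/WM/CSF) for both sequences with solved-for noise so the expected
  cross-sequence global-volume correlations hit configured targets
  (defaults 0.84/0.84/0.56), a linear GM decline with age, within-session
  retest maps with near-unity reliability, axial FoV truncation, and offset
  brain-age predictions. Everything is reproducible from one seed.

## Worked example

Run the whole pipeline on a default synthetic cohort (64 participants, 10
with a retest scan):

```r
library(rapidvol)
config <- rapid_config(seed = 1)
report <- run_pipeline(config, n_boot = 2000)
print(report)
```

```
Cross-sequence comparison report
  64 participants, seed 1

Global cross-sequence associations:
 tissue contrast_a          contrast_b    rs        p    r2  n
     GM   standard               rapid 0.897 1.29e-23 0.783 64
     GM      rapid standard_fovreduced 0.898 9.28e-24 0.782 64
     WM   standard               rapid 0.888 1.37e-22 0.767 64
     WM      rapid standard_fovreduced 0.888 1.37e-22 0.767 64
    CSF   standard               rapid 0.689 3.09e-10 0.452 64
    CSF      rapid standard_fovreduced 0.689 3.09e-10 0.452 64

Voxel-wise correlation summaries (Md [Q1, Q3]):
 tissue n_voxels median    q1    q3
     GM     3832  0.789 0.763 0.814
     WM     5440  0.837 0.821 0.852
    CSF     3448  0.669 0.651 0.688

GM volume vs age:
            contrast     rs      p    r2  n
            standard -0.260 0.0382 0.105 64
               rapid -0.294 0.0185 0.140 64
 standard_fovreduced -0.258 0.0396 0.105 64

Brain-age metrics:
            sequence    rs        p     r2   mae null_mae null_mae_ratio  n
            standard 0.760 3.17e-13 0.6301  3.81     9.53          2.502 64
               rapid 0.589 3.14e-07 0.4293 13.97     9.53          0.683 64
 standard_fovreduced 0.207 1.00e-01 0.0439  8.90     9.53          1.071 64

LOO-adjusted rapid-sequence MAE: 4.25 years

Test-retest reliability (global ICC):
 tissue   icc lower upper        p  n
     GM 0.988 0.952 0.997 6.93e-09 10
     WM 0.992 0.970 0.998 8.15e-10 10
    CSF 0.997 0.989 0.999 1.01e-11 10
```

Reading the output: global volumes agree strongly across sequences for GM
and WM and more weakly for CSF (the configured behaviour, mirroring the
empirical pattern); voxel-wise agreement sits somewhat below the global
values with the same ordering. GM volume declines with age under every
contrast. The rapid sequence's brain-age predictions correlate well with age
(rs 0.59) but carry a systematic offset: a 13.97 y median error — worse than
predicting a constant for everyone (ratio 0.68) — which the leave-one-out
regression correction reduces to 4.25 y, close to the standard sequence's
3.81 y. Retest reliability of rapid-sequence global volumes is near unity.

The FoV-offset mechanism in isolation:

```r
print(fov_offset_experiment(config, n_train = 200, seed = 1))
```

```
FoV offset experiment (train n = 200, test n = 64, 2 slices dropped, seed 1)
  full FoV:      MAE 4.43 y, rs 0.17
  truncated FoV: MAE 11.56 y, rs 0.16
  after LOO regression adjustment: MAE 4.17 y
```

Feeding the same Gaussian-process model features from truncated maps nearly
triples the prediction error without destroying the rank correlation —
an offset, not noise — and the regression adjustment restores full-FoV
accuracy.

Datasets round-trip through standard formats (`write_dataset()` /
`read_dataset()` / `load_external()`): maps as NIfTI-1 with voxel
dimensions in the header, tables as TSV, the generator configuration as
YAML, so externally produced data in the same layout can replace any
generated component.

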