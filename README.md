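# choroborder

Agreement analysis of choroidal tumor border annotations across fundus
imaging modalities.

## The problem

Knowing where the edge of a choroidal nevus or melanoma lies drives
surveillance and treatment: size estimation, growth monitoring, and the
placement of localized therapy (which typically adds a 2 mm safety margin
around the visible border). Borders are usually drawn on *en face* images —
color fundus photography (CFP) or scanning laser ophthalmoscopy (SLO) — but
these rely on pigment contrast and can misplace the border of nonpigmented
or mixed-pigmented tumors. A multimodal consensus that adds enhanced-depth
OCT is the natural reference standard.

`choroborder` is for ophthalmic imaging researchers who want to quantify
that disagreement reproducibly. It provides the full analysis pipeline:

1. **Coregistration** — each modality's annotations live in its own pixel
   frame; a least-squares similarity transform (uniform scale, rotation,
   translation; no reflection) is estimated from shared anatomical
   landmarks (optic disc, fovea, vascular bifurcations) and maps them into
   a common millimetre reference frame.
2. **Cropping** — annotations are clipped to the largest region of fundus
   visible across all modalities, so no comparison is biased by
   field-of-view differences.
3. **Metrics** — for two closed borders *A* and *B*, boundary points are
   densified at spacing *h* and the shortest Euclidean distance from every
   boundary point of one annotation to the other's boundary polyline is
   collected in both directions. The 95th-percentile Hausdorff distance is

   HD95(A, B) = Q₀.₉₅ { d(a, ∂B) : a ∈ ∂A } ∪ { d(b, ∂A) : b ∈ ∂B }

   (pooled, symmetric; the maximum of the pooled set is the full Hausdorff
   distance). Spatial overlap is summarized by the Dice coefficient
   2·|A∩B| / (|A| + |B|) from exact polygon intersection. HD95 is in mm, so
   an HD95 above the 2 mm clinical margin flags a clinically significant
   disagreement.
4. **Statistics** — medians/IQRs/ranges per grader × modality comparison,
   counts above the 2 mm threshold (overall and by pigmentation), paired
   Wilcoxon signed-rank tests between graders and modalities, and
   univariable Gaussian generalized estimating equations (patient-clustered,
   cluster-sandwich errors, Δmean contrasts vs pigmented lesions) with joint
   Wald chi-squared tests for multi-level predictors.
5. **Synthetic cohorts** — no patient data ship with the package. A
   generator emulates the study structure (64 lesions / 63 patients;
   pigmentation 11/12/41; 39 nevi; log-normal basal diameters, median
   5.65 mm) with pigmentation- and modality-dependent correlated boundary
   noise plus rare segmental "gross errors" that produce the > 2 mm tail,
   so every stage is testable end to end.

## Worked example

```r
library(choroborder)
st <- run_study(pipeline_config(seed = 1, densify_spacing_mm = 0.02))
print(st)
```

```
Simulated border-agreement study: 64 lesions / 63 patients (seed 1)

HD95 by comparison (threshold 2.0 mm, strict >):
      comparison stratum  n median_mm q1_mm q3_mm min_mm max_mm n_exceeding pct_exceeding
 g1_CFP_vs_multi overall 64     0.399 0.344 0.591      0  2.960           2         3.125
 g1_SLO_vs_multi overall 64     0.351 0.283 0.536      0  2.893           2         3.125
    g1_vs_g2_CFP overall 64     0.544 0.407 0.714      0  3.283           4         6.250
    g1_vs_g2_SLO overall 64     0.510 0.407 0.802      0  2.980           3         4.688
 g2_CFP_vs_multi overall 64     0.452 0.376 0.681      0  3.541           2         3.125
 g2_SLO_vs_multi overall 64     0.378 0.322 0.544      0  3.097           1         1.562

Wilcoxon signed-rank comparisons:
                 label n_effective    W  p_value        method
 interrater_CFP_vs_SLO          64 1184 3.37e-01 normal_approx
         g1_CFP_vs_SLO          63 1550 2.10e-04 normal_approx
         g2_CFP_vs_SLO          64 1749 2.16e-06 normal_approx
       g1_vs_g2_on_CFP          64  467 1.29e-04 normal_approx
       g1_vs_g2_on_SLO          63  574 3.00e-03 normal_approx

GEE delta-mean HD95 (vs pigmented reference):
      comparison        level estimate robust_se  p_value  joint_p
 g1_CFP_vs_multi nonpigmented    0.772    0.2720 4.52e-03 2.09e-24
 g1_CFP_vs_multi        mixed    0.318    0.0314 4.18e-24 2.09e-24
 ...
```

Reading it: each grader's unimodal borders sit a median ~0.35–0.45 mm from
the multimodal consensus (well under the 2 mm margin), a few percent of
lesions exceed 2 mm, and nonpigmented / mixed-pigmented lesions disagree
with the consensus by several tenths of a millimetre more than pigmented
ones — the qualitative signature the generator is calibrated to emulate.

Individual stages are exported too: `generate_cohort()`,
`register_cohort()`, `evaluate_agreement()`, `estimate_transform()`,
`hd95()`, `dice_coefficient()`, `summarize_agreement()`,
`fit_gaussian_gee()`, and friends. A command-line front end with
`simulate` / `register` / `evaluate` / `summarize` / `stats` / `run-all`
subcommands is in `inst/cli/choroborder.R`.

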