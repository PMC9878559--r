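# confcascade

Predicting which apo-protein conformations from a molecular-dynamics
ensemble are **binding conformations** — the minority of frames that
ligands select for binding — from tables of per-frame physico-chemical
descriptors (MOE-style global properties such as `pro_asa_vdw` or
`pro_hyd_moment`), for computational chemists running
conformational-selection and ensemble-docking studies.

The package implements a complete analysis framework for this severely
class-imbalanced problem:

1. **Consensus feature selection.** Four univariate scorers rank every
   descriptor — one-way ANOVA F between the binding/non-binding groups,
   mutual information *I(X; y) = Σ p(x,y) log p(x,y)/(p(x)p(y))* with
   quantile-binned descriptors, recurrence-quantification entropy
   *ENTR = −Σⱼ p(j) ln p(j)* over the diagonal-line lengths of each
   descriptor's frame-ordered recurrence plot, and absolute Spearman
   rank correlation |ρ| with the label. Only descriptors in the top-x
   list of all four methods (a 0–4 consensus vote) survive.
2. **Two-stage imbalance-aware cascade** (`cascade_fit()`). Stage 1:
   gradient-boosted trees (ŷ = Σₖ tₖ(x), regularized logistic
   objective, via xgboost) on the raw 30% training split. The split is
   then rebuilt at exactly its original size: all real binding rows
   kept, a GAN (min_G max_D E log D(x) + E log(1 − D(G(z)))) trained on
   them generates synthetic binding rows up to a 1:1 balance, and the
   majority side is K-Means-undersampled from the rows stage 1
   classified correctly. Stage 2: a 1-D CNN and a two-layer LSTM
   (implemented in-package) trained on the rebuilt set.
3. **Enrichment-ratio evaluation** on the held-out 70%:
   base = binders/total (the random-selection hit rate),
   ML = TP/(TP+FN) within a ranked subset of the truly binding
   conformations, final = ML/base — the fold-improvement over random
   selection, reported over a grid of four data-selection filters ×
   {0.5, 1, 5, 10}% subset sizes.

A seeded synthetic-data generator emulates the shape of the published
GPCR datasets (ADORA2A, ADRB2, OPRD1, OPRK1 presets with exact row,
descriptor and binding counts, planted informative descriptors, AR(1)
frame correlation), so the whole framework is testable without the
unreleased originals. See `vignettes/conformation-cascade.Rmd` for the
model, its assumptions and every numerical choice.

## Worked example

```r
library(confcascade)

rec <- run_pipeline(pipeline_config(preset = "PLANTED", effect_size = 2,
                                    seed = 7))
print(rec)
#> <run_record> PLANTED: 3000 x 50 (300 binding), seed 7
#>   consensus (threshold 4): pro_asa_vdw, pro_asa_hyd, pro_asa_hph, pro_volume, pro_dipole_moment
#>   cnn track: accuracy 0.961, sensitivity 0.976; max final enrichment 10.0 (filter A, 0.5%)
#>   rnn track: accuracy 0.963, sensitivity 0.986; max final enrichment 10.0 (filter A, 0.5%)
#>   stage-1 on test: accuracy 0.982, sensitivity 0.886
```

Reading the output: the `PLANTED` preset is a 3000-frame, 50-descriptor
synthetic ensemble with 10% binding frames and five informative
descriptors. The four scorers agreed on exactly those five (the
consensus line). On the held-out 70% (2100 frames, 210 binding; base
enrichment ratio 0.10), both deep tracks detect ≈ 98% of the binding
conformations — versus 88.6% for the boosted trees trained on the raw
imbalanced split, the detection gain the rebalancing stage exists for —
and the top-ranked short-lists are pure binders, so the final
enrichment ratio reaches its theoretical ceiling 1/base = 10: selecting
conformations with the cascade is ten times richer in binders than
random selection.

Per-cell tables, per-conformation predictions, the rebuilt training set
with real/generated provenance, and a log of every configuration
default are written to `out_dir` when set. The same run is available
from a shell:

```sh
Rscript inst/scripts/confcascade.R run --preset PLANTED --effect-size 2 --seed 7 --out results/
Rscript inst/scripts/confcascade.R generate --out data/   # synthetic GPCR suite
```

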