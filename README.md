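# bispecfam

Alignment-free protein family classification from higher-order spectral
images of primary sequence.

Sequence alignment struggles to place diverged proteins into families.
`bispecfam` implements an alignment-free pipeline that treats a protein
sequence as a one-dimensional numeric signal and classifies families from
that signal's third-order spectrum:

1. **Encoding** — residues are one-hot encoded over the fixed alphabet
   `[A C D E F G H I K L M N P Q R S T V W Y]` (plus an unknown unit) and
   flattened into a binary time series, z-scored per family on training
   data and globally elsewhere.
2. **Bispectrum** — the direct segment-averaged estimator of
   `B(f1, f2) = E[X(f1) X(f2) conj(X(f1+f2))]` exposes quadratic phase
   coupling between frequency components; its magnitude over the
   `[0, Nyquist]^2` plane is rendered as an image.
3. **CNN features** — a compact reference backbone (three conv blocks and a
   replaced classification head trained by RMSProp) yields one feature per
   class per backbone; two backbones see two different spectral grids.
4. **Fusion** — canonical correlation analysis (whitened cross-covariance
   SVD) and discriminant correlation analysis (between-class whitening plus
   a cross-view rotation) reduce the concatenated features to `2 x classes`
   fused columns, fitted on training rows only.
5. **Classifier** — a 50-tree bagged ensemble of unpruned decision trees
   with surrogate splits, combined by soft probability averaging:
   `y_hat = argmax_c (1/N) sum_i P(h_i(x) = c)`.
6. **Metrics** — per-class precision / sensitivity / specificity / F1 (in
   percent, half-up rounding), overall accuracy, and one-vs-rest ROC/AUC.

A motif-based synthetic family generator with controllable separability
makes the whole pipeline testable without external databases, and the
per-class confusion counts of a published 16-family Globin-like benchmark
are bundled as exact worked examples for the metric layer.

## A worked example

```r
library(bispecfam)

# Four synthetic families, 60 sequences each, easy separability
res <- run_pipeline(pipeline_config(scenario = "split_70_30", seed = 1))
res
#> <pipeline_result> scenario: split_70_30 | seed: 1
#>   test       accuracy 86.1% (n = 72)

glance(res)
#> # A tibble: 1 x 6
#>   report     n n_classes accuracy macro_f1 mean_auc
#>   <chr>  <int>     <int>    <dbl>    <dbl>    <dbl>
#> 1 test      72         4     86.1       86    0.956
```

The report says: of the 72 held-out sequences (18 per family), 86% were
assigned to the correct family; the mean one-vs-rest AUC near 1 shows the
soft-vote probabilities rank positives far above negatives. Averaged over
seeds 1–3 the test accuracy exceeds 90%, and a label-shuffled control falls
to the 25% chance level.

The metric layer reproduces the bundled benchmark tables exactly:

```r
t1 <- reference_counts("test_70_30")
per_class_metrics(t1, rounding = "integer")[1:2, ]
#> # A tibble: 2 x 5
#>   class    precision sensitivity specificity    f1
#>   <chr>        <dbl>       <dbl>       <dbl> <dbl>
#> 1 Family01        97          98         100    97
#> 2 Family02        82          88          99    85
overall_accuracy(counts = t1, total = attr(t1, "stated_total"),
                 rounding = "integer")
#> [1] 93
```

Lower-level pieces are exported individually — `encode_sequence()`,
`estimate_bispectrum()`, `render_image()`, `build_backbone()` /
`train_head()` / `extract_features()`, `fit_cca()`, `fit_dca()`,
`fuse_pipeline()`, `train_bagging()` / `predict_soft()`,
`confusion_counts()`, `roc_auc_ovr()` — and every fitted object has
`tidy()` / `glance()` / `autoplot()` methods where they make sense. A thin
command-line wrapper lives at `inst/scripts/bispecfam`
(`synth`, `run`, `evaluate`).

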