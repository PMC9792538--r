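# fractalstage

Multifractal spectrum features and k-nearest-neighbour staging of 2D
brain-section images.

## The problem

Progressive brain atrophy (as in Alzheimer's-type dementia) changes the
*geometry* of a brain section: tissue area shrinks, fluid-filled gaps
multiply, and the matter distribution becomes more heterogeneous. These
changes are poorly captured by a single fractal dimension but well captured
by a *spectrum* of dimensions. `fractalstage` is for researchers who want a
transparent, fully classical pipeline: estimate the multifractal geometry of
a binarized (or grayscale) section, reduce it to ten interpretable scalar
features, and stage images with a from-scratch KNN — no deep learning, every
step testable against closed-form oracles.

## The method

For a normalized mass distribution over the pixel grid, boxes of side `r`
receive probabilities `P_i(r)`, and the generalized dimensions are

    D_q = 1/(1-q) * lim_{r->0} ln( sum_i P_i(r)^q ) / ln(1/r)

estimated by least squares over dyadic scales (`D_1` via the entropy sum
`sum P_i ln P_i`). The mass exponent `tau(q) = (q-1) D_q` yields the
singularity spectrum by Legendre transform:

    alpha(q) = d tau / d q,     f(alpha) = q alpha(q) - tau(q)

Ten features feed the classifier: `D1`, `D2`, `alpha0`, `alpha_min`,
`f(alpha_min)`, `alpha_max`, `f(alpha_max)`, the spectrum width
`W = alpha_max - alpha_min`, the symmetry shift
`|alpha0 - (alpha_min + alpha_max)/2|`, and the apparent section area `A`.
Classification is k-nearest-neighbour (default `k = 5`) on z-scored
features, evaluated by a seeded per-class split-and-average protocol with
confusion matrices, sensitivity/specificity/precision, and one-vs-rest
ROC/AUC.

Everything is validated against independent oracles: multiplicative-cascade
measures with closed-form spectra, a brute-force KNN, the Mann–Whitney
statistic for AUC, and stage-parameterized synthetic phantoms.

## Worked example

A deterministic quadrant cascade with weights (0.4, 0.3, 0.2, 0.1) has
known dimensions — capacity 2, information 1.846, correlation 1.737 — and
the estimator recovers them:

```r
library(fractalstage)

m <- cascade_measure(c(0.4, 0.3, 0.2, 0.1), depth = 7)
spec <- mf_spectrum(m)
spec
#> <mf_spectrum> 41 moment orders; D0 = 2.0000, D1 = 1.8464, D2 = 1.7370
#>   alpha range [1.4301, 3.2797] over the moment grid

extract_features(spec, area = 128^2 / 4)
#>       d1    d2 alpha0 alpha_min f_alpha_min alpha_max f_alpha_max  width  shift  area
#>   1.8464 1.737 2.1767    1.4301       0.885    3.2797      0.2628 1.8496 0.1782  4096
```

`D1` and `D2` match the closed forms to three decimals; the width 1.85
reflects the strong weight imbalance (a uniform measure gives width 0), and
the small shift says the spectrum is nearly symmetric about its apex.

Staging on synthetic per-stage Gaussian feature tables (four stages, 140
rows each, 100 train / 40 test per class, 7 runs):

```r
tab <- sample_feature_table("kaggle", n_per_stage = 140, seed = 1)
ev <- knn_evaluate_split(tab, n_train_per_class = 100, n_test_per_class = 40,
                         k = 5, n_runs = 7, seed = 1)
ev
#> <knn_eval> 7 runs, k = 5; mean accuracy 99.91% (per run: 100.0, 100.0, 100.0, 99.4, 100.0, 100.0, 100.0)
glance(ev)
#>   mean_accuracy mean_sensitivity mean_specificity mean_precision min_class_sensitivity n_runs k
#>          99.911           99.911            99.97         99.913                99.643      7 5
```

The image pipeline itself (`pipeline_extract()` → `pipeline_train()` →
`pipeline_evaluate()`) runs the same machinery on image files; a thin CLI
over these functions ships in `inst/cli/fractalstage.R` with subcommands
`extract`, `train`, `predict`, `evaluate`, and `simulate`.

## Documentation

The methods vignette (`vignettes/multifractal-staging.Rmd`) documents the
model, the estimator's numerical choices, what the synthetic generators do
and do not emulate, and the package's design decisions in detail.
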