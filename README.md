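# microstatr

Resting-state EEG **microstate** analysis in R: deterministic
preprocessing, global-field-power peak extraction, TAAHC clustering
into K global maps, polarity-invariant back-fitting with temporal
smoothing, microstate features, transition-syntax permutation testing,
and covariate-adjusted group statistics — plus a synthetic cohort
generator with planted ground truth so every stage is verifiable.

## The scientific problem

The multichannel EEG at rest does not wander continuously through
topography space: the scalp potential field stays quasi-stable for
tens of milliseconds and then switches abruptly to another
configuration. These quasi-stable periods — *microstates* — are
summarised by a handful of canonical topographies (classically four,
labelled A–D), and their temporal statistics (how long each map lasts,
how often it appears, which map follows which) change in clinical
conditions. Comparing those statistics between two groups of subjects,
adjusting for demographic covariates, is the analysis this package
implements end to end.

## Core model

Under the average reference, the potential vector
$v(t) \in \mathbb{R}^C$ is modelled as

$$ v(t) = a(t)\,\Gamma_{s(t)} + \varepsilon(t), $$

with fixed unit-norm maps $\Gamma_1,\dots,\Gamma_K$, a
piecewise-constant label sequence $s(t)$, and a signed intensity
$a(t)$. Because $a(t)$ is signed, map comparison uses the
polarity-invariant spatial correlation $|r|$ (equivalently the global
map dissimilarity, $\mathrm{GMD}^2 = 2(1-|r|)$). Topographic strength
is the global field power
$\mathrm{GFP}(t) = \sqrt{\tfrac{1}{C}\sum_c v_c(t)^2}$; maps are
clustered at GFP maxima, where signal-to-noise is highest, and the
quality of a segmentation is its global explained variance
$\mathrm{GEV} = \sum_t (\mathrm{GFP}_t r_t)^2 / \sum_t
\mathrm{GFP}_t^2$. Per class, the features are mean **duration** (ms),
**occurrence** (segments/s) and **coverage** (fraction of time);
transition *syntax* is tested against an occurrence-only null by a
subject-level permutation test. See the methods vignette
(`vignettes/microstate-methods.Rmd`) for every stage, tunable and
numerical choice.

## Worked example

Simulate a small two-group cohort with planted maps and label
sequences, run the full pipeline, and score it against the ground
truth:

```r
library(microstatr)

spec <- simulation_spec(
  n_subjects  = c(DS = 3L, `DS-AD` = 3L),
  epochs_mean = c(DS = 40, `DS-AD` = 40),
  epochs_sd   = c(DS = 5, `DS-AD` = 5),
  seed = 42
)
res <- run_pipeline(config = pipeline_config(n_perm = 1000, seed = 42),
                    spec = spec)
res
res$maps
```

```
<ms_pipeline> 6/6 subjects, K = 4, mean GEV = 94.9%
<ms_maps> 4 maps x 19 channels (taahc): A, B, C, D
```

```r
print(res$features, n = 6)
```

```
# A tibble: 24 × 8
  subject_id   gev class duration_ms occurrence_hz coverage n_runs present
  <chr>      <dbl> <chr>       <dbl>         <dbl>    <dbl>  <int> <lgl>
1 sub01      0.957 A            90.9          2.03    0.185     63 TRUE
2 sub01      0.957 B            99.7          2.19    0.219     68 TRUE
3 sub01      0.957 C           108.           2.84    0.306     88 TRUE
4 sub01      0.957 D           116.           2.52    0.291     78 TRUE
5 sub02      0.952 A            89.1          2.02    0.180     87 TRUE
6 sub02      0.952 B            93.3          2.53    0.236    109 TRUE
# ℹ 18 more rows
```

```r
res$syntax
```

```
# A tibble: 2 × 5
  group statistic p_value n_subjects n_perm
  <chr>     <dbl>   <dbl>      <int>  <int>
1 DS      0.0122    0.242          3   1000
2 DS-AD   0.00628   0.512          3   1000
```

Every recovered map correlates with its planted template, and the
sample-wise label accuracy against the hidden ground truth is
reported by `evaluate_against_truth()`:

```r
round(evaluate_against_truth(res)$map_corr, 3)
evaluate_against_truth(res)$accuracy
```

```
    A     B     C     D
0.999 0.999 1.000 1.000
[1] 0.8886943
```

The group-statistics stage produces a summary table (per-group mean
(SD) for each class × feature, with a covariate-adjusted p-value row)
and symptom-score correlations:

```r
res$report$correlations
```

```
# A tibble: 2 × 4
  class    rho p_value     n
  <chr>  <dbl>   <dbl> <int>
1 A     0.429    0.397     6
2 D     0.0286   0.957     6
```

`autoplot(res$maps)` draws the recovered topographies;
`run_pipeline(..., out_dir = "results/")` writes `maps.csv`,
`features.csv`, `transitions.csv`, `syntax.csv`, the group-report CSVs
and scatterplots, and a reproducibility `manifest.json`.

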