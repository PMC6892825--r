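---
title: "Microstate analysis: model, tunables and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis: model, tunables and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the model behind `microstatr`, every tunable
with its default and rationale, what the synthetic cohort generator
does and does not emulate, the numerical choices made where the
methods literature leaves freedom, and the package's limitations. It
states no empirical result: all quantitative claims about the package
are made (and checked) by the test suite and by
`scripts/acceptance.R`, never here.

## The microstate model

Resting-state EEG topographies do not vary continuously; they remain
quasi-stable for tens of milliseconds and then switch abruptly. The
microstate model approximates the average-referenced scalp potential
vector $v(t) \in \mathbb{R}^C$ as

$$ v(t) = a(t)\, \Gamma_{s(t)} + \varepsilon(t), $$

where $\Gamma_1,\dots,\Gamma_K$ are $K$ fixed unit-norm topographies
("maps"), $s(t) \in \{1,\dots,K\}$ is a piecewise-constant label
sequence, and $a(t)$ is a signed scalar intensity. Because $a(t)$ is
signed, all map comparisons must be polarity-invariant: the package
uses the absolute spatial Pearson correlation $|r|$ and the global map
dissimilarity $\mathrm{GMD}$, which are linked by the identity
$\mathrm{GMD}^2 = 2(1-|r|)$ (verified to $10^{-9}$ in the tests by
computing both sides through independent routes).

Global field power, $\mathrm{GFP}(t) = \sqrt{\tfrac1C \sum_c
v_c(t)^2}$ under the average reference, measures momentary topographic
strength. Topographies at local GFP maxima have the highest
signal-to-noise ratio, so clustering operates on GFP-peak maps only.

## Pipeline stages and tunables

All tunables live in one place, `pipeline_config()`. Defaults and
rationale:

* `preproc_band = c(1, 70)` Hz, `notch_band = c(45, 55)` Hz —
  standard broadband cleaning for clinical EEG reviewed at 50 Hz mains.
  Filters are windowed-sinc FIR (Hamming) designed with
  `signal::fir1`; the order is derived from a 1 Hz transition width
  (2 Hz for the notch, where a 1 Hz transition would double the kernel
  for no analytical benefit). Filtering is applied by FFT convolution
  with exact linear-phase delay compensation, so the net filter is
  zero-phase (asserted in the tests via cross-correlation at lag 0).
* `amp_thresh = 100` µV, `min_epochs = 30` — 1-s epochs with any
  channel exceeding ±100 µV are screened; up to 2 bad channels are
  repaired by spherical-spline interpolation (Perrin order $m=4$,
  20 Legendre terms, regularisation $10^{-5}$), 3 or more reject the
  epoch; subjects keeping fewer than 30 epochs are excluded.
* `ms_band = c(2, 20)` Hz — the conventional microstate band:
  microstate dynamics ride on alpha/theta; excluding slow drifts and
  beta/gamma noise stabilises GFP peaks.
* `min_peak_dist_ms = 10`, `sd_mult = 2` — GFP maxima closer than
  10 ms are redundant samples of the same quasi-stable state; peaks
  whose GFP exceeds the mean + 2 SD of peak GFP are treated as
  residual artifacts and dropped.
* `peak_cap = "auto"` — when pooling peaks across subjects for group
  clustering, each subject contributes at most the peak count of the
  subject with the fewest peaks (largest-GFP peaks kept), so no
  subject dominates the group maps.
* `K = 4` — the canonical four microstate classes A–D. The clustering
  itself supports 2–8.
* `smooth_ms = 30` — segments shorter than 30 ms are below the
  accepted microstate duration scale and are treated as back-fitting
  noise.
* `n_perm = 5000`, `seed` — syntax permutation test settings (below).

### Clustering (TAAHC)

Pooled GFP-peak maps are clustered by the topographic
atomize-and-agglomerate hierarchical procedure: starting from
singleton clusters, the cluster contributing least global explained
variance is atomized and its members reassigned to the cluster whose
prototype they correlate with best (polarity-invariant); prototypes
are the first principal component of member maps, which is the
polarity-invariant analogue of the mean. Unlike modified k-means,
TAAHC is deterministic given its input — there is no restart seed.

The $K$ prototypes are then matched to canonical archetype
topographies (left-posterior–right-anterior A, right-posterior–
left-anterior B, symmetric occipital–frontal C, fronto-central D) by
the label permutation maximising total $|r|$, enumerated exactly.

### Back-fitting, smoothing and features

Every sample of the 2–20 Hz data is assigned the map with the highest
$|r|$. Runs shorter than `smooth_ms` are then relabelled: first a
per-sample pass moves each sample of a short run to its next most
likely class until a fixpoint; any residual short run is absorbed
whole into the neighbouring class with the better mean correlation.
The second phase is this package's own convergence guarantee — the
per-sample rule alone can oscillate on adversarial fits — and yields
the checkable postcondition that no run under `smooth_ms` survives.

Per subject and class the package reports mean duration (ms),
occurrence (runs/s), coverage (fraction of samples) and global
explained variance $\mathrm{GEV} = \sum_t (\mathrm{GFP}_t
r_t)^2 / \sum_t \mathrm{GFP}_t^2$, partitioned by class. Coverage
sums to 1 and equals duration × occurrence / 1000 by construction;
both identities are tested exactly.

### Syntax analysis

Observed transition probabilities are run-to-run counts normalised
over all off-diagonal cells. The null expectation assumes transitions
depend only on occurrence rates: $e_{ij} = p_i p_j / \sum_{k \ne l}
p_k p_l$. The test statistic is the chi-square distance between the
subject-mean observed and expected matrices; the null distribution is
built by randomly swapping each subject's observed/expected pair with
probability ½ (exact under exchangeability), with the add-one
estimator $p = (1 + \#\{T^\ast \ge T\}) / (1 + n_\mathrm{perm})$.

### Group statistics

Feature comparisons between two groups use a log-scale ANCOVA,
`lm(log(y) ~ group + age + gender)`; the log link turns
multiplicative duration effects into additive coefficients and
stabilises variance for strictly positive features. Covariates with
fewer than two distinct values are dropped (and flagged) rather than
breaking the fit. Demographics use the Wilcoxon rank-sum test (exact
enumeration when both groups have ≤ 10 subjects and no ties);
symptom-score correlations use Spearman's rank correlation.

## The synthetic cohort generator

`simulation_spec()` / `generate_cohort()` produce a two-group cohort
(10 + 15 subjects by default) with planted ground truth, so every
pipeline stage can be scored against a known answer:

* **Labels**: a semi-Markov chain — gamma dwell times (shape 2, mean
  equal to the group/class mean duration, floored at 10 ms), next
  class drawn proportionally to the group's occurrence bias with
  self-transitions excluded. The default per-group mean durations and
  occurrence biases differ between groups (group 2 has a longer
  class-A and shorter class-D duration), so group-level recovery is
  testable.
* **EEG**: $v(t) = a(t)\Gamma_{s(t)} + \varepsilon(t)$ with a 10 Hz
  carrier under a slowly varying log-normal envelope, spatially
  correlated Gaussian noise (squared-exponential kernel on the
  electrode sphere) scaled to a broadband amplitude SNR of 4, and
  per-sample average referencing. 19 channels (10–20 montage) at
  1 kHz; 30–170 one-second epochs per subject drawn from per-group
  truncated normals.
* **Demographics**: per-group age, gender and symptom-score
  distributions, the last separated between groups so the correlation
  stage has signal.

What it deliberately does **not** emulate: eye blinks or muscle
artifacts with realistic morphology (screening is exercised by
synthetic amplitude spikes in the tests instead), 1/f background
spectra, non-stationary alpha reactivity, electrode drift or
impedance changes, and any within-subject session structure. The
generator's purpose is verifiability of the analysis code, not
biophysical realism; absolute feature values from it should not be
read as clinical reference values.

Every random draw is a pure function of the spec's master seed via
fixed per-subject, per-purpose substreams, so cohorts are reproducible
across sessions and platforms and individual subjects can be
regenerated in isolation.

## Numerical choices

* **FFT convolution** for FIR filtering: kernels reach thousands of
  taps at 1 kHz with a 1 Hz transition; direct convolution would be
  quadratic in practice.
* **First principal component** prototypes via the eigenvector of the
  $C \times C$ cross-product matrix — cheap at 19 channels and
  polarity-invariant by construction.
* **Transposed prototype storage** in TAAHC so each reassignment is a
  single matrix product over candidate maps.
* **Vectorised permutations** in the syntax test: the statistic under
  a sign-swap is the baseline statistic plus a swap-matrix product,
  so all permutations are evaluated with one matrix multiplication.
* **16-bit EDF** I/O is written by hand (no EDF reader was available
  as a dependency): symmetric physical range per channel chosen from
  the data, 1-s records, deterministic headers. Round-trip error is
  bounded by the quantisation step and tested.
* **Problem sizes** used by the tests and acceptance script (25
  subjects, 1 kHz, tens of thousands of pooled peaks, 500-dataset
  calibrations) are the package's own choice: large enough that
  clustering, back-fitting and the permutation machinery are
  exercised at realistic scale, small enough to keep the whole suite
  comfortably runnable on a single CPU.

## Open-design decisions

Where the methods literature does not fully pin the algorithm down,
the package fixes a choice and documents it here: the greedy
largest-first GFP-peak picker with exclusion windows; atomizing the
lowest-GEV-contribution cluster (rather than smallest membership) in
TAAHC; the two-phase smoothing rule above; global (not row-wise)
normalisation of transition matrices so observed and expected live on
the same simplex; and dropping degenerate covariates in the ANCOVA
instead of erroring. Each choice is locked by at least one test.

## Limitations

* Microstate results depend on $K$; the package takes $K$ as a config
  input and does not implement meta-criteria for choosing it.
* The ANCOVA assumes log-normal features and homogeneous slopes; no
  interaction terms are fitted.
* The syntax test's exactness holds under subject-level
  exchangeability of observed and expected matrices; with few
  subjects its resolution is limited to $2^{n}$ sign patterns.
* The EDF writer covers the subset of EDF needed for round-tripping
  this package's recordings (continuous, equal-rate channels); it is
  not a general EDF implementation.
* The spherical-spline interpolator assumes electrode positions on a
  unit sphere and at most a few bad channels per epoch; screening
  rejects epochs beyond that rather than attempting repair.
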