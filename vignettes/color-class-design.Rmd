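---
title: "Designing AgN-DNA fluorescence colors from sequence: methods and modeling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing AgN-DNA fluorescence colors from sequence: methods and modeling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agndesign)
```

## The problem

DNA-stabilized silver nanoclusters (AgN-DNAs) are fluorophores of 10-30
silver atoms templated by short single-stranded DNA. The nucleobase
sequence of the templating oligomer selects the cluster's size and
therefore its emission color, from green through the near-infrared (NIR)
tissue-transparency window. The sequence space of 10-base templates
(4^10 = 1,048,576 oligomers) is far too large to screen exhaustively in the
lab, and the emitters of greatest interest — bright NIR species — are by far
the rarest. `agndesign` models the sequence-to-color map from a modest
measured library and uses the model to rank every possible 10-mer for a
target color class.

Five color classes are used, defined on the peak emission wavelength
lambda_p of the brightest fitted spectral peak:

| class  | interval            |
|--------|---------------------|
| Green  | lambda_p < 580 nm   |
| (gap)  | 580-600 nm, excluded from training |
| Red    | 600-660 nm          |
| Far Red| 660-800 nm          |
| NIR    | > 800 nm            |
| Dark   | no bright emission  |

The 580-600 nm band is excluded because the cluster composition there is
not established; class boundaries are open/closed such that a boundary
value falls in the gap or the shorter-wavelength side (Red is (600, 660],
Far Red (660, 800], NIR (800, Inf)). All boundaries are configurable
through `curation_config()`.

## Staple features

Crystal structures of AgN-DNAs show that both adjacent and non-adjacent
nucleobase pairs chelate the silver core, in analogy to the two-ligand
"staple motifs" of monolayer-protected metal clusters. The feature map
follows that observation: a sequence is represented by the counts of all
ordered, gapped nucleobase pairs `X_mY` — base X followed, m arbitrary
bases later, by base Y — for m = 0..8. For 10-base sequences this gives
4 x 4 x 9 = 144 integer counts whose total is always
sum(m = 0..8) (9 - m) = 45. The canonical column order is X outermost
(A, C, G, T), then Y, then m (`feature_names()`), and `X_mY` is distinct
from `Y_mX`: pairs are read 5'→3'. Counts enter the classifiers raw — they
share a common 0-9 scale, and standardization would only blur the sparsity
pattern that L1 regularization is meant to expose. A positional one-hot
encoding (length 4L = 40) is provided for comparison studies
(`one_hot()`).

One property worth knowing: with the full gap window m <= 8 the staple map
is *injective* on 10-mers — we verified by exhaustive enumeration of all
4^10 sequences that no two share a count vector, because gaps up to L-2
expose every pairwise distance (the `X_8Y` components pin the two strand
ends). The representation is therefore "positionally independent" only in
the sense that position is encoded implicitly and degenerately; for
restricted windows (e.g. dimer counts, m_max = 0) genuinely distinct
sequences do collide, as a property test demonstrates.

## Spectral peak fitting

Well-plate emission spectra are fitted as sums of one to three Gaussians
*in energy* (E = hc/lambda, hc = 1239.842 eV nm), where molecular-like
emission bands are closer to symmetric (`fit_peaks()`). Numerical choices,
all configurable:

- **Initialization.** Peak guesses are the k largest local maxima of a
  Savitzky-Golay-smoothed copy of the signal (window 7, order 3) —
  deterministic given the input.
- **Nesting.** The k-component fit starts from the (k-1)-component optimum
  plus one component at the largest residual, so the optimal residual sum
  never increases with k.
- **Model selection.** The smallest k is kept for which adding another
  component would reduce the residual sum by less than 5% (elbow rule,
  `elbow_fraction`).
- **Amplitude floor.** Components with amplitude below 3x the median
  absolute deviation of the fit residuals are dropped; a spectrum with no
  surviving component yields an empty peak set, which is how Dark wells
  arise.
- **No intensity Jacobian.** Raw detector counts are fitted against
  energy; the d(lambda)/dE factor is available behind the `jacobian` flag
  of `to_energy()` but off by default, since peak-center extraction is
  insensitive to it at these bandwidths.

Peak areas are divided by the area of a control emitter measured on the
same plate (`normalize_brightness()`), making brightness comparable across
wells. A peak is "bright" above a normalized-brightness threshold (default
0.15); peaks between 0.5x and 1x the threshold are "mediocre". Both values
are package choices exposed in `curation_config()`, as is everything they
feed.

## Curation rules

`curate_training()` builds the training set: label = class of the
brightest bright peak; no bright (or mediocre) peak at all → Dark;
bright peaks in two or more color classes → excluded (`multiclass`),
because such sequences likely fold into different conformations around
different cluster species and would blur the sequence-color signal;
brightest peak in the 580-600 nm gap → excluded (`gap`); strongest peak
only mediocre → excluded (`mediocre`). Every input sequence lands in
exactly one of the labeled set or the exclusion log.

NIR emission is measured on a separate detector whose brightness scale is
not directly comparable to the visible reader. Two curation conventions
are therefore supported: the default applies the multiclass rule to all
classes alike; `nir_overrides_training = TRUE` instead labels any sequence
with a bright NIR peak as NIR regardless of its visible peaks, matching
how NIR libraries are compiled in practice. Design *outcomes* are always
judged with the NIR-aware convention (`evaluate_design_outcome()`): a
visible-target design succeeds if the brightest visible peak is in the
target class, an NIR-target design succeeds if any bright NIR peak exists,
and a sequence with both gets both labels.

Class cutoffs themselves can be derived from data with
`kmeans_cutoffs()`: 1-D k-means solved *exactly* by dynamic programming
over the sorted values (weighted over unique values), rather than Lloyd
iterations. In one dimension the optimal clustering is a contiguous
partition, so the DP removes all seed dependence at negligible cost; a
multi-start Lloyd run agrees to floating-point precision in the tests.
Midpoints between consecutive centroids are the natural class boundaries.

## The classifier ensemble

The core model (`agn_ensemble()`) is built for small, heavily imbalanced
libraries — NIR sequences are roughly 10x rarer than Far Red ones:

- one **one-versus-one** task per unordered pair of the five classes
  (10 pairs); pairwise models outperform single multiclass models at these
  data sizes;
- per pair, **10 balanced subsamples**: the larger class is randomly
  subsampled (without replacement) to the smaller class's size, and one
  linear classifier is trained per subsample — 100 classifiers total.
  Consensus over subsamples retains sensitivity to the minority class
  without discarding majority-class information;
- each member is an **L1-penalized linear margin classifier**, fitted with
  `glmnet` (binomial loss, alpha = 1, single lambda). The penalty is
  parameterized as a cost c (default 0.1) with lambda = 1/(n c), matching
  the usual "C x loss + ||w||_1" convention. The L1 penalty performs
  feature selection by construction: most of the 144 weights are exactly
  zero;
- member margins d are calibrated to probabilities with the logistic map
  p = 1/(1 + exp(-d)) — for the binomial loss this is the model's own
  likelihood, so the calibration is exact rather than a post-hoc fit —
  and a pair's probability is the mean over its 10 members;
- **consensus prediction** assigns the class whose *minimum* pairwise
  probability is largest; ties are broken by the fixed class order
  Dark < Green < Red < FarRed < NIR and flagged.

`agn_cv()` reports repeated stratified 10-fold cross-validation per pair,
re-drawing the balanced subsample on every repeat so the reported
standard deviation includes subsampling variability.

## Feature importance

`shadow_importance()` scores features per pair against randomized
controls: each repeat appends one permuted "shadow" copy of every real
column, fits a 100-tree random forest (`ranger`), and records each real
feature's importance and the maximum shadow importance. A feature is
selected when its mean importance over 10 repeats exceeds the mean maximum
shadow importance (MISA rule); for pairs containing NIR, where subsampling
the tiny class inflates the variance, the rule relaxes to mean + sd >=
max shadow. Attribution uses the forest's impurity decrease; the selection
contract is attribution-agnostic, so any per-feature importance could be
substituted.

Per-class **net importance scores** (`net_importance()`) fold the four
pairwise importances of a feature into one signed number per class:
adding the importance where the feature is more frequent in the class than
in the pair partner, subtracting where it is less frequent, and
contributing zero on exact ties. A positive NIS marks a motif that both
matters and is enriched — on both synthetic and real libraries,
consecutive-G motifs (`G_0G`) carry large positive NIS for the
long-wavelength classes and negative NIS for Dark.

## Sequence design

`design_top_k()` scores all 4^L sequences: a sequence's score for a target
class is the **minimum** over the four target-containing pairs of the
average target probability — a sequence is only ranked highly if *no*
competing class can claim it. The space is streamed in blocks (default
65,536), feature vectors are built directly from base-4 codes, and only a
bounded top-k pool is retained, so memory does not grow with 4^L. Ties
break lexicographically (the enumeration index), making the ranking fully
deterministic. The default k = 124 reflects a 384-well plate run as three
targets plus ten controls. The full 4^10 screen takes well under a minute
per target on one CPU.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the classifier
assumes: each class has a linear score over staple counts (planted motifs
with weights, plus an intercept), the noiseless label is the argmax, and
sequences are drawn class-conditionally by rejection sampling from
motif-biased proposals. Defaults, chosen once to mirror a realistic
library: proportions Dark 0.40, Green 0.12, Red 0.15, Far Red 0.30, NIR
0.03 (a ~10:1 FarRed:NIR imbalance); planted motifs `G_0G` → NIR,
`G_1G`/`G_2G` → Far Red, `C_0G`/`G_0C` → Red, `C_1C`/`C_2C` → Green, and a
weak `T_1T` plus intercept for Dark — consecutive Gs driving the largest,
longest-wavelength clusters, as observed experimentally. Label noise flips
each label to a uniform other class with configurable probability.
`generate_spectra()` adds the spectral layer: one Gaussian peak per
emissive record, centered inside the class interval, above the bright
threshold, with additive Gaussian noise.

Because the generative rule is linear in the same features the classifier
uses, perfect recovery is achievable at zero noise — by design, so that
failures indict the implementation, not the representation. What passing
these tests does *not* show: real libraries are not linearly labeled, real
spectra have correlated baselines and detector roll-off, and real NIR
data arrive through a separate bandpass instrument. The generator is a
correctness harness, not a photophysics model. A deliberate stress case is
documented in the tests: rules whose classes are XOR-like combinations of
motifs are not representable by any linear member, which is the model's
expected failure mode.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script use: training sets of 5,000
synthetic records (1,500 for module-level fixtures), hold-outs of
1,000, 25-100 cross-validation repeats, 10 importance repeats with
100-tree forests, and one full 4^10 design screen — sizes chosen so the
entire suite runs in minutes on a single CPU while still exercising the
study-scale imbalance. All randomness flows from one integer seed through
derived child seeds; identical seeds give byte-identical datasets, models
and rankings. Models serialize to JSON with 17 significant digits, so a
save/load round trip reproduces pair probabilities exactly.

## Limitations

- The model is trained on, and enumerates, 10-base templates only;
  the feature formulas extend to other lengths but no trained
  cross-length transfer is claimed.
- Brightness thresholds, the mediocre band, and the 800 nm Far Red/NIR
  cutoff are configuration values, not re-derived from data here.
- Probability calibration uses the logistic margin map; Platt-style
  refitting is intentionally not implemented since member losses are
  already likelihood-based.
- Detector responsivity correction, excitation spectra and absolute
  quantum yields are out of scope.
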