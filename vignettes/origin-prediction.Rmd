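---
title: "Predicting replication origins from pseudo nucleotide composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting replication origins from pseudo nucleotide composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriforest)
```

## The problem

DNA replication in eukaryotes initiates at many specific loci, the origins
of replication (ORIs). Experimental mapping of ORIs (e.g. by ChIP) is slow
and costly, so a sequence-based classifier that scores a 300-bp window as
ORI or non-ORI is a useful screening tool. The difficulty is that
metazoan origins lack a crisp consensus motif: the signal, to the extent
there is one, lives in composition and in local DNA *structure* — the
helical geometry of successive base-pair steps — rather than in an exact
sequence word. oriforest therefore encodes windows by a representation
that mixes both, and classifies them with a random forest.

## The model

### Type-1 pseudo k-tuple nucleotide composition

A window $D = N_1 N_2 \cdots N_L$ over $\{A, C, G, T\}$ is mapped to a
vector of dimension $Z = 4^k + \lambda$:

$$
\phi_u \;=\;
\begin{cases}
\dfrac{f_u}{\sum_{i=1}^{4^k} f_i + w \sum_{j=1}^{\lambda} \theta_j}
  & 1 \le u \le 4^k,\\[2ex]
\dfrac{w\,\theta_{u-4^k}}{\sum_{i=1}^{4^k} f_i + w \sum_{j=1}^{\lambda} \theta_j}
  & 4^k < u \le 4^k + \lambda,
\end{cases}
$$

where $f_u$ is the normalized frequency of the $u$-th k-mer (overlapping
count divided by $L - k + 1$, lexicographic order) and $\theta_j$ is the
tier-$j$ structural correlation factor

$$
\theta_j = \frac{1}{L-j-1} \sum_{i=1}^{L-j-1}
  \Theta\!\left(N_i N_{i+1},\, N_{i+j} N_{i+j+1}\right),
\qquad
\Theta(a, b) = \frac{1}{\Phi} \sum_{\nu=1}^{\Phi}
  \left[P_\nu(a) - P_\nu(b)\right]^2 .
$$

$P_\nu$ is the $\nu$-th physicochemical property of a dinucleotide step;
the default table carries $\Phi = 6$ helical parameters — the angular
twist, tilt, roll and the translational shift, slide, rise — giving
$6 \times 16 = 96$ values. Because $\sum f_i = 1$, every feature vector
is non-negative and sums exactly to 1; this is asserted property-style in
the tests and the encoder is additionally checked against an independent
naive transcription of the formulas to $10^{-10}$.

The three tunable encoding parameters are:

* **k** — the k-mer tier capturing local composition. Default 4. Above 4
  the $4^k$ k-mer space outgrows benchmark-sized datasets, so values
  beyond 4 produce a warning rather than an error.
* **lambda ($\lambda$)** — how many correlation tiers (lags) of global
  structure are included. Default 7. A tier $j$ requires $L \ge j + 2$;
  the encoder enforces $\lambda \le L - 2$.
* **w** — the weight balancing the k-mer block against the correlation
  block, in $(0, 1]$. Default 0.9.

The defaults are the configuration selected by grid search on the human
benchmark (below).

### Property standardization

Raw property values are standardized per property row to mean 0 and SD 1
over the 16 dinucleotides before entering $\Theta$. We use the
*population* SD (denominator 16), the convention of the pseudo-composition
lineage this encoding descends from. Under either convention the
transformation is idempotent — re-standardizing a standardized row changes
nothing — but the convention must be fixed for the "SD = 1" invariant to
be self-consistent; the tests assert idempotence to $10^{-12}$.

The bundled table (`default_property_table()`) is a **synthetic
stand-in**: values with physically plausible magnitudes (twist
≈ 31–39°, rise ≈ 3.3 Å, …) obeying complementary-strand symmetry, not
measurements from a specific crystallographic survey. Since only
standardized *differences* between dinucleotides enter $\Theta$, every
structural property of the encoder (normalization, dimension, symmetry,
oracle agreement) is independent of the particular values. Users with a
preferred parameter set supply it as a 6 × 16 TSV via
`load_property_table()`; models remember a fingerprint of their table and
refuse to score against a different one unless forced.

### The decision engine

The classifier is a random forest of 100 trees fitted after `set.seed(1)`
(both configurable), so training is fully deterministic for a given
feature matrix. The score of a query is the fraction of trees voting
ORI — a ranking score, not a calibrated probability — and the label call
thresholds it at 0.5, ties going to ORI. Tree hyperparameters other than
count follow `randomForest`'s defaults and can be overridden through
`rf_engine(...)`. Exact tree structures are implementation- and
RNG-specific, so cross-implementation comparisons should be made on
metrics, never on tree equality.

## Evaluation protocol

`jackknife()` implements leave-one-out cross-validation: each sample is
scored by a forest trained on the remaining $n - 1$. It is the least
arbitrary protocol — unique for a given dataset and seeded engine — and
is what the headline numbers are quoted from. The $n$ held-out vote
fractions are thresholded at 0.5 for the confusion counts and pooled
as-is for the ROC; the curve sweeps all distinct scores and the AUC is
the trapezoid integral, which (ties grouped) equals the normalized
Mann–Whitney U statistic — the tests assert that identity on random
score sets.

Metrics are reported in the intuitive error-rate form

$$
Sn = 1 - \frac{fn}{N^+},\quad
Sp = 1 - \frac{fp}{N^-},\quad
Acc = 1 - \frac{fn + fp}{N^+ + N^-},\quad
MCC = \frac{1 - \left(\frac{fn}{N^+} + \frac{fp}{N^-}\right)}
{\sqrt{\left(1 + \frac{fp - fn}{N^+}\right)\left(1 + \frac{fn - fp}{N^-}\right)}},
$$

with $fn$ the ORIs called non-ORI and $fp$ the non-ORIs called ORI.
These are algebraically identical to the conventional TP/TN/FP/FN
formulas (asserted numerically over the exhaustive grid of all count
quadruples with class sizes up to 12). When a predicted class is empty
the MCC denominator vanishes; we report 0 with an `mcc_undefined` flag,
a standard convention. The computed MCC is clamped into $[-1, 1]$ to
absorb floating-point spill of a few ulp.

`kfold()` is the faster surrogate used inside the grid search: folds are
stratified by label with a seeded shuffle. `grid_search()` evaluates the
canonical 400-point grid ($k \in 1..4$, $\lambda \in 1..10$,
$w \in 0.1..1.0$) with **one shared fold assignment** across
configurations, removing fold-sampling noise from the comparison (the
protocol itself does not specify this; it is this package's choice).
Selection is by accuracy — the headline metric — with ties broken by
higher MCC and then by smaller feature dimension $4^k + \lambda$, i.e.
preferring the more parsimonious encoding. `w` is enumerated as the exact
decimals `1:10 / 10` so configuration identity never drifts with
floating-point formatting.

## The benchmark and its stand-in

The reference benchmark is 283 experimentally confirmed human (HeLa)
ORI windows of 300 bp plus 282 matched negatives, each negative taken
from the window $[-600, -300)$ upstream of its ORI start (0-based
half-open; `extract_negative()` implements exactly this rule, on the
same strand, with no reverse-complementing). Redundancy removal in the
original pipeline used external greedy clustering at 0.75 identity; that
step is documented but deliberately not re-implemented — datasets are
accepted as-is. The benchmark FASTA itself is not redistributable with
the package, so `load_benchmark()` parses any user-supplied copy (labels
in headers or paired files) and the package's self-tests run instead on
synthetic data.

### What the synthetic generator emulates

`synthesize_dataset()` draws fixed-length sequences from first-order
Markov chains: the non-ORI class from the uniform chain, the ORI class
from the uniform chain interpolated by `epsilon` toward a fixed skewed
transition matrix. The skewed matrix strongly favours the A→T and T→A
transitions (AT/TA dinucleotide enrichment, echoing the AT-richness of
real origins) and is **doubly stochastic**, so its stationary single-base
composition remains uniform: the planted signal lives at the dinucleotide
level and above, which is precisely what the $k \ge 2$ /
correlation-tier machinery is supposed to detect, and what the recovery
test checks (grid search prefers $k \ge 2$ over the $k = 1$ baseline).
At `epsilon = 0` the classes are generated identically, so jackknife
accuracy must sit at chance — the package's null calibration.

What the generator does *not* emulate: real origins' sharing of motifs
with genomic background, long-range chromatin context, G-quadruplex
structure, CpG islands, and inter-sequence redundancy. Passing the
synthetic recovery tests therefore demonstrates that the pipeline is
correct and can recover a planted compositional signal at realistic
sample sizes (100 per class, 300 bp) — not that it attains any particular
accuracy on real human data.

## Scanning long queries

`scan_sequence()` slides a 300-bp window at step 1: a query of length
$L$ yields $L - 300 + 1$ calls (a 514-bp query yields exactly 215), and
queries shorter than 300 bp are rejected — the classifier is only
defined at its training width. Window $i$ (1-based, the server-style
index) covers the 0-based half-open interval $[i-1, i-1+300)$; both
coordinate systems are reported to prevent off-by-one misuse.
`merge_calls()` collapses consecutive identical calls into maximal runs
losslessly, and `write_bed()` emits the ORI runs as BED6 with the mean
window vote fraction × 1000 (truncated) as the score. The reverse strand
is not scanned unless asked (`both_strands = TRUE`), since the window
classifier is trained on a single strand.

## Numerical and design choices, in brief

* Lexicographic k-mer and dinucleotide order everywhere, so models and
  feature TSVs are portable across runs.
* k-mer frequencies are normalized by the window count $L - k + 1$; any
  consistent normalization cancels in the PseKNC denominator, since the
  k-mer block enters through $\sum f_i$.
* Lowercase input is upcased with a notice; any character outside
  A/C/G/T is an error naming the position — never silently skipped.
* The encoder accepts sequences shorter than 300 bp (unit-testable
  primitives); the 300-bp floor is enforced only where the fitted
  classifier is applied to queries.
* Degenerate inputs fail loudly: constant property rows (zero SD),
  single-class training labels, correlation tiers beyond $L - 2$,
  feature-dimension mismatches at prediction time.
* Jackknife at the sizes used in the examples (200 sequences of 300 bp,
  19-dimensional features, 100-tree forests) takes a few seconds; the
  full 400-point grid at benchmark size is an hours-scale computation
  and is sampled down in examples and tests.

## Limitations

* The bundled property table is a labelled synthetic stand-in (above);
  absolute scores obtained with it are not comparable to scores computed
  with a published parameter set, although all structural behaviour is.
* Vote fractions are uncalibrated; use them for ranking and
  thresholding, not as probabilities.
* Only single-label binary classification is supported; the metric set
  is not valid for multi-label problems.
* Forest determinism is per-implementation: the same seed in a different
  random-forest implementation yields different trees, so reproduction
  across implementations is expected only within metric tolerances.
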