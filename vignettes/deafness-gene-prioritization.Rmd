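---
title: "Positive-unlabeled prioritization of deafness genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positive-unlabeled prioritization of deafness genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

deafPU prioritizes candidate deafness genes from bulk RNA-seq of inner-ear
sensory epithelia. This vignette explains the statistical model, the
assumptions behind each stage, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the design
choices we made where the problem left the design open.

## 1. The PU model

Let $y \in \{0, 1\}$ indicate whether a gene is a deafness gene (DG) and
$s \in \{0, 1\}$ whether it is *labeled* as one (i.e. on the curated list).
Every labeled gene is a DG, but unlabeled genes are a mixture: $s = 1
\Rightarrow y = 1$, not conversely. Under the *selected completely at
random* assumption — the curated genes are a random subset of all DGs, so
labeling is independent of the features given $y = 1$ — a classifier trained
to predict $s$ estimates

$$ g(x) = p(s = 1 \mid x) = c \, p(y = 1 \mid x), \qquad c = p(s = 1 \mid y = 1). $$

Ranking by $g$ is therefore already correct; calibrated positivity
probabilities additionally require dividing by an estimate of $c$. The
assumption is untestable on real data (discovery of deafness genes is
plausibly biased toward, e.g., highly expressed genes); on synthetic data it
holds by construction, which is exactly what the test suite exploits.

### Features

Four per-gene features are computed from counts (`gene_features()`):
average log2-CPM over all samples, and three log2 fold changes — age
(P0/E16.5), tissue (cochlea/vestibule), and their interaction,
$\log_2 \frac{(C/V)_{P0}}{(C/V)_{E16.5}}$. Fold changes are differences of
group-mean log2-CPMs with a prior count (default 0.5, added per gene with
$2\cdot$prior in the library size) keeping everything finite. This is a
deliberate simplification relative to a full GLM-based differential
expression fit: numerical agreement with GLM contrasts is not a goal, and
the direction conventions (age = P0 over E16.5, tissue = cochlea over
vestibule) are recorded in the output's `"directions"` attribute. Only the
interaction direction is fixed by its definition; the others are
conventions.

### Bagging with downsampling

With ~130 positives against ~15,000 unlabeled genes, each base learner is
fit on a balanced set: all labeled positives in the training split plus an
equal number of unlabeled genes drawn uniformly without replacement. The
ensemble (default 1000 CART trees per split, 2000 repeated stratified 75/25
splits; ranking quality typically plateaus near 150 splits) averages the
trees' leaf class probabilities over learners, then over the splits in
which a gene fell in the test set. Genes never seen in any test set (only
possible at very small split counts) are reported `NA`, never imputed.

### Base-learner regularization

`tree_control()` defaults to standard CART regularization (`minsplit = 20`,
`minbucket = 7`, `cp = 0.01`). This choice is load-bearing for the
maximum-based estimator e3: fully grown trees (`minbucket = 1`) have pure
leaves, so every tree votes 0/1 and, on separable data, the deepest
positives receive unanimous votes — $g(x)$ pins to exactly 1 and e3
saturates at its ceiling regardless of the true $c$. With a minimum leaf of
7, a leaf that mixes a hidden positive into the positive region reports an
interior proportion, the ensemble's maximum stays off the boundary, and e3
becomes a usable estimator (we measure e3 $= 0.27 \pm 0.03$ for a true
$c = 0.3$ in the recovery experiment below). Fully grown trees remain one
argument away for users who only care about ranking.

A related scale caveat: if the number of labeled genes in a training split
is below about `minsplit`/2, every tree is an unsplittable stump, all
probabilities collapse to 0.5 and the downstream corrections amplify this
into nonsense. The pipeline is intended for tens of labeled genes or more.

### Bias corrections

Two corrections are applied per split, in a fixed order:

1. **Undersampling.** Training on balanced subsamples inflates
   probabilities. With $\beta$ the probability of selecting a negative
   instance (`n_labeled / n_unlabeled` by default, e.g. $130/15076$), the
   corrected probability is $p' = \beta p_s / (\beta p_s - p_s + 1)$ — a
   strictly increasing bijection of $[0,1]$ fixing the endpoints, inverted
   by substituting $1/\beta$.
2. **PU correction.** $p'$ estimates $p(s=1\mid x)$; dividing by an estimate
   of $c$ gives $p(y=1\mid x)$, truncated at 1 (truncations are counted and
   reported). The three estimators are computed per split on that split's
   test set, from the undersampling-corrected (untruncated) scores, and
   aggregated as mean ± SD across splits.

e1 averages $g$ over labeled validation genes and underestimates $c$
whenever labeled positives are not all near-certain; e3, the validation
maximum, estimates $c$ well when some genes are unambiguous positives and
the ensemble is not overconfident (see above). Calibration is assessed by
the Brier score and an 11-bin reliability curve with exact Clopper–Pearson
95% intervals per bin. The implied total number of positives,
`n_labeled / c`, is reported raw and rounded to two significant figures.

### The rerun classifier

Given calibrated probabilities $p_g$, the rerun stage treats each unlabeled
gene as positive with probability $p_g$, independently before every
iteration, while labeled genes are always positive. Splits restratify on
the reassigned classes (they are the training labels — the one open choice
here, flagged as an assumption), negatives are downsampled to the realized
positive count, and no PU correction is applied at the end — reassigned
classes are soft truth, not PU labels. A single undersampling correction
uses the expectation-based $\beta = E(N^+)/(N - E(N^+))$ with
$E(N^+) = \sum_g p_g$ (labeled genes contributing 1), computed once from
the input probabilities rather than per-iteration realized counts.
Evaluations of the rerun against deafness-associated genes exclude the
known labeled genes, whose training role would inflate their scores.

### Threshold selection

Association evidence from three text-mining-style sources is reduced to a
per-gene table; a DiGSeE-style source scores
$n_{articles} + n_{sentences}/(\max n_{sentences} + 1)$, so articles
dominate and sentences break ties. The combined score is the mean ascending
rank across sources, shifted to a minimum of 0 — invariant to monotone
per-source rescaling, with genes absent from a source all tied at the
bottom. Two thresholds are offered: the Youden point (maximum sensitivity +
specificity against binary association, ties resolved to the smallest
threshold) and the threshold whose one-tailed rank-sum comparison of
association scores (above vs not above) is most significant for the
combined score; local maxima of the $-\log_2 p$ curve are reported as
alternatives. Known labeled genes are excluded from both.

## 2. Rank-based tests

One-sided rank-sum p-values use the exact null distribution when it is
available (untied samples up to 50 per side via the standard algorithm, or
full enumeration over assignments up to ~200k arrangements when ties
preclude it) and the tie- and continuity-corrected normal approximation
otherwise. The two-sided proportion test is the chi-square with Yates
continuity correction, $\chi^2 = (\max(|x - np_0| - 0.5,\, 0))^2 / (np_0(1-p_0))$,
which reproduces printed values such as $p = 2.19\times10^{-5}$ for 57 of 76
genes; an exact binomial option is provided for comparison. The age–tissue
interaction screen z-scores each age's cochlea/vestibule log-ratios (so the
ages are comparable), applies a paired one-sided signed-rank test per
annotated term, and corrects by Benjamini–Hochberg within each direction's
list; the z-scored medians per term and age are returned as plotting
coordinates (the z-scored values are used both for selection and for the
medians — an assumption where either convention was defensible). DeLong's
test for two correlated ROC curves is implemented via the mid-rank
placement form and cross-checked in the tests against both an independent
implementation and a paired bootstrap.

## 3. Deconvolution

Mixing proportions solve $\min_w \lVert S w - m \rVert^2$ subject to
$w \ge 0$, $\sum w = 1$, on log2(CPM + 1) expression — log-scale
deconvolution is a documented bias in general, but linear-scale estimates
of hair-cell content are known to go badly wrong in this tissue, and the
log-scale contract is part of the method. With at most four cell types the
solver enumerates all supports and solves each equality-constrained KKT
system exactly (pseudo-inverse on rank-deficient supports, with a warning),
so the returned optimum is global and noiseless mixtures round-trip to
machine accuracy.

Signatures are the top-$k$ genes by variance of log expression across the
four reference profiles (hair cells and supporting cells of cochlea and
utricle), after removing genes below 1 CPM in any reference condition; ties
break by gene id for determinism. $k$ is chosen by scanning $k = 2..1000$
and minimizing estimated cross-tissue contamination (mean percentage of
cochlear weight in vestibular samples plus the converse). Because noise
makes this curve wiggle, local minima whose descent basin spans fewer than
`min_width = 10` genes are discarded — the automated analogue of manually
ignoring a narrow spurious dip — and remaining ties resolve to the smallest
$k$. Per-age signatures are independent.

The selection heuristic is only meaningful when the references and the
mixtures are *independent measurements*: if mixtures are synthesized from
the very reference matrix being used, every gene is informative, the
objective decreases indefinitely and the scan correctly returns a huge $k$.
The generator therefore provides `perturb_profiles()`, an independent
log-normal re-measurement of the references, for realistic benchmarking.

## 4. What the synthetic data emulate — and what they do not

`gen_counts()` draws gene baselines log-normal on the log2-CPM scale
(mean 4, sd 2), plants a DG subset with a tissue shift of configurable
magnitude and random sign (default ±2, split symmetrically between
tissues), a positive age shift (default +1, split between ages) and a
positive interaction shift (default +1, applied to the P0-cochlea group so
the interaction feature equals it in expectation), and samples
negative-binomial counts with a shared dispersion (default 0.05, a typical
within-group value for inbred-mouse bulk RNA-seq; 0 gives Poisson) around
expected counts of `lib_size` (default 5e6) times renormalized relative
abundances, for 3 replicates per (tissue, age) group. Defaults for the full
scale mirror the motivating study design: ~15,206 expressed genes and ~250
true DGs labeled at rate ~0.52, yielding ~130 labeled genes. The
non-syndromic/syndromic distinction is not modeled as a class — the split
is descriptive only.

Known departures from real data: genes are independent (no co-expression),
dispersion is shared, library sizes are equal in expectation, association
scores have a simple hit/miss structure, and planting one-sided shifts
slightly deflates CPM fold changes of all genes in the boosted groups (a
compositional effect of ~0.1–0.2 log2 at the scales used — present in real
RNA-seq too, but here it is the *only* such distortion). Passing tests
therefore demonstrate that the algorithms recover what they are designed to
recover under their own assumptions; they say nothing about curation bias,
batch structure, or ortholog-mapping noise in real studies.

One global integer seed feeds explicit per-operation seeds; no generator
touches the caller's RNG state, and fixed seeds reproduce outputs bitwise.

## 5. Problem sizes used by the test suite

The recovery experiment runs 2,000 genes with 100 planted DGs labeled at
$c = 0.3$, 150 splits of 200 trees — sizes at which the c-estimate and
ranking results are stable while a full check stays inside a few minutes on
a single core. The deconvolution benchmark uses 1,500 genes with 50 tissue
and 50 cell-type markers, 16 mixture samples and a $k$ scan to 1000. The
pipeline determinism check runs a deliberately small end-to-end
configuration (300 genes, 10 splits) twice and compares output bytes.

## 6. Known limitations

* The SCAR assumption (labeled DGs are a random subset) is built into both
  the correction and the generator; violations bias $c$ and all implied
  totals.
* e3 is a maximum statistic: it is usable only with a smoothed ensemble and
  enough validation genes, and it is biased downward when no gene is a
  near-certain positive.
* The Wilcoxon threshold scan inherits the granularity of its grid (default:
  the observed probabilities).
* Deconvolution assumes the mixture is a convex combination of the
  references in log space; heavy contamination by unmodeled cell types
  violates this silently.
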