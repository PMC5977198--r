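---
title: "Ensemble filtering, cross-entropy redundancy screening, and wrapper gene selection"
author: "entroSelect maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble filtering, cross-entropy redundancy screening, and wrapper gene selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entroSelect)
```

## The problem

Two-class expression studies — tumour versus normal being the canonical
case — routinely measure thousands of genes on a few dozen samples. A
classifier built on all genes overfits badly, and most genes are either
irrelevant to the class or near-copies of one another (co-regulated
probes, members of the same pathway). The goal of this package is to
select a *small, non-redundant, highly discriminative* gene subset, on
which a simple classifier reaches high cross-validated accuracy.

The selection proceeds in four stages, each removing a different kind of
uselessness:

1. **Normalization.** Each gene is centred to mean 0 and scaled to unit
   sample standard deviation (denominator $n-1$).
2. **Ensemble filtering (relevance).** Three univariate filters score
   every gene against the class; the union of their top-$N$ lists forms
   the candidate set $F$.
3. **Cross-entropy screening (redundancy).** Candidates too dependent on
   already-kept candidates — measured by a normalized cross-entropy on
   discretized expression — are dropped, leaving the non-redundant set
   $G$.
4. **Wrapper selection (usefulness to a classifier).** Greedy forward
   selection over $G$, scored by stratified cross-validated accuracy of
   a pluggable classifier, returns the final subset $R$.

By construction $R \subseteq G \subseteq F \subseteq$ all genes, and the
package asserts this containment on every run.

## Stage 1: the three filters

For a gene $g$ with class means $\mu_+,\mu_-$, class standard deviations
$\delta_+,\delta_-$ (sample convention), class variances $s_1^2, s_2^2$
and class sizes $n_1, n_2$:

* **Signal-to-noise ratio**: $\mathrm{SNR} = |\mu_+-\mu_-| /
  (\delta_+ + \delta_-)$, ranked by its (non-negative) value.
* **t-statistic** (Welch form): $t = (\bar x_2 - \bar x_1) /
  \sqrt{s_1^2/n_1 + s_2^2/n_2}$, ranked by $|t|$.
* **Pearson correlation** between the gene and the $\{0,1\}$-coded
  label, ranked by its absolute value.

Two-class relevance is sign-symmetric (an under-expressed marker is as
useful as an over-expressed one), which is why the ranking key for $t$
and the correlation is the magnitude. Degenerate genes are handled by
explicit conventions rather than errors: a gene with zero within-class
spread but distinct class means is maximally discriminative by the
formula's own logic and receives an infinite score (ranked first, ties
in input order); with equal means it scores 0. Tie-breaks everywhere use
ascending input position, so rankings are fully deterministic.

The per-filter top-$N$ lists are merged by `unionTopN()`. With $L$
filters the union size is between $N$ and $L N$. Candidates are ordered
by their best rank across contributing filters (ties by mean
contributing rank, then input order); this ordering matters because the
redundancy screen processes candidates sequentially and keeps the first
member of each dependent group it meets — so the most relevant
representative survives.

Default $N = 50$: the protocol this package follows explored 50, 100
and 200 per filter and found 50 the best choice on five public tumour
microarray sets; larger candidate sets mostly feed the wrapper noise.

## Stage 2: normalized cross-entropy

Dependence among $n$ discrete variables with marginal Shannon entropies
$H_1,\dots,H_n$ and joint entropy $H$ is measured by

$$\bar D_n \;=\; \frac{H_1 + \dots + H_n - H}{(n-1)\,H},$$

a normalization of the total correlation (multi-information). The
numerator is zero exactly when the empirical joint distribution
factorizes, and $H_i \le H$ gives the upper bound, so
$0 \le \bar D_n \le 1$: 0 means empirically independent, 1 maximal
dependence (e.g. a duplicated non-constant variable). The logarithm base
cancels in the ratio; the implementation uses bits internally.

Entropies are plug-in (maximum-likelihood) estimates of the empirical
frequency distribution. Expression is continuous, so each gene is
discretized first. The package defaults to **equal-frequency binning**
with $\lceil\sqrt{n_\text{samples}}\rceil$ bins (floored at 2), ties
assigned to the lower bin: quantile cuts are robust to outliers and
invariant under strictly monotone transforms, both desirable on
microarray intensities. Equal-width binning is available for
comparison.

A candidate $g_j$ is compared against the kept set $G$ by
`redundancyAgainstSet()`. Two aggregation modes are implemented because
the method's description is genuinely ambiguous between them:

* `pairwise_max` (default): $\max_{g \in G}\bar D_2(g, g_j)$ — the
  candidate is redundant if it is strongly dependent on *any* kept
  gene. This is the statistically sane choice at microarray sample
  sizes.
* `joint`: one $\bar D_n$ over $G \cup \{g_j\}$. Faithful to the
  $n$-variable formula, but with tens of samples the joint plug-in
  entropy over more than a few genes saturates (every sample lands in
  its own cell of the product space), making the measure vacuous — use
  it only for very small kept sets.

Elimination (`eliminateRedundant()`) walks $F$ in order and admits a
candidate iff its redundancy against the admitted set is **strictly
below** the threshold $T$; the first candidate is always admitted. The
default $T = 0.5$ follows the published protocol, which scanned
$T = 0.1,\dots,0.9$ and found the selected sets stable for
$T \in [0.4, 0.8]$. Note that $T$ is compared against plug-in estimates,
which are upward-biased for the joint entropy at small $n$; exact
duplicates still give exactly $\bar D_2 = 1$ after any discretization,
so duplicate groups always collapse to one member for any $T \le 1$.

## Stage 3: the wrapper

`forwardSelect()` searches over the ordered non-redundant list $G$,
scoring each candidate subset by stratified $K$-fold cross-validated
accuracy ($K = 10$ by default; leave-one-out available). Fold
assignment is a seeded, within-class shuffle dealt round-robin, drawn
**once** per run and reused for every subset evaluation, so the search
is deterministic given the seed and candidate comparisons are not
confounded by fold noise. Improvement comparisons use exact integer
counts of correctly classified samples — never floating-point
equality.

Two search strategies are provided because the method's published
description admits both readings:

* `best_first` (default): at every step all remaining candidates are
  evaluated joined to the current subset and the best is admitted iff
  it strictly improves accuracy; stop at 100 % accuracy, at no strict
  improvement, or when $G$ is exhausted.
* `scan`: after the best single gene, remaining candidates are examined
  once in $G$'s order and each strict improvement is admitted
  immediately.

The two differ in a way that matters on small samples: best-first
climbs the steepest path and therefore *saturates* quickly — with 60
samples, one or two strong genes often classify 59–60/60 held-out
samples, after which no third gene can strictly improve, so selected
subsets are very small. The scan strategy follows shallower gradients
and typically admits more genes at slightly lower intermediate
accuracy. Both are deterministic; ties go to the earlier position in
$G$.

Classifiers are delegated to standard implementations: KNN with
Euclidean distance (`class::knn`, default $k = 3$, odd so two-class
votes cannot tie), linear-kernel SVM with cost 1 (`e1071::svm`), and
Gaussian naive Bayes (`e1071::naiveBayes`). The reported accuracy is
the selection-set cross-validated accuracy — the same folds steer the
search and produce the headline number. This is optimistically biased
(the maximum over many candidate evaluations), which replicates the
protocol this package follows; for honest generalization estimates hold
out data before calling the pipeline.

A related deliberate bias: z-score normalization is computed once on
the full dataset *before* cross-validation, again mirroring the
protocol. A leakage-free variant is a one-liner (normalize inside each
training fold), but it is not what the published procedure does, so the
package default replicates it; `normalize = FALSE` lets you feed
pre-normalized or fold-wise-normalized data.

## The synthetic generator

`simulateMicroarray()` emulates the structure of two-class tumour
microarray data at configurable size: class-conditional Gaussian
**informative** genes (unit variance, between-class mean shift =
`effectSize`, so the parameter is the standardized mean difference),
**redundant** genes that are a parent informative gene plus
$N(0, \sigma^2)$ perturbation, and independent standard-normal
**noise** genes. Defaults are 60 samples, 500 genes, 5 informative
genes at effect size 2.0 with 4 redundant copies each, balanced
classes.

The copy perturbation defaults to $\sigma = 0.1$: copies must behave as
near-duplicates (parent–copy correlation $\approx 0.995$) so their
discretized dependence is near 1 and the elimination path is genuinely
exercised at $T = 0.5$. Gene order is shuffled under the seed so no
stage can exploit position. Gaussian class-conditional shifts were
chosen because all three filters are mean/correlation statistics whose
behaviour under such shifts is analytically predictable, making
recovery tests sharp.

What the generator does *not* model — probe-level intensity noise,
batch effects, heavy-tailed and intensity-dependent variance,
correlated noise blocks, class imbalance beyond a single fraction —
means that passing recovery tests demonstrates correctness of the
algorithms under clean, favourable conditions, not performance on real
microarray data.

## Numerical and degenerate-input choices

* Standard deviations use the sample convention ($n-1$) everywhere.
* Zero-variance genes: z-score maps them to all-zeros with a warning;
  the Pearson filter scores them 0 with a warning.
* $\bar D_n$ with all-constant inputs (joint entropy 0): defined as 0
  with a warning — no dependence is measurable.
* Labels are canonicalized to $\{0,1\}$ by sorted order of the two
  observed label strings; deterministic for any input coding.
* Equal-frequency bin edges are sample quantiles (R type 7); a value
  equal to a cut point goes to the lower bin.
* If the smallest class has fewer samples than $K$, the fold count is
  reduced to that class size with a warning.

## Problem sizes used by the test suite

The shipped tests exercise the full default study shape (60 samples,
500 genes, 20 replicate seeds) for end-to-end recovery, and smaller
instances (8–80 genes, 12–40 samples) for oracle-equivalence and
property checks; the bound property of $\bar D_n$ is checked on 1,000
random discrete instances. These sizes make the whole suite run in
under a minute on one core while keeping every structural property at
full strength.

## Known limitations

* The redundancy measure depends on the (unreported in the original
  protocol) discretization; results on continuous data are stable under
  monotone transforms only for equal-frequency binning.
* Plug-in entropies are biased at small $n$; no bias-corrected
  estimators are provided.
* The selection-set CV accuracy is an optimistic estimate by design
  (see above).
* Best-first forward selection saturates on small samples; if you want
  larger panels at equal accuracy, use `strategy = "scan"` or LOOCV
  (finer accuracy granularity, $1/n$ instead of roughly $K/n$).

## A worked run

```{r, eval = FALSE}
sim <- simulateMicroarray(seed = 7)
res <- runPipeline(sim$dataset, pipelineConfig(seed = 7))
res
selectedGenes(res)
```
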