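---
title: "Benchmarking pathway-analysis methods without a gold standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking pathway-analysis methods without a gold standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathbench)
```

## The problem

Pathway-analysis (PA) methods map a two-cohort expression dataset and a
gene-set collection to a ranked list of perturbed pathways. Evaluating such
methods is hard because for most clinical or experimental conditions the
truly perturbed pathways — the gold standard — are unknown, incomplete, or
contested. pathbench implements a gold-standard-free evaluation strategy
built on two complementary, resampling-based metrics:

* **Recall** measures *consistency*. A large dataset $D$ with $N$ samples is
  resampled without replacement into sub-datasets $d$ of $n < N$ samples.
  The method's top-$K$ pathway list $A$ from $D$ and $a$ from $d$ are
  compared by
  $$r(A, a) = \lVert A \cap a \rVert / \lVert A \rVert,$$
  the fraction of the full-dataset pathways recovered from the sub-dataset.
  An effective method should recover most of them, increasingly so as $n$
  grows.

* **Discrimination** measures *specificity*. Given two datasets $D$, $D'$
  from different conditions with full-data lists $A$, $A'$ and $M$
  sub-dataset lists $a_i$, $a_i'$ from each, a sub-dataset is *correctly
  associated* when its recall with its own parent strictly exceeds its
  recall with the other condition:
  $$s = \bigl[\lVert a_i : r(A, a_i) > r(A', a_i)\rVert +
        \lVert a_i' : r(A', a_i') > r(A, a_i')\rVert\bigr] / 2M.$$
  Ties count as incorrect, so a trivial method that reports the same
  pathways for every dataset has $s = 0$ even though its recall is 1. The
  same idea generalizes to more than two conditions
  (`generalized_discrimination()`): a sub-dataset must beat *every* foreign
  condition.

Because both metrics compare a method with itself across resampled and
contrasted data, no assumed truth enters the evaluation. Fixing the list
length $K$ (rather than a significance cutoff) removes the bias that methods
declaring more pathways significant would otherwise enjoy; $K = 20$ and
$K = 50$ per direction are the conventional choices.

## The six method variants

All variants consume log2-scale expression with a treatment/control
assignment and a gene-set collection restricted to the measured genes
(`restrict_to_measured()`), and emit top-$K$ up- and down-regulated lists
ranked by ascending one-sided p-value (`pa_rank()`).

* **ORA** — genes with a two-sided pooled-variance t-test p-value below
  `de_alpha` (default 0.05) are the differentially expressed (DE) genes,
  split by the sign of $t$. Each pathway is tested per direction with a
  hypergeometric upper tail on the overlap between its members and the DE
  list, over the universe of measured genes present in the collection. ORA
  as usually stated is direction-blind; splitting the DE genes by $t$ sign
  and running two one-sided tests is the minimal extension that yields the
  up/down lists the benchmark requires, and a pathway may then appear in
  both lists.
* **AFC / AFCs** — the pathway score is the mean over member genes of the
  per-gene mean fold change (treatment mean minus control mean of log2
  values). Significance comes from a permutation null: gene-label
  permutation for AFC, sample-label for AFCs.
* **GSEA / GSEAs** — the weighted Kolmogorov–Smirnov running-sum enrichment
  score over genes ranked by their t-statistic (fold-change ordering by
  flag). The running sum gains $|z|^p / \sum_{hits} |z|^p$ at member genes
  and loses $1/(N - N_{hits})$ at non-members; the score is the extreme
  deviation, signed. The weight exponent defaults to $p = 1$ (the original
  GSEA default); $p = 0$ recovers the classical unweighted KS statistic.
* **GSA** — the maxmean statistic: positive and negative parts of the
  member t-statistics are averaged separately over the whole set and the
  larger-magnitude part wins, signed. Its null combines both permutation
  axes by restandardization (below).

### Permutation nulls

One-sided p-values use the add-one estimator
$p_{up} = (\#\{S_b \ge S_{obs}\} + 1)/(B_{eff} + 1)$, which cannot be zero
and keeps ranks well defined; `B` defaults to 1000, giving $10^{-3}$
resolution — adequate for top-50 ranking. Exact ties between a null score
and the observed score are counted with a relative tolerance of $10^{-9}$ so
that the observed assignment, when it reappears among enumerated
assignments, registers as the tie it is regardless of floating-point
evaluation order.

*Gene-label* permutation shuffles which gene carries which statistic (one
shared permutation per replicate, all pathways rescored) and so preserves
the sample structure but destroys gene–gene correlation. *Sample-label*
permutation reassigns cohort labels over samples, preserving co-expression;
per-gene statistics are recomputed for every assignment. When the number of
distinct assignments is at most `B` the null is enumerated exactly rather
than sampled; complementary assignments are identified when the cohorts have
equal size (swapping all labels only flips signs), so a 3-vs-3 dataset has
exactly $\binom{6}{3}/2 = 10$ distinct assignments
(`count_distinct_label_assignments()`). Sample-label methods therefore need
at least 3 samples per cohort in a sub-dataset to have a usable null; the
experiment drivers skip smaller sizes with a warning rather than erroring.

*Restandardization* (GSA) compares
$(S_{obs} - \mu^\dagger_{obs})/\sigma^\dagger_{obs}$ against
$(S_b - \mu^\dagger_b)/\sigma^\dagger_b$ over sample-label assignments $b$,
where $\mu^\dagger, \sigma^\dagger$ are the moments of the maxmean statistic
under gene randomization (random gene sets of the same size) computed from
the corresponding data. The maxmean randomization moments have no convenient
closed form, so they are estimated by Monte-Carlo over `gsa_random_sets`
(default 200) random sets per distinct set size, with one index design drawn
up front and reused for the observed data and every permutation — the shared
design cancels most of the Monte-Carlo noise out of the comparison.

### Ranking and tie-breaks

`rank_top_k()` sorts each direction by ascending p-value, breaking ties by
descending score magnitude and then lexicographic pathway id, so rankings
are deterministic. For signed-score methods a pathway competes only in the
direction matching its score's sign (non-negative scores compete as "up");
for ORA both directions are scored independently. If a direction has no DE
genes, ORA ranks that direction on $p = 1$ through the same tie-break chain.

## The resampling experiments

`run_recall_experiment()` computes $A$ once from the full dataset, then for
each size $n$ draws $M$ stratified sub-datasets (default $n/2$ from each
cohort; proportional allocation by flag, since unbalanced designs admit no
single obvious rule) and records $r$ per direction. Sub-datasets are drawn
independently across replicates — duplicates may occur by chance, which is
what independent resampling means. `run_discrimination_experiment()` does
the same for a dataset pair; the $a_i$ and $a_i'$ draws are unmatched.
`cross_dataset_overlap()` compares the full-data top-$K$ lists of a small
and a large dataset of the same condition, the cross-study analogue of
recall. Every replicate derives its own seed from the master seed and the
(dataset, method, size, replicate) labels (`derive_seed()`), so runs are
reproducible, order-independent, and safely parallelizable.

Whether sub-dataset draws should be shared between the recall and
discrimination experiments is not determined by the procedure itself; here
every experiment draws fresh, seed-controlled replicates.

## The synthetic test bed

`generate_dataset()` draws log2 expression as
$x_{gj} = \mu + \sigma\bigl(\sqrt{\rho}\,u_{s(g)j} + \sqrt{1-\rho}\,
\varepsilon_{gj}\bigr)$: Gaussian baseline with mean $\mu = 7$ and
$\sigma = 1$ by default (typical magnitudes for RMA-normalized arrays), with
genes of one set sharing an equicorrelated component of weight $\rho$. Each
perturbed set adds $\pm\delta$ (up, down, or half-and-half for "mixed") to a
fraction $f$ of its member genes in the treatment samples only; genes in
several perturbed sets accumulate shifts, and a gene in several sets takes
its shared component from the first set containing it. The default
benchmark layout is `block_collection()`: 100 disjoint sets of 20 genes
over 2000 genes, cohorts of 60/60, $\delta = 1$, $\rho \in \{0, 0.3\}$ —
small enough for routine runs, large enough that perturbed sets separate in
rank.

The generator emulates the *structure* that the evaluation strategy needs —
two cohorts, thousands of genes, designated perturbed sets with additive
log-scale shifts, optional co-expression — and deliberately not the noise
anatomy of real microarrays (probe effects, background, batch, heavy tails)
or RNA-seq counts. Equicorrelated noise is the simplest model that
exercises the known weakness of gene-label permutation under co-expression,
which is precisely the GSEA-vs-GSEAs and AFC-vs-AFCs contrast the benchmark
is meant to expose. Passing tests on this generator therefore demonstrate
correctness of the machinery and the qualitative sample-size behaviour of
the metrics, not performance claims about any particular real dataset.

Under $\delta = 0$ the cohorts are exchangeable, which gives an exact
ground truth for calibration: every permutation p-value is marginally
uniform. The test suite and the acceptance script verify this per dataset
with Kolmogorov–Smirnov checks. One caveat: within a single run the
pathway p-values are mutually dependent — they share one permutation stream,
and for GSA also the restandardization moment estimates — so a per-run KS
test across pathways is an approximate diagnostic and can occasionally flag
a (dataset, permutation-stream) fluke even though pooled p-values across
runs are uniform.

## Gene-set handling

GMT collections are size-filtered to 20–400 genes by convention
(`filter_by_size()`), *before* intersecting with the measured genes —
matching how curated collections are usually constructed independently of
any platform. Callers preferring to count only measured genes simply apply
`restrict_to_measured()` first and `filter_by_size()` after; the functions
compose in either order. Gene identity is exact, case-sensitive string
match; no symbol aliasing is attempted. Sets emptied by restriction are
dropped with a warning; the universe of a collection is always exactly the
union of its member sets.

## Numerical choices and degenerate inputs

* Pooled-variance (Student) t by default, Welch by flag. Zero
  within-group variance yields $t = \pm\infty$, $p \approx 0$ (or $t = 0$,
  $p = 1$ when the means also agree), logged.
* Enrichment-score candidates are bounded by 1, so they are rounded at
  $10^{-12}$ before the extreme comparison; exact positive/negative ties
  resolve positive. All-zero hit weights (possible with $p > 0$) fall back
  to equal weighting.
* Stratified allocation requires even $n$; proportional allocation rounds
  but never drops a cohort below 2 samples.
* `run_recall_experiment()` with $M = 0$ returns an empty result; $K$
  larger than the collection returns all pathways with a warning.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run entirely on the synthetic
test bed at sizes chosen to make every check sharp but routine: calibration
uses 20 unperturbed 2000-gene, 60/60 datasets with $B = 200$; the
recall-versus-$n$ experiment uses the fixture design ($\delta = 1$, two
perturbed sets) with $M = 100$ replicates at $n \in \{6, 12, 24, 48\}$ and
$B = 1000$; discrimination uses disjointly perturbed pairs ($\delta = 2$,
two sets up and two down per condition) with $M = 50$ at $n = 24$. The
random-stub sanity check (expected recall $K/P$) uses $10^4$ draws.

## Known limitations

* Covariate-aware stratification beyond the cohort label is not
  implemented; with many replicates the sub-datasets mirror the parent's
  covariate distribution on average, but rare covariates at small $n$ are
  not protected.
* Recall and discrimination are reported descriptively; the package does
  not test the significance of differences between methods' metric
  distributions.
* No multiple-testing correction is applied — by design, the benchmark
  fixes list length instead of a significance threshold.
* Topology-aware PA methods and RNA-seq count models are out of scope.
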