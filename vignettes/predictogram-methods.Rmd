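---
title: "Predicted association networks and their dark matter: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicted association networks and their dark matter: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predictogram)
```

## The problem

Experimental screens of protein functional associations are biased and
incomplete: membrane proteins, transient regulatory contacts and whole
organisms' worth of pairs are systematically under-sampled. Computational
predictors cover that space differently, so a network built purely from
integrated predictions (a *Predictogram*, PG) and a network built from
experimental evidence resources (a *Knowledgegram*, KG) are complementary
screens of the same underlying interactome. This package implements the full
comparison pipeline: score normalization, meta-statistical integration,
benchmarking against gold standards, network construction and randomization,
topology diagnostics, dark-matter quantification with dark-hub ranking,
functional enrichment of ranked lists, and second-order (shared-neighbor)
prediction — plus a synthetic-world generator so all of it runs, and is
tested, without external downloads.

## Score model and normalization

Each prediction method emits a raw score per unordered protein pair, with
higher score meaning stronger prediction (a loader flag negates inverted
conventions). The working assumption is a Gaussian null for the bulk of each
method's scores, with method-specific mean and spread. `fit_null()`
estimates the null robustly — median for location, MAD for scale — so that a
genuine signal tail does not inflate the fitted null; an empirical-ECDF
fallback is available per method for score distributions the Gaussian cannot
describe. `score_to_pvalue()` takes the right tail,
$p = 1-\Phi\!\left((s-\mu)/\sigma\right)$, floored at $1/(n_{\mathrm{fit}}+1)$
so that $-\ln p$ is always finite; `gaussian_adequacy_test()` is the
right-tailed Z-test of a score sample against the fitted null (default
$\alpha = 0.05$). Under the null the emitted p-values are uniform, a property
the test suite checks by Kolmogorov–Smirnov at $n = 10^4$.

## Integration

Two untrained integrators are implemented. *Simple* integration takes the
most significant per-method p-value. The *weighted Fisher* score is

$$S = \sum_i w_i \,(-\ln p_i),$$

with a method absent on a pair contributing 0 (equivalent to $p_i = 1$);
that convention keeps $S$ monotone in accumulating evidence under partial
coverage. Combined scores are renormalized to p-values on their own
empirical distribution (right tail, same floor); those integrated p-values
are the PG edge weights.

### Weight search

The weights maximize an **unsupervised** signal-concentration objective, so
that the integrator never touches the experimental data used later for
comparison. For candidate weights $w$, each pair's combined score is compared
against its analytic null: under uniform p-values, $-\ln p_i \sim
\mathrm{Exp}(1)$, so $S$ is a weighted sum of exponentials restricted to the
methods present on the pair. Pairs sharing a presence pattern share a null,
so only one tail quantile per pattern and significance level is needed; the
quantile comes from a Lugannani–Rice saddlepoint inversion (`qwexp_tail()`),
exact for single-method and equal-weight patterns and accurate to a few
percent relative error deep in the tail. The tail accuracy matters: a
moment-matched gamma, the obvious shortcut, carries roughly twice the nominal
mass at the $10^{-3}$ threshold for markedly unequal weights, and that bias
manufactures spurious "discoveries" precisely at degenerate weight vectors,
derailing the search. The objective is the excess of significant pairs over
the null expectation, expressed as binomial z-scores and averaged over the
confidence ladder $\alpha \in \{10^{-2}, 10^{-3}, 10^{-4}\}$ — "power" is
discoveries, "confidence" is the ladder. An alternative
divergence-from-uniform objective (Anderson–Darling on the integrated
p-values) was evaluated and rejected: it rewards degenerate corner weights,
because one method's extremes look maximally non-uniform against a
single-method null, whereas the excess-discovery objective correctly prefers
near-uniform weights for identically informative methods and concentrates
weight on the informative method when only one carries signal.

The search itself is simulated annealing on the weight simplex: five
stratified Monte-Carlo proposals per temperature step (each perturbing one
coordinate in rotation by a multiplicative log-normal kick), geometric
cooling ($T \leftarrow 0.95\,T$, 200 steps), Metropolis acceptance, three
restarts (uniform start plus two random simplex points), and a final greedy
coordinate polish of the best accepted weights. The search is deterministic
for a fixed seed, and `n_steps = 0` returns the uniform weights.

### Method dependence

`mutual_information()` quantifies statistical dependence between two
methods' p-value vectors over shared pairs, after rank-based equal-frequency
binning (10 bins by default, so a dataset against itself scores
$\log_2 10 \approx 3.32$ bits and any monotone transform leaves the value
unchanged). The same measure motivates collapsing dependent evidence
resources into one dependency group on the KG side.

## Benchmarking with random-model false positives

True negatives cannot be enumerated for an interactome, so false positives
are estimated by chance: at each ranking threshold, TP counts predictions in
the gold-standard pair set, and FP is the mean hit count of `n_random`
(default 1000) freshly drawn pair sets of the same size as the gold standard,
uniform over the node universe with self-pairs excluded. Because the random
sets are size-matched, precision $TP/(TP+\overline{FP})$ tends to 0.5 for a
no-signal ranking, and 0.9 means nine true hits for every chance hit. Recall
is the cumulative predicted hit count (false-negative rates are deliberately
not estimated). Degree-preserving resampling of the gold set is available as
an alternative null, but the uniform reading is the default since it is the
one under which the 50% limit argument holds exactly. Curve points whose FP
standard deviation exceeds one third of the mean FP can be dropped
(`filter_unstable()`; the boundary value is kept) — with few scored pairs the
FP counts are Poisson-small and the filter may legitimately remove every
point, which is why validation functions expose the filter as an option.

`prediction_power()` is the trapezoidal area under precision-vs-recall,
anchored at recall 0 and normalized by maximum recall. When ranking methods
against each other the power must be computed over a **common recall
window** (the `max_recall` argument; the test suite uses the smallest
method's total hit count): normalizing each curve by its own maximum
systematically favours short, pure lists over longer rankings that dominate
at every shared depth, and under that bias no integration method could ever
"win" even while being strictly better at each fixed list size.

## Networks and randomization

A network is a tibble of canonical edges (lexicographically smaller protein
first; self-pairs forbidden) with a kind, a defining cutoff and the node set
(edge endpoints — isolated proteins are not nodes). `build_pg()` cuts
integrated predictions at a p-value; `build_kg()` counts, per edge, the
number of distinct *dependency groups* reporting it — resources in one group
(for instance two ontology-derived semantic-similarity sets) contribute at
most one evidence — and cuts at a minimum count.

Two nulls mirror the two things a weighted network asserts: the *weights
random model* permutes edge weights on the fixed topology (weight multiset
and all topology metrics preserved exactly), and the *adjacency random
model* redraws both endpoints of every edge uniformly over the node set,
removing any self-pairs produced and collapsing duplicates (first-drawn
weight kept), so the realized edge count can drop slightly. For intersection
baselines the randomization is applied to the **full** weighted matrices
(all scored pairs, all evidence pairs) and the PG/KG cutoffs are re-applied
before intersecting — under weight shuffling the cut edge set changes even
though the full topology does not, which is the only reading under which a
weight-shuffled baseline differs from the real overlap.

## Topology diagnostics

Degree histograms, local and average clustering ($C_i = 2e_i/k_i(k_i-1)$,
zero below degree 2), the $C(k)$ profile (flat = non-hierarchical),
degree assortativity (Pearson correlation over edge-endpoint degree pairs,
both orientations), and BFS distance metrics (characteristic path length,
eccentricities, radius, diameter — all on the largest component, the
convention extended from radius/diameter to the path length as well) are
computed via igraph with brute-force oracle tests on small graphs.

`fit_power_law()` follows the field's descriptive convention: least-squares
regression of $\log_{10}$ frequency on $\log_{10} k$ over non-empty degree
classes, reporting the slope magnitude as the exponent $\gamma$ and the
Pearson correlation of the fit (maximum-likelihood fitting is deliberately
not the default, to match how such exponents are conventionally reported in
this literature). `gaussian_degree_test()` classifies a histogram as
heavy-tailed, gaussian-like or ambiguous by comparing that power-law
regression against a Gaussian-type bell (quadratic in $k$ on the log-count
scale); both fits weight degree classes by node count, because unweighted
residuals are dominated by singleton tail classes and cannot separate a
preferential-attachment histogram from a Poisson one (the weighted versions
separate them by two orders of magnitude). The decision margin is a factor
of 2 in degrees-of-freedom-adjusted weighted RSS; near-ties, and the
degenerate case where both models fit perfectly (for example a flat
histogram), are "ambiguous".

## Dark matter, dark hubs, enrichment

`network_intersection()` reports shared edges and their endpoints, the
intersection density (edges/nodes), and `%PGe` — the percentage of PG edges
backed by the KG. `intersect_with_baselines()` adds per-null baseline means
and standard deviations over (by default) 1000 randomization iterations and
the enrichment ratio real-`%PGe` / baseline-`%PGe` (reported infinite when
the baseline is 0). `dark_node_fraction()` is the percentage of PG nodes
with zero KG degree.

Dark hubs are ranked by the degree-enrichment ratio

$$\mathrm{PGki\_er} = \frac{\mathrm{PGki} - \mathrm{KGki}}{\mathrm{KGki} + 1},$$

with KG degree 0 for proteins absent from the KG and ties broken by protein
identifier for a deterministic ranking. `ranked_enrichment()` tests ontology
terms (annotations propagated to ancestors) for concentration at the top of
a ranked protein list: at a fixed cutoff `n` it reports the hypergeometric
tail $P(X \ge b)$ and $E = (b/n)/(B/N)$ exactly; with a flexible cutoff it
scans every prefix ending at an annotated protein and reports the minimum
tail probability with its optimal `n`. The flexible mode is a simplified
minimum-hypergeometric screen — it does not apply the exact multiple-cutoff
correction of the full mHG statistic, so its p-values are optimistic and
are meant for ranking and screening at stringent thresholds (default
$10^{-9}$), not for calibrated inference.

## Second-order prediction

For a pair of proteins, $b_1$ is the number of shared neighbors and $b_2$
the size of the symmetric difference of the two neighbor sets (each set
excluding the other protein of the pair). Scores: *bits* $= b_1$;
*specific bits* $= b_1 \cdot (-\log(b_1/(b_1+b_2)))$ (natural log by
default; the base is configurable and only the ranking matters downstream;
0 when $b_1 = 0$ by convention, 0 when $b_2 = 0$ since $\log 1 = 0$);
*congruence* $= -\log_{10}$ of the hypergeometric probability of sharing at
least $b_1$ neighbors given the two degrees and the network size. Candidate
pairs share at least a third of their combined neighborhood
($b_1/(b_1+b_2) \ge 1/3$, boundary included; the alternative reading
$b_1 \ge \min(k_1,k_2)/3$ sits behind `share_rule = "min_degree"`).
Because second-order predictions are *additional* pairs, network-adjacent
pairs are excluded from scoring by default (a flag restores them).
Validation maps the ranked scored pairs onto KG gold standards (pairs in at
least two independent evidence groups by default) through the same
random-model precision/recall machinery.

## The synthetic world

The generator plants the conditions the statistics assume:

- **Truth**: preferential attachment (fractional mean degree via per-node
  attachment counts; asymptotic exponent 3 in the linear-kernel regime, with
  log-log regression estimates near 2–2.4 at desk scale) with optional
  *triadic closure* — per attachment edge, probability `clustering_strength`
  of adding one triangle-closing chord — and optionally planted *protein
  complexes* (near-cliques of Poisson-distributed size over disjoint protein
  sets). Real interactomes are both heavy-tailed and highly clustered; plain
  preferential attachment has vanishing clustering, and without planted
  clustering a dense noise network would out-cluster the truth and invert the
  clustering-vs-reliability contrast. Pipeline worlds use
  `clustering_strength = 0.3` (average clustering ≈ 0.14 at 600 proteins);
  complexes push clustering to ≈ 0.37, at the cost of genuinely degrading
  log-log degree linearity (the complex sizes add mid-degree mass), which is
  why the topology checks plant the clustering claim and the degree-tail
  claim in separate worlds; an Erdős–Rényi control is available.
- **Predictors**: each scores a uniform fraction (`coverage`) of all pairs;
  non-true pairs draw from $\mathcal N(\mu_0, \sigma_0)$ and covered true
  pairs from $\mathcal N(\mu_0 + \delta, \sigma_0)$. The default panel
  (coverage 0.4–0.7, shifts 1.2 and 1.5 SD on two informative methods, two
  pure-noise methods) emulates proteome-wide runs with graded,
  individually-weak signal: every covered true pair carries some signal and
  inability to assess a pair is expressed through coverage. This is the
  regime in which summing weak concordant evidence (weighted Fisher) can
  genuinely beat taking the best single vote (simple integration); with
  sparse strong detections instead, minimum-p is optimal by construction and
  no integration gain exists to measure.
- **Evidence resources**: each reports a fraction of true edges plus a count
  of spurious pairs; resources sharing a `dependency_group` sample from a
  common pre-draw, which elevates their mutual information and exercises the
  KG's group-collapsing rule.
- **Ontology**: a rooted $b$-ary tree with uniform per-protein annotations;
  with probability `bias` a true edge co-annotates both endpoints with one
  shared non-root term, so true pairs acquire Resnik-similarity signal
  (their most informative common ancestor is at least the shared term).

What the generator does **not** emulate: proteome-scale pair counts (~10⁷
– 10⁸ pairs), method-specific score distributions, annotation evidence-code
structure, correlated predictor errors, or degree-dependent experimental
ascertainment bias. Passing tests therefore demonstrate that the statistics
behave as designed under their own assumptions — uniform nulls, planted
signal, independent noise — not that any particular biological dataset will
show the same effect sizes.

## Numerical choices and degenerate inputs

- p-value floors at $1/(n+1)$ everywhere a zero would break $-\ln p$.
- MAD of a >50%-tied score sample is 0; the fit falls back to the standard
  deviation rather than failing. All-identical scores are an error.
- Equal-frequency MI binning uses rank order; ties are split by first
  occurrence.
- Threshold grids for precision/recall evaluate every distinct value up to
  10⁴ points, then thin to uniform quantiles.
- Duplicate pairs with conflicting weights are a load-time error naming the
  lines; identical duplicates collapse silently; self-pairs are dropped with
  a warning and count.
- Randomization-produced duplicate edges collapse keeping the first-drawn
  weight; the realized edge count is recorded rather than re-drawn.
- Assortativity of a constant-degree graph is `NA`, not an error.
- Test and vignette problem sizes (300–1000 proteins, 4 predictors, 6
  resources, 20–1000 randomization iterations depending on the statistic)
  were chosen as the smallest worlds at which the distributional claims are
  stable across seeds.
- Average clustering of a cutoff network is U-shaped in the cutoff: a dense
  random graph has clustering equal to its edge density, so the
  clustering-rises-with-reliability contrast is only observable on cutoff
  grids whose loosest network is sparser than the truth is clustered. The
  packaged topology checks choose their grids accordingly.

## Known limitations

- The integrated p-value is normalized on the pooled combined-score
  distribution, not conditioned on the per-pair method-presence pattern, so
  pairs scored by many methods have a systematic score advantage over pairs
  scored by few; both integrators share this convention, which follows the
  pooled-renormalization approach described for the original method.
- The saddlepoint tail of the weighted-Fisher null is an approximation
  (a few percent relative error); the weight-search objective stops its
  confidence ladder at $10^{-4}$, below which desk-scale excess counts are
  too sparse to be informative anyway.
- The flexible-cutoff enrichment p-value is uncorrected (see above).
- Congruence is quadratic in network size through the candidate matrix and
  is intended for networks up to a few thousand nodes.
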