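---
title: "Group-specific differential interaction networks with diffnetx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-specific differential interaction networks with diffnetx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffnetx)
```

## The problem

Differential co-expression analysis asks a different question than
differential expression: not *which molecules change in abundance between
conditions*, but *which interactions between molecules change in strength*.
A pair of entities (two transcripts, a kinase and its substrate, a receptor
and its ligand) may be tightly coupled in one patient group and decoupled
in another even when neither entity's mean level moves much. diffnetx
extracts such group-specific differential interaction networks from one or
more pre-normalized omic layers, restricting attention to pairs with prior
literature support supplied as a reference network, so that every reported
edge is both statistically supported and biologically interpretable.

The method operates on each omic layer independently and in three steps,
then stacks the per-layer results:

1. **Node activation.** For every feature $v$ and group $k$, compute the
   summary expression $x_{v,k}$ (the median by default) over the group's
   samples. A feature is *active* in $k$ when $x_{v,k} \ge \tau$, with the
   inclusive step function $f_{v,k}(x) = \mathbf 1[x \ge \tau]$. Groups are
   thresholded independently, so each acquires its own subnetwork of the
   reference graph.
2. **Common-edge removal.** Edges whose both endpoints are active in
   *every* group carry no group-specific activation signal and are removed
   from all groups' candidate sets; an edge missing from even one group is
   retained wherever it is present.
3. **Edge activation.** Every remaining candidate edge $(u, v)$ is tested
   with an interaction-term regression on **all** samples,
   $$u = \beta_0 + \beta_1 v + \beta_2 k + \beta_3 (v \odot k) +
   \varepsilon,$$
   where $k \in \{0,1\}^n$ encodes group membership. $\beta_3$ is the
   change in the $u$–$v$ coupling slope between groups; its two-sided
   p-value, corrected within the (layer, group) family, decides whether the
   edge enters the differential set at the user's $\alpha_{adj}$
   (Bonferroni at 0.05 by default).

With three or more groups the same model structure is assessed with an
ANCOVA homogeneity-of-slopes F-test (group-specific slopes against a common
slope, $F_{K-1,\,n-2K}$); with two groups that F-test reduces to the square
of the t statistic, and the implementation delegates accordingly.

## Adaptive thresholding by percolation scan

The activation threshold $\tau$ controls a trade-off. Lowering it admits
more nodes and therefore more candidate edges — but every extra candidate
tightens the multiple-testing correction applied to its family. Raising it
prunes noise but eventually fragments the network. `percolation_scan()`
sweeps $\tau$ over quantiles of the pooled per-(feature, group) summary
distribution and, at each grid point, runs the complete downstream pipeline
and counts the edges that survive correction. The selected threshold is

$$\tau^\ast = \arg\max_\tau \lvert E_{sig}(\tau) \rvert,$$

the point where additional biological signal outweighs the statistical
penalty. Ties are broken toward the **higher** quantile — the stricter,
sparser network — because the low-threshold side of a tie sits closer to
the over-connected "hairball" regime in which spurious connections
dominate. For the same reason quantiles below 0.35 are refused outright
under the default floor rather than silently clamped; users who insist can
lower `floor_quantile` explicitly.

Numerical conventions fixed here: the quantile estimator is type-7 linear
interpolation between order statistics; the quantile reference distribution
pools the per-group summaries of one layer (one $\tau$ per layer, so it is
comparable across groups); the default grid is 0.35 to 0.95 in steps of
0.05. The per-edge fits do not depend on $\tau$ (only candidacy does), so
the scan memoizes each edge's regression and costs little more than a
single pass.

The summary statistic is the **median** by default — it is the natural
choice next to a robust edge regression — with `statistic = "mean"`
exposed as an alternative, since either convention is defensible and the
two can disagree on skewed layers.

`permutation_threshold_test()` provides the robustness companion: it
re-runs the scan with group labels permuted (50 iterations by default) and
reports, per quantile, where the observed significant-edge count sits in
the permutation null — a peak that survives this comparison is not an
artifact of the threshold choice.

## Edge statistics

* **OLS** (`fit_interaction_ols`): my own QR least-squares path (the same
  algebra as `summary.lm`), two-sided t-test on $\beta_3$ with $n-4$
  residual degrees of freedom.
* **Robust** (`fit_interaction_robust`): Huber M-estimation via
  `MASS::rlm` (tuning constant 1.345, MAD scale, IRLS tolerance $10^{-8}$,
  at most 50 iterations). Classical `rlm` summaries emit no p-values; the
  package reports the standard Wald reconstruction $t = \hat\beta_3 /
  \mathrm{se}(\hat\beta_3)$ against $t_{n-4}$. Non-convergence flags the
  edge untestable rather than producing a doubtful number.
* **ANCOVA** (`fit_interaction_ancova`): nested-model F comparing
  group-specific against common slopes for $K \ge 3$.

Orientation matters: the p-value of "regress $u$ on $v$" is not identical
to "regress $v$ on $u$". For a directed reference edge
source $\to$ target, the target is the response; for undirected edges the
lexicographically larger identifier is the response. The convention is
arbitrary but deterministic, and direction never influences which edges
are tested — it is literature-derived orientation metadata only.

Degenerate designs (a group below 3 samples, a covariate constant within a
group, fewer than 6 complete observations, an essentially perfect fit) are
flagged untestable with a recorded reason and excluded **before**
correction, so the family size $m$ counts testable edges only. Missing
values are removed pairwise per edge; the package never imputes.

Corrections: Bonferroni (default), Holm, Benjamini–Hochberg, and Storey's
q-values with the fixed-$\lambda = 0.5$ estimator
$\hat\pi_0 = \min\{1, \max(\overline{\mathbf 1[p > 0.5]}/0.5,\ 1/m)\}$;
the $1/m$ floor keeps the single-test case equal to the raw p-value.
Note that Storey q-values with $\hat\pi_0 < 1$ may legitimately fall below
the raw p-value; the monotonicity guarantee $p_{adj} \ge p$ holds for the
other methods.

## Multi-omic assembly

Layers are processed on their own samples — no cross-omic sample matching,
no shared normalization — and stacked only at the end
(`integrate_layers()`). Cross-layer identifier correspondences (e.g. gene
symbol to protein accession) become a distinct *correspondence* link class
rather than merged nodes, because each layer's statistics derive from
different samples and must stay attributable. Exports: a flat TSV edge
table, versioned JSON (round-trippable with `import_network_json()`), and
GraphML with a $-\log_{10} p_{adj}$ thickness attribute capped at 10 to
keep underflowing p-values finite. `validate_graphml()` checks the
GraphML structurally (namespace, declared keys, endpoint integrity);
full XSD validation is not performed because the schema documents live
online and the package works offline.

`bootstrap_stability()` quantifies edge reproducibility: samples are
resampled with replacement *within* groups (preserving group sizes — the
conservative choice), the entire pipeline including threshold selection is
re-run, and each edge's selection frequency over resamples is reported.

## Feature engineering for prediction

`fit_filter()` / `transform_features()` wrap the pipeline as a supervised
fit/transform pair. The fit runs the full analysis on training data only
and freezes the learned threshold and the ranked differential edges
(ascending adjusted p, ties broken by larger absolute statistic) in a
serializable model object. The transform emits, for each admitted edge,
one **ratio feature** `A:B` $= A/B$ — the numerator is the edge
regression's response entity — plus, when `keep_single = TRUE`, the
individual endpoint features. Ratios are plain quotients of the supplied
(already log-scale) values; a zero denominator yields a flagged missing
value, never an infinity.

Because the internal percolation scan fixes how many edges are
significant, the filter sizes itself; `max_features` is only a cap.
Singles and ratios count **jointly** toward the cap and edges are admitted
greedily in rank order until the budget would be exceeded. The transform's
output schema and each row's values depend only on the model and that row,
which is exactly the property that makes the pair leakage-safe inside
nested cross-validation: `nested_cv_demo()` fits the filter per outer
training fold, tunes an elastic-net logistic classifier by inner
cross-validation, and evaluates on the untouched outer test fold, pooling
test predictions within each repeat into one AUC (per-fold AUC on a
handful of samples is too noisy to average meaningfully).

## What the synthetic generators emulate — and what they do not

`simulate_edge()` draws $v \sim N(0,1)$, balanced groups, and
$u$ from the interaction model with chosen $(\beta_0,\beta_1,\beta_2,
\beta_3)$ and noise SD; `inject_outliers()` shifts a fixed fraction of
responses by $\pm 5$ noise-SD units. `simulate_study()` builds a full
layer on a log2-like abundance scale (2–12): planted differential edges
couple a shifted, slope-changing response (response band 8–8.6, covariate
band 10–12, $\beta_2 = 2$, $\beta_3 = 1$, SD 0.5 as the strong-signal
default) so that one activation threshold between the bands captures every
planted edge in the second group; null edges come as group-shifted pairs
with unchanged slopes (they enter the tested family and probe
specificity), always-active pairs (removed as common edges), and
low-abundance pairs (excluded by the floor).

These generators reproduce the *mechanisms* the method exploits —
activation contrasts, slope changes, correction pressure, contamination —
but not the full texture of real omic data: no correlated gene modules
beyond the planted pairs, no batch structure, no heteroscedasticity, no
missingness mechanism, Gaussian noise throughout. Passing tests therefore
demonstrate correctness of the machinery and realistic operating
characteristics under the stated conditions, not performance guarantees on
any particular cohort.

## Benchmark protocol

`run_benchmark()` evaluates detection over the factorial grid noise SD
$\in \{0.5, 0.8, 1.2\}$ × outlier fraction $\in \{0.10, 0.20, 0.30\}$ ×
$\beta_3 \in \{0.5, 0.75, 1.0\}$. Per condition and replicate it simulates
one edge family — **2 true + 8 null edges, 500 samples per group** —
applies one family-wise Bonferroni correction at $\alpha_{adj} = 0.05$,
and accumulates TP/FN/TN/FP with Clopper–Pearson intervals.

The family size and sample size were fixed once by a power analysis of the
regimes the method is expected to exhibit: near-ceiling sensitivity for
$\beta_3 \ge 0.75$ at low noise, high but sub-ceiling sensitivity for
strong signals under heavy contamination with the robust fit, partial
power (on the order of 60%) for $\beta_3 = 0.5$ at high noise and 30%
outliers, and specificity above 99% everywhere that Bonferroni control
implies ($1 - \alpha/m = 0.995$ per null edge at $m = 10$). Smaller
families (heavier per-edge correction) or smaller samples push the
weak-signal regime toward zero power; much larger ones push it toward
ceiling. All knobs (`n_per_group`, `n_true_edges`, `n_null_edges`,
`outlier_magnitude`, `replicates`) are exposed as ordinary configuration.

`scripts/acceptance.R` re-runs this benchmark end to end (300 replicate
families per cell for the full-grid specificity figure, 500 for the three
sensitivity figures) and writes the four headline numbers as JSON; the
test suite exercises the same regimes at 200–250 replicates per cell.

## Known limitations

* Two-group layers use the t-based paths; the ANCOVA path covers
  $K \ge 3$ but reports no single $\beta_3$ (there are $K-1$ interaction
  contrasts).
* An edge can only be detected if its *activation* differs between groups
  (step 2 removes universally active edges); a pair whose coupling flips
  while both endpoints stay highly expressed in all groups is invisible by
  design. This mirrors the method's focus on group-specific subnetworks.
* The tie-break toward higher quantiles can, in rare resamples, trade a
  true edge at a permissive threshold for a false positive at a stricter
  one; `bootstrap_stability()` makes such fragility visible.
* Storey's method uses a single fixed $\lambda$; no spline smoothing.
* The nested-CV demonstration uses one classifier (elastic-net logistic
  regression); it demonstrates leakage-freedom and calibration, not a
  model comparison.
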