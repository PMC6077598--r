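---
title: "Methods: network pharmacology of multi-herb formulas with netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network pharmacology of multi-herb formulas with netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

`netpharm` chains five analysis stages that together turn raw herbal
compound tables into network-level and cohort-level statements about a
formula's mechanism. This vignette explains each stage's model, its
assumptions, the tunable parameters, and the design choices made where the
field's conventions leave room.

## ADME screening

A compound enters the active set when its oral bioavailability (OB, the
percentage of an oral dose reaching systemic circulation unchanged) and its
drug-likeness (DL) both clear a threshold. DL is the Tanimoto index of the
compound's molecular-descriptor vector $A$ against a reference vector $B$
(conventionally the average descriptor vector of a large drug catalogue):

$$f(A,B) = \frac{A\cdot B}{\lVert A\rVert^2 + \lVert B\rVert^2 - A\cdot B}.$$

For nonnegative vectors the index lies in $[0,1]$ and equals 1 only for
identical nonzero vectors. Defaults are `ob_min = 30` (percent) and
`dl_min = 0.18` (unitless), the standard screening values for herbal
formulas; **both comparisons are inclusive** (a compound at exactly 30 /
0.18 is retained), which matches the usual "at least" phrasing of these
cutoffs. DL is normally supplied; when a descriptor column and a reference
vector are given instead, DL is recomputed with the formula above, and a
supplied value wins over a disagreeing recomputation (warning at
$|\Delta| > 10^{-6}$), since published tables are usually the authority.
Compound identity is the (name, herb) pair after trimming and
case-folding: the same sterol listed under two herbs is deliberately two
records.

## Network construction

Compound–target predictions carry an SVM-style confidence score; records
with score **strictly** greater than `score_min = 0.7` survive. Note the
asymmetry with the ADME screen: score filtering is conventionally written
as "> 0.7", so the boundary record at exactly 0.7 is dropped. Surviving
associations form a simple bipartite graph (duplicate associations
collapse; predictions referencing unknown compounds are skipped with a
warning rather than failing, to support partial reruns). Intersecting with
a disease-target list keeps matching targets and prunes compounds left
without edges. Gene symbols are always matched after upper-casing. PPI
edges are consumed as an undirected, untyped edge list (SIF or two-column
TSV); self-loops and duplicate edges are dropped with logged counts.
Whether to pre-filter PPI edges by confidence is left to the user (an
up-stream decision, not a default), since exported interaction lists often
arrive already filtered.

## Topology and hub screening

`topology_report()` computes the NetworkAnalyzer-style suite. Conventions
that required a decision:

* **Closeness** is component-restricted: for node $v$,
  (number of reachable nodes) / (sum of distances to them) — not harmonic
  closeness. On connected graphs this is the familiar
  $(n-1)/\sum_u d(v,u)$.
* **Betweenness** is normalized by $(n-1)(n-2)/2$.
* **Shortest-path count** and **characteristic path length** are over
  *ordered* pairs at finite distance: a connected 98-node graph yields
  $98 \times 97 = 9506$ paths, which is how the standard reports count.
* **Clustering coefficient** is the unweighted mean of local clustering
  coefficients with degree-&lt;2 nodes contributing 0 and included in the
  mean. Published summary tables cannot adjudicate this convention without
  the underlying edge list; this choice matches NetworkAnalyzer's.
* **Centralization** uses Freeman's ratio form
  $\frac{n}{n-2}\left(\frac{d_{max}}{n-1} - \text{density}\right)$; the
  test-suite asserts it equals the sum form
  $\sum_i (d_{max}-d_i)/((n-1)(n-2))$ on every test graph.
* **Heterogeneity** is the coefficient of variation of degree
  (population variance), zero exactly for regular graphs.

Hubs are nodes with degree at least `hub_multiplier = 2` times the mean
degree, **inclusive**. On the curated 98-node example the threshold
($2 \times 20.959 = 41.918$) is non-integral, so inclusive vs. strict
cannot disagree there; inclusive is the documented general rule. Ranking
ties (equal centrality) break by ascending node name so that top-$k$
tables are reproducible across platforms.

## Over-representation analysis

For a query of size $n$ inside a reference universe of size $N$, a
category with $C$ reference genes and overlap $O$ receives

$$E = \frac{nC}{N}, \qquad R = \frac{O}{E}, \qquad
\text{rawP} = P(X \ge O), \; X \sim \mathrm{Hypergeom}(N, C, n),$$

with the upper tail inclusive and computed by `phyper` in log-space.
$R$ is reported at full precision (human-readable rounding is left to the
caller; rounded expected counts in published tables make back-computed
ratios disagree in the second decimal, which is why the package never
rounds internally). Benjamini–Hochberg adjustment runs over $m$ = the
number of *tested* categories in the collection — not the number of rows
ultimately reported; published adjusted p-values are only consistent with
this convention (a reported 10-row table with adjP/rawP ratios near 300
implies a collection of roughly that many categories). The default
reference universe is the union of all category genes; a larger curated
universe can be supplied and is recommended when available, since $N$
directly scales $E$ and hence $R$. Top-pathway selection is strict:
adjP &lt; `adjp_max = 0.01`, then truncation to `top_k = 10`.

## Cancer-genomics mining

The alteration matrix records events of four types (amplification, deep
deletion, missense, truncating). A sample counts as *altered* when it has
at least one event of any type in any query gene. OncoPrint ordering sorts
genes by descending alteration frequency and samples by the memo-sort
rule: each sample's altered/unaltered profile over the ordered genes is a
binary string sorted descending, with ties keeping declared order —
deterministic by construction. Mutual exclusivity between two genes is the
two-sided Fisher exact test on the 2×2 altered/unaltered table (the
approach documented by the major portals), with a Haldane $+0.5$ correction
applied to the log2 odds ratio only when a cell is zero; the direction
label (co-occurrence / exclusivity / none) is assigned only at p &lt; 0.05.
When one display glyph per cell is needed, type precedence is
amplification &gt; deep deletion &gt; truncating &gt; missense; the data
keep all types.

Survival uses the Kaplan–Meier product-limit estimator and the two-group
log-rank test (chi-square with 1 df, no continuity correction), both via
the `survival` package; the test suite checks them against hand-computed
product-limit and $O-E/V$ tabulations. Samples lacking survival records
are excluded with a logged count; an empty partition (e.g. every sample
altered) downgrades to a single-curve output with a warning instead of an
error.

## What the synthetic generators emulate — and what they do not

All generators derive independent substreams from one root seed, so
regenerating one input never perturbs another, and every output is a pure
function of the configuration. Defaults mirror the scale of a four-herb
formula study:

* **Compound library**: per-herb counts (48/143/140/98), OB log-normal
  (meanlog $\log 27$, sdlog 0.45 — right-skewed, most mass between 15 and
  60 %), DL Beta(1.3, 4.5). Roughly a fifth of the library passes the
  (30, 0.18) screen, matching the attrition seen in curated tables.
* **Target map**: target degrees follow a discrete power law (exponent
  2.3, lower cutoff 4), giving the heavy-tailed hub structure of real
  target catalogues; scores are uniform on $[0,1]$, so the strict 0.7
  filter keeps ~30 %.
* **PPI**: a uniform draw among simple graphs with exactly the requested
  node/edge counts (98 / 1027 by default), rejected until connected. This
  matches the published summary *scale* but deliberately not its degree
  *shape*: a uniform random graph's degrees concentrate near the mean, so
  the twice-mean hub rule correctly returns an empty hub list on it. Tests
  of hub screening therefore use curated degree tables or star-like
  constructions; the synthetic PPI exercises the topology bookkeeping, not
  hub biology.
* **Gene sets**: 300 categories of size 50–200 in a 2000-gene universe;
  the query is drawn with sampling weight `planted_enrichment_fold` on one
  category's genes (fold 1 = exact hypergeometric null).
* **Cohort**: per-gene Bernoulli alterations (rate 0.13: across a 7-gene
  query about 60 % of samples are altered, as in real prostate-cohort
  queries), with pairwise dependence induced by a shared per-sample latent
  state solved numerically from `planted_log_odds`; survival is
  exponential with `baseline_hazard` 0.02 / month, multiplied by
  `hazard_ratio` for altered samples, under independent exponential
  censoring (0.01 / month).

Passing tests on these inputs show the *statistics* are correct and
calibrated; they do not show that real compound libraries, interactomes or
cohorts satisfy the generators' independence and distributional
assumptions (real PPIs are scale-free and clustered; real alteration
matrices have subtype structure; real survival has non-exponential
hazards).

## Calibration, numerical choices, problem sizes

* The hypergeometric test is discrete, hence conservative: under the null
  the attainable rejection rate at nominal 0.05 sits slightly below 0.05
  (≈ 0.035–0.045 at the default category sizes). The calibration tests
  accept 0.025–0.075.
* The log-rank type-I rate at the default cohort scale is ≈ 0.056 (mild,
  well-known anti-conservativeness at moderate event counts); the same
  band applies.
* Test problem sizes were chosen to keep the full suite around half a
  minute while leaving the Monte-Carlo bands comfortably away from their
  thresholds: exhaustive hypergeometric checks to $N \le 25$, Fisher
  enumeration to table totals of 40, brute-force centrality oracles on
  graphs of ≤ 12 nodes, 60–100 enrichment replicates and 400 log-rank
  null replicates.
* Reports are fully deterministic for fixed inputs — provenance records a
  config hash and software versions, deliberately no wall-clock timestamp,
  so that re-running a pipeline re-creates byte-identical exports.
* Degenerate inputs fail loudly and specifically: topology needs ≥ 2
  nodes, both Tanimoto vectors zero is undefined, an empty query after
  universe mapping is an error, while empty *optional* stages (no survival
  file, no alterations) skip with a message.

## Known limitations

Upstream predictions (bioavailability models, target-prediction SVMs,
descriptor computation) are out of scope: their outputs are consumed as
inputs. Published cohort-level claims (alteration percentages, survival
p-values of specific studies) depend on external clinical datasets and are
not recomputable here; the package instead demonstrates calibration and
power of the same estimators on cohorts with known ground truth. Pairwise
mutual exclusivity is the only exclusivity analysis implemented; set-level
combined statistics exist in the literature but are not uniquely defined
by the portals' outputs.
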