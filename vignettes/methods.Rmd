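---
title: "Models and design choices in megasignet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in megasignet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megasignet)
```

# The scientific problem

Obesity raises the incidence of myocardial infarction (MI), yet obese
patients with acute MI repeatedly show lower mortality than non-obese
patients. One way to look for a mechanism behind such a protective effect
is to combine two evidence streams: signed, literature-derived regulatory
relations (does obesity up- or down-regulate a gene? does that gene promote
or inhibit MI?), and case-control expression data from independent MI
cohorts. `megasignet` implements that workflow as reusable, tested pieces:

1. **relations** — quality control and set accounting over signed
   disease–gene relation tables, and extraction of the two *protective*
   sign motifs (`obesity ⊣ g → MI` and `obesity → g ⊣ MI`);
2. **meta** — a per-gene cross-dataset "mega-analysis" of expression
   log2 fold-changes with heterogeneity-driven fixed/random-effects model
   selection;
3. **enrich** — over-representation of a gene set against GMT collections;
4. **paths** — signed shortest-path exploration with polarity composition;
5. **synthdata** — a generator of relation tables and multi-study
   expression data with planted truth, so that every stage can be validated
   end-to-end without any download.

# Signed relation tables

A relation is one directed assertion `subject → object` with polarity
(`positive`/`negative`), an entity kind per endpoint, and a supporting
reference count. Quality control keeps relations with at least
`min_refs = 3` references and a defined polarity; everything else —
including rows whose polarity token could not be interpreted — is removed,
never silently repaired.

Duplicate `(subject, object)` rows are aggregated before any graph or set
operation: reference counts are summed per polarity and the polarity with
more evidence wins. An exact tie leaves the pair's sign undefined, and
undefined edges are dropped. The evidence-majority rule was an open design
choice; it is the least surprising aggregation consistent with treating
reference counts as evidence volume. Gene symbols are matched
case-insensitively and stored upper-case; no alias resolution is attempted,
because the whole workflow operates at symbol level.

Set accounting considers only entities of kind `gene`: the targets of the
upstream disease, the regulators of the downstream disease, their
intersection, and the upstream-only remainder. The protective motifs are
then pure sign-pattern scans over the aggregated edges.

# The mega-analysis model

For gene $g$ in study $i$, the effect size is the log2 fold-change
$y_{gi} = \bar{x}^{case}_{gi} - \bar{x}^{ctrl}_{gi}$ with unpooled
(Welch-style) sampling variance

$$v_{gi} = \frac{s^2_{case}}{n_{case}} + \frac{s^2_{ctrl}}{n_{ctrl}}.$$

The unpooled form is deliberate: several of the emulated study designs are
highly unbalanced (4 controls against 34 cases in the most extreme one),
where a pooled variance would be dominated by the larger group.

Heterogeneity across the $k$ studies measuring a gene is quantified by
Cochran's
$Q = \sum_i w_i (y_i - \hat\theta_F)^2$ with fixed-effect weights
$w_i = 1/v_i$, compared against its homogeneity expectation
$df = k - 1$, and summarised as
$I^2 = \max\{0, 100\,(Q - df)/Q\}$.

Model selection follows the $Q$-versus-$df$ rule: when $Q \le df$ the
observed dispersion does not exceed what sampling noise alone predicts,
$I^2$ is set to zero and the **fixed-effect** model pools with weights
$1/v_i$; otherwise the **random-effects** model pools with weights
$1/(v_i + \hat\tau^2)$. The between-study variance uses the
DerSimonian–Laird moment estimator

$$\hat\tau^2 = \max\!\left(0,\; \frac{Q - df}{\sum w_i - \sum w_i^2 / \sum w_i}\right),$$

chosen because it is the standard closed-form estimator and matches the
$Q$/$df$ framing of the selection rule; no estimator was prescribed, so this
was a design decision. The pooled effect is the weighted mean, its standard
error $(\sum w)^{-1/2}$, and the p-value a two-sided Wald z-test — again a
design choice, as the underlying analysis names no test.

Reporting uses strict thresholds: `pooled_lfc > 1` or `< -1`, **and**
`p < 0.05`. No multiple-testing correction enters this call — that mirrors
the analysis being emulated — but Benjamini–Hochberg q-values are computed
and reported alongside for the reader. Genes present in fewer than two
datasets are flagged `analyzable = FALSE` rather than dropped silently.

Diagnostics: `forest_data()` exposes per-study effects, 95% intervals
(±1.96·√v) and normalized model weights; `volcano_data()` the usual
LFC-versus-−log10 p table; `qq_check()` standardizes the per-gene
$y/\sqrt{v}$ statistics by their own mean and standard deviation and
reports the Kolmogorov–Smirnov distance to the standard normal, flagging a
dataset when the distance exceeds 0.1 (configurable). The mean/sd
standardization is taken from the procedure's definition; note it is not
robust — a single astronomically large statistic inflates the sample sd and
can itself push the KS distance past the flag, whereas any realistically
extreme outlier (tens of sds) cannot.

# Enrichment

Over-representation uses the hypergeometric upper tail (one-sided Fisher
exact test) of the overlap between the query and each set, restricted to a
background universe (default: the union of all collection members —
configurable, since the emulated analysis never states its background).
A set is reported when all three criteria hold: $q \le 0.005$
(Benjamini–Hochberg), background-restricted set size $\le 1000$, and
overlap percentage $\ge 2\%$ with set size as the denominator. The
denominator choice fits the size cap: a percentage of the query would make
the cap redundant. "Number of genes involved" is read as the
background-restricted size; with typical genome-scale backgrounds the raw
and restricted sizes coincide.

# Signed shortest paths

Paths are simple and directed; hop count is the length metric because the
relation graph has no meaningful edge weights. All minimum-length paths are
enumerated (capped at `max_paths`, default 100, to bound dense fixtures) in
lexicographic node order, which makes outputs deterministic. Each path's
net sign is the product of its edge polarities. Intermediate nodes are then
classified by their *direct* edge into the disease of interest — promoter,
inhibitor, or indirect when no direct edge exists — and the overall verdict
is "mixed" when both promoter- and inhibitor-class intermediates occur,
the situation in which a gene's net influence cannot be read off the graph.

# The synthetic-data generator

`simulate_expression()` draws, for gene $g$ and study $i$, a study-level
true effect $\theta_{gi} \sim N(\mu_g, \tau^2_g)$, then control samples
from $N(\beta, \sigma^2)$ and case samples from
$N(\beta + \theta_{gi}, \sigma^2)$ on the log2 scale. This is exactly the
hierarchical model the random-effects pooling assumes, so planted values
are recoverable and the model-selection rule can be exercised in both
regimes ($\tau^2 = 0$ and $\tau^2 > 0$).

Defaults: the seven study designs mirror the published MI mega-analysis
cohort sizes (controls/cases 4/34, 7/17, 50/49, 7/10, 48/49, 21/31,
14/84 — the printed design table lists its duplicated accession as two
separate rows, and the generator mirrors the seven printed rows without
interpreting the duplication); `noise_sd = 1` log2 unit, a typical
within-group spread for array expression; `baseline_mean = 8`, mid-range
log2 intensity. Those two values are the generator's own realism choices —
nothing in the emulated analysis pins them — and all results reported by
the package are computed, not assumed, under them.

What the generator does *not* emulate: probe-level artifacts, batch
effects, correlated genes, non-Gaussian heavy tails, and array
normalization pipelines. Passing tests therefore demonstrate correctness
of the statistics and the planted-truth recovery loop, not robustness to
real-array preprocessing — which is also why the published real-data
effect sizes (for example the extreme PTH fold-changes, whose printed
magnitude is implausible on a log2 scale and suggests a different scale in
the source data) are out of scope for machine verification.

`simulate_relations()` plants the full set structure — upstream-only,
downstream-only and shared genes in all four sign patterns — plus optional
noise rows (sub-threshold reference counts, unknown polarity) that QC must
remove, closing the loop for the relations stage. The packaged fixtures
(`mi_promoter_fixture()`, `pth_path_fixture()`) carry the published
protective-network gene list and a path fixture whose unnamed molecules
are explicitly marked synthetic.

# Numerical choices and degenerate inputs

* Pooling requires $k \ge 2$ and all $v_i > 0$; a non-positive variance
  names the offending dataset in the error.
* $\hat\tau^2$ is truncated at zero; $I^2$ is exactly zero on the
  $Q \le df$ branch, so `model == "fixed"`, `Q <= df` and `isq == 0` are
  equivalent by construction and asserted on random inputs in the tests.
* Linear-scale detection uses `max > 30` before `log2(x + 1)`; the branch
  taken is recorded and the threshold is an argument.
* Probe collapsing uses the per-sample median, a deterministic and
  outlier-tolerant summary.
* Ties in polarity aggregation yield "unknown", never an arbitrary pick.
* All simulations take explicit integer seeds; equal config plus seed gives
  byte-identical serialized output.

# Problem sizes used in validation

The test-suite simulations use 1,000 random pooling instances for the
oracle comparison, 2,000 null genes under the seven-study design for the
type-I check, 200 genes across ten planted (LFC, τ²) cells for recovery,
500 random tables for the hypergeometric oracle, and 200 random digraphs
of up to 12 nodes for path enumeration — sizes at which the Monte-Carlo
error of each check is comfortably below its asserted margin.

# Known limitations

* Symbol-level gene identity; no alias or ortholog handling.
* The relation tables are inputs: no text mining is performed, and the
  proprietary knowledge base the emulated analysis drew from is not
  queried.
* The significance rule uses raw p-values by design; treat the reported
  q-values as the multiplicity-aware view.
* Between-study variance is estimated per gene from at most seven studies;
  $\hat\tau^2$ is noisy at such $k$, which is inherent to the design, not
  to the implementation.

# A worked example

```{r example, eval = FALSE}
nets <- protective_networks(qc_filter(mi_promoter_fixture()), "OBESITY", "MI")
nets$genes$inhibited_promoters

sim <- simulate_expression(sim_config(n_genes = 500,
                                      planted_lfc = c(-2, rep(0, 499)),
                                      tau2 = 0.1, seed = 1))
res <- mega_analysis(sim$datasets)
head(res)
significant_genes(res)
```
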