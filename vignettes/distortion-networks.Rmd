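---
title: "Co-occurrence network analysis of cognitive distortion labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence network analysis of cognitive distortion labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distortnet)
```

## The analytical problem

Texts annotated with cognitive-distortion labels (catastrophizing,
all-or-nothing thinking, personalization, and so on) are multi-label data:
a single comment typically manifests one or two distortions, sometimes
more. When distortions systematically co-occur, the pattern of
co-occurrence can be treated as a network — nodes are distortion
categories, edges are above-chance co-occurrence — and interrogated with
the tools of network psychometrics: centrality, clustering, hub
identification, and stability analysis.

`distortnet` implements that pipeline over a binary text-by-label
incidence matrix (the `label_matrix`): association mining for label
pairs, a triadic enrichment statistic, network construction and metrics,
bootstrap node stability, split-half reliability via the quadratic
assignment procedure (QAP), and a misclassification noise-injection
robustness analysis. Because large hand- or model-annotated corpora are
rarely redistributable, the package ships a synthetic corpus generator
that reproduces the statistical structure such corpora exhibit, so every
stage can be validated end to end against planted ground truth.

## The statistics

**Pairwise association.** For labels $i, j$ with marginal counts $N_i,
N_j$ in a corpus of $N$ texts, the observed co-occurrence $O$ is the
number of texts containing both; the expected count under independence is
$E = N_i N_j / N$, and the lift ratio is $O/E$. Lift above 1 indicates
positive association. Significance comes from Pearson's chi-square on the
2x2 table (both / only $i$ / only $j$ / neither), one degree of freedom,
no continuity correction by default (configurable; at the corpus sizes
this method targets the correction is immaterial). With $D = 18$ labels
there are $\binom{18}{2} = 153$ pairs, and the family-wise level is
Bonferroni-corrected to $\alpha/153$; the exact quotient $0.05/153
\approx 3.27 \times 10^{-4}$ is used rather than a rounded constant.
Edges enter the headline network when lift strictly exceeds 1, the
observed count is at least 1, and the corrected p-value criterion holds.
Resampling analyses (bootstrap, noise) use the same rule with the
significance criterion switched off — a two-criterion reconstruction
that mirrors how such resampling is normally reported — and each
resampling function takes its own `association_config()` so either
convention is available everywhere.

**Triadic enrichment (ISM).** For each of the $\binom{18}{3} = 816$
label triples the Integrated Significance Metric multiplies three
components,

$$\mathrm{ISM} = f_{rel} \times P_{avg} \times \mathrm{OER},$$

where $f_{rel}$ is the triple's relative frequency (count over $N$;
an alternative denominator — the total number of triadic instances
$\sum_t \binom{k_t}{3}$ — is available behind a switch), $P_{avg}$ is
the mean of the three pairwise-conditioned probabilities $P(i \mid j
\wedge k)$, $P(j \mid i \wedge k)$, $P(k \mid i \wedge j)$ (a
conditional with an empty conditioning set contributes 0), and OER is
the observed-to-expected ratio under independence with plug-in marginal
proportions, $O / (N \pi_i \pi_j \pi_k)$. The product is high only when
frequency, conditional probability and enrichment are simultaneously
elevated, which suppresses triples that score well on a single
component. Significant triads are those at or above the 99th percentile
of all 816 ISM values (type-7 linear-interpolation quantile, ties at the
cutoff kept); an explicit cutoff mode is available since percentile
conventions differ between software stacks and the inclusive-tie count
at a 99th percentile of 816 values is necessarily convention-dependent
(roughly 9 triads under type-7 interpolation).

**Network metrics.** The network is simple, undirected, and weighted by
lift. Density is realized edges over $\binom{|V|}{2}$. Clustering is
reported two ways: the headline value is the mean local clustering
coefficient with degree-below-2 nodes contributing 0 (the convention of
the Python network stack, for comparability), and the global
transitivity is reported alongside. Betweenness uses edge distances
$1/\mathrm{lift}$ — stronger associations are shorter paths — normalized
by $(n-1)(n-2)/2$. Degree assortativity is the Pearson correlation of
degrees over edge endpoints; for regular graphs (zero endpoint-degree
variance) it is reported as missing, never NaN. Hubs are the top-5 nodes
by degree, ties broken by weighted degree then label order — an
arbitrary but deterministic rule, needed because hub sets feed Jaccard
comparisons.

**Bootstrap node stability.** The corpus rows are resampled with
replacement $k$ times (default 10,000; analyses in this package's
scripts use 1,000–2,000, which stabilizes appearance proportions to
about $\pm 0.01$–$0.03$); each resample is refiltered and rebuilt, and a
node "appears" when it retains at least one surviving edge (isolated
nodes do not count — exclusion semantically means "no surviving
connections"). The dual-threshold rule classifies nodes as core
(appearance $\ge$ 95%), exploratory ($\ge$ 60%), or excluded, with
inclusive boundaries. Density and clustering are summarized by 2.5/97.5
percentile intervals; the percentile bootstrap does not guarantee the
full-data point estimate falls inside, so a violation triggers a warning
rather than an error.

**QAP reliability.** Two networks over the same node set are compared by
the Pearson correlation of their adjacency upper triangles
(lift-weighted by default, binary optionally). Because edges sharing a
node are dependent, the null distribution is built by jointly permuting
the rows and columns of one matrix (default 5,000 permutations) — the
quadratic assignment procedure — and the p-value uses the add-one
convention $(1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(B+1)$, two-sided on
$|r|$. Split-half reliability applies this to networks built from two
random halves of the corpus; stratified reliability applies it to
high- versus low-activity groups (threads), partitioned by median group
size, Pareto top-20%, or top-quartile rules. Both half-networks are
always built on the full 18-label node set so the matrices stay
conformable when a label drops out of one half.

**Noise robustness.** Misclassification is simulated by flipping cells:
at error rate $\varepsilon$, with $L$ positive cells,
$\mathrm{round}(\varepsilon L/2)$ positives are deleted (false
negatives) and the same number of negatives added (false positives),
chosen uniformly. $\varepsilon$ is thus the fraction of positive labels
that are erroneous; the even split preserves the positive-cell count
exactly and is configurable (`fn_fraction`). The sweep runs 11 levels
(0–50% in 5% steps) times 50 replicates = 550 reconstructions,
recording density, clustering and the Jaccard similarity between each
noisy network's top-5 hubs and the reference hubs. Per-level mean hub
Jaccard classifies regimes: stable ($\ge 0.95$), degrading ($\ge
0.60$, the conventional hub-stability threshold), collapse (below).
Networks in the sweep are built on the fixed 18-label node set: with a
dropped-isolate policy the density denominator would change with the
node set, and a small high-lift core would read as density 1.0,
masking the diagnostic pattern — rising density under noise — that
distinguishes spurious densification from genuine structure.

## The synthetic generator

`generate_corpus()` draws, per text, a label count $k$ from a
configurable distribution, then fills the label set by
prevalence-weighted sampling without replacement (exponential-keys
weighted reservoir sampling, vectorized across texts). Planted structure
comes from *bundles*: with probability equal to the total bundle weight a
text is seeded by one bundle (mutually exclusive per text, which keeps
the planted-lift arithmetic tractable), all bundle members are included
($k$ is raised to the bundle size if the draw was smaller), and the
remainder is filled by ordinary sampling.

The defaults emulate the marginal structure of a large naturalistic
distortion corpus: mean 1.78 labels per text; 82.3% of texts with 1–2
labels, 12.7% with 3, 5.0% with 4 or more (the open tail realized as a
truncated geometric over 4–8, ratio 1/2 — the tail shape is otherwise
unidentified and is bounded by the taxonomy size); positive skewness
near 1.97; a geometrically decaying prevalence profile topping out near
15.5%; and one planted pair (All-or-Nothing Thinking +
Catastrophizing, lift calibrated to about 1.96) plus one planted triad
(adding Disqualifying the Positive). The drawn count distribution and
prevalence weights are pre-compensated for the bundle mechanics (bundle
seeding raises small drawn counts and boosts member marginals), so the
*realized* corpus hits those targets; the calibration was done once,
analytically plus a single large-sample check, and frozen.

Two structural facts about the generator matter for interpreting
results. First, a fixed per-text count distribution induces mild
negative association among unplanted labels: under weighted sampling
without replacement the baseline pairwise lift is
$\tfrac{18}{17}\,\mathbb{E}[k(k-1)]/\mathbb{E}[k]^2 \approx 0.8$ under
the default counts, not 1. Exact pairwise independence corresponds to a
Binomial$(18, p)$ count distribution (equivalently, independent
Bernoulli labels), which is what the exchangeability and type-I-error
validations use. Second, stacking many bundles on one hub label inflates
its marginal and dilutes each individual pair's lift — a hub with many
strong partners cannot have uniformly high lift to all of them. The
`planted_structure_config()` scenario therefore gives its nine core
labels a *low* base prevalence so bundle-driven joints dominate, which
yields a recoverable hub-and-periphery core (planted lifts 2.4–6.4 at
$n = 20{,}000$) over a quiet background.

What the generator does **not** emulate: correlated annotator error
(noise is independent by design), thread-level topic structure beyond
group-size heterogeneity (groups are assigned by a symmetric
Dirichlet-multinomial with concentration 1, giving realistic size
skew but no content differences between threads), text content
(everything starts at the label matrix), and the broad positive
association background of real discourse corpora. Passing tests
therefore demonstrate that the pipeline recovers structure it was
designed to detect under controlled conditions — not that any
particular real corpus has that structure.

## Numerical and design choices

- **Length filter boundary**: "shorter than 200 characters" excludes
  lengths up to 199; exactly 200 is retained.
- **Ordering of corpus filters**: the length filter precedes removal of
  unlabeled texts in `run_pipeline()`, matching the natural
  preprocessing order (length is a property of raw text; labels arrive
  afterwards).
- **Skewness**: the adjusted Fisher–Pearson estimator (the common
  default across statistical software); significance by D'Agostino's
  skewness z-test, which requires $n \ge 8$ — below that the p-value is
  reported as missing rather than extrapolated.
- **Zero-margin pairs**: a label absent from the corpus gives $E = 0$;
  lift is reported as missing (never infinite) and such pairs never pass
  the edge filter. Zero-margin chi-square tables give statistic 0 and
  p-value 1.
- **Zero-count triples**: all ISM components are reported as 0, so
  ISM = 0 exactly.
- **Determinism**: every randomized operation takes an explicit seed and
  restores the caller's RNG state; sweep replicates derive their seeds
  as `seed + 1000 * level_index + replicate_index` so any single design
  cell is reproducible in isolation. No function reads global RNG state
  implicitly.
- **QAP degenerate input**: zero variance in either adjacency's
  off-diagonal makes $r$ undefined; it is reported as missing with a
  warning, and the minimal attainable p-value is $1/(B+1)$ by the
  add-one convention.
- **Problem sizes**: the validation suite exercises the study-scale
  combinatorics exactly (153 pairs, 816 triads, 11 x 50 = 550 noise
  reconstructions, split halves of 124,707) while scaling simulation
  corpora to 20,000–249,414 texts and replication to 200 Monte-Carlo
  replicates, 1,000–2,000 bootstrap iterations and 199–5,000 QAP
  permutations; at these sizes every Monte-Carlo check is stable to
  well within its stated tolerance.

## A worked example

```{r example}
# a small corpus with the default planted structure
corpus <- generate_corpus(synthetic_config(n_texts = 30000, seed = 1))
summarize_counts(corpus)

# pairwise association + headline filter
ps <- pair_stats(corpus)
edges <- filter_edges(ps, association_config())
edges[order(-edges$lift), c("label_i", "label_j", "observed", "lift")]

# triadic enrichment
ts <- triad_stats(corpus)
thr <- threshold_triads(ts, percentile = 99)
head(thr$significant_triads[, c("rank", "label_i", "label_j", "label_k",
                                "count", "ism", "oer")], 3)

# network and metrics
net <- build_network(edges)
network_topology(net)
top_hubs(net, 5)
```

## Limitations

The pipeline operates on binary incidence; label confidence scores or
multi-annotator votes must be thresholded upstream. Lift-based networks
capture marginal pairwise association, not conditional dependence — a
graphical model (e.g. an Ising model) would answer a different question
and is out of scope. The ISM is a descriptive enrichment index with a
percentile threshold, not a calibrated test; its null behavior depends
on the marginal profile. Bootstrap appearance proportions are
conditional on the chosen edge filter: under the permissive
two-criterion rule, rare labels with *any* co-occurrence almost always
retain an edge (a single co-occurrence of a rare label has lift
$O \cdot N / (N_i N_j) \gg 1$), so exclusion in practice identifies
labels that are both rare and isolated. And all validation rests on the
synthetic generator's assumptions listed above.
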