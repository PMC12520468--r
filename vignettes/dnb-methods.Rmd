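---
title: "Detecting tipping points with dynamic network biomarkers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tipping points with dynamic network biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnbtip)
```

## The problem and the model

Many biological systems — a tumour acquiring metastatic competence, a cell
committing to a fate — move between stable states through an abrupt
transition. Shortly before such a transition, dynamical systems theory
predicts a characteristic signature in a small group of molecules (the
*dynamic network biomarker*, DNB): their fluctuations grow, they fluctuate
increasingly *together*, and they decouple from the rest of the system.
For a candidate gene module at timepoint $t$, with the replicates at $t$
as the sample space, dnbtip computes

* $SD_{in}(t)$ — the mean over module genes of the per-gene replicate
  standard deviation (log-expression units),
* $PCC_{in}(t)$ — the mean absolute Pearson correlation over all
  within-module gene pairs,
* $PCC_{out}(t)$ — the mean absolute Pearson correlation over all
  module-by-background gene pairs,

and combines them into the criticality index

$$CI(t) \;=\; \mathrm{size} \cdot \frac{PCC_{in}(t)\, SD_{in}(t)}{PCC_{out}(t) + \epsilon}.$$

The timepoint at which the detected module's CI peaks is reported as the
tipping point: the last observation window before the transition. The size
factor can be dropped (`use_size_weight = FALSE`); both readings of the
composite are in circulation and for a fixed module they locate the same
peak. The $\epsilon$ guard (default $10^{-6}$) keeps the index finite for a
module that is entirely uncorrelated with the background.

**Assumptions.** Expression is on a log scale and already normalized;
replicates at a timepoint are exchangeable; the replicate set (typically
$n = 3$) is the only sample space in which the pre-transition variance
inflation is visible, because averaging replicates away would also average
away the fluctuation signal. With $n = 3$ the individual correlations are
extremely noisy — the expected absolute correlation between two
*independent* genes is already $2/\pi \approx 0.64$ — and only module-level
averages of many pairs carry information. This noise floor drives several
design choices below.

## Finding the module

The statistics above score a *given* module; finding one is a model-search
problem the index alone does not solve. dnbtip searches as follows.

**Candidates** come from agglomerative clustering of genes with distance
$1 - |r|$, cut at several heights (default 0.3, 0.5, 0.7), keeping every
cluster whose size falls in `[min_size, max_size]` (defaults 5 and half
the gene count). Two correlation passes feed the clustering, both using
*all samples pooled* rather than one timepoint's replicates:

1. raw pooled correlations — maximal degrees of freedom;
2. correlations of within-timepoint-centred residuals — invariant to mean
   trajectories, so genes that merely share an expression shift over time
   cannot masquerade as a fluctuation-coupled module.

Per-timepoint clustering is also available
(`candidate_modules(series, timepoint = ...)`) but is not the default: at
$n = 3$ the standardized replicate vectors lie on a circle, chance-aligned
genes form tight clusters, and a genuine module cannot be separated from
them.

The default linkage is *complete*, which bounds the cluster diameter: every
gene pair in a candidate must have pooled $|r| \ge 1 - h$. Average linkage
tends to produce large loosely-connected clusters which, combined with the
size-weighted index (next paragraph), win the search for the wrong reason.

**Selection.** Candidates of different sizes are compared with a
$\sqrt{\mathrm{size}}$-weighted criticality score rather than the
linear-size CI. Against the $2/\pi$ per-timepoint correlation floor the
linear-size index grows roughly linearly as arbitrary genes are added, so
a diluted supercluster outscores the coherent module it contains; the
square-root weight still rewards coherent growth but penalises dilution.
All *reported* CI values use the standard formula; for a fixed module both
weightings peak at the same timepoint.

**Refinement** (`refine = TRUE`). The winning candidate is polished in two
steps: greedy backward elimination removes any gene whose removal raises
the selection score (stopping at a local maximum or `min_size`), and genes
whose own replicate SD does not peak at the tipping timepoint are dropped —
the member-level counterpart of the $SD_{in}$ criterion. Without this, the
detected module typically carries one to three chance-aligned genes, which
matters downstream when single genes are ranked. `refine = FALSE` gives
the bare search result.

**Criteria flags.** The result records whether $SD_{in}$ and $PCC_{in}$
are *significantly* elevated, and $PCC_{out}$ significantly depressed, at
the tipping point: the statistic must exceed the other timepoints' maximum
(fall below their minimum) by at least one standard deviation of those
remaining values. A bare extremum comparison is misleading here, because
the tipping timepoint is itself chosen as the CI maximum — its components
are selected extremes, and under a null with constant covariance the bare
$SD_{in}$ flag alone would fire in roughly 80% of runs. With the margin,
all three flags fire jointly in about 1% of null runs (measured by the
test suite) while a genuine transition still raises the $SD_{in}$ and
$PCC_{in}$ flags in the large majority of reference runs.

**Significance.** Because the search optimises the very statistics the
flags describe, significance for a *searched* module comes from
`permutation_null()`: random modules of the same size are drawn, their CI
computed at the same timepoint, and the empirical p uses the add-one
correction $(1 + \#\{CI_{null} \ge CI_{obs}\})/(B + 1)$. Gene-label
permutation assumes the tested module is exchangeable with the background;
it is a null for "this module is nothing special", not for "there is no
transition anywhere".

## The synthetic-data generator

`simulate_critical_transition()` plants exactly the covariance signature
the criteria describe, with a one-factor model: a latent factor
$z_{t,r} \sim N(0, s(t)^2)$ is drawn once per (timepoint, replicate), with
$s(t) = s_1$ at the transition timepoint and $s_0$ elsewhere. Module genes
load on the factor with gene-specific loadings $\lambda_g$; background
genes load weakly (`background_coupling`) before the transition and not at
all from it on, so module-background correlation falls while within-module
variance and correlation jump. A one-factor model was chosen over an
explicit stochastic system near a bifurcation because the criteria
constrain only second moments, and the factor structure makes the expected
statistics available in closed form for oracle tests — for loadings of 1
the within-module correlation at the transition is
$s_1^2 / (s_1^2 + \sigma_e^2)$, which the tests verify by Monte Carlo.

Reference defaults: 200 genes, a 20-gene module, 5 timepoints × 3
replicates, $s_0 = 0.2$, $s_1 = 2.0$, $\sigma_e = 0.5$, coupling 0.3,
transition at the third timepoint, gene means uniform on [4, 8]
(log2-expression units). These are the conditions under which the
acceptance checks run; the per-seed detection ceiling is genuinely below
1 because with 3 replicates the realized factor spread at the transition
is $s_1^2 \chi^2_2/2$-distributed and occasionally small — in such runs no
method can see the transition.

An optional `mean_shift` adds a persistent expression shift to module and
planted-neighbor genes from the transition on — a state change, not a
one-timepoint blip — giving differential-expression calls and the
neighbor-intersection steps a planted truth. The transition otherwise
affects only covariance, deliberately isolating the DNB signal from mean
effects.

`simulate_ppi()` plants a complete bipartite module-neighbor edge set plus
independent background edges, so neighbor recovery has exact ground truth.

**What the generator does not emulate:** count noise and library-size
effects (the pipeline operates on log expression), batch structure,
heavy-tailed expression, correlated background blocks, and any real
regulatory network topology. Passing the planted-recovery tests shows the
machinery is correct and calibrated under the stated covariance structure,
not that real tissue time courses satisfy that structure.

## Differential expression

Contrasts are each later timepoint against the baseline. The statistic is
a variance-moderated two-group t: the pooled per-gene variance (residual
df $d$) is shrunk toward a prior $s_0^2$ (default: the median gene
variance) with `prior_df` $d_0 = 4$ pseudo-observations,
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, and
$t = \Delta/(\tilde s\sqrt{1/n_1 + 1/n_2})$ on $d_0 + d$ df. With
$d_0 = 0$ this is exactly the classical pooled t (the tests verify both
this limit and agreement with an independent shrinkage implementation).
$d_0 = 4$ roughly doubles the effective variance df of an $n=3$ design
while letting genuinely variable genes keep their own variance. BH
adjustment is within contrast; DEG calling uses strict thresholds
(|log2FC| > 1, p < 0.05 by default, raw p rather than q because small
time-course designs are usually screened permissively and the adjusted
column is always available).

## Temporal clustering

`standardize_profiles()` averages replicates per timepoint and z-scores
each gene across timepoints (zero-variance genes are excluded — they carry
no pattern). `fuzzy_cmeans()` is the classical alternating-optimization
fuzzy c-means: memberships
$u_{ij} = 1/\sum_l (d_{ij}/d_{il})^{2/(m-1)}$, centroids
$c_j = \sum_i u_{ij}^m x_i / \sum_i u_{ij}^m$, objective
$J_m = \sum_{ij} u_{ij}^m d_{ij}^2$, which the implementation asserts is
non-increasing. Defaults $k = 4$ (the number of broad temporal archetypes
— rising, falling, transient-up, transient-down) and fuzzifier $m = 2$,
the conventional compromise between hard assignments ($m \to 1$) and
uniform memberships (large $m$). Initial centroids are $k$ distinct
profiles chosen by distance-weighted (k-means++-style) sampling, which
near-guarantees one seed per well-separated group; `nstart` restarts keep
the lowest-objective run, and an explicit `centroids` argument gives a
fully deterministic path used by the equivariance tests. A profile
coincident with a centroid receives membership 1 there (the standard
zero-distance convention). Clustering is descriptive in this pipeline —
tipping detection does not depend on it.

## Network analysis around the module

First PPI neighbors of the detected module (minus the module itself) are
intersected with the DEGs of the contrasts up to the tipping point, then
with user-supplied metastasis gene sets (GMT). Correlation edges between
the module and the resulting genes use Pearson r over all samples pooled
(`sample_scope = "all_samples"`; timepoint means are available but leave
few samples and weak p-values), with
$t = r\sqrt{(n-2)/(1-r^2)}$ p-values and *strict* threshold conventions:
an |r| exactly at the cutoff fails. Defaults: 0.8 for module-neighbor
edges, 0.5 for gene-pathway associations, 0.7 for the dysregulation
network, all with p < 0.05, unadjusted (a BH option exists). Per-module-gene
counts of passing neighbors, sorted with lexicographic tie-break, rank the
module genes by metastasis-neighbor connectivity.

The pathway activity score is deliberately simple: per-gene z-score across
samples, averaged over the pathway members present (at least 2). It is
transparent, exactly testable, and monotone in coordinated member
expression; it is *not* a rank-based enrichment score, and pathways whose
members move in opposite directions will score near zero.

## Numerical and degenerate-input conventions

* Genes with zero replicate variance contribute $|r| = 0$ to every pair,
  with a warning — statistics stay defined on degenerate replicates.
* Ties: the tipping point takes the earliest timepoint; candidate ties the
  lexicographically smallest gene set; cluster hard labels the lowest
  index.
* Candidate clustering sorts genes lexicographically first, so results do
  not depend on input row order.
* All randomness flows from explicit integer seeds through fixed offsets;
  re-running any function with the same inputs and seed reproduces its
  output bit for bit (the pipeline writes a byte-identical result manifest).
* Expression TSVs are written with 17 significant digits so round trips
  are exact; network TSVs use 16-digit scientific notation.

## Problem sizes used by the checks

The test suite and the acceptance script work at the reference scale (200
genes, 5 × 3 samples) with 50-seed replication for recovery and ranking
properties, 200 runs for permutation-p calibration, 100 for the null
criteria check, and 20 for clustering recovery — sizes at which every
Monte-Carlo bound tested has comfortable binomial resolution while the
whole suite runs in well under a minute per property.

## Known limitations

* With 3 replicates the per-timepoint correlation floor is $2/\pi$;
  modules smaller than ~5 genes or factor spreads realized small cannot be
  distinguished from chance, and roughly one reference run in ten misses
  the transition for exactly that reason.
* The searched module's criteria flags remain selection-biased even with
  the significance margin; the permutation p is the quantity to report.
* The planted coupling-drop (0.3 loading on an $s_0 = 0.2$ factor) moves
  $PCC_{out}$ by ~$10^{-3}$ — detectable in expectation, rarely flagged per
  run. A real system approaching a transition may show a much larger
  decoupling; the generator is conservative here.
* Gene identifiers are opaque strings; no symbol mapping is attempted, and
  gene sets, PPI edges and expression must share an identifier space.
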