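---
title: "Methods: multi-omics correlation network integration with momicnet"
author: "momicnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics correlation network integration with momicnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momicnet)
```

# The problem

Multi-omics studies measure several molecular layers — for instance mRNA,
miRNA and protein abundances, or host transcriptome and microbial
community composition — on the same samples. Features from different
layers rarely share identifiers, so module-overlap strategies that match
"the same genes" across tables do not apply. momicnet links layers
through *behavior* instead: each layer is reduced to a small set of
co-expression modules, each module is summarized by one representative
profile (its eigengene), and layers are connected by directly correlating
eigengenes across networks. Because each layer contributes only a handful
of eigengenes, the number of cross-layer tests is small and statistical
power is preserved.

# Per-layer weighted correlation networks

For one layer with samples in rows, we compute a feature correlation
matrix $r_{ij}$ (Pearson by default, Spearman optional) and raise it to a
soft threshold: unsigned adjacency $a_{ij} = |r_{ij}|^\beta$ or signed
$a_{ij} = ((1+r_{ij})/2)^\beta$. The exponent $\beta \ge 1$ suppresses
weak correlations smoothly instead of imposing a hard cutoff.

**Choosing $\beta$.** For each candidate we compute connectivities
$k_i = \sum_{j \ne i} a_{ij}$, bin them into 10 equal-width bins (empty
bins dropped), and regress $\log_{10}$(bin frequency) on $\log_{10}$(bin
center). The signed fit index $\mathrm{sign}(-b)\,R^2$ penalizes degree
distributions that *increase* with $k$. The chosen power is the smallest
candidate whose signed $R^2$ reaches the target (0.8 by default);
otherwise the best-fitting candidate is returned with a warning. The
default candidate grid runs 1–10, then 12–20 in steps of 2, then 25 and
30: on small or strongly modular layers the fit index keeps improving
well past 20, and a grid that stops there would cap the selection rule
rather than let it operate. When the fit is inconclusive (degenerate
degree distribution), the conventional unsigned default $\beta = 6$ is
used. Note that an automatically chosen large $\beta$ can empty small
networks downstream; `runNetworkAnalysis(autoPower = FALSE)` (the
default) keeps the conventional power.

**Topological overlap.** Adjacency is smoothed into the topological
overlap matrix
$$\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}
 {\min(k_i, k_j) + 1 - a_{ij}}, \qquad
 \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},$$
which credits feature pairs for shared neighborhoods, and the
dissimilarity $1 - \mathrm{TOM}$ is clustered by average-linkage
hierarchical clustering.

**Module detection.** We cut the tree statically at a fixed fraction
(default 0.99) of its maximum merge height; clusters smaller than
`minModuleSize` (default 20) are left unassigned (label 0, displayed
grey), and the remaining modules are renumbered by decreasing size. The
static cut is a deliberate simplification of the dynamic hybrid
tree-cutting algorithm: it is fully deterministic, has two transparent
parameters, and recovers planted modules essentially perfectly at the
reference conditions below. Its known limitation is nested module
structure at very different heights, which a static cut cannot separate;
lowering `cutHeight` and re-running is the workaround.

**Eigengenes.** A module's eigengene is the first left singular vector of
its standardized (zero-mean, unit-variance features) sample-by-feature
submatrix, scaled to unit variance and oriented so it correlates
nonnegatively with the module's mean standardized profile. A singleton
module's eigengene is the standardized feature itself. Modules whose
eigengenes correlate above $1 - $ `mergeCut` (default correlation 0.75)
are merged iteratively, recomputing eigengenes after each merge.

**Module–trait association.** Eigengenes are correlated with every
annotation column; qualitative traits are expanded to one indicator
column per level (point-biserial correlation) rather than integer-coded,
because integer coding would impose an arbitrary level order. Two-sided
p-values come from $t = r\sqrt{n-2}/\sqrt{1-r^2}$ with $n - 2$ degrees of
freedom, and Benjamini–Hochberg adjustment is applied across the whole
module-by-trait-column grid.

# Cross-layer integration

All modules of all layers are associated by correlating their eigengenes
across layers (within-layer pairs and the unassigned label 0 are
excluded; unassigned features are not cohesive by construction).
P-values use the same $t$ reference; BH is applied jointly across **all**
inter-layer module pairs, not per layer pair, because the power argument
for the dimensionality reduction concerns the total number of
correlations performed. Edges with $q \le \alpha$ (default 0.05, exposed
as a flag) form the multilayer module graph; nodes participate if they
carry a retained edge or are themselves trait-significant at $\alpha$.

For display, the graph is laid out as a hive plot: one radial axis per
layer (axes in alphabetical layer order, evenly spaced — 120° apart for
three layers), each module placed by the rank of its anchor-trait
correlation scaled to (0, 1], ties broken by module id. For a qualitative
anchor trait each module reports the indicator level with the largest
|r|. Any module pair can be expanded into a bipartite feature network:
features of the two modules are correlated 2-by-2 (Spearman by default)
and pairs with $|r|$ strictly above the threshold (default 0.35) are
linked; per-edge p and BH q values are reported alongside so users can
post-filter on significance, but the edge rule itself is magnitude-based,
matching the displayed convention.

# OPLS validation of module–trait links

A module–trait association can be cross-validated by orthogonal partial
least squares: the module's features predict the trait with one
predictive component after removing `nOrth` (default 1) components of
X-variation orthogonal to the response (orthogonal-signal-corrected
NIPALS). Predictors are standardized internally; quantitative responses
are standardized, qualitative responses dummy-coded with centered
columns, giving the discriminant variant. One predictive component is
always used — the use case is single-trait validation — and multi-class
traits keep the same single component on the dummy block; multi-block
VIP variants are out of scope. With a unit predictive weight vector $w$,
$\mathrm{VIP}_j = \sqrt{p}\,|w_j|$, so $\sum_j \mathrm{VIP}_j^2 = p$
exactly. Predictive ability is summarized by $Q^2 = 1 -
\mathrm{PRESS}/\mathrm{SSY}$ over seeded $k$-fold splits (default 7,
stratified by class for qualitative responses); $Q^2 \le 0$ means the
model predicts no better than the response mean. One caveat worth
knowing: with correlated predictors and *no* orthogonal components,
a single PLS component does not fully explain even a noiseless linear
response; the orthogonal correction is what restores $R^2_Y \to 1$.

# Ordination

PCA (via the standard QR/SVD route) and principal coordinates analysis
(classical scaling of $-D^2/2$, negative eigenvalues reported, optional
Cailliez constant-shift correction) cover single-table exploration;
Euclidean, Bray–Curtis and presence/absence Jaccard distances are a
minimal defensible metric set for PCoA. Axis signs everywhere follow one
convention: the element of largest magnitude (loading where available,
coordinate otherwise) is made positive.

**Co-inertia and its multi-table extension.** Pairwise co-inertia takes
the SVD of the cross-product of two centered tables; the axis-$k$
covariance is the $k$-th singular value divided by $n$. For 2–3 tables we
maximize the *summed pairwise covariances* of the per-table scores
(the MAXDIFF criterion), with each centered table first scaled to unit
total inertia so no layer dominates by sheer variance. This criterion —
rather than the leading eigenvector of the summed projection operators,
i.e. the PCA of the concatenated tables — was chosen deliberately: only
the pairwise-covariance criterion reduces *exactly* to pairwise
co-inertia when two tables are supplied (we verified the concatenated-PCA
variant deviates already on the first axis), and that consistency is one
of the package's tested guarantees. The solver is a power iteration
(deterministic start from the merged-table first principal component,
convergence tolerance $10^{-10}$ on the criterion, at most 500
iterations per axis); after each axis every table is deflated in feature
space by its unit weight vector, so per-table weights are orthonormal
across axes. PCA-style centering and inertia scaling are used for all
tables — including compositional layers, which enter after the centered
log-ratio transform and may hence be negative — a documented dialect
difference from correspondence-analysis-style multi-table preprocessing.
Per-axis "drivers" are features ranked by |weight|, ties broken
lexically.

**Procrustes.** Two ordinations of the same samples are compared by
optimal translation, scaling and orthogonal rotation; the badness-of-fit
is the symmetric statistic
$m^2 = 1 - (\sum_k d_k)^2 / (\mathrm{tr}\,A'A \cdot \mathrm{tr}\,B'B)$
on centered configurations. Significance uses the PROTEST convention:
rows of the second configuration are permuted with a user-supplied seed
and $p = (1 + \#\{m^2_{perm} \le m^2_{obs}\}) / (B + 1)$ with $B = 999$
by default; the seed is mandatory in the CLI so published p-values are
reproducible.

# Preprocessing

Compositional layers (sequencing counts) are centered-log-ratio
transformed: $\mathrm{clr}_{ij} = \ln(x_{ij} + \delta) - \overline{\ln(x_{i\cdot} + \delta)}$.
The pseudocount $\delta$ defaults to 1 for integer counts and to half
the smallest positive value for real-valued compositional tables; both
choices avoid $\ln 0$ while preserving the ranking of abundances.
Prevalence filtering keeps features with value $> 0$ in at least the
requested fraction of samples, ties kept. log2(x+1), total-sum scaling
and per-feature standardization are provided under one `transformLayer`
dispatch. Outlier screening follows the sample-network convention:
affinity $((1 + r)/2)^2$ between sample profiles, connectivity
standardized, samples below $z = -2.5$ *reported* — removal is an
explicit user action, never automatic. On homogeneous data the
standardized connectivities are approximately normal, so occasional
single-sample flags at $-2.5$ are expected by chance; the flag is a
screen, not a verdict.

# The synthetic-data generator

Validation runs on generated data with known ground truth, emulating the
role of public multi-omics example sets. Each module is driven by one
latent factor $f \sim N(0,1)$ over samples; feature $j$ of the module is
$x_{ij} = \lambda_j f_i + \varepsilon_{ij}$, $\varepsilon \sim N(0,
\sigma^2)$. Loadings are drawn uniformly in $[0.8, 1.2]$ — avoiding
degenerate identical features — then rescaled by a root-finder so the
*expected* within-module correlation hits the configured target (a
consequence worth noting: shrinking $\sigma$ alone does not drive
correlations to 1, because the calibration compensates). Cross-layer
structure is planted by letting modules in different layers share a
group factor: the first member uses it directly, later members mix it
with fresh noise at a configurable correlation. Quantitative traits are
linear in a chosen factor plus noise; qualitative traits threshold a
factor at configured quantiles, which yields controllable point-biserial
effects. Compositional count layers are drawn per sample as multinomial
reads over softmax-transformed latent values. `makeNull()` keeps every
marginal property but makes factors independent across layers and traits
independent of everything, for FDR and type-I error checks.

What the generator does *not* emulate: overdispersed sequencing noise
beyond multinomial sampling, batch effects, heavy-tailed abundance
distributions, or feature-feature structure beyond one factor per
module. Tests passing on these data therefore demonstrate correctness of
the algorithms under the stated factor model, not robustness to every
pathology of real omics data.

# Reference study conditions

Two fixed configurations back the package's validation, chosen once as
realistic desk-scale conditions:

* `referenceSyntheticConfig()` — 3 layers × 150 features over 60
  samples, three planted modules of 40 per layer (30 noise features),
  within-module correlation 0.7, one binary and one quantitative trait
  driven by the first module. Used for module recovery (adjusted Rand
  index vs truth) and scale-free fit checks.
* `sharedFactorSyntheticConfig()` — 3 layers × 60 features over 50
  samples, two modules of 30 per layer; the first modules of two layers
  share a factor at correlation 0.8, which also drives a binary trait.
  Used for cross-layer edge retention and, via `makeNull()`, for the
  empirical FDR of retained edges.

Simulation sizes in the test suite (tens of seeds, hundreds for null
calibration) were sized to keep the whole suite fast while leaving the
pass margins comfortable; `scripts/acceptance.R` re-runs the same
pipeline at 10–50 seeds per quantity.

# Numerical conventions and edge cases

* Correlation p-values are clamped into $(0, 1]$; constant columns yield
  NA correlations, excluded from BH (q computed over the non-NA tests).
* BH is `stats::p.adjust`; hierarchical clustering is `stats::hclust`;
  PCoA is `stats::cmdscale` (whose `add = TRUE` provides the Cailliez
  constant); distances other than Euclidean come from `vegan::vegdist`.
  The package's own Procrustes (needed for the seeded PROTEST scheme
  above) is cross-checked against `vegan::procrustes` in the tests.
* TOM guards against floating-point overshoot by clipping at 1;
  asymmetric input beyond $10^{-10}$ is an error, not silently
  symmetrized.
* Degenerate soft-threshold fits (single occupied degree bin) yield NA
  and are never chosen.
* `detectModules` with `minModuleSize` above the feature count warns and
  returns an all-unassigned partition rather than failing.
* All stochastic routines (generator, permutation tests,
  cross-validation folds) take explicit seeds and are bit-reproducible.

# Known limitations

Block-wise decomposition for very large feature sets (tens of thousands)
is not implemented; the dense TOM is quadratic in features. Consensus
(multi-dataset) networks, more than three layers, constrained ordination
and figure rendering are out of scope: the package emits layout and
driver *tables* (TSV/GraphML) for external plotting.
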