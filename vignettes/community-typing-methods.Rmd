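---
title: "Methods: paired gut-oral community typing, core extraction and pathway projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired gut-oral community typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orogut)
```

## The problem

Gut and oral bacterial communities sampled from the same subjects can be
stratified into a small number of discrete community types — enterotypes
in stool, orotypes in saliva — each dominated by a characteristic driver
genus. Around that typing sit several standard questions: which genera
form a *core microbiome* shared by most subjects at both sites; whether
the same genus co-varies between a subject's gut and mouth; and how the
predicted functional (pathway) content of a community differs between
types. `orogut` implements this whole analysis for paired genus-level
abundance tables, together with a synthetic cohort generator that plants
known structure so every stage can be checked against ground truth.

## The typing engine

Typing operates on relative genus abundances. Each sample is a
probability vector $p_i$ over genera, and the pairwise distance is

$$ d(i, j) = \sqrt{\mathrm{JSD}(p_i', p_j')}, \qquad
   \mathrm{JSD}(p, q) = H\!\left(\tfrac{p+q}{2}\right)
     - \tfrac{H(p) + H(q)}{2}, $$

with Shannon entropy $H$ in nats, so that
$\mathrm{JSD} \in [0, \ln 2]$. Two numerical choices are made here.
First, the square root: JSD itself violates the triangle inequality,
while $\sqrt{\mathrm{JSD}}$ is a true metric, which downstream
clustering and ordination quietly assume. Second, each profile $p'$
receives a pseudocount of $10^{-10}$ and is renormalized before the
entropies are computed; this makes profiles with disjoint support
well-defined (their distance is $\sqrt{\ln 2}$ minus an error far below
any tolerance used in this package) and absorbs rows whose sums fell
slightly below one after abundance filtering.

Before distances are computed, genera whose *mean* relative abundance
across all samples is strictly below `filter_threshold` (default
$10^{-4}$, i.e. 0.01%) are removed as noise. Rows are deliberately
**not** renormalized after this filter: renormalization happens once,
inside the distance layer, so the filter stays side-effect free and the
single renormalization point is auditable. The flag exists because it
is genuinely unknowable from the published description whether the
original workflow renormalized at this point; the difference is below
the filter threshold by construction.

Clustering is k-medoids (PAM). The BUILD phase seeds medoids greedily;
the SWAP phase examines the full medoid/non-medoid exchange
neighbourhood and applies the steepest cost-reducing swap until no
exchange improves the objective. All ties break toward the lowest
sample index, making the fit a deterministic function of the distance
matrix. On very small problems (fewer than 500 candidate medoid sets)
the objective is minimized exactly by enumeration instead — steepest
descent can stall in a swap-stable set that is not globally optimal,
the enumeration is cheaper than SWAP at that scale, and the global
optimum is itself swap-stable, so the fitted object satisfies the same
contract. Cohort-scale fits (n = 83, k ≥ 2) always use BUILD+SWAP.

The number of types $k$ is chosen by the Calinski-Harabasz index over
`k_range` (default 2–6; the search range is a package choice, as no
range is fixed by the underlying literature), computed directly from
distances:

$$ W = \sum_c \frac{1}{2 n_c} \sum_{i, j \in c} d_{ij}^2, \qquad
   T = \frac{1}{2n} \sum_{i,j} d_{ij}^2, \qquad
   CH = \frac{(T - W)/(k - 1)}{W/(n - k)}. $$

For Euclidean distances this equals the classical centroid form, which
is exactly how the implementation is tested. Ties in $CH$ go to the
smaller $k$. One caution worth stating: $CH$ is only a consistent
selector when clusters are not profitably splittable — with very few
points per cluster the within-dispersion of a split can collapse faster
than the $(k-1)$ penalty grows, and the index drifts to larger $k$.
The preset cohorts (28–34 subjects per component) are comfortably in
the consistent regime.

Clustering quality is the mean silhouette width
$s_i = (b_i - a_i)/\max(a_i, b_i)$; members of singleton clusters are
assigned $s_i = 0$ by convention. Its significance comes from a
permutation null: each taxon column is permuted independently across
samples — destroying all inter-taxon structure while preserving every
taxon's marginal — and the *identical* pipeline (distance, PAM over the
full `k_range`, CH selection, mean silhouette) is applied to each null
dataset. The p-value is $(1 + \#\{s_{null} \ge s_{obs}\})/(1 + B)$.
The choice of null model is the package's: the source description says
only that the null models "no clustering", and independent column
permutation is the least structured null that keeps the marginals.
Because rows of a permuted table no longer sum to one, the null path
runs on raw matrices and relies on the distance layer's internal
renormalization. One honest caveat: compositional closure (rows summing
to one) induces weak negative inter-taxon correlation that permutation
destroys, so the test is approximately, not exactly, calibrated — the
acceptance suite bounds its null rejection rate at $\alpha = 0.05$
within $[0.01, 0.12]$ over 200 replicates rather than asserting
exactness.

Between-class analysis (BCA) supports the typing and names the driver
taxa. The implementation eigen-decomposes the class-size-weighted
covariance of the column-centred class means and projects all samples
on the resulting axes (at most $k - 1$); the between-class inertia
ratio reports the share of total inertia carried by the class means.
Centred (not scaled) data is the default, with a `scale` flag, since
the original tooling's choice is not recorded. Drivers are identified
per type as the taxon maximizing mean abundance inside the type minus
mean abundance outside, ties broken lexicographically — at preset
conditions this recovers the planted driver of every component.

Types are named by descending size (`E1..Ek` for gut, `O1..Ok` for
oral); the numbering convention of the original analysis is unstated,
and size order is reproducible and site-symmetric.

## Core microbiome

Prevalence is the fraction of samples with abundance strictly greater
than zero — no detection floor, because none is defined by the source
material. The core filter keeps taxa with prevalence $\ge$ 30%
(inclusive boundary: taxa *below* 30% are the ones attributed to
individual variability, so exactly-30% survives; at $n = 83$ this makes
$25/83 \approx 0.301$ core and $24/83 \approx 0.289$ not). The
cross-site core is the plain set intersection of the per-site cores,
reported in gut-table order. The study this package models reports 154
gut, 60 oral and 63 core taxa — a 63-element core cannot be a subset of
a 60-element oral core, so whatever construction produced those numbers
was not a plain intersection; the intersection is implemented as the
documented, reproducible default and this tension is surfaced here
rather than resolved by guessing.

## Cross-site statistics

Same-taxon coupling is measured per core taxon as the Spearman
correlation between its gut and oral relative abundances across paired
subjects. P-values use the t approximation (adequate at $n$ in the
tens), with Benjamini-Hochberg adjustment across the taxa tested in the
call; taxa constant at either site are reported as missing rather than
silently dropped. Both raw and adjusted p-values are always emitted;
the headline "significant" flag uses BH at 0.05, switchable to raw —
the source material marks significance without naming a correction, so
the conservative choice is the default and both are exported.

The taxon-profile heatmap pipeline treats each taxon-at-a-site as an
object with the paired subjects as coordinates: Euclidean distances
between these profiles, UPGMA (average-linkage) agglomeration, and
export of both the merge list and a Newick tree. Sample-level
ordination uses Bray-Curtis dissimilarity, principal coordinates
(Gower double-centring; axes from positive eigenvalues only, negative
eigenvalues reported), and a one-way PERMANOVA whose pseudo-F is
computed from squared-distance sums with free label permutation — no
strata, since no blocking design is described. Kruskal-Wallis
comparisons (mid-rank ties, $\chi^2_{k-1}$ reference) wrap the standard
implementation; fully constant input returns $H = 0$, $p = 1$ instead
of an error so that pathway screens over many columns never abort.

Correlation heatmaps conflate "correlation" and "distance" in the
source figures; the package exports both the $\rho$ matrix and
$1 - \rho$ explicitly labelled as a correlation-derived distance.

## Functional projection

Full phylogenetic metagenome prediction (ancestral-state
reconstruction, NSTI filtering) is out of scope. The package instead
uses a declared linear surrogate: predicted pathway abundance is
relative taxon abundance times a non-negative taxon-by-pathway
gene-copy matrix, summed over taxa. This keeps every downstream
statistic identical in form to the published workflow — ranking by
$\log_{10}(\text{mean abundance} + \varepsilon)$ with
$\varepsilon = 10^{-12}$ so empty pathways stay finite and last;
Kruskal-Wallis type enrichment with BH control; the representative type
of a significant pathway as the type with maximal mean abundance; and
Spearman taxon-pathway grids — while making the prediction step exact,
linear, and controllable in synthetic data. The gene-copy reference is
user-supplied or generated (`1 + Poisson(2)` copies with a configurable
zero fraction).

## The synthetic cohort generator

The generator exists to give every stage a ground truth. Its defaults
are the study conditions: 83 paired subjects; mean sequencing depth
66,902 reads with negative-binomial variation (size 20 — only the mean
depth is reported for the real cohort, and depth variation is what
makes prevalence filtering non-trivial); three components per site with
drivers Bifidobacterium / Ruminococcus / Prevotella (gut) and
Neisseria / Prevotella / Streptococcus (oral); four cross-site coupled
taxa (Eubacterium_g11, Actinomyces, Atopobium, Enterococcus); a
20-genus universal core block; and a 12-taxon rare block with
per-sample presence probability 0.15 ($< 0.3$, so the 30% prevalence
filter has true negatives by construction).

Per subject and site: component $\sim$ mixture weights; the component's
driver concentration is multiplied by the boost; each coupled taxon's
concentration is multiplied at *both* sites by a shared per-subject
lognormal factor $\exp(\sigma Z)$, which produces positive cross-site
rank correlation without dictating marginals; rare taxa are zeroed by
Bernoulli presence draws; the profile is drawn Dirichlet, depth
negative-binomial, counts multinomial. All randomness flows from one
integer seed through one substream per subject (shared coupling draws)
plus one per subject-site, so output is independent of evaluation
order.

Effect sizes are the one thing the generator cannot take from the
study, which publishes neither mixing proportions nor separations. The
driver boost (15) and coupling strength ($\sigma = 1$) were fixed once
from Dirichlet variance arithmetic — the boosted driver carries roughly
a third of its component's concentration mass, several within-component
standard deviations away from its share elsewhere, and the coupling
signal-to-noise at $\alpha_c = 1.5$ gives cross-site $\rho$ near 0.5 —
so that recovery is achievable but not trivial. They are calibration
constants of the synthetic conditions, not fitted quantities. The
`null-single-component` preset (one component, no boosts, no coupling)
is sized at 40 subjects and 30 taxa: it anchors no study quantity and
exists for repeated-calibration experiments, where hundreds of
replicates of the full select-k pipeline must run.

What the generator does **not** emulate: taxonomic misassignment,
chimeras, read-level error, over-dispersion beyond Dirichlet
multinomial, phylogenetic correlation between genera, and real
covariate structure. Passing tests therefore demonstrate that the
algorithms recover structure of the planted kind at realistic sample
sizes and depths — not that real cohorts contain such structure, nor
that the real effect sizes match.

## Problem sizes and verification scales

The test and acceptance suites run the full preset conditions
(n = 83, 75 gut / 65 oral taxa) for recovery checks over ten seeds;
silhouette-null calibration uses 200 replicates of the null preset with
19 null datasets each (the smallest the test's contract admits, at
which rejection at $\alpha = 0.05$ means the observed silhouette beats
all nulls); PERMANOVA and Kruskal-Wallis calibration use 200–300
replicates at n = 24–30. Exhaustive oracles (brute-force k-medoids,
all-triples triangle inequalities, centroid-form CH) run at n ≤ 20.
These scales are the package's own verification design.

## Known limitations

* The silhouette null test inherits the approximate calibration
  discussed above; treat p-values near the threshold with care.
* The CH index is searched over 2–6 and cannot return "no clustering";
  that judgement belongs to the null test.
* The linear pathway surrogate shares PICRUSt's form, not its
  phylogenetic machinery; absolute pathway inventories from real
  references are out of reach by design.
* BIOM input is accepted read-only and only through the `biomformat`
  package; all other I/O is plain TSV.
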