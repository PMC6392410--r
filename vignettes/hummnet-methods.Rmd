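---
title: "Methods: models, null ensembles and design choices in hummnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, null ensembles and design choices in hummnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hummnet` analyses binary bipartite mutualistic networks between
hummingbird clades and the plant families they use as nectar sources. This
vignette documents the models and procedures, the parameters that matter,
the numerical choices, and what the synthetic-data generator does and does
not emulate — so that a reader can judge what a passing test suite implies
about real data.

## The interaction matrix

The unit of analysis is a qualitative matrix: rows are plant families,
columns are the nine hummingbird clades, and a cell is 1 when at least one
species-level visitation record links the two groups. A single record
suffices; the matrix is deliberately binary because visitation counts
compiled across heterogeneous sources (different sampling effort, duration,
spatial extent) are not comparable, and a quantitative matrix built from
them would mostly encode study design.

Two choices here are easy to miss but shape everything downstream:

* **Native filtering is record-level, not family-level.** When non-native
  plants are excluded, individual records of exotic species are removed
  *before* aggregation. A family with both native and exotic members
  therefore stays in the native matrix, with fewer links; families visited
  only through exotic species drop out entirely. This asymmetry is the
  reason the native matrix can lose whole families and individual links at
  the same time.
* **All-zero rows and columns are dropped at build time.** Degree fits and
  NODF assume positive degrees, and a family that no hummingbird visits is
  not part of the network in any meaningful sense.

Degree ordering sorts rows and columns by descending link count with
alphabetical tie-breaks — ties are arbitrary scientifically, and the
alphabetical rule makes outputs deterministic. Externally supplied
(phylogenetic) orders are validated as exact permutations of the current
labels; tip orders can be read from single-tree Newick files, where the tip
sequence is the left-to-right traversal order and branch lengths are
ignored.

## Connectivity distribution

The cumulative distribution P(k) = Pr(degree ≥ k), pooled over both guilds,
is fitted to three candidate forms:

| model | form | free parameters |
|---|---|---|
| exponential | exp(−k/γ) | γ (rate, links) |
| power law | k^(−γ) | γ (exponent) |
| truncated power law | k^(−γ)·exp(−k/k_c) | γ, k_c (cutoff, links) |

Fitting is nonlinear least squares on the *untransformed* probabilities,
not log–log regression and not maximum likelihood. The objective matters: a
log–log fit would weight the sparse tail heavily, and discrete-power-law
likelihood machinery answers a different question (goodness of a generative
model) than the descriptive curve-comparison intended here. Model selection
uses the least-squares AIC, n·ln(RSS/n) + 2p. Because the truncated power
law nests both alternatives (k_c → ∞ recovers the power law; γ → 0 recovers
the exponential), its RSS is never meaningfully larger, and the 2-point AIC
penalty is what arbitrates. Consequently AIC *ordering* across the three
models is a robust output, while the absolute AIC values depend on the
number of distinct degrees and are not comparable across data sets.

Numerical choices: starting values come from a log–log (or semi-log) slope
with the cutoff started at the largest degree; RSS is floored at 1e−12 so a
numerically perfect fit yields a finite AIC rather than −∞; a
non-convergent model is excluded from selection with a warning rather than
failing the whole analysis.

## Nestedness (NODF)

For an ordered pair of rows (u above v), the pair contributes 0 when
degree(u) ≤ degree(v) — the *decreasing fill* condition, deliberately
strict so equal-degree pairs contribute nothing — and otherwise
100 · |overlap| / degree(v). Column pairs are scored identically;
`nodf_rows`/`nodf_cols` are means over row/column pairs and `nodf_total`
pools all pairs. The strict tie rule is what makes the 2×2 identity matrix
score exactly 0 and a strictly nested triangular matrix score exactly 100.

Two ordering modes are provided because they answer different questions.
*Sorted* mode sorts by degree internally and measures how nested the matrix
can look; it is invariant to any permutation of the input. *Fixed* mode
scores the matrix exactly as ordered — typically a phylogenetic order — and
measures how much of that potential nestedness survives when node positions
are pinned by evolutionary history. Sorting maximises the decreasing-fill
condition, so fixed-order NODF never exceeds sorted NODF; the gap between
the two is the phylogenetic signal in node placement.

## Null ensembles

Three null models differ in what they hold fixed:

* **ER** reassigns the observed number of 1s uniformly over all cells —
  only total fill is conserved. It conserves the exact link count (a
  permutation of the 1s) rather than redrawing each cell Bernoulli(fill),
  so the ensemble is conditioned on the observed sampling intensity.
* **CE** occupies cell (i, j) with probability equal to the arithmetic mean
  of the row and column fill probabilities, ½(r_i/C + c_j/R) — expected
  fill is conserved and occupancy tracks both partners' generalisation.
* **FF** preserves both margin vectors exactly, sampled by curveball
  trades: two rows are picked, their exclusive presences pooled, shuffled
  and dealt back, so the number of elements actually traded is
  hypergeometric *including zero*. (Forcing at least one element to trade
  looks harmless but introduces parity artefacts on small matrices — the
  2×2 checkerboard would deterministically return to its starting state
  after an even number of trades.) The default of 5 × links trades is a
  standard mixing allowance.

ER and CE can produce empty rows or columns, on which NODF is undefined;
such draws are rejected and resampled up to a cap (default 1000), after
which the generator stops with a too-sparse diagnosis. This conditioning
slightly inflates the expected fill of accepted CE draws on sparse
matrices; it is the price of keeping the statistic's domain assumptions
intact, and it is shared by the observed matrix itself (which also has no
empty nodes).

Ensembles report SES = (observed − null mean)/null sd and an upper-tail
empirical p with the add-one correction (1 + #{null ≥ obs})/(1 + n), which
avoids p = 0 artefacts at finite n. A degenerate ensemble (null sd = 0,
e.g. the link count under FF) reports SES = 0 with a warning rather than
NaN. On nested matrices the null means order ER < CE < FF — each model
absorbs more of the observed structure — so the SES shrinks in the same
order; the FF comparison is the conservative one.

## Modularity

Modularity is maximised on the unipartite view of the bipartite graph (one
node per family and clade, one edge per 1-cell) using the Newman–Girvan
index M = Σ_s [l_s/L − (d_s/2L)²]. A bipartite-specific index (Barber's)
is the modern alternative; the unipartite form is retained here because the
surrounding workflow — node roles, ER/FF comparisons — is defined against
it, and the known cost (bipartite graphs cap attainable M) applies equally
to observed and null matrices.

The search is simulated annealing with single-node moves plus one module
merge and one split proposal per temperature, followed by a greedy pass so
the returned partition is a local maximum under single-node moves. The
schedule (initial temperature 1/n, geometric cooling 0.995, n² node
proposals per temperature, stop at 10⁻³ of the initial temperature) is
configurable because annealing quality is a budget choice; on all tested
graphs with ≤ 8 nodes the default schedule matches the exhaustive-partition
optimum exactly. Reproducibility is by seed: the annealing core draws from
R's RNG, so identical seeds give identical partitions on any platform.

Because module labels are arbitrary across runs, consensus membership works
through co-membership frequencies: the reference partition is the
highest-M run; the *core* of a reference module is the subset of its
members never separated from one another in any run (falling back to the
single most stable member when no node is that consistent); and a node is
assigned to its reference module only when its mean co-membership with that
core exceeds the threshold (default 0.9 — the "assigned in > 90 % of runs"
rule). Nodes below threshold stay unassigned rather than being forced into
a module.

Node roles use z (within-module degree, standardized over the module's
members with the sample n−1 standard deviation; z = 0 when the spread is
zero, which covers singleton and degree-uniform modules) and c = 1 −
Σ_t (k_it/k_i)² (among-module connectivity). Quadrants are cut at z = 2.5
and c = 0.62, with the strict inequality on the high side, so a node
sitting exactly on a cutoff takes the lower role. Significance testing
compares the consensus mean M against M maximised on ER and FF null
matrices (best of a configurable number of anneals per null, default 1);
negative SES — the network *less* modular than its nulls, typical of
strongly nested matrices — is reported as such.

## Biogeography and niche conservatism

The per-species table carries three non-exclusive region flags (Nearctic,
Neotropical, Austral), latitudinal and elevational limits (southern
latitudes negative, elevations in metres) and a center of diversification
(North or South America). Species recorded only on oceanic islands can
carry no mainland-region flag at all; such rows stay in the table but are
excluded from region-based summaries' multi-region logic and from the GLMs.
Clade summaries report flag percentages (which can sum past 100 because
the flags overlap), means with sample (n−1) standard deviations, and
clade-level ranges computed as the *difference of the clade means* — not
the mean of per-species ranges, which is a different quantity whenever
limits vary across species.

The niche-conservatism model is a binomial GLM of multi-region occupancy
(success = present in ≥ 2 regions) on the center of diversification or on
clade, with logit (default) or probit link. South America is the reference
level, so the exponentiated center coefficient is directly the odds ratio
for northern versus southern diversification. Single-species clades are
excluded — a one-observation level estimates nothing and destabilises the
fit. Term significance is the likelihood-ratio (deviance-difference)
chi-square; the Wald statistic is also available through the contrast
machinery and typically differs slightly, which is worth remembering when
comparing chi-square values across software. Pairwise clade contrasts are
Wald chi-squares on coefficient differences with Bonferroni correction over
*all* pairs tested (28 for 8 clades); the overdispersion check is the
Pearson chi-square over residual df, flagged above 1.5, with the usual
caveat that a strictly binary response carries little information about
dispersion.

## The synthetic-data generator

`generate_records()` simulates species-level visitation from a
latent-generalism model: species carry scores u_i, v_j ~ N(0, 1) and
interact with probability plogis(α + η(u_i + v_j)); α is calibrated by root
finding so the expected fill matches the target, and realised fills outside
±10 % are rejected and redrawn (exact-fill conditioning would distort the
probabilistic structure). η controls nestedness continuously; with blocks,
between-block probabilities are damped by (1 − block affinity), so affinity
0 means no modular structure and affinity 1 gives disconnected blocks.
Species are assigned to clades and families with heavy-tailed (Zipf-like)
group sizes, every group non-empty.

Defaults emulate the scale of the compiled continental data set this
package is designed around: 292 hummingbird species in 9 clades, 1287 plant
species in 100 families, species-level fill 0.012, η = 2 (which yields the
strongly nested aggregated matrices typical of mutualistic networks).

One emergent property deserves emphasis: **aggregation alone creates
nestedness.** Even with η = 0 — a completely neutral species-level process
— grouping species into heavy-tailed clades and families produces a
clade × family matrix whose degree heterogeneity reads as significant
nestedness against an ER null. The generator's neutrality is therefore
only testable unaggregated (one species per group), and observed
nestedness in aggregated empirical matrices should never be interpreted
without nulls that account for group sizes (CE, FF). The test suite
asserts both sides of this: calibrated ER rejection rates unaggregated,
and positive SES after aggregation.

`generate_biogeo()` draws each species' multi-region success from its
center's colonization odds (defaults near 1.07 vs 0.118, an odds ratio of
about 9), assigns the second region by center (Nearctic for northern,
Austral for southern), and draws latitudinal/elevational limits from
normal distributions with min ≤ max enforced by construction. What it does
*not* emulate: within-clade heterogeneity in the center of diversification,
correlated ranges among related species (no phylogenetic autocorrelation),
island-only species, and any coupling between a species' network degree
and its geographic range. Tests passing on generated tables therefore
validate the estimators' statistical behaviour (calibration, coverage,
power), not the biological realism of any particular data set.

## Stand-in data

The empirical species-level compilation is not redistributable, so
`inst/extdata/` ships synthetic stand-ins (all prefixed `synthetic_`)
constructed to satisfy the published marginal constraints of the compiled
data set: a 9 × 105 matrix with 409 links whose native filter leaves
100 families and 385 links, a 14/36/50 syndrome split, and a 292-species
biogeography table reproducing the per-clade region percentages, the
region-combination counts, the per-clade latitudinal/elevational means and
the niche-conservatism GLM contingency structure. The interaction stand-in
uses an idealised top-k nested backbone; it reproduces counts and degree
profiles faithfully but is *more* regular than real data (its modularity
behaviour, for instance, differs from a realistic nested matrix, which is
why directional modularity checks use generated networks instead).

## Problem sizes and budgets

The test suite runs the heavier stochastic properties at sizes chosen to
balance statistical resolution against runtime: exhaustive modularity
comparisons on 50 random graphs of ≤ 8 nodes, ER type-I calibration over
1000 trials of 99-replicate ensembles on 10 × 8 matrices, FF margin
preservation over 1000 random matrices, confidence-interval coverage over
500 replicates at n = 300 species, and consensus/null modularity on
default-scale generated networks with a shortened annealing schedule
(cooling 0.95). These are the package's own reference sizes; all are
configurable upward.

## Known limitations

* Binary matrices only: no quantitative (weighted) NODF, no Patefield or
  weighted null models.
* Unipartite Newman–Girvan modularity, not Barber's bipartite modularity;
  M values are comparable within this package, not across algorithms.
* The least-squares degree fits are descriptive; they are not a test of
  scale-freeness in the Clauset–Shalizi–Newman sense.
* No fuzzy taxon matching: species labels must map exactly onto the
  supplied clade/family tables.
* No phylogenetic regression; the GLMs treat species as independent, which
  overstates precision in the presence of phylogenetic signal.
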