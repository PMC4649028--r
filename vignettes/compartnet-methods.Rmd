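---
title: "Methods: compartment-resolved co-occurrence networks and Markov-stability clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment-resolved co-occurrence networks and Markov-stability clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compartnet)
```

## The analysis problem

Soil prokaryotic communities are spatially structured at the millimetre
scale: nutrient hotspots such as the rhizosphere (root-influenced soil) and
the drilosphere (earthworm burrow linings) harbour communities distinct
from the oligotrophic bulk soil, and these contrasts change with depth.
`compartnet` implements a complete analysis chain for amplicon OTU tables
from such a design — two depths (topsoil, subsoil) by three compartments
(bulk, drilosphere, rhizosphere) with replicated plots:

1. **Count-level preprocessing** — subsampling all samples to a common read
   depth, relative-abundance closure, the Hellinger transform, adjustment
   by 16S rRNA gene copy numbers per genome, and correction of qPCR totals.
2. **Co-occurrence network inference** — pairwise Spearman correlations on
   relative abundances, with significance assessed against a
   permutation-renormalization null that accounts for compositional
   closure, and conjunctive thresholds (|rho| > 0.6 and p < 0.05).
3. **Community detection** — Markov-stability optimization of the positive
   subgraph across a grid of Markov times, with the community number chosen
   by the longest stable plateau with more than two communities.
4. **Compartment biology** — an intrinsic core microbiome, ternary
   compartment coordinates, attribution of clusters to design cells, and a
   cross-cluster negative-correlation table.
5. **A synthetic-data generator** with planted structure, so that every
   stage is testable against a known truth without any sequencing data.

## Compositionality and the ReBoot-style null

Relative abundances are compositional: because each sample's proportions
sum to one, an increase in any taxon forces all others down, inducing
spurious (mostly negative) correlations. `reboot_pvalues()` estimates, for
every OTU pair, a null distribution that retains this closure effect: in
each iteration every OTU row of the *count* table is independently
permuted across samples, each sample is re-closed to proportions, and the
full Spearman matrix is recomputed. A bootstrap distribution (samples
resampled with replacement, re-closed) is computed alongside and reported
as a per-pair confidence summary.

All correlations are Fisher-z transformed and the default p-value z-scores
the **observed** coefficient against the null:

\[ z = \frac{z_{\mathrm{obs}} - \overline{z}_{\mathrm{null}}}{\mathrm{sd}(z_{\mathrm{null}})}, \qquad p = 2\Phi(-|z|). \]

Two properties drove this convention, both verified by simulation in the
test suite:

* On exchangeable Dirichlet-multinomial tables (no true associations) the
  rejection rate at alpha = 0.05 is close to 0.05, i.e. the test is
  calibrated.
* On a strongly closed table (one dominant OTU, independent small OTUs)
  the null mean tracks the closure-induced negative correlation
  (approximately -0.5 in our simulations), so the spurious negatives that
  a naive Spearman test flags more than half the time are suppressed to
  the nominal level.

An alternative convention, `method = "pooled"`, compares the bootstrap and
null distributions with a pooled variance,
\(z = (\overline{z}_{\mathrm{boot}} - \overline{z}_{\mathrm{null}}) / \sqrt{s^2_{\mathrm{boot}} + s^2_{\mathrm{null}}}\).
It is markedly conservative (measured rejection about 0.008 at a nominal
0.05, the \(\sqrt{2}\) inflation of the denominator), and using the
bootstrap mean in the numerator injects a rank-tie attenuation bias —
bootstrap resampling duplicates samples, ties shrink \(|z_{\mathrm{boot}}|\),
and when the null mean is far from zero this shrinkage masquerades as
signal. We therefore keep it only as an option.

What the null can and cannot absorb: row permutation with re-closure
reproduces *denominator sharing* — the artifact by which two taxa look
correlated only because they are divided by the same fluctuating total.
It cannot reproduce correlations transmitted by a *common factor* (for
example, a highly variable dominant taxon whose blooms suppress everything
else jointly); those are genuine co-variation in the relative data, and no
pairwise permutation scheme can declare them artifacts.

## Markov stability and plateau selection

The positive co-occurrence subgraph (unweighted: one edge per pair above
threshold) is clustered with Markov stability. For adjacency \(A\), degree
\(d\), total weight \(m\) and stationary distribution \(\pi = d/2m\), the
quality of a partition with indicator matrix \(H\) at Markov time \(t\) is
\(R(t, H) = \mathrm{trace}\, H^{\mathsf T} B(t) H\), with

* exponential mode: \(B(t) = \Pi \exp(-t(I - D^{-1}A)) - \pi\pi^{\mathsf T}\),
  computed from one spectral decomposition of \(D^{-1/2} A D^{-1/2}\) and
  reused across the whole time grid;
* linearized mode: \(B(t) = (1-t)\Pi + tA/2m - \pi\pi^{\mathsf T}\), which
  at \(t = 1\) makes \(R\) exactly the Newman–Girvan modularity (asserted
  against igraph's implementation to 1e-12 in the tests).

\(R\) is optimized at each time by a generalized Louvain procedure (greedy
node moves plus aggregation on the dense quality matrix, implemented in
C++), best of `n_restarts = 20` random sweep orders, deterministic under a
seed. Small times fragment the graph, large times coarsen it; the
community number `k(t)` therefore falls with `t`, and `select_partition()`
returns the partition at the midpoint of the longest contiguous run of
grid points with identical `k > 2` whose partitions are mutually
consistent (pairwise variation of information at most `0.05 log n`; VI
guards against label churn at constant `k`). Ties break toward larger `k`,
then smaller `t`.

Numerical and structural choices:

* default time grid: 60 logarithmic points on \([10^{-2}, 10^{2}]\), wide
  enough to bracket both the fragmentation and coarsening regimes of
  networks with tens to hundreds of nodes;
* mode: exponential for graphs up to 2000 nodes, linearized beyond (one
  dense eigendecomposition is cheap at these sizes and the full diffusion
  merges weakly bridged modules later, which stabilizes the plateau);
* nodes without positive edges carry no diffusion process and are set
  aside (they are reported as unconnected); connected components smaller
  than `min_component_size = 4` are also set aside before clustering and
  reported as minor components. The reason is statistical, and it is worth
  stating plainly: with 18 samples, the null tail of Spearman's rho at the
  0.6 threshold is near 1% per pair, so any network over many taxa
  contains a scatter of false dyads and triads. Each such fragment would
  be one extra community at *every* Markov time and the `k > 2` plateau
  rule would track noise rather than structure. A two- or three-node
  fragment cannot express intra- versus inter-module contrast anyway, so
  excluding them loses nothing the selection rule could use.

## The intrinsic core microbiome

An OTU is *core* when (a) it is present (count > 0 after subsampling) in
at least 2 of the 3 biological replicates of **every** depth-by-compartment
cell, and (b) the standard deviation of its relative abundance across all
in-scope samples does not exceed its mean. "Presence" after equal-depth
subsampling keeps the criterion comparable across samples; the sd/mean
screen is evaluated over all samples in scope rather than per cell, which
reads the criterion as "low variation between the samples" overall.
Scoped variants apply the same criteria within one depth. The reported
`fraction_of_reads` is the summed relative abundance of core members on
the evaluated table.

## Ternary coordinates, attribution and negative tables

`ternary_coordinates()` averages relative abundance over each
compartment's replicates (mean before re-closure, so unequal replicate
depths cannot bias a coordinate), re-closes the three compartment means to
barycentric coordinates, and drops OTUs below an absolute-abundance cutoff
(default 5 reads). `attribute_clusters()` scores a community by the summed
relative abundance of its members ("community biomass", not member
counts), averages within each of the six design cells, normalizes, and
attributes the community to the argmax cell, with deterministic
lexicographic tie-breaks and a tie flag; a complete-linkage ordering of
samples by their community profiles is emitted for dendrogram-style
display. `cross_cluster_negative_table()` tallies, for each ordered
cluster pair (X, Y), the OTUs of Y by their number of negative edges into
X; no truncation is applied — ranking is reported and cutoffs are left to
the reader.

## Supporting statistics

Richness, the natural-log Shannon index and analytic rarefaction
(hypergeometric expectation, no Monte Carlo) are delegated to vegan;
per-OTU one-way ANOVA with Tukey HSD and a compact letter display is
Bonferroni-adjusted across the OTUs tested within one factor family;
PerMANOVA on Euclidean distances of Hellinger-transformed abundances is
delegated to vegan's `adonis2` with free permutation of sample labels
(999 by default) and a mandatory seed. The test suite cross-checks the
pseudo-F against a hand-computed decomposition of the distance matrix and
the rarefaction values against the closed-form binomial-coefficient
expression.

## The synthetic generator: what it emulates and what it does not

`synthetic_design()` encodes the study conditions: 18 samples (2 depths x
3 compartments x 3 replicates), read depths near 5000 (drawn uniformly
from 4800–5200, close to typical subsampling minima for bacterial
libraries), four planted clusters of co-occurring OTUs each enriched
8-fold in one home cell, a small stable core, and a large rare background,
with counts drawn from a Dirichlet-multinomial (concentration 200) so that
overdispersion is honest.

The default abundance architecture was chosen to mirror what real tables
of this kind look like once closure is taken seriously, and each choice
has a measurable reason:

* **1000 OTUs, most of them rare.** Real OTU tables are dominated by taxa
  that never reach the network's prevalence filter (6 reads in 3 samples).
  Rare-background parameters (`background_scale = 0.25`, base log-normal
  sd 0.7, per-sample noise sd 0.4) put the background median count near
  0.5, so only a handful of background OTUs pass the filter. This matters
  because OTUs that *barely* pass are sparse (zeros in most samples), and
  sparse rows produce presence-coincidence correlations whose tail the
  permutation null cannot fully absorb; in development runs a bursty
  background (noise sd 0.7–1.0) produced dozens of spurious edges and
  four-node noise components that corrupted the community count.
* **A small abundant stable core** (8 OTUs, roughly half the reads,
  per-sample noise sd 0.6). Someone has to carry the community's mass: if
  the prevalent mass sat in the planted clusters, their 8-fold blooms
  would swing every sample's denominator and imprint a common factor on
  all other taxa. A stable core keeps the denominator calm. The mild
  independent noise on core OTUs is equally deliberate — perfectly
  constant abundant taxa would correlate with each other through whatever
  denominator variation remains.
* **Clusters of 10 OTUs at moderate abundance** (`cluster_scale = 14`,
  shared per-sample log-normal factor sd 1.2 plus the 8-fold home-cell
  effect). This drives within-cluster Spearman correlations to ~0.65–0.75,
  comfortably above the 0.6 edge threshold, while keeping each cluster's
  mass share small enough that its blooms do not couple unrelated taxa.

With these defaults the full pipeline recovers the planted structure —
community number 4 by the plateau rule and adjusted Rand index at least
0.9 against the planted assignment — in 19 of seeds 1–20 and 20 of seeds
21–40; the residual failures are honest tail events (a chance noise
component reaching four nodes, or a chance bridge between two clusters).
The ARI is evaluated over clustered nodes that belong to planted clusters;
background and core OTUs have no planted community, and the few that
attach to a cluster by a chance edge are counted separately.

What the generator does **not** emulate: sequencing error, chimeras, taxa
shared between core and clusters, phylogenetic signal in the taxonomy
(lineages are synthetic labels), depth-dependent library quality, or any
temporal dynamics. Passing the planted-recovery tests therefore shows the
pipeline's inferential machinery is sound under the stated statistical
shape — not that real soil data meet that shape.

## Determinism and degenerate inputs

Every stochastic step (subsampling, ReBoot iterations, Louvain restarts,
permutations, the generator) requires an explicit integer seed and leaves
the caller's RNG stream untouched; two runs of `run_pipeline()` with one
configuration produce byte-identical artifacts. All-zero samples stay
zero with a warning; constant OTU rows have undefined correlations and
never form edges; empty filter results are legal; partitions over
mismatched node sets, depths exceeding sample sums, missing seeds and
missing metadata are errors caught before computation.

## Worked example

A 12-OTU by 18-sample fixture (`worked_micro_example()`, also shipped as
TSV under `inst/extdata/`) is constructed so the filter, core and ternary
outcomes can be checked by hand: exactly OTUs 1–7 survive the default
prevalence filter, OTUs 1–2 form the intrinsic core (joined by OTU 5 in
the topsoil scope), OTU 3 sits at the rhizosphere tip of the ternary
plot, and every sample holds at least 100 reads so the table rarefies to
depth 100.

```{r example}
ex <- worked_micro_example()
otu_ids(prevalence_filter(ex$counts))
core_microbiome(ex$counts, ex$metadata)
```

## Known limitations

* With 18 samples the Spearman null is wide; the rho > 0.6 threshold
  admits roughly 1% of null pairs, so networks over many taxa always
  contain some false edges. The pipeline reports unconnected nodes and
  minor components rather than pretending the network is clean.
* The permutation null corrects denominator sharing only; common-factor
  compositional effects remain in the network and are indistinguishable
  from genuine co-occurrence at the pairwise level.
* The plateau rule assumes the true community structure occupies a wide
  Markov-time range; a bridge between two genuine modules can shift mass
  to a coarser plateau.
* Copy-number adjustment is only as good as the lookup table; the
  nearest-classifiable-level walk falls back to a global average (the
  mandatory `root` entry) for unclassified lineages.
* Archaea and bacteria should be analysed as separate tables with
  separate subsampling depths; the package never merges domains.
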