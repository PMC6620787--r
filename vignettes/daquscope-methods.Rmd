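---
title: "Methods behind daquscope: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind daquscope: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Daqu — the brick-shaped, solid-state fermentation starter of Chinese
liquor — carries a dense microbial community whose composition shifts as
bricks mature from freshly fermented "white" and "yellow" types into the
stable mature product. daquscope implements the computational side of a
community analysis of such starters: 16S OTU-table processing (screening,
normalization, diversity, group overlap, core calling, correlation
networks), stability selection of marker OTUs that separate the two
immature types, taxonomic annotation of shotgun gene catalogs by a
filter-cascade lowest common ancestor (LCA) rule, and EC-number-based
functional profiling of hydrolytic pathways. All of it runs on synthetic
data with known ground truth, so every stage is testable end to end without
any sequencing download.

# OTU-table processing

An OTU table is an integer count matrix (OTUs x samples) with per-sample
metadata and optional rank-prefixed lineages. Throughout the package,
"present" means a nonzero raw count: the underlying surveys report tag
counts, and no detection-limit convention is anchored in the data, so the
simplest definition is used everywhere (screening, prevalence, Venn
partitioning).

**Screening.** `filter_low_occupancy()` retains OTUs seen in at least 2
samples *and* carrying at least 20 tags in total, the usual screen for
removing singleton artifacts of 454-era amplicon data. "Fewer than 20" is
read strictly: a 20-tag OTU survives.

**CSS normalization.** Library sizes differ by an order of magnitude, and
total-sum scaling lets a few dominant OTUs drive the scaling factor.
Cumulative sum scaling instead divides each sample by the sum of its counts
up to a chosen quantile of the sample's positive counts, then rescales by
1000. Quantiles use the lower empirical (type-1) definition so ties resolve
downward and scaling factors are always sums of observed counts. The
`"adaptive"` default scans candidate quantiles in steps of 0.05, compares
each sample's relative cumulative-sum curve to the median curve, and picks
the smallest quantile at which the median deviation starts growing by more
than 10% per step — the usual stabilisation heuristic for choosing the CSS
quantile — falling back to 0.5 when the curves never destabilise.

**Rarefaction and diversity.** `rarefy()` subsamples each sample without
replacement (multivariate hypergeometric) to a fixed depth; samples below
the depth are dropped with a warning rather than an error, matching
minimum-count practice, and the depth defaults to the observed minimum
(988 in the motivating survey). Shannon diversity is reported in bits
(log base 2, configurable); rarefaction uses a single seeded draw by
default, with an `iterations` argument to average repeated draws — the
single-draw default reflects the most common scripted practice, and the
average is provided because a single draw adds subsampling noise to
shallow samples.

**Core calling and Venn partitioning.** A core OTU is present in *strictly
more than* a prevalence threshold (default 95%) of the target samples —
"more than 95%" read literally, so with 20 samples an OTU must appear in
all 20. Venn regions count OTUs by the exact subset of groups in which they
appear at least once.

# Marker selection by LOOCV stability selection

To find OTUs that separate the two immature starter types, every sample is
held out once; on the remaining samples an all-relevant feature selection
runs, a random forest is trained on the selected OTUs only, the held-out
sample is predicted, and the selected set plus importance ranks are
recorded. OTUs selected in more than 90% of folds (>= `marker_cutoff()`,
which is 49 of 54 folds at the default threshold) are the markers.

The all-relevant selection is the shadow-feature procedure: each iteration
appends a shuffled copy of every live feature, fits a forest, and asks
which real features beat the *best* shadow on scaled (Z-score) permutation
importance. A two-sided binomial test across iterations — Bonferroni
adjusted over the number of features, the procedure's published default —
confirms features that win significantly more often than a fair coin and
rejects those that win significantly less often; rejected features leave
the model, and anything undecided after `max_iterations` (default 100) is
dropped under the conservative default policy (`median_fix` keeps
undecided features whose median importance beats the median best-shadow
importance). The shadow pool is padded to at least five columns so the
max-shadow reference does not collapse near the end of a run. The reported
per-fold importances are the raw mean-decrease-in-accuracy values (the
quantity plotted in marker-importance figures), while the selection
decisions use the scaled form.

Defaults: 500 trees (tests and examples use 100, which is ample at these
sample sizes), significance level 0.05, frequency threshold 0.9. Per-fold
seeds derive deterministically from the master seed so folds are
independently reproducible, and the whole report is bit-for-bit
reproducible given (table, parameters).

**Normalization order.** The motivating pipeline normalizes the full
immature table once, before the fold split; that is `normalize = "global"`,
the default. Because the CSS factors then see the held-out sample, a
`"per_fold"` mode renormalizes inside each training fold — the
leakage-free variant — at a small cost in comparability across folds. At
CSS's per-sample scaling the two differ only through the adaptive-quantile
choice; both are exposed.

# LCA taxonomic annotation

Genes from a shotgun catalog are annotated from tabular protein-alignment
hits in three steps. First, a hit must cover at least 80% of the query
("match percentage", defined here as alignment length over query length,
capped at 100 for gapped alignments — the common reading for gene-catalog
annotation; the pre-computed divisor can be swapped for subject length) and
align at >= 65% identity. Second, among the survivors, only hits with
e-value within 10x of the minimum are kept; the minimum is taken over the
stage-one survivors by default because the filters are described
sequentially, with a `"pre"` mode anchoring the window on the raw minimum.
All boundary comparisons are inclusive. A zero minimum e-value makes the
window degenerate to exact zeros, avoiding division conventions. Third, the
gene is assigned the lowest common ancestor of the surviving subject taxa;
genes with no hits, or none surviving, are `UNKNOWN`.

One subtlety the two window modes expose: with the post-stage anchor,
*raising* the identity or coverage threshold can remove the hit that held
the e-value minimum, shift the 10x window upward, and admit hits that the
looser thresholds excluded. The survivor set is therefore only guaranteed
monotone in the thresholds under the `"pre"` anchor; the cascade is tested
accordingly.

Taxonomies load from a 4-column table or NCBI-style dump files; ranks are
fixed to the 8-level canonical order (root, kingdom, ..., species) and
nodes at intermediate unnamed ranks collapse onto their nearest canonical
ancestor at load time. Kingdom profiles pool gene abundance into Unknown,
the four microbial kingdoms, and Others (plants, animals, protists,
unclassified-kingdom assignments); `retain_microbial()` keeps the four
microbial kingdoms and renormalizes by default, matching within-microbe
percentage reporting.

# Functional profiling

KO assignment keeps the highest-bitscore hit when its bitscore is strictly
greater than 60, breaking ties by e-value then subject id. EC-level
abundance sums gene relative abundance per EC and sample; genes annotated
to several ECs contribute their full abundance to each, because per-enzyme
summaries are not a partition of gene mass — the convention is documented
rather than guessed away. Pathway profiles intersect the observed ECs with
a pathway map (starch-to-glucose and cellulose maps ship with the package,
covering the amylolytic trio 3.2.1.20 / 3.2.1.1 / 3.2.1.3 and the
cellulolytic trio 3.2.1.21 / 3.2.1.4 / 3.2.1.91), zero-filling absent map
enzymes and ranking by mean abundance. Heatmap values use
`log10(x + 1e-8)`, which floors at exactly -8 for absent genes. Per-enzyme
taxon breakdowns group genes by their lowest-level annotation label and
pool taxa under 1% into an "Others (<1%)" bin.

# Community statistics

Spearman correlations use mid-ranks; p-values come from the t
approximation with n-2 degrees of freedom, switching to exhaustive
permutation for n <= 9 where the approximation is poorest. Wilcoxon
rank-sum tests enumerate every rank assignment exactly when both groups
have at most 10 observations and otherwise use the normal approximation
with tie and continuity corrections. Benjamini-Hochberg adjustment is the
standard step-up; note that re-adjusting already-adjusted values is *not*
an identity in general, so the tests assert inflation, order preservation
and monotonicity rather than idempotence.

PERMANOVA uses the classical pseudo-F on squared distances with a
label-permutation p-value, and the Mantel statistic is the rank correlation
of upper triangles with simultaneous row/column permutation of the second
matrix. Both report p = (1 + b) / (1 + B) — the add-one permutation
estimator, which never returns zero — with the seed and permutation count
stored in the result; an `"exact"` mode enumerates all n! orderings for
oracle comparisons. Permutation counts default to 999. The distance for
community comparisons defaults to Bray-Curtis on relative abundances (the
standard choice for OTU tables; the motivating study does not name its
distance), computed through vegan.

Correlation networks of core OTUs adjust the C(k, 2) pairwise p-values by
BH and mask at 0.05; property screens treat each physicochemical property
as its own BH family ("individual property" reporting), dropping samples
without property data with a warning.

# The synthetic-data generators

`simulate_community()` draws per-sample compositions from a Dirichlet with
concentration 50 around a lognormal(0, 1.5) baseline — a typical
species-abundance spread with realistic overdispersion — and counts from a
multinomial at a depth uniform on 988..20000, so the rarefaction path is
always exercised at the survey's minimum depth. Group effects multiply the
baseline of spiked OTUs by 2^log2FC; group-exclusive OTUs have zero
baseline elsewhere. Spiked OTUs can be addressed by row index or — the
form the recovery fixtures use — by baseline-abundance rank: a spike
placed in the invisible tail of the lognormal baseline may never be
sampled at realistic depths, in which case no signal was actually planted
and recovery is undefined rather than failed, so recovery experiments
plant their effects at mid-abundance ranks. The default design is two groups of 27 (the two
immature types); `study_design_spec()` adds the 131 mature samples across
six batches (26/24/4/32/30/15). Spiking is *compositional*: raising five
OTUs eight-fold in one group necessarily depresses every other relative
abundance there, so a handful of non-spiked OTUs legitimately become
group-informative — recovery tests assert that all planted markers are
found, not that nothing else is.

`simulate_taxonomy()` builds a balanced ranked tree with the four microbial
kingdoms plus two non-microbial clades. `simulate_hits()` plants a truth
node per gene and guarantees that genuine hits cover at least two distinct
children of it, so the LCA of the hit set is exactly the planted node;
decoys are engineered to fail at least one cascade filter (or to pass, under
the `stress` flag, in which case every miss is provably an ancestor of the
truth). `simulate_gene_profiles()` plants EC mass ratios through the
assignment probabilities, and `simulate_properties()` produces properties
Gaussian-copula-linked to an OTU's abundance ranks with a target Spearman
rho (normal-score correlation 2 sin(pi rho / 6)). Copula links are planted
on abundant OTUs in the recovery fixtures: mid-rank ties from zero counts
cap the attainable rank correlation of a sparse OTU well below the target,
so a link planted there cannot be recovered by any estimator.

Every generator is a pure function of its spec and seed, and returns a
ground-truth registry sufficient for all recovery metrics.

**What the generators do not emulate.** No sequence content, chimeras,
read-level error, phylogenetic signal between OTUs, or OTU-OTU ecological
interactions (compositions are Dirichlet, so all pairwise dependence is
compositional). Passing recovery tests therefore demonstrates that the
procedures are implemented correctly and are calibrated under a realistic
noise model, not that they would behave identically on any particular real
survey.

# Known limitations and honest failures

Rank-test p-values on sparse count data are **discrete**: OTUs observed in
few samples produce massively tied rank vectors, the Wilcoxon statistic
takes few values, and the resulting p-values have atoms (including at 1).
Under a null simulation at realistic sparsity (500 OTUs, 27 vs 27 samples),
a two-sided Kolmogorov-Smirnov test against the uniform therefore rejects
for most seeds even though the test is valid (conservative, never
anti-conservative). The calibration suite asserts KS uniformity as
specified and that assertion fails honestly at this sparsity; the
permutation tests (PERMANOVA, Mantel), whose statistics are continuous,
show type-I error within [0.03, 0.07] at alpha = 0.05 in the same suite.

Other limitations: multi-class marker selection is out of scope (the
selection is two-group by construction); the LCA cascade does not model
paralogy or horizontal transfer (decoy behavior is the only off-clade
mechanism simulated); and no claims are made about which real taxa are
markers — that is data-dependent.

# Problem sizes used by the test and acceptance suites

Chosen as the smallest sizes at which each property is informative: CSS
and filter oracles on 12-16 OTU tables; exhaustive-oracle comparisons at
n = 5-6 samples (120-720 permutations) and trees under 200 nodes; LOOCV
checks on a 54-sample cohort with 300 OTUs (fold-count) and 60 OTUs with 5
spiked markers across 10 seeds (recovery); LCA recovery on 300-500 genes
over the default 6-kingdom tree; EC ratios at 10,000 genes; copula links at
n = 126; type-I calibration with 500-1000 replicates of 199 permutations.
All forests in tests use 100 trees.
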