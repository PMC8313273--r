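---
title: "Methods: compositional networks, co-abundance groups and biomarker screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional networks, co-abundance groups and biomarker screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otunet)
```

# The problem

16S rRNA amplicon surveys deliver an OTU count table whose rows are closed
to a fixed sequencing depth: only relative information survives. Naive
Pearson or Spearman correlations between OTU abundances on such data are
spurious — an increase in one abundant taxon mechanically depresses every
other relative abundance. `otunet` implements an analysis chain built
around estimators that respect this compositionality: SparCC correlation
inference, signed co-occurrence networks with MCODE module detection,
co-abundance groups (CAGs) with permutational validation, the standard
alpha/beta-diversity toolkit with PERMANOVA effect sizes, and a LEfSe-style
discriminant effect-size screen. The motivating application is a porcine
reproduction design — gut microbiota sampled across the four oestrus stages
of a 21-day heat cycle (E1 dioestrus, E2 pro-oestrus, E3 oestrus, E4
metoestrus) and from gilts with a normal heat cycle (NA) versus gilts
failing to enter oestrus (NO) — but every function is generic over a
samples-by-OTUs count matrix.

# SparCC

For `m` OTUs, SparCC works from the log-ratio variation matrix
$T_{ij} = \mathrm{Var}\,[\ln(x_i/x_j)]$, which is invariant to per-sample
totals. Writing $\omega_i$ for the latent (basis) variances,
$T_{ij} = \omega_i + \omega_j - 2\rho_{ij}\sqrt{\omega_i\omega_j}$.
Under the sparsity assumption that most pairs are uncorrelated, summing
over $j$ gives the linear system
$\sum_j T_{ij} = (m-2)\,\omega_i + \sum_j \omega_j$, solved directly; the
correlations follow as
$\hat\rho_{ij} = (\omega_i + \omega_j - T_{ij}) / (2\sqrt{\omega_i\omega_j})$.
Strongly correlated pairs violate the sparsity approximation, so the
strongest pair with $|\hat\rho|$ above an exclusion threshold (default 0.1)
is removed from the system and the variances re-solved, one pair per round,
up to `m %/% 3` rounds. Zeros are handled by drawing fractions from a
per-sample Dirichlet posterior with a uniform pseudocount
(`counts + 1`); the reported estimate is the median over 20 such resamples
(medians, not means, for robustness). These defaults follow the algorithm's
reference implementation; the source study states none of them. Estimates
outside $[-1, 1]$ (possible from the quadratic) are clipped and counted.

Pseudo-p-values (`sparcc_pvalues()`) permute each OTU column independently
across samples — destroying all between-OTU association while preserving
marginals — and recompute the estimate per bootstrap; the two-sided
pseudo-p is `(1 + #{|rho_boot| >= |rho_obs|}) / (1 + n_bootstrap)`. Two
properties of this scheme are worth knowing: because every pair is tested
against the same bootstrap tables, pseudo-p-values are correlated across
pairs (their empirical distribution is much less variable than independent
p-values would be), and column permutation breaks the compositional
row-sum constraint of the original table, which makes the procedure
mildly conservative in the mid-range of the p distribution.

# Co-occurrence networks, stability, complexity, MCODE

Networks connect OTU pairs with $|\hat\rho| > 0.65$ (the threshold is a
parameter; 0.65 is the convention this pipeline reproduces), keeping the
sign as an edge attribute. Two summary statistics have ecological
readings: *stability* is the percentage of negative (competitive) edges,
and *complexity* is the average number of edges per node, `2E/V`. `V`
counts non-isolated nodes by default because unconnected nodes are
conventionally omitted from rendered networks; a switch divides by all
nodes instead.

MCODE (`mcode()`) detects dense modules on the unsigned graph. Each vertex
is weighted by `k * density(k-core)` of its closed neighbourhood's highest
k-core; complexes grow greedily from the highest-weighted unused seed,
admitting neighbours whose weight is at least `(1 - node_score_cutoff)`
times the seed weight (default cutoff 0.2); the haircut step keeps the
2-core, removing singly connected members; modules below 3 members are
dropped and each module is scored `density * size`. Parameters are the
published plugin defaults. Ties in vertex weight are broken by OTU ID, so
the output is deterministic. Because modules are induced subgraphs, every
reported score is bounded by the brute-force maximum of `density * size`
over induced subgraphs — a property the test suite checks exhaustively on
small random graphs.

Module identity across stages is never asserted: the cycle pipeline
reports a Jaccard-overlap matrix between the module sets of different
stages and leaves the reading to the analyst.

PCIT (`pcit_filter()`) is available as an optional edge filter: for every
triad the three first-order partial correlations are computed, the
tolerance is the mean partial/direct ratio, and an edge survives unless it
falls below the tolerance-scaled magnitude of both other edges in some
triad. The default pipeline does not apply it — the network edges are
SparCC magnitudes alone — because combining both filters answers a
different question than either alone. Note the published rule only masks
an indirect edge when the chain is of moderate strength; for a very strong
chain (e.g. direct correlations 0.9, indirect 0.81) the indirect edge stays
within the tolerance and is kept.

# Co-abundance groups

OTUs retained for CAG construction are those with at least one partner at
$\hat\rho > 0.5$. This is deliberately an OTU-retention rule rather than an
edge rule: Ward clustering needs a complete distance matrix over the
retained set, so the full correlation-distance matrix $d = 1 - \hat\rho$
(including sub-threshold entries; negative correlations give $d > 1$,
still a valid dissimilarity) is clustered with `hclust(method = "ward.D2")`
— the modern Ward semantics; `ward.D` is available by flag, as is the
alternative reading that sets sub-threshold distances to 1. The tree is
cut into `n_cags` groups; auto mode scans downward from `max_cags`
(default 40) and returns the largest count at which every multi-member CAG
validates, since no principled selection rule is standard for this
construction.

Validation treats the retained OTUs as observations and their abundance
profiles across samples as the multivariate response: Bray-Curtis
dissimilarities among profiles, PERMANOVA of this-CAG-versus-rest
membership under 999 label permutations, acceptance at p < 0.005. Profiles
are normalised per OTU (each profile sums to one) by default: a
co-abundance group is a claim about the *shape* of co-variation, and
raw-profile Bray-Curtis is dominated by between-OTU abundance-level
offsets — in planted-block simulations the normalised test separates a
tightly co-varying block from null OTUs at the permutation floor while the
raw-profile test does not. `profile_normalise = FALSE` restores the raw
behaviour. Note the permutation floor: a p below `1/(n_perm + 1)` is
impossible, and with very few retained OTUs the number of distinct label
splits (e.g. `choose(10, 5) = 252`) caps the resolution further.

Group differences in per-sample CAG abundance (sum of member relative
abundances) use the two-sided Wilcoxon rank-sum test with no multiplicity
correction by default, reflecting the descriptive, hypothesis-generating
role of the comparison; Benjamini-Hochberg is a flag.

# Diversity and PERMANOVA

Chao1 uses the bias-corrected estimator
$S_{obs} + F_1(F_1 - 1) / (2(F_2 + 1))$, defined even without doubletons;
the classic form is a flag. Shannon entropy is reported in natural-log
units (the convention of the mothur toolchain), base-2 by flag. Faith's PD
is the branch length of the minimal subtree spanning the observed taxa and
the root. Unweighted UniFrac follows the root-to-taxon indicator form:
the branch length seen by exactly one community over the branch length
seen by either. Bray-Curtis is computed on relative abundances by default
so that depth differences do not masquerade as turnover.

PCoA eigendecomposes the Gower-centred $-D^2/2$; negative eigenvalues are
reported but excluded from the variance-explained denominator, and each
axis is oriented with its first nonzero loading positive so ordinations
are reproducible. PERMANOVA (via `vegan::adonis2`) partitions the total
sum of squares sequentially in the user-given factor order — the
convention here is the printed order batch, stage, farm, genetics — with
free permutation of sample labels. Free permutation deliberately ignores
the repeated-measures structure of a cycle design (the same animals
sampled at all four stages), matching the standard `adonis` usage for this
analysis; a restricted within-animal permutation would be the
conservative alternative and can be performed by pre-stratifying the
input. A marginal (`by = "margin"`) mode is provided. Aliased factors and
single-level factors are rejected rather than silently dropped.

The beta-diversity-along-axes question (whether single ordination axes
differ between stages) is exposed as per-axis Kruskal-Wallis on the PCoA
coordinates — an interpretation, labelled as such, since no named test
exists for it.

# Biomarker screening

`lda_effect_size()` follows LEfSe semantics: per-sample rescaling to a
total of $10^6$; a Kruskal-Wallis screen at `alpha = 0.05`; then, over 30
bootstrap iterations subsampling two-thirds of each class, a
ridge-regularised Fisher discriminant on the surviving features. The
per-feature effect size of an iteration is the arithmetic mean of the
feature's contribution to the projected class-mean gap (on the unit
discriminant axis) and the raw class-mean gap, maximised over class pairs
in multi-class designs; the reported score is `log10` of the iteration
mean, floored at 1. Two simplifications are documented rather than hidden:
the subclass (pairwise-Wilcoxon) stage of the original tool is omitted
because the supported designs are one-factor, and numeric parity with the
web tool is not promised — correctness is established by calibration and
recovery properties. The conventional thresholds are `LDA > 2.0` for taxa
and `LDA > 1.0` for predicted-pathway tables (a per-run flag). A feature
constant across samples is assigned p = 1 before rescaling, since
rescaling would re-introduce depth variation into a flat feature.

One behaviour worth understanding when interpreting results: the screen
operates on relative abundances, so planting a large shift on an abundant
feature renormalises every other feature in the opposite direction —
compositional closure makes those echoes real class differences, and the
screen legitimately detects some of them. Calibration statements therefore
compare identically distributed classes.

Pathway-taxon association uses tie-corrected Spearman rank correlation
with the t-approximation p-value, restricted by default to the OTUs the
screen flagged.

# The synthetic-data generator

`simulate_dataset()` emulates the study design the pipeline targets:
a balanced stage-by-group layout (default 22 samples per stage, the
emulated cohort size), each animal sampled at all four stages, with
sample-level batch and animal-level farm/genetics covariates. Counts are
generated from a latent Gaussian log-abundance model — baseline per-OTU
log-means (SD 1.5 across OTUs), per-sample noise (SD 1.0), equi-correlated
block factors for planted co-abundance blocks, a one-period sinusoid over
the four ordered stages for stage-periodic taxa (emulating
rise-to-oestrus-then-fall trajectories), and a signed log2 fold change in
NO samples for group taxa — followed by softmax to a composition and a
Dirichlet-multinomial draw of exactly `depth` reads (default 34,949, the
emulated rarefaction depth). The default overdispersion 1e-4 corresponds
to a Dirichlet concentration of 10,000: mild relative to the read depth,
which keeps planted latent structure recoverable — the regime the
generator's recoverability contract promises (within-block SparCC
estimates clear the 0.65 network threshold at block correlation 0.8 and
depth 20,000). For the same reason planted-structure taxa receive baseline
log-means from the centre of the drawn abundance distribution (by swap, so
the overall distribution is unchanged): recovery tests are meant to
measure the estimators, not read-depth detection limits on accidentally
rare taxa. The tree is a random coalescent (topology and branch lengths
are all that PD/UniFrac consume) and the taxonomy is carved from its
nested clades, so genera and families are monophyletic by construction.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: zero inflation beyond the
Dirichlet-multinomial, phylogenetic signal in abundances (taxonomy and
abundance are independent), batch effects on composition, and uneven
library sizes (rows sum exactly to `depth`, as rarefied data would).

# Numerical choices and problem sizes

Every stochastic function takes an explicit seed and restores the caller's
RNG state; pipeline stages derive child seeds from one master seed so any
stage can be rerun in isolation, and reruns are byte-identical. Vertex-
weight ties in MCODE break by OTU ID; basis variances that solve to
non-positive values are floored at a small positive constant; SparCC
estimates are clipped to $[-1, 1]$ with a diagnostics count; degenerate
inputs (all samples sharing one composition) are rejected on the observed
compositions before Dirichlet resampling, whose noise would otherwise mask
them. The test suite runs its simulations at reduced but informative sizes
chosen once: recovery at 200 samples and depth 20,000; PERMANOVA
calibration over 500 null datasets of 40 samples at 199 permutations
(which resolves the 0.05 level exactly); CAG null calibration over 2,000
random groupings at 399 permutations; screen calibration over 50-100
generator replicates.

# Limitations

SparCC assumes sparsity of true correlations; dense interaction structure
biases the basis-variance solution. The CAG validation PERMANOVA treats
OTUs as exchangeable observations, which ignores phylogenetic relatedness.
LEfSe-style scores are permissive by design (the family-wise rate over
many features is well above per-test alpha). PCIT at O(m^3) is practical
only for the post-filter OTU counts this pipeline produces. The pipelines
analyse one table at a time; meta-analysis across cohorts is out of scope,
as are raw-read processing, OTU picking, taxonomic classification and
functional prediction — the pipeline consumes their outputs.
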