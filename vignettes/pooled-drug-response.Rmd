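---
title: "Models and methods for pooled multi-cell-line drug-response assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for pooled multi-cell-line drug-response assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicpool)
```

# The assay and what this package computes

In a pooled (mosaic-tumor) drug-response experiment, cells from many
genetically distinct cancer models — cell lines, organoids or xenograft
derivatives — are mixed into one 3D culture or flank xenograft, treated
with a drug or vehicle, dissociated, and profiled by droplet single-cell
RNA sequencing. Two identities must be reconstructed per droplet: the
*sample* of origin (which treatment arm/replicate), encoded by hashtag
oligonucleotides (HTOs), and the *line* of origin, encoded by each line's
natural SNPs. Once every cell carries both labels, the pool becomes a
massively internally controlled experiment: a line's share of the pool
under drug versus vehicle is its survival phenotype, its transcriptome the
molecular response, and every line is measured under identical conditions.

`mosaicpool` implements the desk-side analysis of such experiments:

1. **Demultiplexing** (`assign_hash`, `assign_genotype`,
   `assign_clusters_by_pseudobulk`) — sample and line assignment with
   doublet detection.
2. **QC and phenotypes** (`flag_apoptotic`, `score_cell_cycle`,
   `composition_chisq`, `g1_dose_trend`) — apoptotic-state flags and
   cell-cycle composition shifts.
3. **Sensitivity** (`relative_representation`, `relative_survival`,
   `dose_slope`, `balance_seeding`, `mutation_lasso`) — pool-representation
   phenotypes and their genetic correlates.
4. **Heterogeneity** (`gini`, `cluster_shift_z`, `mi_enrichment`) —
   whether survival is confined to transcriptomic subpopulations.
5. **Cross-model differential expression** (`per_line_log2fc`,
   `cross_model_aggregate`, `group_delta`, `geneset_shift_test`,
   `downsample_models`) — treating each line as a biological replicate.
6. **Synergy** (`bliss_expected`, `bliss_from_survival`,
   `phenotype_bliss`, `fit_treatment_model`, `synergy_covariates`) —
   Bliss-independence scoring and gene-level synergy covariates.
7. **CRISPRi screens** (`guide_z`, `normalize_z`, `gene_rho`,
   `rho_group_test`) — guide-to-gene aggregation for pooled knockdown
   screens run against the same drug.

A synthetic-data generator (`simulate_pool`, `simulate_allele_counts`,
`simulate_guide_screen`, `simulate_synergy_pseudobulk`) emulates the
structure of these experiments with known ground truth; every statistical
claim in the test suite and the acceptance script is a recovery or
calibration property measured against that truth.

# Demultiplexing model

## Genotype assignment

Each line's genotype is summarized as an alt-allele dosage
$d_{\ell v} \in \{0, \tfrac12, 1\}$ at biallelic SNP $v$ (uncalled sites
are missing and skipped). A read at $v$ from a cell of line $\ell$ is alt
with probability $p = (1-\varepsilon)d_{\ell v} + \varepsilon(1 -
d_{\ell v})$, where $\varepsilon$ is the per-read error rate (default
0.01, sequencing-error scale). The cell's singlet log-likelihood is the
per-read product over covered variants,

$$\log L(\ell) = \sum_v \big[a_v \log p_{\ell v} + r_v \log(1 - p_{\ell v})\big],$$

with $a_v, r_v$ the alt/ref read counts. The binomial coefficient is
omitted: it is constant across candidate lines and pairs, so posteriors
and argmax calls are unchanged, and the value then equals the brute-force
per-read product that the unit tests enumerate. Doublets are modeled as an
equal mixture of two lines' dosages ($\alpha = 0.5$), i.e.
$d_{(\ell,\ell')v} = (d_{\ell v} + d_{\ell' v})/2$, over all unordered
pairs. The call is the maximum-posterior hypothesis with prior mass
`doublet_prior` (default 0.05) spread over pairs and the rest over
singlets. Cells with fewer than `min_reads = 10` informative reads are
`ambiguous`: below this, posterior margins are noise-dominated in
simulation.

At the assay's operating point (hundreds of SNP panel sites, tens of
informative reads per cell), a single discordant homozygous site
contributes $\approx \log(0.99/0.01) \approx 4.6$ nats, so line calls
separate sharply; heterotypic doublets shift many sites to intermediate
alt fractions that no singlet dosage explains. Homotypic (same-line)
doublets are genotypically invisible by construction; the generator
therefore plants heterotypic doublets, and recall is defined on those —
the standard convention for genotype-based doublet evaluation.

## Hash assignment

The published pipelines in this area use unpublished or tool-internal HTO
classifiers; we re-specify a deterministic, parameter-light rule: HTO
counts are centered-log-ratio transformed within each cell, each channel
is thresholded across cells by a one-dimensional Otsu (between-class
variance) split, and a cell is assigned to its unique positive channel,
called a hash doublet with two or more, and unassigned with none.

## Cluster-to-line mapping

When per-cell assignment is marginal (shallow allele coverage),
expression clusters can be genotyped instead: cluster members' reads are
pooled into per-variant alt fractions and each cluster is assigned the
line with the highest Pearson correlation against the reference dosages.
Ties (identical reference lines) break deterministically by line order
with a warning. Cluster labels are an *input* everywhere in this package —
any clustering may produce them; graph clustering itself is out of scope.

# QC thresholds and cell-cycle scoring

Apoptotic cells are flagged, not removed, by the conventional droplet
thresholds: fewer than 1,000 detected genes, fewer than 2,000 total
counts, or a mitochondrially encoded count fraction above 0.15
(`qc_thresholds()`); flagged-cell counts per condition are themselves a
drug-response phenotype, tested by a two-sided Pearson chi-squared.
Mitochondrially encoded genes are recognized by the `MT-` symbol prefix
(standard human nomenclature) unless an annotation table overrides.

Cell-cycle phases use background-matched geneset scoring on CP10k/log1p
expression: the score is the mean expression of the phase set minus the
mean of a random control set matched by average-expression bin (25 bins,
50 controls per target gene, seeded). G1 is called when both S and G2M
scores are non-positive, otherwise the larger score wins. The gene lists
are configurable — no particular published list is asserted. The
cytostatic phenotype of a targeted inhibitor appears as a dose trend in
the G1 fraction, tested by OLS on log10(dose) with the Pearson-R t test
(vehicle excluded; a vehicle-anchored variant is available).

# Sensitivity phenotypes

Pool construction seeds lines inversely to growth rate
($r = \ln(Y_t/Y_0)/t$) so that days of growth do not collapse the pool
onto its fastest line. "Inverse to growth rate" is ambiguous between
$1/r$ and $e^{-rT}$; `balance_seeding` defaults to $e^{-rT}$ (equal
expected representation at horizon $T$) and offers the literal $1/r$ mode,
which requires all rates positive.

The survival phenotype of line $\ell$ is built from pool fractions:
$f_\ell$ = cells assigned to $\ell$ over the sample total, with a
Haldane–Anscombe pseudocount of 0.5 on zero counts. Relative survival is
$\log_2 (f_\ell^{\mathrm{drug}} / f_\ell^{\mathrm{vehicle}})$, replicate
fractions averaged before the ratio. The dose-slope score regresses
$\log_{10}$ of the dose-to-vehicle representation ratio on
$\log_{10}(\mathrm{dose})$; more negative means more sensitive, and the
one-sided Pearson-R p value points in the depletion direction. Note the
compositional caveat: fractions must sum to 1, so strong depletion of one
line mechanically enriches the others; the planted-truth comparisons in
the tests therefore compute expected fractions, not raw survival, as the
reference.

Mutation association uses an L1-penalized regression of per-line survival
scores on a binary mutation incidence matrix (glmnet), with the penalty
chosen by leave-one-out cross-validation — the right-sized tool for
a ~11-line pool. Mutations carried by fewer than 2 lines are dropped as
unidentifiable.

# Heterogeneity statistics

Survival can be confined to transcriptomic subpopulations. For one line,
each cluster's *relative count* is the treated-cell share of the cluster
normalized by the line's overall treated share; the Gini coefficient
$G = \sum_{ij} |x_i - x_j| / (2 n^2 \bar{x})$ of these relative counts
measures concentration. Significance comes from permuting condition
labels across the line's cells (n_perm = 1,000 by default), which
preserves cluster sizes — the resampling null re-specified here from the
ambiguous "randomly sampled clusters of equal size" wording. Under the
null the z score is calibrated (mean ≈ 0, SD ≈ 1 in 200-simulation
checks); confined survival produces z well above 3. On the original
deposited data this statistic yields values like z ≈ 6.6 for a strongly
heterogeneous line; reproducing any such number requires that dataset and
its exact clustering, so tests assert calibration and power, not
dataset-specific values.

The binning-based enrichment statistic quantizes a continuous per-cell or
per-gene vector into equal-frequency bins (rank-based, stable under ties)
and measures the mutual information (nats) between bin membership and a
binary vector (treated cells; geneset membership), with a permutation z
and per-bin hypergeometric tail p values signed by over/under-
representation. The per-bin p is the single tail in the observed
direction, which is what the exhaustive-enumeration oracle in the tests
computes.

# Cross-model differential expression

Per line, log2 fold change of mean CP10k expression (pseudocount 1)
between arms, with a two-sided Wilcoxon rank-sum p per gene; lines with
fewer than 20 cells in an arm are skipped. Across lines, each line's fold
changes are z-scored (making lines comparable regardless of their
response magnitude) and averaged per gene into a mean difference z. The
bootstrap null resamples genes' line-level z vectors with replacement
(B = 10,000), preserving inter-line correlation; each gene's mean
difference z is t-tested against that distribution two-tailed and
BH-corrected. Whether the original procedure resampled genes or lines is
not stated; gene resampling is the default and line resampling is exposed
via `resample = "lines"`.

Group-specific responses (e.g. 8 mutant vs 2 wild-type lines) are the
per-gene difference of group mean fold changes with a Welch t test.
Geneset shifts are tested two ways — Mann–Whitney U and two-sample t —
against an explicit background (e.g. all non-member genes, or
non-mitochondrial genes when testing mitochondrial sets).

`downsample_models` asks how many models are enough: for each subset size
k it redraws line subsets, reruns the aggregation and geneset tests, and
records median p values; planted shared signals gain significance with k
while random genesets stay flat. For this property to be informative the
planted shift must be weak and heterogeneous enough that small-k subsets
have only partial power — a strong homogeneous shift saturates the rank
test at every k. The acceptance design therefore plants per-line shifts
graded from −0.55 to −0.2 log2 on a 40-gene program.

# Synergy

Bliss independence predicts a combined effect $e_A + e_B - e_A e_B$ for
inhibition-scale effects in [0, 1]; synergy is observed minus expected.
From replicate survival readings, effects are $1 - s/\bar{s}_{\mathrm{ctrl}}$
clamped to [0, 1] (stimulation is reported but excluded from synergy by
default), and the p value is a two-tailed two-sample t of the per-replicate
combination deviation from expectation against the no-drug replicates'
deviation from 1. On phenotypes, the G1-arrest effect is
$\max(0, (G1_c - G1_v)/(1 - G1_v))$ — the arrested share of the
still-cycling pool; a raw-difference variant is exposed because the
normalization choice is not settled.

Gene-level synergy covariates come from negative-binomial pseudobulk
models. Cells are summed per line x condition x replicate; depth enters as
a median-of-ratios size-factor offset; per-gene dispersion is estimated by
method of moments with a 1e-8 floor and no empirical-Bayes shrinkage —
a deliberately simple estimator whose validation is recovery-based
(planted effects are recovered within tolerance; an independent NB GLM fit
cross-checks coefficients in the tests). Models are fit per line with a
condition-group design, which makes each group's coefficient a
one-dimensional NB MLE (vectorized Newton across genes) and matches the
per-line definition of the covariate
$s = (\beta_A + \beta_B) - \beta_{AB}$ on the natural-log scale: the
additive single-agent expectation minus the dual-agent coefficient.
Covariates are averaged across lines, t-tested against a gene-resampling
bootstrap null, standardized into a robust z (median/MAD, so a small
planted tail cannot shift the null), and rank ordered. Because a
*negative* interaction (combination suppressing beyond additivity) makes
$\beta_{AB}$ more negative than the sum, such genes appear at the
*positive* extreme of $s$.

# CRISPRi screen scoring

Per guide, counts are summed within arm and treated-vs-vehicle read
proportions compared by the pooled two-proportion z — the score statistic
of a binomial logit model of per-read arm membership weighted by totals
(the Wald z of the iterative fit coincides with it away from extreme
effects, which the tests verify). Guide z scores are normalized by a
deterministic rank-based inverse-normal transform (Blom offset),
replacing a data-dependent transform selector that would not be
reproducible from its description; the transform is monotone, which is
all the downstream ranking consumes. Per gene, the Stouffer combination
$\rho = \bar{z}\sqrt{k}$ over its k guides gives a two-tailed normal p,
BH-corrected across genes (non-targeting controls are scored but excluded
from the BH family). Annotation groups (protective/sensitizing) are tested
by one-sample t against 0, and screens are compared by two-sample t on
shared genes' $\rho$.

# The synthetic-data generator

`simulate_pool` collapses growth and treatment into per-condition
sampling weights — a line's cell count in a sample is multinomial with
weight $w_\ell \propto \mathrm{base}_\ell \cdot e^{r_\ell t} \cdot
S_\ell(\mathrm{dose})$ — because the assay's readout is end-point
representation, not growth trajectories. Survival follows a Hill form
$S(d) = 1 - \mathrm{maxkill}\cdot d^h/(\mathrm{IC50}^h + d^h)$; the
functional form is a simulator choice, not a claim about any dataset.
Gene counts are negative binomial (global dispersion 0.3 at the
single-cell level) around per-line expression profiles (gamma baseline,
lognormal line effects, ~8% mitochondrial share); planted programs
multiply member-gene expression by $2^{\mathrm{shift}}$ in treated cells,
with the compositional dilution that real UMI data would show (the
naive-recovery test therefore plants programs on mid-expression genes
whose share is small). Doublets sum two distinct lines' draws; apoptotic
cells get ~0.08x library sizes with a 10x mitochondrial share boost so
they cross all three QC thresholds; HTO counts have NB signal/background
structure with a staining-failure rate; allele reads are Poisson-coverage
binomial draws from the line's (or doublet mixture's) dosages. Identical
seeds give identical output.

What the generator does **not** emulate: ambient RNA and index hopping,
batch and chemistry effects, lineage or microenvironment structure,
UMI saturation, cluster-correlated expression programs (ground-truth
cluster labels are sampled independently of expression), and real
genotype linkage disequilibrium. Passing tests therefore demonstrate that
the estimators recover what they claim under the stated noise model —
not that any particular biological dataset is reproduced.

## Problem sizes used in tests and the acceptance script

Chosen as the smallest sizes at which each property is stable: 2,000
cells / 8 lines / 200 SNPs / mean depth 60 for demultiplexing; 5,000
cells per arm for survival recovery (10 lines, planted survival
0.05–1.0) and dose slopes (3 doses x 2 replicates, planted IC50s within
the dose range); 200 null + 100 planted simulations of 400 cells for the
cluster-shift calibration; 2,000 genes / 50 planted interactions / 2
lines x 2 replicates x 100 simulations for synergy covariates; a
492-gene screen (46 protective + 46 sensitizing + 400 null, 5 guides
each, 4 replicates per arm at 5e5 reads, dispersion 0.25, planted
effects graded ±0.25–2.5 log2); 8 lines x 1,200 cells per arm with a
40-gene program at per-line shifts −0.55…−0.2 log2 for cross-model
aggregation and downsampling.

# Numerical choices and degenerate inputs

- Pseudocounts: 0.5 on zero cell counts (fractions/ratios), 1 on CP10k
  means (fold changes).
- Ties: equal-frequency binning and rank INT use stable/average ranking;
  genotype and cluster ties break by line order with a warning.
- Seeding: every stochastic routine takes a seed; permutation and
  bootstrap defaults are 1,000 and 10,000 draws.
- Degenerate inputs error early: all-zero Gini vectors, single clusters,
  empty genesets, zero marginals in contingency tables, vehicle G1
  fraction of 1, non-positive growth inputs.
- `singlet_loglik` returns exactly 0 with no informative evidence; calls
  on such cells are `ambiguous`, never guessed.

# Known limitations

- The NB dispersion estimator is method-of-moments without shrinkage;
  with very few replicates per group, per-gene dispersions are noisy and
  coefficients correspondingly heavier-tailed than a shrunken estimator
  would give. Validation is recovery-based by design.
- Offset invariance of the pseudobulk model is exact only up to the
  likelihood re-weighting that changing one sample's counts implies;
  tests assert near-invariance.
- The compositional nature of pool fractions means absolute survival is
  unidentifiable from representation alone; all scores are relative to
  the pool.
- Genotype demultiplexing assumes the reference panel contains every
  pooled line; contamination by an unreferenced line surfaces as
  ambiguous/doublet calls, not as a named assignment.
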