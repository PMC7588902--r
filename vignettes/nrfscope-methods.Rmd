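---
title: "Methods: defining NRF target gene sets with nrfscope"
author: "nrfscope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: defining NRF target gene sets with nrfscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrfscope)
```

# The scientific problem

The Cap'n'collar transcription factors NRF1 (NFE2L1), NRF2 (NFE2L2) and
NRF3 (NFE2L3) drive overlapping but distinct stress-response programs by
binding antioxidant response elements (AREs) in target-gene loci. A
standard way to define each factor's functional target set is to
overexpress a constitutively active transgene against an empty-vector
control, profile the transcriptome (and proteome), and then harden the
resulting differential calls by intersecting them with an independent
study of the same perturbation and with protein-level concordance.
`nrfscope` implements that analysis pipeline end to end:

1. per-gene Welch differential testing of an RPKM-like abundance matrix;
2. cross-study intersection and fold-change concordance regression;
3. tiered consensus gene sets ("RNA" and "RNA + Protein");
4. gene-set enrichment (running-sum score with a permutation null) and
   hypergeometric over-representation analysis;
5. multi-tissue co-expression coherence of the consensus genes.

Because the original expression matrices live in external repositories,
the package ships a synthetic-data generator that emulates every input
with *planted ground truth*, so the full pipeline runs, and can be
validated quantitatively, with no downloads.

# Differential expression

## Model and test

Each gene is tested between two conditions with the two-sample
**unequal-variance (Welch) t-test**: unpooled group variances,
Welch–Satterthwaite degrees of freedom, two-sided p-value from the t
distribution. Testing is performed on `log2(abundance + pseudocount)`
(pseudocount 1 by default): the log transform stabilizes the variance of
RPKM-like data and makes the test scale consistent with the reported
fold change,

$$\mathrm{log_2FC} = \log_2\frac{\bar{x}_\mathrm{alt} + c}
{\bar{x}_\mathrm{ref} + c},$$

the pseudocounted log-ratio of raw condition means. A gene is called
significant when **p < 0.05 and |log2FC| > 0.075**, both strict
inequalities; these defaults are set in `Thresholds()` and are the
pipeline's operating point throughout. No multiple-testing correction
enters the primary decision rule (the raw-p rule is the
decision rule this pipeline defines); BH-adjusted q-values are reported as an informational
column.

Genes first pass an **active-transcriptome filter**: maximum abundance
across all samples strictly above `minExpression` (default 0, i.e. any
evidence of expression). "Actively transcribed" has no standard
operational definition, so the floor is exposed rather than fixed.

Degenerate genes whose two groups both have zero variance are not
dropped (dropping would misalign output with input); they are tested
with a variance floor of 1e-12 and flagged `degenerate`, which yields
t = 0, p = 1 when the means agree and a decisive p when they differ.

## Small-sample behaviour of the Welch test

With three replicates per arm the Welch–Satterthwaite approximation is
**conservative**: simulating 10,000 null genes (both arms N(0,1), n = 3
vs 3) gives an empirical type-I error near 0.032 at the 0.05 level, and
the null p-value distribution is measurably non-uniform (a
Kolmogorov–Smirnov test against U(0,1) rejects at 10,000 genes). This
is a property of the test itself at triplicate scale, not of the
implementation — `stats::t.test` reproduces it exactly — and the test
suite asserts the honest property (size control, never
anti-conservative) rather than exact nominal calibration. Users should
expect slightly deflated false-positive rates, never inflated ones.

## Comparative Ct

`deltaDeltaCt()` implements qPCR relative quantification:
ΔCt = mean(target Ct) − mean(reference Ct) per condition,
ΔΔCt subtracts the control condition, relative abundance = 2^(−ΔΔCt);
the control maps to 1 by construction.

# Consensus construction

`intersectDE()` intersects the significant calls of the primary study
with a companion differential table, **requiring sign concordance by
default**: a gene up in one study and down in the other carries no
directional evidence and is kept study-specific. The four output sets
(shared up, shared down, A-only, B-only) partition the union of
significant genes. Gene identity is matched on upper-cased symbols with
no alias resolution — both tables are expected to carry official
symbols, and alias mapping would silently import an external database.

`regressFoldChanges()` quantifies concordance by ordinary least squares
of one study's log2 fold changes on the other's, with a free intercept
(forcing the fit through the origin would conflate slope and offset).
r² is reported as the squared Pearson correlation, which is invariant
to which study plays the explanatory role; the slope is not, and both
directions are available by swapping the arguments.

`buildConsensus()` forms the tiers: `rnaUp`/`rnaDown` copied from the
shared sets, and `rnaProtein` restricting their union to genes whose
protein p-value clears the same `pMax` as the RNA tier (a single
significance level is used across both molecular layers) and whose
protein fold change matches the RNA direction. The tiers are nested by
construction and the class validity asserts it on every object.

# Enrichment analysis

## Running-sum enrichment score

`enrichmentScore()` implements the weighted Kolmogorov–Smirnov-style
statistic: walking the ranked list, positions held by set members
increment the running sum by $|r_i|^\alpha / N_R$ (with $N_R$ the sum
of member weights), non-members decrement by $1/(N - N_h)$; the
enrichment score is the signed maximum deviation and the leading edge
contains the members at or before (after, for negative ES) the
extremum. The weight exponent defaults to 1 (the standard weighted
form); 0 gives the classic equal-increment form used by the brute-force
oracle tests.

Numerical tie-break: when the positive and negative extrema of the walk
tie in magnitude — which happens systematically at weight 0, where the
running sum lives on a lattice — the **positive side wins**, with a
1e-12 tolerance that absorbs sub-ulp differences between accumulation
orders. A consequence is that the "reversing the ranking negates the
weight-0 ES" identity holds exactly only when the two extrema do not
tie; the test suite checks the identity off ties and magnitude equality
on them.

Ranking ties are broken lexicographically by gene identifier, so a
ranking is a deterministic function of the metric table.

## Permutation null and NES

`gseaPermutation()` uses **gene-label permutation**: null scores come
from random member sets of the same size drawn from the ranked
universe. Phenotype permutation — the classical default of running-sum
enrichment tools — is unavailable at this design scale: with three
replicates per arm only 20 relabelings exist, which cannot resolve
nominal p-values at the 10^-3 scale enrichment analyses routinely
report. The nominal p-value is sign-stratified and
additively smoothed,

$$p = \frac{1 + \#\{\mathrm{null\ same\ sign},\ |ES_0| \ge |ES|\}}
{1 + \#\{\mathrm{null\ same\ sign}\}},$$

so it is never zero, and the normalized score NES divides the observed
ES by the mean |null ES| of the same sign. FDR machinery across
collections is intentionally out of scope (the pipeline reports
nominal p only).

## Over-representation

`oraTest()` is the DAVID-style term test reduced to its statistical
core: a one-sided hypergeometric upper tail of the query/term overlap
against the background universe, BH-corrected across the supplied
terms. Terms are intersected with the background first; the EASE
variant (subtract one observed success) is exposed as an option and off
by default.

# Tissue co-expression coherence

Per tissue, `correlationMatrix()` computes pairwise Pearson (default;
Spearman exposed) correlations of `log2(abundance + 1)` across donors.
`clusterCorrelationProfiles()` clusters genes on their correlation
profile rows — k-means with 50 random restarts keeping the best
within-cluster sum of squares, or average-linkage hierarchical
clustering cut at k as the alternative, both being standard choices
for correlation-profile grouping; k defaults to 3. The diagonal stays in the profile vectors
(a constant 1 shifts no Euclidean distance between rows). Labels are
renumbered by descending mean intra-cluster correlation so "cluster 1"
is always the most internally coherent group; singleton clusters score
0 (no internal evidence). Clustering runs on the gene-ID-sorted matrix
and maps labels back, making the result exactly equivariant under
permutations of the input gene order.

`classifyCoherence()` operationalizes "correlated / anti-correlated"
membership, a category tissue co-expression tables report without a
standard definition:
the **core cluster** is the most internally coherent one, and each gene
is classified by its mean correlation to the core genes — "correlated"
at or above `tauPos` = 0.3, "anti-correlated" at or below `tauNeg` =
−0.1, otherwise unclassified. The asymmetry is deliberate: genuine
anti-correlation is rarer and weaker than positive co-regulation, so
the negative threshold is lenient. Near the −0.1 boundary, background
genes are occasionally swept in by sampling noise of a mean correlation
(sd ≈ 0.06 at 200 donors and a 25-gene core); this is a property of any
fixed-threshold rule at finite n.

`crossTissueOrder()` reproduces the cross-tissue display logic: genes
are sorted by the reference tissue's clusters (within a cluster, most
representative first), all tissue matrices are re-indexed to that
order, and a long-format assignment table records each gene's cluster
and class per tissue.

# The synthetic-data generator

The generator defines the study conditions the pipeline is validated
under; its defaults are fixed, not tuned per run.

- **Overexpression experiment** (`simulateOverexpression`): triplicates
  per condition; per-gene baseline log2 abundance N(5, 2) (RPKM-like
  values spanning ~1–1000); a `deFraction` = 0.1 of genes carries a
  planted effect of magnitude N(1.5, 0.25) log2 units with
  Bernoulli(0.5) signs (overexpression programs include both induced
  and repressed targets); i.i.d. per-cell log2 noise with sd 0.25. Abundance is
  simulated on the log2 scale and exponentiated, so values are
  positive by construction.
- **Companion study** (`simulateCompanionStudy`): a fraction
  `overlapFraction` of planted genes is reported significant with
  log2FC = true effect + N(0, `fcNoiseSd`); non-detected planted genes
  keep their noisy fold change but draw p ~ U(0.05, 1), so the overlap
  parameter controls the significant-call overlap exactly; null genes
  draw p ~ U(0, 1) with near-zero fold changes; 2% of null genes become
  decoy study-specific calls, emulating the large study-specific
  fringes real cross-study Venn diagrams show.
- **Proteome** (`simulateProteome`): a random `coverage` fraction of
  genes is detected; detected planted genes get protein log2FC =
  attenuation × RNA effect + N(0, `noiseSd`) with a p-value implied by
  the effect size; detected null genes get calibrated uniform
  p-values.
- **Tissue panel** (`simulateTissuePanel`): per tissue, the gene set is
  split 40/30/30% into coherent / anti / background modules; a shared
  donor-level latent factor gets loading +λ (coherent),
  −0.6λ (anti) or 0 (background) with λ = σ√(r/(1−r)), so the expected
  within-coherent-module correlation equals `rWithin`. The anti
  loading multiplier is 0.6 by design: at 1.0 the anti module would be
  exactly as internally coherent as the core module and the
  "most-coherent cluster" rule would be a coin flip, whereas weaker
  coupling of anti-correlated genes both reflects real tissue data and
  keeps the rule well defined. Baselines are N(10, 0.5) — well
  expressed genes, so the downstream log2(x + 1) transform is
  effectively linear and the correlation calibration carries through.
  Module membership is re-drawn per tissue, emulating the observed
  tissue-specific rewiring of co-expression.

Every generator is a pure function of its inputs and one seed (the RNG
state is saved and restored around each call), which is what makes the
end-to-end pipeline bit-reproducible.

What the generator does **not** emulate: library-size and composition
effects, batch structure, count-level (negative-binomial) noise,
correlated gene-gene noise outside the planted modules, missingness
patterns of real TMT proteomics, and covariate structure of real donor
panels. Passing the planted-truth tests therefore demonstrates that the
statistical machinery is correct and calibrated under the declared
model, not that real data meet that model.

# Problem sizes and numerical choices

The validation suite runs the pipeline at desk scale, chosen so each
check exercises the same code paths as a full-size analysis: 5000 genes
× 3 + 3 replicates for differential/consensus recovery; 10,000 null
genes × 3 seeds for test calibration; exhaustive enrichment-score
enumeration over universes of up to 12 genes × all member subsets of
size ≤ 4; 500 random sets × 200 permutations for the permutation-null
calibration; 60 genes × 3 tissues × 200 donors for co-expression
recovery; 20 seeds for attenuation recovery. The headline counts of a
full-size study (tens of thousands of active genes) change runtimes,
not code paths.

Other fixed numerical choices: the variance floor (1e-12) for
zero-variance genes; the ES tie tolerance (1e-12); correlation matrices
are symmetrized as (C + Cᵀ)/2 with the diagonal forced to exactly 1 and
values clamped to [−1, 1] so the symmetry/diagonal invariants hold
exactly, not approximately; k-means uses `iter.max` = 100.

# Known limitations

- The Welch small-sample conservativeness described above.
- The consensus counts of any particular published analysis depend on
  that analysis's exact (unpublished) rule for combining tiers; the
  tiered output makes every candidate rule available rather than
  asserting one.
- Gene matching is symbol-based; cross-study tables using different
  annotation vintages will silently lose renamed genes.
- The permutation null conditions on the observed ranking; it does not
  model inter-gene correlation, which inflates GSEA significance on
  real data (a known property of gene-label permutation).
- The coherence classifier is threshold-based; near-boundary background
  genes are occasionally classified by sampling noise.

# Reproducing a full run

```{r pipeline, eval = FALSE}
cfg <- defaultPipelineConfig()
out <- runPipeline(cfg, "nrfscope-run")
out$manifest$md5[1:3]
```

The manifest records the configuration, per-stage seeds and the MD5
hash of every output file; rerunning with the same configuration
reproduces the hashes exactly.
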