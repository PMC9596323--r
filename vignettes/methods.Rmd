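---
title: "Methods: genome-wide versus MHC diversity in pedigreed cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide versus MHC diversity in pedigreed cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcdiv)
```

# The problem

Mate-choice and heterozygosity–fitness studies often need to know whether
genome-wide genetic diversity predicts diversity at specific functional
loci. The major histocompatibility complex (MHC) is the canonical test
case: it is under strong balancing selection, so an individual's MHC
diversity may decouple from its genome-wide heterozygosity, and dyadic
MHC sharing may decouple from genome-wide kinship. `mhcdiv` implements
the full analysis chain needed to ask these questions in a small
pedigreed cohort genotyped with (a) reduced-representation SNP data and
(b) MHC amplicon sequencing of four loci — class I A and B (195 bp
alpha-1 segments) and class II DQA (188 bp) and DRB (252 bp) — plus a
synthetic-data generator that makes every stage testable without any
external download.

# Amplicon allele calling

MHC loci are multi-gene families: an individual can carry many distinct
sequences per locus, and PCR/sequencing artifacts (point errors and
single-breakpoint chimeras) masquerade as rare alleles. The caller works
on *collapsed pools* (unique sequence, copy number) and applies, in
order:

1. **Locus assignment and length filter.** Each read is assigned to the
   locus of its highest-identity catalog sequence (Hamming identity on
   equal-length sequences); reads equidistant from catalog entries of
   different loci are discarded as unassignable, as are reads whose
   length is not the locus target length. Gapped alignment is
   deliberately out of scope: the amplicons are fixed-length and the
   simulator emits substitution errors only.
2. **Rare k-mer filter.** With a 15 bp scanning window, a sequence is
   removed when it contains 12 or more consecutive window positions
   whose k-mer coverage falls below 15% of the pool's median k-mer
   coverage. *Coverage* of a distinct k-mer is its copy-weighted number
   of occurrences across the pool's unique sequences, and the median is
   taken over distinct k-mers of the pool — this per-k-mer reading makes
   "12 in a row" well defined, whereas a per-read median would not. The
   filter runs per individual pool; chimeras are its intended target,
   because their junction spans a run of k-mers seen nowhere else. A
   pool with a single unique sequence is always kept (its coverage is
   the median).
3. **Read-fraction threshold with rescue.** Per individual and locus,
   sequences comprising at least 5% (inclusive, reading "at minimum 5%"
   literally as `>=`) of the filtered reads are kept. In parallel,
   sequences with strictly more than 1000 copies that exceed 5%
   (strictly) of reads in at least one *other* individual are rescued.
   The two criteria are applied as parallel tests whose union is
   retained; rescued calls are labelled as such. The observed 10–100×
   copy-number drop around the rescue threshold is exposed as a
   diagnostic (`copyNumberDropStat()`), never as a filter.
4. **Classification.** Exact string identity (100% identity, 0 gaps) to
   a catalog sequence of the same locus marks a call as previously
   described; everything else is a new allele with a provisional name
   `{locus}-new-{i}` indexed by lexicographic sequence order within the
   locus across the cohort, so naming is independent of individual and
   read order.

# Genome-wide layer

* **LD pruning** uses sliding windows of 50 sites advanced by 5 sites;
  within a window, one member of every pair with genotype-count
  `r^2 >= 0.5` is removed uniformly at random (seeded). `r^2` is the
  squared Pearson correlation of 0/1/2 codes — the common dialect of
  that pruning flag — not composite-haplotype LD. Monomorphic pairs have
  undefined correlation and are treated as `r^2 = 0`. `ldPruneAudit()`
  re-checks every surviving within-window pair after the fact.
* **stMLH** divides an individual's heterozygous-call proportion by the
  mean cohort heterozygosity of the loci *typed in that individual*
  (Coltman-style), so the statistic degrades gracefully under
  missingness; under complete typing the cohort mean is exactly 1.
* **Kinship** uses the robust between-family estimator built from
  shared-heterozygote, opposite-homozygote and per-individual
  heterozygote counts. It is not mean-centred by construction, but it
  yields negative estimates for pairs less related than a typical pair,
  the behaviour such analyses describe informally as "average kinship
  set to zero"; an explicit centring step is *not* applied, because the
  estimator as published does not include one (an optional flag-free
  centring would change the reported range and is left to the user).
  Positive kinship doubles into relatedness (`r = 2 * phi`); negative
  kinship maps to `r = 0`, matching the published mapping of the
  observed range (−0.21, 0.24) onto (0, 0.48).

# Supertyping

Alleles are translated (per-locus frame offsets; alleles with internal
stop codons are excluded with a warning), and the residues at positively
selected sites (PSS) are described by the five published z-descriptors
(hydrophobicity, steric bulk, polarity, two electronic-effect scales;
shipped as a data file). Class I alleles (A and B) are pooled into one
grouping because the amplicons are equal length and share polymorphism
patterns; DQA and DRB are clustered separately. Because all amplicons in
a grouping are equal-length and gap-free by construction, multiple
sequence alignment reduces to column stacking — a declared
simplification recorded in every run manifest.

Two PSS routes exist. The faithful route is an externally supplied site
list (from codon-model Bayes empirical Bayes inference run outside this
package). The built-in route is a deliberately simple counting screen:
per codon column, synonymous and nonsynonymous differences over all
allele pairs (Nei–Gojobori pathway averaging) are compared against the
column's mutational opportunity with a one-sided binomial test,
BH-corrected at FDR 0.05. It is a screen, not a substitute likelihood
analysis, and the run manifest says so. If neither route yields sites,
all variable columns are used and flagged.

Clustering is average-linkage (UPGMA) on Euclidean distances with a
deterministic tie rule — among equal-distance candidate merges, the pair
whose member labels sort lexicographically smallest merges first — so
dendrograms do not depend on input order. The tree is then cut
adaptively: the sorted merge heights are scanned for their largest gap,
and when that gap exceeds `min_gap_frac` (default 0.2) of the tree
height the tree is cut inside it; otherwise everything is one cluster.
Branches smaller than `min_cluster_size` (default 2) are left
unassigned rather than forced into a supertype. The variant and its
parameters are exposed because the upstream method family offers
several; the largest-gap rule was chosen as the smallest mechanism that
(a) finds *k* well-separated groups for any *k*, (b) returns one
cluster for homogeneous data, and (c) isolates outliers. Its known
limitation: a single global cut resolves only the coarsest separation
scale; nested cluster structure at finer scales is not chased.

# Diversity and complementarity indices

Seven per-individual heterozygosity indices: allele counts per class
(class I = A+B, class II = DQA+DRB), mean pairwise amino-acid
differences among an individual's alleles (class I combined, DQA and
DRB separate — their segments derive from different receptor domains),
and supertype counts per class (class I supertypes live in the combined
A+B universe; DQA and DRB supertype universes are disjoint, so class II
counts add). Four dyadic complementarity indices: shared alleles and
shared supertypes per class, with totals as set unions. Alleles are
compared as called name sets — rescued alleles count like any other —
and amino-acid differences are computed on the amplicon-region
translation only, the only region available.

# Statistical layer

* **Kinship-random-effect LMM** (`lmmKinshipFit()`): `y = Xb + g + e`
  with `cov(g) = sg2 * A`, `A = 2 * phi` off-diagonal and unit diagonal
  (outbred scaling; the diagonal treatment is a package choice since
  the source analysis does not state one). The likelihood is profiled
  over the variance ratio on the eigendecomposition of `A` (one GLS
  solve per candidate ratio), with the ratio-zero boundary checked
  explicitly so degenerate kinship collapses to OLS exactly. ML is the
  default, REML a flag; p-values are Wald z against the normal
  reference, matching the output style of the usual kinship-LMM
  fitters. Non-positive-semidefinite estimated kinship matrices are
  shifted by their smallest eigenvalue, with a warning.
* **Robust Poisson regression** (`robustPoissonFit()`): a
  bounded-influence M-estimator — the maximum-likelihood score is
  replaced by Huber-winsorised Pearson residuals with an analytic
  Fisher-consistency correction (the correction terms have closed
  forms in Poisson cdf/pmf identities; they are unit-tested against
  brute-force summation). The tuning constant defaults to 1.345, the
  classical Huber choice, because the source analysis names the method
  but not the constant; `tuning = Inf` recovers the classical ML fit
  exactly. Standard errors come from the M-estimation sandwich with a
  model-based middle matrix. Dyadic non-independence (each individual
  appears in many dyads) is deliberately not modelled, matching the
  source analysis.
* **Robust Wald test** (`robustWaldTest()`): quadratic form on the
  dropped coefficients and their robust covariance block against
  chi-square — the nested comparison used to test the kinship term.
* **BH correction** delegates to `p.adjust`; **VIF** is `1/(1 - R^2)`
  from each predictor's regression on the others; the **power solver**
  inverts the exact noncentral-F power function (noncentrality
  `f2 * (u + v + 1)`) by root finding, with the boundary `power <=
  alpha` returning zero effect.

`runAssociationModels()` reproduces the three-tier battery: class I
diversity predicting class II diversity (2 mixed models), stMLH
predicting each of the seven MHC indices (7 mixed models,
BH-corrected), and the four dyadic robust Poisson models with robust
Wald tests on kinship (BH-corrected). Constant indices — which small
synthetic cohorts do produce, for instance when every individual
carries every class I supertype — yield `NA` rows rather than
degenerate fits.

# The synthetic-data generator

The generator emulates the study conditions end to end:

* **Pedigree**: founders plus random mating among opposite-sex
  non-siblings of the previous generation (monogamy by default,
  polygyny available), because the real breeding design is unpublished;
  this scheme yields the mix of parent–offspring, half-sib-like and
  unrelated dyads the kinship layer needs to be exercised on. The
  default pipeline cohort (8 founders, two generations of two offspring
  per pair) lands near the 22-individual scale of the motivating study.
* **SNPs**: gene dropping from Hardy–Weinberg founders at MAFs uniform
  on [0.05, 0.5]; LD blocks duplicate one underlying variant per block
  (so pruning has exact structure to find); genotyping error is a
  symmetric single-allele flip, the simplest model that exercises stMLH
  robustness. No recombination map — sites segregate independently.
* **MHC alleles**: per-locus pools (16 A / 32 B / 9 DQA / 27 DRB, the
  observed olive-baboon tallies) built from a shared backbone, a few
  residue-profile centers carrying nonsynonymous substitutions at the
  variable codons (planted supertype structure), silent third-position
  wobble at reserved four-fold-degenerate codons to keep alleles
  distinct, and occasional extra substitutions for within-center
  spread. A configurable fraction (default 0.55, matching the 46/84
  known fraction) forms the reference catalog; the rest surface as
  "new" alleles.
* **Reads**: per-allele depth from a truncated normal law (default mean
  4031, SD 2313 — the reported class I per-allele depth), independent
  per-base substitution errors, and single-breakpoint two-parent
  chimeras, the dominant PCR artifact class. Chimeras of chimeras and
  indel errors are not modelled. FASTQ output uses constant Q35
  qualities; quality trimming is upstream of this package's scope.
* **Dyadic counts**: `Poisson(exp(b0 + bk * phi + bt * total))` per
  dyad, the generative counterpart of the complementarity regressions,
  used for calibration and power checks of the robust layer.

What passing tests on these data do *not* show: robustness to indels,
alignment artifacts, allelic dropout correlated with sequencing depth,
population structure beyond a single pedigree, or real MHC haplotype
architecture (the simulator assembles haplotypes as random allele
multisets, not from observed linkage).

# Numerical choices and problem sizes

Determinism: every stochastic function takes a seed and restores the
caller's RNG state; pipeline stages derive their streams from one
master seed, and a rerun is byte-identical (hashes recorded in
`manifest.json`). Threshold semantics: the 5% read fraction is
inclusive, the 1000-copy and 5%-in-another-individual rescue conditions
are strict, read literally from their descriptions. Ties: equidistant
locus assignment discards the read; equal-distance merges follow the
lexicographic rule. Degenerate inputs: single-sequence pools pass the
k-mer filter; monomorphic alignments yield no PSS; all-identical
z-rows form one supertype; zero or identity kinship collapses the LMM
to OLS; dyads with no shared typed sites get `NA` kinship.

The shipped tests run at deliberately modest sizes — cohorts of 22–48
individuals, 10,000-site genotype matrices for kinship recovery (2,000
unrelated pairs, several hundred parent–offspring dyads), 20 seeded
amplicon cohorts at 1000 reads per allele, and 500-replicate null
calibrations of the robust Wald test — chosen so the whole suite
completes in a few minutes while still pinning each estimator to its
expected behaviour.

# Known limitations

The built-in PSS screen is a counting approximation, not a site-model
likelihood analysis; use an external site list for publication-grade
supertypes. The largest-gap tree cut resolves one scale of cluster
structure. The robust sandwich treats dyads as independent; a dyad
bootstrap would be the next step if calibrated dyadic inference
matters. VCF support covers GT-only biallelic records. The kinship LMM
fits a single genetic variance component; maternal or shared-
environment effects are out of scope.
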