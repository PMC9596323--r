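# mhcdiv

Does genome-wide genetic diversity predict diversity at the genes that
matter? `mhcdiv` is an R package for comparing genome-wide
heterozygosity and kinship with diversity and complementarity at the
major histocompatibility complex (MHC) in small pedigreed cohorts — the
question behind MHC-based mate-choice and heterozygosity–fitness
studies in primates and other vertebrates.

It is aimed at molecular ecologists who have (or want to simulate):

* a biallelic SNP matrix (e.g. from ddRAD genotyping) for a cohort, and
* MHC amplicon sequencing of class I (A, B) and class II (DQA, DRB)
  loci, plus a reference catalog of known alleles.

## What it computes

**MHC genotyping from amplicon read pools.** Locus assignment and
length filtering; a rare k-mer artifact filter (a sequence is removed
when 12 consecutive 15 bp window positions fall below 15% of the pool's
median k-mer coverage); a per-individual read-fraction threshold (keep
sequences at `>= 5%` of filtered reads) with a cross-individual rescue
rule (keep sequences above 1000 copies that exceed 5% of reads in
another individual); and classification of calls as previously
described (exact catalog match) or new.

**Genome-wide summaries.** Sliding-window LD pruning
(`--indep-pairwise`-style: 50-site windows, step 5, remove one of each
pair with r² ≥ 0.5 at random); per-individual heterozygosity and
standardized multilocus heterozygosity,

    stMLH(i) = prop. heterozygous loci in i / mean cohort heterozygosity
               of the loci typed in i   (cohort mean = 1 under complete typing);

KING-robust pairwise kinship,

    phi(i,j) = (N_Aa,Aa − 2·N_AA,aa) / (N_Aa(i) + N_Aa(j)),

and the relatedness transform `r = 2·phi` for positive kinship (0
otherwise).

**Supertyping.** Translation, positively-selected-site screening (or an
external PSS list), z-descriptor matrices over the selected residues,
deterministic average-linkage clustering and an adaptive minimum-size
branch cut.

**Diversity indices.** The seven per-individual MHC heterozygosity
indices (allele counts, mean pairwise amino-acid differences, supertype
counts, per class) and four dyadic complementarity indices (shared
alleles/supertypes per class).

**Statistics.** Kinship-random-effect linear mixed models (profile ML
on the eigendecomposition of 2·kinship), bounded-influence robust
Poisson regression with robust Wald-type nested tests,
Benjamini–Hochberg correction, variance inflation factors, and a
minimum-detectable-effect power solver on the exact noncentral-F
distribution.

**Synthetic data.** A seeded generator for pedigrees, SNP matrices with
LD blocks, MHC allele pools with planted supertype structure, amplicon
reads with sequencing error and PCR chimeras, and Poisson dyad tables —
so the whole pipeline is testable offline.

## Worked example

```r
library(mhcdiv)

cfg <- pipelineConfig(
  sim = simConfig(n_founders = 8, n_generations = 2, n_sites = 5000,
                  ld_block_size = 2),
  mhc = mhcSimSpec(depth_mean = 1000, depth_sd = 0))
res <- runPipeline("example_run", cfg, seed = 42)
rep <- reportRun("example_run")

rep$allele_counts
#>  locus previously_described newly_identified total
#>      A                    5                4     9
#>      B                   11                9    20
#>    DQA                    3                2     5
#>    DRB                    9                8    17
#>    All                   28               23    51
```

The cohort has 18 individuals; 2,223 of 5,000 SNPs survive LD pruning.
Pairwise kinship spans −0.025 to 0.262 (unrelated founders through
parent–offspring dyads), and stMLH spans 0.939–1.041 with mean exactly
1. The allele table separates calls that matched the simulated
reference catalog from newly identified sequences, per locus, with a
column-summing total row.

The dyadic models ask whether genome-wide kinship predicts MHC sharing.
With this seed the class II shared-allele model recovers a strong
kinship effect while the class II shared-supertype model does not:

```r
res$models[res$models$model %in%
             c("shared_alleles_classII", "shared_supertypes_classII"), ]
#>                      model  estimate        se         z           p
#>     shared_alleles_classII 1.4174435 0.4573382 3.0993336 0.001939565
#>  shared_supertypes_classII 0.1422125 0.4778305 0.2976212 0.765992290
#>        p_adj
#>  0.007758261
#>  1.000000000
```

(`p` is the robust Wald-type test of dropping kinship; `p_adj` is
BH-corrected across the four dyadic models.)

A cohort of 22 with one predictor (numerator df 1, denominator df 20)
can detect effects of at least Cohen's f² ≈ 0.39 at 80% power:

```r
round(powerMinEffect(u = 1, v = 20, alpha = 0.05, power = 0.8), 2)
#> [1] 0.39
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/mhcdiv.R` (subcommands `simulate`, `run`, `report`,
`genomewide`, `power`).

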