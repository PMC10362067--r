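---
title: "Gene-usage QTL mapping in IGH: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-usage QTL mapping in IGH: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighqtl)
```

## The problem

The immunoglobulin heavy chain locus (IGH) encodes the V, D and J gene
segments that are somatically joined by V(D)J recombination to form antibody
heavy chains. The fraction of a donor's B cell clones that use a given
germline gene — its *usage* — varies widely between individuals, and much of
that variation tracks germline variation in the locus itself: structural
variants (SVs) that delete or duplicate whole genes, and SNVs that sit in
regulatory elements guiding recombination. `ighqtl` implements a gene-usage
QTL (guQTL) analysis: it quantifies per-gene usage from clone-level
AIRR-seq tables, filters a hemizygosity-aware variant call set to common
variants, tests every gene against every variant with covariate-adjusted
linear and ANOVA models, and follows up with conditional scans, gene-variant
network cliques, regulatory and GWAS-catalog enrichment, coding-allele
linkage and genotype-similarity analyses.

## Usage quantification

Clone tables are reduced to a genes-by-samples count matrix `C`. Four groups
of near-identical duplicated genes are merged into single entities
(IGHV3-23/-23D; IGHV3-30/-30-3/-30-5/-33; IGHV1-69/-69D; IGHD4-4/IGHD4-11),
two genes with unreliable assignments are excluded (IGHD5-5, IGHV3-16),
assignments to genes deleted from both chromosomes of a sample are removed,
and comma-separated multi-assignments are kept only when the genomic data
identify a single present candidate (an equal-split counting mode exists but
is off by default, because only genomically resolvable reassignment has a
defensible justification). Samples need at least 100 reads per isotype and
200 clones. Usage fractions are normalised *within* each segment class —
every clone uses exactly one V, one D and one J gene, so V fractions sum to
1 over V genes, and likewise for D and J. Whole-repertoire normalisation is
available by passing a single-class matrix, but class normalisation is the
default because per-gene usage is reported as a fraction of clones, which is
class-conditional by construction.

## Variant handling

Variants carry diploid, hemizygous or missing calls; hemizygous calls arise
when a heterozygous deletion removes one chromosome's copy of an SNV
position. Common variants are those genotyped in at least 40 individuals
with minor allele frequency at least 0.05; SNVs additionally require an
exact-test Hardy-Weinberg p-value of at least 1e-6, computed on diploid
calls only (hemizygotes are excluded because HWE is defined on diploid
genotype frequencies, and hemizygous loci depart from it by construction).
For regression, hemizygous genotypes are encoded by a "haploid-doubled"
policy — the single allele is the sample's full dosage (0 or 2) — which
preserves the mean-dosage interpretation of the one remaining chromosome; a
categorical encoding is available since the choice is not forced by theory.
Multi-allelic SVs are never dosage-encoded and are tested categorically.

## The association model

For gene *g* and variant *v* the package fits

    usage_g ~ dosage_v + age + platform        (linear regression)
    usage_g ~ genotype_v + age + platform      (ANOVA, categorical genotype)

on pairwise-complete samples, with sequencing platform as a 3-level factor.
Platform enters as a covariate rather than through an upstream batch
correction, which keeps the statistical core self-contained while modelling
the same confounder. Genotype classes with fewer than 3 samples are dropped
from the test and from fold-change groups — the generalisation of excluding
the rare 3-copy-haplotype carriers from the duplication analysis. The
significance gate is the regression p for biallelic variants and the ANOVA p
for multi-allelic ones (both are always reported). Reported effect metrics
are the dosage coefficient, the adjusted R² gained by the genotype term over
the covariate-only model, and the ratio of the larger to the smaller
homozygote-group mean usage (fold change).

Multiple testing is Bonferroni-corrected at the family-wise 0.05 level over
*effective* tests: variants in perfect LD (r² = 1, transitive closure) are
collapsed to a single test. A single global threshold is shared by all genes
(every gene faces the same variant set); per-gene effective counting is
available behind a flag. Co-leads tied at the minimum p — typically a
perfect-LD group — are all reported, with the left-most by locus position
anchoring conditional stratification.

Conditional scans re-run the analysis inside the homozygous-reference and
homozygous-alternate strata of a gene's lead variant, re-applying the
common-variant filters and the LD-collapsed threshold within the stratum;
strata with fewer than 50 individuals are skipped and logged. Both strata
are scanned and reported, since restricting to one is a strictly weaker
analysis.

## Downstream analyses

*Networks.* Genes significantly sharing variants form a graph whose edge
weights count shared variants; edges with weight below 3 ("more than 2"
shared variants) are pruned and maximal cliques enumerated (igraph).
Cliques of size 2 are retained; only singletons are suppressed.

*Enrichment.* Significant SNVs are overlapped with 0-based half-open
feature intervals (cCRE classes, TFBS) and tested per class with a
one-sided Fisher exact test against the background of tested-but-never-
significant SNVs; depletion is never flagged. Class-level p-values are
reported raw, with a Benjamini-Hochberg column for reference only. GWAS
rows with p below 4e-6 are intersected with significant variants by id,
then by position.

*Similarity.* The allele sharing distance between two samples is the mean
over diploid pairwise-complete loci of 2 minus the multiset intersection of
the allele pairs, divided by 2. Sample pairs are binned by ASD quartiles
(the binning rule is a documented choice; the quantile count is
configurable) and the lowest and highest bins' repertoire-wide usage
correlations are compared with a two-sample KS test. The test treats pairs
as independent although they share samples; this mirrors the analysis the
package reproduces and is flagged as a caveat in the output. Both lead-only
and all-significant guQTL genotype sets are analysed.

*Allele linkage.* Coding-allele genotypes (unordered pairs; hemizygous
samples form single-allele classes, preserving the information hemizygosity
carries) are cross-tabulated against lead-guQTL genotypes and tested with
Fisher's exact test — exact up to table totals of 200, seeded Monte-Carlo
(1e5 draws) beyond, with the method recorded, since no exact procedure is
prescribed for large multi-way tables. Novel alleles are accepted when
absent from the database and supported by >= 10 exact-match long reads in
one sample or observed in >= 2 individuals.

## The synthetic cohort generator

The generator exists so that every stage is testable with known ground
truth. It is explicitly a modelling choice, not an empirical claim: the
study it emulates is observational and states no generative model.

A `locus_model` specifies genes, SVs (per-allele gene-to-copy maps and
deleted ranges), SNVs in LD blocks, cis effects, baseline weights,
coding-allele tags and covariate effects. Haplotypes are drawn per block
from a two-haplotype pool, so within-block SNVs are in perfect LD (the
extreme but observed case — published lead sets include 10 SNVs at r² = 1)
and across-block r² is near zero. SV alleles are drawn independently per
stated frequencies. A gene's unnormalised recombination weight in a sample
is

    sum over haplotypes h of: copies(g, h) x baseline(g) x cis multipliers(h, g)
    x platform factor x age factor x lognormal noise

normalised within segment class. Effects are therefore multiplicative on
recombination propensity per haplotype and additive across haplotypes,
which reproduces the additive genotype-to-usage pattern seen for
copy-number series while letting cis effects act on their own chromosome.
Clones are drawn multinomially (V, D and J independently — only marginal
usage is analysed downstream), with negative-binomial clone counts around a
mean of 9,038 per repertoire.

Default conditions (n = 150 diploid individuals): 62 genes (44 V, 12 D,
6 J), three SVs — a 0.30-frequency deletion spanning six D-region genes, an
IGHV3-23D presence/absence event giving merged-entity diploid copy numbers
2-4, and a 3-allele multi-allelic SV over four V genes — about 500 SNVs in
40 blocks, one primary cis effect on IGHV3-66 (multiplier 1.8 per alternate
haplotype) and one secondary effect on IGHD3-3 (1.7) placed *inside* the
deletion's gene set so it is discoverable only by conditional analysis.
The per-sample lognormal noise sd of 0.3 sets genotype-explained variance
for the planted effects in the 0.25-0.75 range, matching the spread of
published lead-variant R² values; the platform batch factors (lognormal sd
0.08 on two of three levels) are deliberately mild so they act as a
recoverable covariate rather than a dominant signal. The IGHV3-23 baseline
weight is calibrated so 2-copy individuals expect 7.4% usage, which under
the additive model implies about 13.8% at 4 copies (the observed series is
quoted as 7.4% to ~13%); the calibration solves the normalisation equation
at the expected weight of the rest of the locus, so realised group means
carry a small upward Jensen shift from the noise term, well within
sampling error at n = 150.

The default model is constructed by a deterministic function
(`default_locus_model()`) rather than shipped as a configuration file: the
function is the single source of truth, and the YAML schema it serialises
to (`write_locus_model()`/`read_locus_model()`, example under
`inst/extdata/`) round-trips byte-identically, which is what a shipped
config would have to guarantee anyway. Master seeds split into per-stage
child seeds by fixed offsets, so haplotypes, covariates, noise and clones
are independently reproducible.

What the generator does *not* emulate: nucleotide sequences, somatic
hypermutation, clonal lineage structure, IgM/IgG selection differences,
ancestry structure, and genuine overdispersion beyond the lognormal noise
term. Passing recovery tests on this cohort therefore demonstrates the
statistical machinery — not that real repertoires satisfy the generative
assumptions.

## Numerical choices

- The HWE test is the exact conditional test computed with a probability
  recurrence over heterozygote counts; ties are included with a 1e-7
  relative tolerance (the standard convention, and the one the
  enumeration oracle in the test suite uses independently).
- Perfect-LD groups use transitive closure with a 1e-12 slack on r² = 1 to
  absorb floating-point rounding of identical dosage vectors.
- p-values are clamped into (0, 1] at the smallest positive double;
  a constant genotype vector is skipped and flagged, and constant usage
  yields beta 0, p 1 by convention.
- Fold change with a zero smaller homozygote mean is reported as Inf and
  flagged rather than silently dropped.
- Coordinates: variant positions are 1-based (VCF), feature intervals
  0-based half-open (BED); the single conversion lives in
  `overlap_variants()` and is tested at both boundary cases.
- Quantile binning of ASD collapses identical breakpoints; a fully
  degenerate ASD distribution is an error rather than a silent 1-bin
  comparison.

## Problem sizes used in the shipped checks

The test-suite recovery studies run the default cohort (n = 150, ~9,000
clones per repertoire) over 20 seeds for lead-variant and conditional
recovery, 20 null cohorts of 200 genes x 500 SNVs for type-I calibration,
50 small null cohorts (60 samples, 60 genes) for the ASD null, and
exhaustive-enumeration oracle comparisons at 100 random instances per
statistic. These sizes are the smallest at which the binomial bounds the
assertions use are meaningful.

## Known limitations

- The background set for enrichment (tested, never-significant variants)
  is a documented choice; the published totals it stands in for do not
  match any single printed variant count, so exact reproduction of those
  totals is out of reach by construction.
- Whether published per-gene guQTL counts tally raw variants or LD groups
  is ambiguous; raw variants are counted.
- Imputation is a frequency-draw stand-in, deliberately simple; it never
  fills positions inside homozygous deletions.
- The KS comparison inherits pair non-independence; its p-values are
  honest only under the same convention used by the analysis it mirrors.
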