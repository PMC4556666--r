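# autozyg

Homozygosity mapping and recessive-variant segregation analysis in
small pedigrees, built around the study design that mapped the feline
congenital myasthenic syndrome of Sphynx and Devon Rex cats to a
*COLQ* missense variant: an affected sib-pair and five close relatives
genotyped on a ~61k SNP array, a shared-homozygosity scan filtered by
the expected carrier status of the relatives, segregation checking of
the candidate variant across an extended family, carrier-frequency
estimation in breed panels, and cross-species conservation analysis of
the substituted residue.

## What it computes

**Shared-homozygosity scan.** With affected individuals
$A_1, \dots, A_k$, a marker is *shared-homozygous* when every affected
with a call is homozygous for the same allele. Maximal runs of such
markers (missing calls neutral, but a run may neither start nor end on
one, and more than `max_missing_run` consecutive missing calls in one
individual break it) with at least `min_markers` signature markers are
candidate autozygous segments.

**Relative-consistency filter.** Under autosomal-recessive
inheritance, an obligate or declared carrier must carry the shared
allele at every signature marker (up to a mismatch `tolerance`) and
must not be homozygous for the whole signature — it would be affected;
an unaffected relative must merely not be homozygous for the whole
signature. Segments are partitioned into `consistent` and `excluded`,
with per-relative verdicts.

**Segregation and carriers.** `classify_compatibility()` scores every
typed individual against its expectation class (affected → hom-alt,
obligate/declared carrier → het, other unaffected → not hom-alt;
parents of affecteds are promoted to obligate carriers automatically),
`concordance()` summarizes the percentage, and `carrier_frequency()`
reports heterozygote percentages with exact Clopper–Pearson 95%
intervals from beta quantiles.

**Variant consequence and conservation.** `map_cdna_variant()` maps a
CDS substitution to its codon and residue change with the standard
genetic code; `pairwise_identity()` computes percent identity under an
explicit, reported method (global identity-scored alignment or a
precomputed alignment, selectable denominator);
`conserved_column_scan()` reports invariant columns — e.g. the
cysteines of the C-terminal cysteine-rich domain — in reference
residue numbering.

**Synthetic data with ground truth.** A gene-dropping simulator
(`simulate_family_dataset()` and the lower-level
`simulate_founder_haplotypes()` / `drop_genes()` /
`implant_recessive_disease()`) generates pedigree SNP genotypes on a
cat-like 18-autosome map under the Haldane map function, implants a
founder-effect recessive mutation on an identical-by-descent founder
segment, and records the true haplotype descent of every allele, so
the whole pipeline is testable by parameter recovery.

## Worked example

```r
library(autozyg)

## segregation of the candidate variant across the 27 genotyped cats
verdicts <- classify_compatibility(segregation_family_pedigree(),
                                   segregation_variant_table())
concordance(verdicts)$percent
#> [1] 100

## carrier percentage in the 81-cat control panel
carrier_frequency(subset(breed_panel_table(), breed == "Control Sphynx"))
#> carriers: 3/81 (3.7%), 95% CI [0.77%, 10.44%]; hom-alt: 0

## protein consequence of the candidate CDS substitution
map_cdna_variant(1190, "G", "A", synthetic_cds(400, 397))
#> c.1190G>A -> p.C397Y: codon 397 (TGC>TAC), C>Y

## map a simulated family: scan, filter, report
fam <- simulate_family_dataset(sim_config(seed = 1))
segs <- shared_homozygosity_scan(fam$genotypes, c("KIT1", "KIT2"))
regions <- apply_consistency_filter(
  segs, fam$genotypes,
  consistency_rules(obligate_carriers = c("SIRE", "DAM"),
                    declared_carriers = "PGM",
                    unaffected_relatives = "KIT3"))
region_report(regions)
#>   chrom  start_bp    end_bp span_bp span_mb n_markers     status
#> 1    C2 136876822 139136963 2260141     2.3        56 consistent
#>                                verdicts
#> 1 SIRE:pass;DAM:pass;PGM:pass;KIT3:pass
```

The reported region is the single segment surviving the filter; it
contains the implanted causal locus (`fam$causal$marker_bp`). The
concordance of 100% says every typed individual matches its
recessive-model expectation; 3.7% is the heterozygote fraction 3/81
with its exact interval.

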