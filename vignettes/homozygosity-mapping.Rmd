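---
title: "Mapping a recessive disease locus in a small pedigree: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive disease locus in a small pedigree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

## The problem

Genome-wide association needs cohorts; a rare recessive disorder in a
closed breed often offers only a sib-pair. Homozygosity mapping turns
that limitation into a design: if the disease allele entered the breed
once (a founder effect), affected animals are homozygous by descent
not just at the causal variant but across the surrounding haplotype,
so the locus sits inside a chromosomal segment where all affecteds are
homozygous for the *same* alleles. With SNP-array genotypes for the
affected sib-pair and a handful of close relatives, two signals
localize the gene:

1. segments of shared homozygosity in the affecteds, and
2. the *consistency* of each segment with what the relatives must be
   under autosomal-recessive inheritance — parents of an affected are
   obligate heterozygotes, a healthy littermate must not carry the
   affected's homozygous signature, and pedigree knowledge may mark
   further animals as carriers.

`autozyg` implements this as an auditable algorithm (the historical
workflow was manual spreadsheet inspection), together with the
downstream checks a candidate variant then faces: segregation
concordance in the extended family, carrier frequency in control
panels, and conservation of the substituted protein residue. The
motivating application is the feline congenital myasthenic syndrome of
the Sphynx and Devon Rex breeds, mapped to a *COLQ* c.1190G>A
(p.C397Y) substitution in the protein's C-terminal cysteine-rich
domain; the bundled fixtures encode that study family and its breed
panels, and the defaults throughout are that study's conditions.

## The scan

A marker is **shared-homozygous** when every affected individual with
a non-missing call is homozygous there, all for the same allele. Any
affected heterozygote, or two affecteds homozygous for opposite
alleles, breaks a run. Missing calls are neutral — they neither
support nor break — with two guards:

* a run may not begin or end on a marker where any affected is
  missing (an unsupported boundary would inflate the segment), and
* more than `max_missing_run` (default 2) consecutive missing calls
  in one affected break the run: a long blind stretch is no evidence
  of continuity.

Maximal surviving runs with at least `min_markers` (default 20)
signature markers are reported. Runs on one chromosome separated by
less than `merge_gap_bp` (default 1 Mb) whose facing signature alleles
agree are merged, treating a short interior break as a genotyping
artifact; merging never crosses chromosomes, and segments sort by
chromosome label (lexicographic) then start. The defaults are design
choices, not estimates: 20 markers at a 61k-array density (about 25
markers/Mb on a 2.4 Gb genome) corresponds to a segment of roughly a
megabase, below which chance homozygosity dominates. Both parameters
are echoed in every report header.

The scan is deliberately rule-based rather than probabilistic — no
hidden-Markov ROH calling, no LD model — because at seven genotyped
animals the relative-consistency filter, not segment statistics,
carries the discriminating information. The test suite pins the scan
to an independent exhaustive window enumeration on matrices up to 30
individuals by 1,000 markers.

## The filter

For each segment, with its per-marker signature alleles:

* an **obligate or declared carrier** fails if (a) at more than
  `tolerance` (default 0) non-missing signature markers it lacks the
  shared allele entirely — i.e. is homozygous for the opposite
  allele — or (b) it is homozygous for the signature at every
  non-missing marker of the segment, which would make it affected;
* an **unaffected relative** fails only under (b).

Rule (a) formalizes "highly probable heterozygous status": array
markers are not all informative, so a carrier is not required to be
heterozygous marker-by-marker, only never to be homozygous for the
non-disease allele at a signature marker. `tolerance` exists because
genotyping error would otherwise exclude true regions; it defaults to
0 and the simulator's error knob (`apply_genotyping_error()`, off by
default) exists precisely so that boundary is testable. A segment is
`consistent` iff every relative passes; verdicts (rule applied,
violation count, first failing marker) are recorded per relative, so
an exclusion is always attributable.

## What the simulator emulates — and what it does not

`simulate_family_dataset()` reproduces the study's data-generating
conditions:

* **Map**: 61,705 biallelic SNPs over the 18 cat autosomes (A1–F2),
  counts proportional to approximate physical chromosome lengths
  (true array densities per chromosome are not published), positions
  uniform; X is excluded since the mapping is autosomal.
* **Founders**: allele frequencies Uniform(0.2, 0.8) per marker,
  mimicking array ascertainment of common SNPs; haplotypes drawn
  independently per marker (no linkage disequilibrium).
* **Transmission**: gene dropping through the three-generation
  pedigree (affected sib-pair, healthy littermate, parents, paternal
  grandparents) with crossovers from the Haldane map function,
  r = (1 − e^(−2d))/2, at a uniform 1 cM/Mb.
* **Founder effect**: the mutation rides on one haplotype of each
  mutation-introducing founder (by default the paternal grandmother
  and the dam), and those haplotypes are made identical by descent
  over a `shared_segment_bp` window (default 4 Mb, matching the
  megabase-scale candidate region such a design detects) around the
  causal locus (default chromosome C2 at 139 Mb). Without this the
  two parental mutant haplotypes would agree only by chance and no
  mappable homozygous region would exist — the founder effect *is*
  the mappability assumption.
* **Ascertainment**: the family is simulated conditionally on its
  recruitment pattern — both kittens of the sib-pair affected,
  everyone else unaffected — by rejection-sampling the causal
  chromosome; all other chromosomes are independent meioses and are
  drawn once. Phenotypes come from true descent: an individual is
  affected iff both haplotypes at the causal marker descend from
  mutation-bearing founder haplotypes, and the truth record keeps
  every allele's origin for parameter-recovery tests.
* **Missingness**: independent per call at 2% (call rates above 95%);
  no marker-level failure mode.

Deliberately absent: coalescent founder ancestry, LD among founder
haplotypes, X-linked inheritance, marker-correlated dropout. The main
consequence is that chance shared homozygosity is rarer in simulation
than in real array data, where LD creates locally identical
haplotypes — real data would show more spurious segments (the
motivating analysis saw six before filtering). Passing recovery tests
therefore demonstrates correctness of the machinery and calibration
under these assumptions, not the empirical false-positive burden of a
real array. The recovery experiment (200 simulated families) checks
that the implanted causal marker lies inside a consistent region in at
least 95% of replicates and that the number of consistent regions
stays in the single digits.

## Segregation, carriers, conservation

Expectation classes are pure functions of pedigree role: affected →
homozygous alternate; obligate carrier (any unaffected parent of an
affected — promoted automatically, since a homozygous-reference parent
of an affected is the informative incompatibility a segregation claim
rests on) and declared carrier → heterozygous; every other unaffected
→ anything but homozygous alternate. An affected with a missing
genotype is `untyped` and leaves the concordance denominator.
Concordance is 100 × compatible/typed, rounded half-up to one decimal.

Carrier frequency is the heterozygote fraction of a panel after
caller-supplied exclusions (the operation never infers relatedness).
The 95% interval is Clopper–Pearson, computed from beta quantiles
(lower = qbeta(α/2, x, n−x+1), upper = qbeta(1−α/2, x+1, n−x)): exact
rather than asymptotic because the counts of interest are tiny (3 of
81). The exact interval is conservative by construction — its true
coverage at small n·p exceeds the nominal 95% — so the calibration
test asserts at-least-nominal coverage on simulated panels.
Homozygous-alternate individuals in a healthy panel are counted and
flagged, never silently dropped.

`map_cdna_variant()` uses the plain standard genetic code (no
initiator-codon or mitochondrial rules) and is pinned against
whole-sequence translation diffing on random coding sequences.
`pairwise_identity()` reports its method because published identity
figures rarely state theirs: mode (global Needleman–Wunsch with
match = 1 / mismatch = 0 and affine gaps, defaults 10/0.5, or a
precomputed alignment) and denominator — full alignment length
including gap columns (default), shorter-sequence length, or gap-free
columns. The three denominators can differ by several points on
diverged proteins; all are first-class options and the choice is
echoed in the result. `conserved_column_scan()` reports columns in
gap-free 1-based reference numbering; a column with any gap is never
conserved. The synthetic ortholog generator gives these operations
exact truths: conserved positions are never mutated, and when a
conserved residue symbol is requested it appears nowhere else in the
reference, so a predicate scan must recover exactly the constructed
columns.

## Numerical and format conventions

* Coordinates are 1-based inclusive bp; region span is end − start
  (boundary difference), reported in Mb rounded half-up to one
  decimal; gene distances use the same boundary arithmetic (0 when
  overlapping), and `gene_overlap()`'s `slop_bp` implements the
  "within the vicinity" rule.
* All percentages round half-up (ties away from zero), so 3.7% means
  3/81 exactly.
* PLINK text round trips: allele symbols per marker are recovered
  from observed calls in sorted order, so the hom-ref/hom-alt coding
  may flip on read while resolved genotypes are preserved; declared
  carrier statuses travel in a side-car TSV (id, status) because
  PLINK has no field for them. Readers reject structural errors
  (ragged rows, duplicate ids, half-missing calls, more than two
  observed alleles) with line or marker references rather than
  repairing silently.
* One global seed fans out to per-stage seeds by stable hashing
  (`derive_seed()`), so any stage can be rerun in isolation and
  byte-identical outputs imply identical inputs, configuration and
  seed; the pipeline manifest hash covers settings and outputs but
  not the output directory.

## Problem sizes used by the test suite

Chosen so the full suite stays comfortably interactive: the oracle
equivalence runs on matrices up to 30 × 1,000 plus a spread of smaller
random cases; the recovery experiment simulates 200 full-size
(61,705-marker) families; interval calibration uses 2,000 simulated
81-cat panels; the translation-diff property uses 300 random coding
sequences. The bundled demo pipeline runs at 12,000 markers — about a
fifth of array density — with `min_markers` scaled down to 8
accordingly; the full-density scan default remains 20.

## Known limitations

* The filter models exactly the three relative roles above; more
  distant constraints (e.g. grandparental phase) are not used.
* Merging compares only the facing signature alleles of adjacent
  segments; it cannot distinguish a genotyping artifact from a true
  double recombinant, which at these marker densities is acceptable
  but worth remembering at higher densities.
* Percent identity between distant orthologs depends on alignment
  parameters; the operation reports its own settings rather than
  asserting comparability with any published figure.
* Carrier-frequency exclusions are the caller's responsibility;
  first-degree-relative lists must be supplied, not inferred.
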