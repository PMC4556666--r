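#' Extended family pedigree for the segregation cohort
#'
#' The 27 genotyped cats plus the four untyped dams of the half-sib
#' litters: the affected Sphynx sib-pair and their relatives (parents,
#' paternal grandparents, four healthy littermates, three sisters of the
#' sire, thirteen paternal half-sibs) and an unrelated affected Devon
#' Rex. The paternal grandmother carries a declared-carrier status (her
#' heterozygosity is inferred from the pedigree, not directly from an
#' affected offspring in the genotyped set).
#'
#' @return a `pedigree` of 31 individuals (27 genotyped + 4 untyped
#'   dams).
#' @export
segregation_family_pedigree <- function() {
  half_dams <- paste0("HDAM", 1:4)
  hs <- sprintf("HS%02d", 1:13)
  hs_dam <- rep(half_dams, c(4L, 3L, 3L, 3L))
  pedigree(
    id = c("PGF", "PGM", "DAM", half_dams, "SIRE",
           paste0("AUNT", 1:3), "AFF1", "AFF2",
           paste0("SIB", 1:4), hs, "AFFDR"),
    sire = c(NA, NA, NA, NA, NA, NA, NA, "PGF",
             rep("PGF", 3L), rep("SIRE", 2L),
             rep("SIRE", 4L), rep("SIRE", 13L), NA),
    dam = c(NA, NA, NA, NA, NA, NA, NA, "PGM",
            rep("PGM", 3L), rep("DAM", 2L),
            rep("DAM", 4L), hs_dam, NA),
    sex = c("male", "female", "female", rep("female", 4L), "male",
            rep("female", 3L), "male", "female",
            rep("unknown", 4L), rep("unknown", 13L), "female"),
    phenotype = c(rep("unaffected", 8L), rep("unaffected", 3L),
                  "affected", "affected", rep("unaffected", 4L),
                  rep("unaffected", 13L), "affected"),
    status = c("none", "declared_carrier", rep("none", 29L))
  )
}

#' Genotyped-relatives variant table
#'
#' The 27 genotyped individuals of the segregation cohort with their
#' c.1190G>A genotypes: 3 affected A/A (the Sphynx sib-pair and the
#' Devon Rex case), both parents and the paternal grandmother G/A, the
#' paternal grandfather G/G, the four healthy littermates G/A, the
#' sire's sisters 1 G/A + 2 G/G, and the thirteen half-sibs 7 G/A +
#' 6 G/G — totals 9 G/G, 15 G/A, 3 A/A.
#'
#' @return a `variant_table` of 27 individuals.
#' @export
segregation_variant_table <- function() {
  variant_table(
    individual = c("AFF1", "AFF2", "AFFDR", "SIRE", "DAM", "PGM", "PGF",
                   paste0("SIB", 1:4), paste0("AUNT", 1:3),
                   sprintf("HS%02d", 1:13)),
    genotype = c("A/A", "A/A", "A/A", "G/A", "G/A", "G/A", "G/G",
                 rep("G/A", 4L), c("G/A", "G/G", "G/G"),
                 c(rep("G/A", 7L), rep("G/G", 6L))),
    breed = c(rep("Sphynx", 2L), "Devon Rex", rep("Sphynx", 24L)),
    ref = "G", alt = "A", variant_id = "c.1190G>A"
  )
}

#' Breed-panel genotype counts
#'
#' Control panels for 14 breeds (306 cats): the Sphynx subpanel carries
#' 3 heterozygotes out of 81; every other breed is homozygous
#' reference.
#'
#' @return data.frame with breed, n_hom_ref, n_het, n_hom_alt.
#' @export
breed_panel_counts <- function() {
  data.frame(
    breed = c("Control Sphynx", "Control Devon Rex",
              "Siamese & Oriental SH and LH", "Persian",
              "British SH and LH", "Birman", "Ragdoll",
              "Norwegian Forest", "Maine Coon", "Chartreux", "Bengal",
              "Abyssinian", "Russian Blue", "Outbred domestic shorthair"),
    n_hom_ref = c(78L, 14L, 22L, 20L, 20L, 27L, 10L, 22L, 21L, 16L,
                  15L, 7L, 4L, 27L),
    n_het = c(3L, rep(0L, 13L)),
    n_hom_alt = rep(0L, 14L),
    stringsAsFactors = FALSE
  )
}

#' Expand breed-panel counts to a per-individual variant table
#'
#' @param counts a counts table as from [breed_panel_counts()].
#' @return a `variant_table` with one row per panel cat.
#' @export
breed_panel_table <- function(counts = breed_panel_counts()) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$n_hom_ref[i] + counts$n_het[i] + counts$n_hom_alt[i]
    data.frame(
      individual = sprintf("%s_%03d",
                           gsub("[^A-Za-z0-9]", "", counts$breed[i]),
                           seq_len(n)),
      breed = counts$breed[i],
      genotype = rep(c("G/G", "G/A", "A/A"),
                     c(counts$n_hom_ref[i], counts$n_het[i],
                       counts$n_hom_alt[i])),
      stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  variant_table(all$individual, all$genotype, breed = all$breed,
                ref = "G", alt = "A", variant_id = "c.1190G>A")
}

#' Synthetic CDS carrying a TGC codon at a given residue
#'
#' Builds a deterministic in-frame coding sequence (ATG start, no
#' internal stops) whose stated codon is TGC (cysteine), for exercising
#' CDS-to-protein variant mapping at positions like c.1190.
#'
#' @param n_codons total codons (default 400).
#' @param cys_codon_index codon set to TGC (default 397).
#' @return a single character string of length 3 * n_codons.
#' @export
synthetic_cds <- function(n_codons = 400L, cys_codon_index = 397L) {
  if (cys_codon_index > n_codons) stop_input("cysteine codon beyond CDS")
  fill <- c("GCT", "GAA", "CTG", "AAA", "GAT", "TTC", "GGT", "CAT")
  codons <- rep_len(fill, n_codons)
  codons[1L] <- "ATG"
  codons[cys_codon_index] <- "TGC"
  paste(codons, collapse = "")
}

#' Write the bundled fixtures to disk
#'
#' Materializes the study fixtures and a small synthetic array dataset:
#' the segregation cohort (pedigree + 27-cat variant TSV), the breed
#' panels (306-cat TSV), a gene-dropped 7-individual PLINK dataset with
#' an implanted recessive locus, and a synthetic ortholog FASTA bundle
#' with ten invariant cysteines in the 375-451 window.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the synthetic parts.
#' @param n_markers marker count of the synthetic array dataset.
#' @return invisibly, named character vector of the files written.
#' @export
make_fixtures <- function(out_dir, seed = 1L, n_markers = 12000L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()

  tab1 <- segregation_variant_table()
  p1 <- file.path(out_dir, "segregation_cohort.tsv")
  write_variant_table(tab1, p1)
  ped <- segregation_family_pedigree()
  p2 <- file.path(out_dir, "segregation_pedigree.tsv")
  utils::write.table(as.data.frame(ped), p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p3 <- file.path(out_dir, "breed_panels.tsv")
  write_variant_table(breed_panel_table(), p3)

  cfg <- sim_config(n_markers = n_markers, seed = seed)
  fam <- simulate_family_dataset(cfg)
  p4 <- write_plink(fam$ped, fam$genotypes,
                    file.path(out_dir, "synthetic_family"))

  cys <- c(375L, 381L, 397L, 400L, 405L, 412L, 423L, 431L, 440L, 451L)
  orth <- generate_ortholog_set(
    reference_length = 455L, n_species = 8L, conserved_positions = cys,
    divergence = 0.13, seed = derive_seed(seed, "orthologs"),
    conserved_residue = "C",
    species_names = c("ref_species", paste0("ortholog_", 1:7)))
  p5 <- file.path(out_dir, "synthetic_orthologs.fasta")
  write_fasta(orth, p5)

  invisible(c(segregation_cohort = p1, segregation_pedigree = p2,
              breed_panels = p3, stats::setNames(p4, rep("plink", length(p4))),
              orthologs = p5))
}
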