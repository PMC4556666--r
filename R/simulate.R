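#' Simulate founder haplotypes
#'
#' Draws two haplotypes per founder; at each marker, allele1 is carried
#' with its stated frequency, independently across markers and haplotypes
#' (no linkage disequilibrium among founder haplotypes).
#'
#' @param map a `marker_map`.
#' @param freqs per-marker allele1 frequency, all in (0,1); recycled.
#' @param n_founders number of founders (>= 2) — ignored if `ids` given.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param ids founder ids; defaults to F1..Fn.
#' @return integer matrix (2 rows per founder, named "<id>.1"/"<id>.2")
#'   of allele indices (1 = allele1, 2 = allele2), class
#'   `founder_haplotypes`.
#' @export
simulate_founder_haplotypes <- function(map, freqs, n_founders = NULL,
                                        seed = 1L, ids = NULL) {
  if (is.null(ids)) {
    if (is.null(n_founders) || n_founders < 2) {
      stop_input("need n_founders >= 2 or explicit founder ids")
    }
    ids <- paste0("F", seq_len(n_founders))
  }
  n <- nrow(map)
  freqs <- rep_len(freqs, n)
  if (any(freqs <= 0 | freqs > 1)) {
    stop_input("founder allele frequencies must lie in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  h <- matrix(0L, nrow = 2L * length(ids), ncol = n,
              dimnames = list(paste0(rep(ids, each = 2L), c(".1", ".2")),
                              map$id))
  for (r in seq_len(nrow(h))) {
    h[r, ] <- ifelse(stats::runif(n) < freqs, 1L, 2L)
  }
  structure(h, class = c("founder_haplotypes", "matrix", "array"))
}

#' Copy an identical-by-descent segment across founder haplotypes
#'
#' Models a founder effect: around a locus inherited from a common
#' (unsampled) ancestor, the carrier founders' mutation-bearing
#' haplotypes are identical. The allele stretch of the first listed
#' haplotype inside the window is copied onto the others; outside the
#' window the haplotypes stay independent.
#'
#' @param founders a `founder_haplotypes` matrix.
#' @param map the corresponding `marker_map`.
#' @param chrom,bp centre of the shared segment.
#' @param length_bp segment length (window is bp +/- length_bp / 2).
#' @param haplotype_labels rownames of the haplotypes to make identical
#'   (e.g. c("PGM.1", "DAM.1")); the first is the template.
#' @return the modified `founder_haplotypes` matrix.
#' @export
share_founder_segment <- function(founders, map, chrom, bp, length_bp,
                                  haplotype_labels) {
  absent <- setdiff(haplotype_labels, rownames(founders))
  if (length(absent)) {
    stop_input("unknown founder haplotypes: ",
               paste(absent, collapse = ", "))
  }
  if (length(haplotype_labels) < 2L) return(founders)
  win <- which(map$chrom == chrom &
                 map$bp >= bp - length_bp / 2 &
                 map$bp <= bp + length_bp / 2)
  if (length(win)) {
    tmpl <- founders[haplotype_labels[1L], win]
    for (h in haplotype_labels[-1L]) founders[h, win] <- tmpl
  }
  founders
}

# one transmitted gamete: recombinant of the parent's two haplotypes.
# r[i] is the crossover probability between markers i-1 and i (0.5 at
# chromosome starts, which also randomizes the starting haplotype).
transmit_gamete <- function(hap_pair, origin_pair, r) {
  n <- length(r)
  cross <- stats::runif(n) < r
  phase <- cumsum(cross) %% 2L + 1L
  idx <- cbind(phase, seq_len(n))
  list(h = hap_pair[idx], o = origin_pair[idx])
}

#' Gene-drop founder haplotypes through a pedigree
#'
#' Forward simulation of transmission with recombination: each gamete is
#' a recombinant of the parent's two haplotypes, with inter-marker
#' crossover probabilities from the Haldane map function applied to the
#' bp distance times `recomb_rate`. Chromosomes segregate independently.
#'
#' @param ped a `pedigree`; every non-founder must have both parents in
#'   the pedigree.
#' @param founders a `founder_haplotypes` matrix covering all pedigree
#'   founders.
#' @param map the `marker_map` the haplotypes are on.
#' @param recomb_rate genetic map density in cM/Mb (0 = no recombination
#'   within chromosomes).
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return list with `genotypes` (a `genotype_matrix`) and `truth` (a
#'   `truth_record`: per-individual haplotype-origin matrices naming the
#'   founder haplotype each allele descends from).
#' @export
drop_genes <- function(ped, founders, map, recomb_rate = 1, seed = NULL) {
  validate_pedigree(ped)
  fids <- founders(ped)
  need <- paste0(rep(fids, each = 2L), c(".1", ".2"))
  if (!all(need %in% rownames(founders))) {
    stop_input("founder haplotypes missing for: ",
               paste(setdiff(need, rownames(founders)), collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  r <- haldane_recomb(map, recomb_rate)
  n <- nrow(map)
  hap_labels <- rownames(founders)
  haps <- list(); origins <- list()
  for (id in topo_order(ped)) {
    row <- ped[ped$id == id, ]
    if (is.na(row$sire)) {
      rows <- paste0(id, c(".1", ".2"))
      haps[[id]] <- founders[rows, , drop = FALSE]
      origins[[id]] <- matrix(rep(match(rows, hap_labels), n),
                              nrow = 2L)
    } else {
      g_pat <- transmit_gamete(haps[[row$sire]], origins[[row$sire]], r)
      g_mat <- transmit_gamete(haps[[row$dam]], origins[[row$dam]], r)
      haps[[id]] <- rbind(g_pat$h, g_mat$h)
      origins[[id]] <- rbind(g_pat$o, g_mat$o)
    }
  }
  calls <- t(vapply(ped$id,
                    function(id) (haps[[id]][1L, ] == 2L) +
                                 (haps[[id]][2L, ] == 2L),
                    integer(n)))
  rownames(calls) <- ped$id
  truth <- structure(list(origins = origins[ped$id],
                          hap_labels = hap_labels, map = map),
                     class = "truth_record")
  list(genotypes = genotype_matrix(calls, map), truth = truth)
}

#' Assign phenotypes from a founder-introduced recessive mutation
#'
#' The mutation rides on haplotype 1 of each carrier founder. An
#' individual is affected iff both of its haplotypes at the causal locus
#' (the nearest map marker to the stated bp) descend from
#' mutation-bearing founder haplotypes.
#'
#' @param truth a `truth_record` from [drop_genes()].
#' @param causal list(chrom =, bp =) position of the causal locus.
#' @param carrier_founders ids of the founders introducing the mutation.
#' @return data.frame with id, n_mutant (0/1/2 mutant haplotypes),
#'   carrier_status ("noncarrier"/"carrier"/"affected") and phenotype.
#' @export
implant_recessive_disease <- function(truth, causal, carrier_founders) {
  map <- truth$map
  on_chrom <- which(map$chrom == causal$chrom)
  if (!length(on_chrom)) {
    stop_input("causal chromosome ", causal$chrom, " not on the map")
  }
  mk <- on_chrom[which.min(abs(map$bp[on_chrom] - causal$bp))]
  mutant <- if (length(carrier_founders)) {
    match(paste0(carrier_founders, ".1"), truth$hap_labels)
  } else integer(0)
  if (anyNA(mutant)) {
    stop_input("carrier founder without haplotypes: ",
               paste(carrier_founders[is.na(mutant)], collapse = ", "))
  }
  n_mut <- vapply(truth$origins,
                  function(o) sum(o[, mk] %in% mutant), integer(1L))
  data.frame(
    id = names(truth$origins),
    n_mutant = unname(n_mut),
    carrier_status = c("noncarrier", "carrier", "affected")[unname(n_mut) + 1L],
    phenotype = ifelse(n_mut == 2L, "affected", "unaffected"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Mask genotype calls at random
#'
#' Each call is independently set to missing with the given probability
#' (no marker-level failure mode).
#'
#' @param gm a `genotype_matrix`.
#' @param rate missing probability in [0, 1).
#' @param seed integer seed, or NULL.
#' @return the masked `genotype_matrix`.
#' @export
apply_missingness <- function(gm, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop_input("missing rate must be in [0, 1)")
  if (rate == 0) return(gm)
  if (!is.null(seed)) set.seed(seed)
  mask <- stats::runif(length(gm$calls)) < rate
  gm$calls[mask] <- NA_integer_
  gm
}

#' Inject random genotyping errors
#'
#' Each non-missing call is independently replaced, with the given
#' probability, by one of the two other genotype codes (uniformly). Off
#' by default in all simulations; exists so the consistency filter's
#' mismatch tolerance can be exercised.
#'
#' @param gm a `genotype_matrix`.
#' @param rate error probability per call in [0, 1).
#' @param seed integer seed, or NULL.
#' @return the perturbed `genotype_matrix`.
#' @export
apply_genotyping_error <- function(gm, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop_input("error rate must be in [0, 1)")
  if (rate == 0) return(gm)
  if (!is.null(seed)) set.seed(seed)
  idx <- which(!is.na(gm$calls) & stats::runif(length(gm$calls)) < rate)
  if (length(idx)) {
    shift <- sample(1:2, length(idx), replace = TRUE)
    gm$calls[idx] <- (gm$calls[idx] + shift) %% 3L
  }
  gm
}

#' Simulate a healthy control panel for a single variant
#'
#' Each individual is heterozygous with probability `carrier_fraction`,
#' otherwise homozygous reference. Homozygous-alternate individuals are
#' never emitted: the panel models healthy controls for a recessive
#' variant.
#'
#' @param n_individuals panel size.
#' @param carrier_fraction probability of carrying one alternate allele,
#'   in [0, 1].
#' @param seed integer seed.
#' @param breed breed label attached to every individual.
#' @param ref,alt allele symbols.
#' @param variant_id variant label.
#' @return a `variant_table` (see [variant_table()]).
#' @export
simulate_panel <- function(n_individuals, carrier_fraction, seed = 1L,
                           breed = "Control", ref = "G", alt = "A",
                           variant_id = "c.1190G>A") {
  if (carrier_fraction < 0 || carrier_fraction > 1) {
    stop_input("carrier_fraction must be in [0, 1]")
  }
  set.seed(seed)
  het <- stats::runif(n_individuals) < carrier_fraction
  variant_table(
    individual = sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", breed),
                         seq_len(n_individuals)),
    genotype = ifelse(het, paste(ref, alt, sep = "/"),
                      paste(ref, ref, sep = "/")),
    breed = breed, ref = ref, alt = alt, variant_id = variant_id
  )
}

#' Generate a synthetic ortholog protein set
#'
#' Emits a reference protein and `n_species - 1` derived orthologs.
#' Positions listed as conserved are never mutated; every other position
#' is substituted independently with probability `divergence` (to a
#' uniformly chosen different residue). When `conserved_residue` is
#' given, the reference carries that residue at every conserved position
#' and never elsewhere, so a conserved-column scan for that residue
#' recovers exactly the constructed positions.
#'
#' @param reference_length residues in the reference.
#' @param n_species total sequences including the reference.
#' @param conserved_positions 1-based residue indices never mutated.
#' @param divergence per-site substitution probability in [0, 1].
#' @param seed integer seed.
#' @param conserved_residue optional single residue symbol forced at the
#'   conserved positions (e.g. "C").
#' @param species_names sequence names; defaults to ref, sp1, sp2, ...
#' @return a [Biostrings::AAStringSet] of equal-length (gap-free)
#'   sequences; an alignment in the trivial sense, suitable for
#'   [conserved_column_scan()].
#' @export
generate_ortholog_set <- function(reference_length, n_species,
                                  conserved_positions = integer(),
                                  divergence = 0.1, seed = 1L,
                                  conserved_residue = NULL,
                                  species_names = NULL) {
  if (length(conserved_positions) &&
      any(conserved_positions < 1 | conserved_positions > reference_length)) {
    stop_input("conserved positions outside the reference length")
  }
  if (divergence < 0 || divergence > 1) {
    stop_input("divergence must be in [0, 1]")
  }
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  pool <- aa
  if (!is.null(conserved_residue)) pool <- setdiff(aa, conserved_residue)
  ref <- sample(pool, reference_length, replace = TRUE)
  if (!is.null(conserved_residue)) ref[conserved_positions] <- conserved_residue
  free <- setdiff(seq_len(reference_length), conserved_positions)
  seqs <- c(paste(ref, collapse = ""),
            vapply(seq_len(n_species - 1L), function(i) {
              s <- ref
              hit <- free[stats::runif(length(free)) < divergence]
              if (length(hit)) {
                s[hit] <- vapply(s[hit], function(a) {
                  sample(setdiff(aa, a), 1L)
                }, character(1L))
              }
              paste(s, collapse = "")
            }, character(1L)))
  if (is.null(species_names)) {
    species_names <- c("ref", paste0("sp", seq_len(n_species - 1L)))
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- species_names
  out
}

#' Simulation configuration for the mapping-family generator
#'
#' Bundles and validates the knobs of [simulate_family_dataset()].
#' Defaults emulate the mapping study's conditions: 61,705 usable SNPs
#' on the 18 cat autosomes, a 3-generation family with an affected
#' sib-pair, founder allele1 frequencies Uniform(0.2, 0.8) per marker
#' (array-ascertained common SNPs), 1 cM/Mb, call rate > 95%.
#'
#' @param n_markers total marker count.
#' @param chrom_lengths named chromosome lengths (Mb).
#' @param founder_freq_range range of per-marker allele1 frequencies.
#' @param recomb_rate cM/Mb.
#' @param missing_rate per-call missing probability (must stay < 0.05).
#' @param error_rate per-call genotyping-error probability.
#' @param causal list(chrom =, bp =) of the implanted locus.
#' @param carrier_founders founders whose haplotype 1 carries the
#'   mutation.
#' @param shared_segment_bp length of the identical-by-descent segment
#'   the mutation-bearing founder haplotypes share around the causal
#'   locus (founder-effect transmission from a common ancestor); this
#'   is what makes the affected sib-pair homozygous-by-descent across a
#'   mappable region rather than at a single point.
#' @param ped the family `pedigree`.
#' @param affected_ids ids required affected under ascertainment.
#' @param ascertain if TRUE, resample the causal chromosome until
#'   exactly `affected_ids` are affected (the family was recruited
#'   because of its affected sib-pair).
#' @param seed integer seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_markers = 61705,
                       chrom_lengths = cat_chromosome_lengths(),
                       founder_freq_range = c(0.2, 0.8),
                       recomb_rate = 1,
                       missing_rate = 0.02,
                       error_rate = 0,
                       causal = list(chrom = "C2", bp = 139000000),
                       carrier_founders = c("PGM", "DAM"),
                       shared_segment_bp = 4e6,
                       ped = mapping_family_pedigree(),
                       affected_ids = c("KIT1", "KIT2"),
                       ascertain = TRUE,
                       seed = 1L) {
  if (missing_rate >= 0.05) {
    stop_input("missing_rate must stay below 0.05 (call rates > 95%)")
  }
  if (!causal$chrom %in% names(chrom_lengths)) {
    stop_input("causal chromosome not in the karyotype")
  }
  if (causal$bp < 1 || causal$bp > chrom_lengths[[causal$chrom]] * 1e6) {
    stop_input("causal position outside its chromosome span")
  }
  if (!all(carrier_founders %in% founders(ped))) {
    stop_input("carrier_founders must be pedigree founders")
  }
  structure(list(n_markers = n_markers, chrom_lengths = chrom_lengths,
                 founder_freq_range = founder_freq_range,
                 recomb_rate = recomb_rate, missing_rate = missing_rate,
                 error_rate = error_rate, causal = causal,
                 carrier_founders = carrier_founders,
                 shared_segment_bp = shared_segment_bp, ped = ped,
                 affected_ids = affected_ids, ascertain = ascertain,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a complete mapping-family dataset
#'
#' Generates a marker map, founder haplotypes, gene-dropped pedigree
#' genotypes, phenotypes from the implanted recessive mutation, and
#' missingness. Under ascertainment (the default) the causal chromosome
#' is resampled until the configured phenotype pattern holds — both
#' kittens of the sib-pair affected, everyone else unaffected — while
#' all other chromosomes, whose meioses are independent, are drawn once.
#'
#' @param config a [sim_config()].
#' @return list with genotypes (`genotype_matrix`), ped (phenotypes
#'   filled in), truth (`truth_record`), phenos (implant table), map,
#'   causal and config.
#' @export
simulate_family_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  map <- cat_marker_map(config$n_markers, config$chrom_lengths,
                        seed = derive_seed(config$seed, "map"))
  set.seed(derive_seed(config$seed, "freqs"))
  freqs <- stats::runif(nrow(map), config$founder_freq_range[1L],
                        config$founder_freq_range[2L])
  ped <- config$ped
  fids <- founders(ped)
  causal_chrom <- config$causal$chrom
  chrom_of <- map$chrom
  subset_map <- function(keep) {
    m <- map[keep, , drop = FALSE]
    class(m) <- class(map)
    m
  }

  drop_chrom <- function(keep, seed, share = FALSE) {
    m <- subset_map(keep)
    fh <- simulate_founder_haplotypes(m, freqs[keep], ids = fids,
                                      seed = seed)
    if (share) {
      fh <- share_founder_segment(
        fh, m, config$causal$chrom, config$causal$bp,
        config$shared_segment_bp,
        paste0(config$carrier_founders, ".1"))
    }
    drop_genes(ped, fh, m, recomb_rate = config$recomb_rate, seed = NULL)
  }

  # causal chromosome, optionally ascertained on the phenotype pattern
  keep_c <- chrom_of == causal_chrom
  want <- ped$id %in% config$affected_ids
  set.seed(derive_seed(config$seed, "causal_chrom"))
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    res_c <- drop_chrom(keep_c, seed = NULL, share = TRUE)
    phenos <- implant_recessive_disease(res_c$truth, config$causal,
                                        config$carrier_founders)
    ok <- identical(phenos$phenotype[match(ped$id, phenos$id)] == "affected",
                    want)
    if (ok || !config$ascertain) break
    if (attempt >= 20000L) {
      stop_input("ascertainment failed after 20000 attempts; ",
                 "is the phenotype pattern reachable?")
    }
  }

  # remaining chromosomes are independent of the ascertainment event
  res_o <- drop_chrom(chrom_of != causal_chrom,
                      seed = derive_seed(config$seed, "other_chroms"))

  ord <- order(match(c(which(keep_c), which(!keep_c)),
                     seq_len(nrow(map))))
  calls <- cbind(res_c$genotypes$calls, res_o$genotypes$calls)[, ord,
                                                              drop = FALSE]
  gm <- genotype_matrix(calls, map)
  if (config$error_rate > 0) {
    gm <- apply_genotyping_error(gm, config$error_rate,
                                 seed = derive_seed(config$seed, "error"))
  }
  gm <- apply_missingness(gm, config$missing_rate,
                          seed = derive_seed(config$seed, "missing"))
  ped$phenotype <- phenos$phenotype[match(ped$id, phenos$id)]
  # realized causal locus: the map marker nearest the requested bp is
  # where the mutation actually sits in the simulation
  onc <- which(map$chrom == config$causal$chrom)
  mk <- onc[which.min(abs(map$bp[onc] - config$causal$bp))]
  causal <- config$causal
  causal$marker_id <- map$id[mk]
  causal$marker_bp <- map$bp[mk]
  origins <- lapply(ped$id, function(id) {
    cbind(res_c$truth$origins[[id]],
          res_o$truth$origins[[id]])[, ord, drop = FALSE]
  })
  names(origins) <- ped$id
  truth <- structure(list(origins = origins,
                          hap_labels = res_c$truth$hap_labels, map = map),
                     class = "truth_record")
  list(genotypes = gm, ped = ped, truth = truth, phenos = phenos,
       map = map, causal = causal, config = config)
}
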