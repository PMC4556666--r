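#' Construct a marker map
#'
#' An ordered table of biallelic SNP markers: chromosome label, 1-based bp
#' position, marker id and the two allele symbols. Positions must be
#' strictly increasing within each chromosome, ids unique and the two
#' alleles of a marker distinct.
#'
#' @param chrom character chromosome labels, one per marker.
#' @param bp integer 1-based positions.
#' @param id marker ids; generated as `chrom_bp` when NULL.
#' @param allele1,allele2 allele symbols per marker (default "A"/"B").
#' @return a `marker_map` data.frame with columns chrom, bp, id, allele1,
#'   allele2, in the input order.
#' @export
marker_map <- function(chrom, bp, id = NULL, allele1 = "A", allele2 = "B") {
  n <- length(chrom)
  bp <- as.integer(bp)
  if (length(bp) != n) stop_input("chrom and bp lengths differ")
  if (is.null(id)) id <- paste(chrom, bp, sep = "_")
  m <- data.frame(
    chrom = as.character(chrom), bp = bp, id = as.character(id),
    allele1 = rep_len(as.character(allele1), n),
    allele2 = rep_len(as.character(allele2), n),
    stringsAsFactors = FALSE
  )
  class(m) <- c("marker_map", "data.frame")
  validate_marker_map(m)
}

validate_marker_map <- function(m) {
  if (any(m$bp < 1L)) stop_input("positions must be 1-based (>= 1)")
  for (ch in unique(m$chrom)) {
    p <- m$bp[m$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop_input("positions not strictly increasing on chromosome ", ch)
    }
  }
  if (anyDuplicated(m$id)) stop_input("duplicate marker ids in map")
  if (any(m$allele1 == m$allele2)) {
    stop_input("marker with identical allele symbols")
  }
  m
}

#' Approximate cat autosome lengths
#'
#' The 18 cat autosomes (A1-A3, B1-B4, C1-C2, D1-D4, E1-E3, F1-F2) with
#' approximate physical lengths in Mb; used to lay out synthetic marker
#' maps with realistic per-chromosome marker counts. X is excluded: the
#' mapping analysis is autosomal.
#'
#' @return named numeric vector of lengths in Mb.
#' @export
cat_chromosome_lengths <- function() {
  c(A1 = 239, A2 = 169, A3 = 142,
    B1 = 205, B2 = 154, B3 = 148, B4 = 144,
    C1 = 221, C2 = 157,
    D1 = 116, D2 = 89, D3 = 95, D4 = 96,
    E1 = 63, E2 = 64, E3 = 43,
    F1 = 68, F2 = 82)
}

#' Build a cat-like synthetic SNP map
#'
#' Distributes `n_markers` over the 18 cat autosomes proportionally to
#' their physical length (the array's true per-chromosome density is not
#' published) and draws sorted uniform positions. Allele symbols are
#' random distinct nucleotide pairs per marker.
#'
#' @param n_markers total marker count (default 61705, the usable-SNP
#'   count of a feline 63k array run).
#' @param chrom_lengths named vector of chromosome lengths in Mb.
#' @param seed integer seed.
#' @return a `marker_map`.
#' @export
cat_marker_map <- function(n_markers = 61705,
                           chrom_lengths = cat_chromosome_lengths(),
                           seed = 1L) {
  set.seed(seed)
  frac <- chrom_lengths / sum(chrom_lengths)
  counts <- floor(n_markers * frac)
  # distribute the remainder to the largest fractional parts
  rem <- n_markers - sum(counts)
  if (rem > 0) {
    extra <- order(n_markers * frac - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  bases <- c("A", "C", "G", "T")
  chrom <- rep(names(chrom_lengths), counts)
  bp <- unlist(lapply(names(chrom_lengths), function(ch) {
    sort(sample.int(chrom_lengths[[ch]] * 1e6, counts[[ch]]))
  }), use.names = FALSE)
  a1 <- sample.int(4L, n_markers, replace = TRUE)
  a2 <- (a1 - 1L + sample.int(3L, n_markers, replace = TRUE)) %% 4L + 1L
  marker_map(chrom, bp,
             id = sprintf("snp_%s_%d", chrom, bp),
             allele1 = bases[a1], allele2 = bases[a2])
}

#' Inter-marker recombination fractions under the Haldane map function
#'
#' Converts adjacent-marker bp distances to recombination fractions:
#' d Morgans = bp / 1e6 * rate_cm_per_mb / 100, r = (1 - exp(-2d)) / 2.
#' The first marker of each chromosome gets r = 0.5 (free recombination
#' between chromosomes).
#'
#' @param map a `marker_map`.
#' @param rate_cm_per_mb genetic map density in cM/Mb (default 1).
#' @return numeric vector of length nrow(map): recombination fraction
#'   between each marker and its predecessor.
#' @export
haldane_recomb <- function(map, rate_cm_per_mb = 1) {
  d_bp <- c(0L, diff(map$bp))
  new_chrom <- c(TRUE, map$chrom[-1L] != map$chrom[-nrow(map)])
  d_morgan <- d_bp / 1e6 * rate_cm_per_mb / 100
  r <- (1 - exp(-2 * d_morgan)) / 2
  r[new_chrom] <- 0.5
  r
}
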