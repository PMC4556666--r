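#' Map a CDS substitution to its protein consequence
#'
#' Locates the codon containing a 1-based CDS position, applies the
#' substitution with the standard genetic code and reports the residue
#' change with HGVS-style c. and p. labels. Synonymous changes are
#' flagged.
#'
#' @param cds_position 1-based position within the CDS.
#' @param ref_base,alt_base reference and alternate bases (single
#'   characters); the CDS must carry `ref_base` at the position.
#' @param cds_sequence the coding sequence (character or
#'   [Biostrings::DNAString]); length must be a multiple of 3.
#' @return a `codon_mapping` list: cds_position, codon_index,
#'   pos_in_codon, ref_codon, alt_codon, ref_residue, alt_residue,
#'   synonymous, hgvs_c, hgvs_p.
#' @export
map_cdna_variant <- function(cds_position, ref_base, alt_base,
                             cds_sequence) {
  cds <- toupper(as.character(cds_sequence))
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop_input("CDS length ", n, " is not a multiple of 3")
  }
  if (cds_position < 1L || cds_position > n) {
    stop_input("position ", cds_position, " beyond the CDS (length ", n, ")")
  }
  observed <- substr(cds, cds_position, cds_position)
  if (observed != toupper(ref_base)) {
    stop_input("reference base mismatch at position ", cds_position,
               ": CDS has ", observed, ", expected ", ref_base)
  }
  codon_index <- (cds_position + 2L) %/% 3L
  pos_in_codon <- (cds_position - 1L) %% 3L + 1L
  ref_codon <- substr(cds, 3L * codon_index - 2L, 3L * codon_index)
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- toupper(alt_base)
  code <- Biostrings::GENETIC_CODE
  ref_residue <- unname(code[ref_codon])
  alt_residue <- unname(code[alt_codon])
  if (is.na(ref_residue) || is.na(alt_residue)) {
    stop_input("codon contains non-ACGT bases: ", ref_codon)
  }
  synonymous <- ref_residue == alt_residue
  structure(list(
    cds_position = as.integer(cds_position),
    codon_index = codon_index, pos_in_codon = pos_in_codon,
    ref_codon = ref_codon, alt_codon = alt_codon,
    ref_residue = ref_residue, alt_residue = alt_residue,
    synonymous = synonymous,
    hgvs_c = sprintf("c.%d%s>%s", cds_position, toupper(ref_base),
                     toupper(alt_base)),
    hgvs_p = if (synonymous) sprintf("p.%s%d=", ref_residue, codon_index)
             else sprintf("p.%s%d%s", ref_residue, codon_index, alt_residue)
  ), class = "codon_mapping")
}

#' @exportS3Method base::print
print.codon_mapping <- function(x, ...) {
  cat(sprintf("%s -> %s: codon %d (%s>%s), %s>%s%s\n", x$hgvs_c, x$hgvs_p,
              x$codon_index, x$ref_codon, x$alt_codon, x$ref_residue,
              x$alt_residue, if (x$synonymous) " [synonymous]" else ""))
  invisible(x)
}

#' Percent identity between two protein sequences
#'
#' Either aligns the two sequences globally (Needleman-Wunsch with
#' identity scoring: match 1, mismatch 0, affine gaps) or takes them as
#' rows of a precomputed alignment (equal length, '-' gaps; columns
#' gapped in both are dropped). Identity is identical residue pairs
#' divided by the chosen denominator, times 100, rounded half-up to the
#' nearest integer. The method and parameters are echoed in the result,
#' since published identity figures rarely state theirs.
#'
#' @param seq_a,seq_b sequences (character or AAString); nonempty.
#' @param mode "global" (align here) or "precomputed".
#' @param denominator "alignment" (full alignment length, terminal and
#'   internal gap columns included — the default), "shorter" (length of
#'   the shorter ungapped sequence) or "gapfree" (columns without gaps).
#' @param gap_opening,gap_extension affine gap penalties for global
#'   mode.
#' @return an `identity_result` list: percent (integer), n_identical,
#'   alignment_length, denominator_value, and the method metadata.
#' @export
pairwise_identity <- function(seq_a, seq_b,
                              mode = c("global", "precomputed"),
                              denominator = c("alignment", "shorter",
                                              "gapfree"),
                              gap_opening = 10, gap_extension = 0.5) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  a <- as.character(seq_a); b <- as.character(seq_b)
  if (!nzchar(gsub("-", "", a)) || !nzchar(gsub("-", "", b))) {
    stop_input("empty sequence")
  }
  if (mode == "global") {
    a <- gsub("-", "", a); b <- gsub("-", "", b)
    letters_ab <- unique(strsplit(paste0(a, b), "")[[1L]])
    subm <- diag(1, length(letters_ab))
    dimnames(subm) <- list(letters_ab, letters_ab)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "global", substitutionMatrix = subm,
      gapOpening = gap_opening, gapExtension = gap_extension)
    ca <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    cb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  } else {
    ca <- strsplit(a, "")[[1L]]
    cb <- strsplit(b, "")[[1L]]
    if (length(ca) != length(cb)) {
      stop_input("precomputed mode needs equal-length aligned sequences")
    }
    both_gap <- ca == "-" & cb == "-"
    ca <- ca[!both_gap]; cb <- cb[!both_gap]
  }
  n_ident <- sum(ca == cb & ca != "-")
  den <- switch(denominator,
                alignment = length(ca),
                shorter = min(sum(ca != "-"), sum(cb != "-")),
                gapfree = sum(ca != "-" & cb != "-"))
  structure(list(
    percent = as.integer(round_half_up(100 * n_ident / den)),
    n_identical = n_ident, alignment_length = length(ca),
    denominator = denominator, denominator_value = den, mode = mode,
    gap_opening = if (mode == "global") gap_opening else NA,
    gap_extension = if (mode == "global") gap_extension else NA,
    scoring = if (mode == "global") "match=1,mismatch=0" else NA
  ), class = "identity_result")
}

#' @exportS3Method base::print
print.identity_result <- function(x, ...) {
  cat(sprintf("identity: %d%% (%d/%d identical, denominator=%s, mode=%s)\n",
              x$percent, x$n_identical, x$denominator_value,
              x$denominator, x$mode))
  invisible(x)
}

#' Scan alignment columns for conserved residues
#'
#' Maps every (gap-free) reference residue to its alignment column and
#' flags columns that are fully conserved (every sequence carries the
#' reference residue, no gaps) and, optionally, columns conserved for a
#' residue set (every sequence carries a residue from the set, no
#' gaps). Residue numbering follows the reference sequence, gap-free
#' and 1-based.
#'
#' @param aln an aligned [Biostrings::AAStringSet] (equal widths).
#' @param reference_id name of the reference sequence in `aln`.
#' @param window optional c(from, to) residue range in reference
#'   numbering; must lie within the reference length.
#' @param residues optional character vector of residue symbols for the
#'   predicate scan (e.g. "C" for cysteines).
#' @return a `conservation_profile` list: profile (data.frame residue,
#'   column, ref_residue, fully_conserved, predicate_conserved),
#'   matching_residues (reference residue numbers where the predicate
#'   holds in every sequence), reference_id, window, n_sequences.
#' @export
conserved_column_scan <- function(aln, reference_id, window = NULL,
                                  residues = NULL) {
  if (!reference_id %in% names(aln)) {
    stop_input("reference '", reference_id, "' not in the alignment")
  }
  w <- Biostrings::width(aln)
  if (length(unique(w)) > 1L) {
    stop_input("sequences are not aligned (unequal lengths)")
  }
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  rownames(m) <- names(aln)
  ref <- m[reference_id, ]
  ref_cols <- which(ref != "-")
  n_res <- length(ref_cols)
  if (is.null(window)) window <- c(1L, n_res)
  if (window[1L] < 1L || window[2L] > n_res || window[1L] > window[2L]) {
    stop_input("window [", window[1L], ", ", window[2L],
               "] outside the reference length (", n_res, " residues)")
  }
  res_idx <- seq(window[1L], window[2L])
  cols <- ref_cols[res_idx]
  no_gap <- colSums(m[, cols, drop = FALSE] == "-") == 0L
  fully <- no_gap & vapply(seq_along(cols), function(k) {
    all(m[, cols[k]] == ref[cols[k]])
  }, logical(1L))
  pred <- if (is.null(residues)) rep(NA, length(cols)) else {
    no_gap & vapply(seq_along(cols), function(k) {
      all(m[, cols[k]] %in% residues)
    }, logical(1L))
  }
  profile <- data.frame(residue = res_idx, column = cols,
                        ref_residue = ref[cols],
                        fully_conserved = fully,
                        predicate_conserved = pred,
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(profile = profile,
                 matching_residues =
                   if (is.null(residues)) integer() else
                     profile$residue[profile$predicate_conserved],
                 reference_id = reference_id, window = window,
                 residues = residues, n_sequences = length(aln)),
            class = "conservation_profile")
}

#' Is a single reference residue fully conserved?
#' @param profile a `conservation_profile`.
#' @param residue reference residue number.
#' @return TRUE/FALSE (errors if the residue is outside the scanned
#'   window).
#' @export
residue_conserved <- function(profile, residue) {
  row <- profile$profile[profile$profile$residue == residue, ]
  if (!nrow(row)) {
    stop_input("residue ", residue, " not in the scanned window [",
               profile$window[1L], ", ", profile$window[2L], "]")
  }
  row$fully_conserved
}

#' Combine a variant mapping with its conservation context
#'
#' Joins the protein consequence of a CDS variant with the conservation
#' status of the affected residue and its membership in a domain window
#' (default: the cysteine-rich C-terminal domain, reference residues
#' 375-451), plus a cross-reference slot for known orthologous disease
#' mutations supplied as a table. No deleteriousness score is computed.
#'
#' @param mapping a `codon_mapping`.
#' @param profile a `conservation_profile` whose window contains the
#'   mapped residue.
#' @param domain_window c(from, to) reference residue range of the
#'   domain of interest.
#' @param known_mutations optional data.frame (residue, change,
#'   phenotype) of known disease mutations in the reference protein.
#' @return a `substitution_report` list: change, residue, conserved,
#'   in_domain, classification, known (cross-reference rows, with a
#'   same_residue flag).
#' @export
substitution_report <- function(mapping, profile,
                                domain_window = c(375L, 451L),
                                known_mutations = NULL) {
  res <- mapping$codon_index
  conserved <- residue_conserved(profile, res)
  in_domain <- res >= domain_window[1L] && res <= domain_window[2L]
  classification <-
    if (in_domain && conserved) "conserved-domain substitution"
    else if (!in_domain) "outside domain"
    else "domain substitution, residue not fully conserved"
  known <- if (is.null(known_mutations) || !nrow(known_mutations)) {
    data.frame(residue = integer(), change = character(),
               phenotype = character(), same_residue = logical(),
               stringsAsFactors = FALSE)
  } else {
    cbind(known_mutations,
          same_residue = known_mutations$residue == res)
  }
  structure(list(change = mapping$hgvs_p, residue = res,
                 conserved = conserved, in_domain = in_domain,
                 domain_window = domain_window,
                 classification = classification, known = known),
            class = "substitution_report")
}

#' @exportS3Method base::print
print.substitution_report <- function(x, ...) {
  cat(sprintf("%s: %s (residue %d, %sconserved, %s domain %d-%d)\n",
              x$change, x$classification, x$residue,
              if (x$conserved) "" else "not ",
              if (x$in_domain) "inside" else "outside",
              x$domain_window[1L], x$domain_window[2L]))
  if (nrow(x$known)) {
    cat("known mutations cross-referenced:",
        paste(x$known$change, collapse = ", "), "\n")
  }
  invisible(x)
}
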