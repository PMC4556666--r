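#' Check variant genotypes against the autosomal-recessive model
#'
#' Every typed individual gets an expectation class from its pedigree
#' role: affected individuals must be homozygous alternate; obligate
#' carriers (unaffected parents of an affected — promoted automatically)
#' and declared carriers must be heterozygous; all other unaffected (or
#' unknown-phenotype) individuals must simply not be homozygous
#' alternate. An affected individual with a missing genotype is
#' "untyped" and drops out of the concordance denominator.
#'
#' @param ped a `pedigree`.
#' @param tab a `variant_table`; every individual must resolve against
#'   the pedigree.
#' @return data.frame of verdicts: individual, genotype, class
#'   (genotype class), expectation, compatible, reason.
#' @export
classify_compatibility <- function(ped, tab) {
  unknown <- setdiff(tab$individual, ped$id)
  if (length(unknown)) {
    stop_input("individuals not in the pedigree: ",
               paste(unknown, collapse = ", "))
  }
  affected <- ped$id[ped$phenotype == "affected"]
  obligate <- unique(stats::na.omit(c(ped$sire[ped$id %in% affected],
                                      ped$dam[ped$id %in% affected])))
  obligate <- setdiff(obligate, affected)
  cls <- genotype_class(tab)
  verdicts <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$individual[i]
    prow <- ped[ped$id == id, ]
    expectation <-
      if (prow$phenotype == "affected") "affected_hom_alt"
      else if (id %in% obligate || prow$status == "obligate_carrier")
        "obligate_carrier_het"
      else if (prow$status == "declared_carrier") "declared_carrier_het"
      else "unaffected_not_hom_alt"
    g <- cls[i]
    if (is.na(g)) {
      return(data.frame(individual = id, genotype = NA_character_,
                        class = NA_character_, expectation = "untyped",
                        compatible = NA, reason = "missing genotype",
                        stringsAsFactors = FALSE))
    }
    ok_reason <- switch(expectation,
      affected_hom_alt = c(g == "hom_alt", "affected not hom-alt"),
      obligate_carrier_het = c(g == "het", "obligate carrier not het"),
      declared_carrier_het = c(g == "het", "declared carrier not het"),
      unaffected_not_hom_alt = c(g != "hom_alt", "unaffected is hom-alt"))
    ok <- as.logical(ok_reason[1L])
    data.frame(individual = id, genotype = tab$genotype[i], class = g,
               expectation = expectation, compatible = ok,
               reason = if (ok) "compatible" else ok_reason[2L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, verdicts)
}

#' Segregation concordance percentage
#'
#' @param verdicts output of [classify_compatibility()].
#' @return list with `percent` (100 x compatible / typed, rounded
#'   half-up to 1 decimal), `n_typed`, `n_compatible` and
#'   `incompatible` (the failing verdict rows).
#' @export
concordance <- function(verdicts) {
  typed <- verdicts[!is.na(verdicts$compatible), , drop = FALSE]
  if (!nrow(typed)) stop_input("no typed individuals to assess")
  n_ok <- sum(typed$compatible)
  list(percent = round_half_up(100 * n_ok / nrow(typed), 1L),
       n_typed = nrow(typed), n_compatible = n_ok,
       incompatible = typed[!typed$compatible, , drop = FALSE])
}

#' Carrier frequency with an exact confidence interval
#'
#' Counts genotype classes in a panel (after caller-supplied
#' exclusions — typically known relatives of the index family), reports
#' the heterozygote percentage rounded half-up to 1 decimal, and a
#' Clopper-Pearson exact 95% CI on the heterozygote count computed from
#' beta quantiles. Homozygous-alternate individuals are counted and
#' flagged — they are unexpected in a healthy control panel.
#'
#' @param tab a `variant_table`.
#' @param exclude_ids individual ids to drop before counting.
#' @param conf_level confidence level (default 0.95).
#' @return a `carrier_stats` list: n_total, n_hom_ref, n_het,
#'   n_hom_alt, n_missing, percent, ci_percent (length-2), flags.
#' @export
carrier_frequency <- function(tab, exclude_ids = character(),
                              conf_level = 0.95) {
  keep <- !tab$individual %in% exclude_ids
  tab <- tab[keep, , drop = FALSE]
  cls <- genotype_class(tab)
  typed <- !is.na(cls)
  n <- sum(typed)
  if (n == 0L) stop_input("panel empty after exclusions")
  n_het <- sum(cls == "het", na.rm = TRUE)
  n_hom_alt <- sum(cls == "hom_alt", na.rm = TRUE)
  a <- (1 - conf_level) / 2
  lo <- if (n_het == 0L) 0 else stats::qbeta(a, n_het, n - n_het + 1L)
  hi <- if (n_het == n) 1 else stats::qbeta(1 - a, n_het + 1L, n - n_het)
  structure(list(
    n_total = n,
    n_hom_ref = sum(cls == "hom_ref", na.rm = TRUE),
    n_het = n_het, n_hom_alt = n_hom_alt,
    n_missing = sum(!typed),
    percent = round_half_up(100 * n_het / n, 1L),
    ci_percent = 100 * c(lo, hi),
    conf_level = conf_level,
    n_excluded = sum(!keep),
    flags = if (n_hom_alt > 0L) {
      sprintf("%d homozygous-alternate individual(s) in a control panel",
              n_hom_alt)
    } else character(0)
  ), class = "carrier_stats")
}

#' @exportS3Method base::print
print.carrier_stats <- function(x, ...) {
  cat(sprintf(
    "carriers: %d/%d (%.1f%%), %d%% CI [%.2f%%, %.2f%%]; hom-alt: %d\n",
    x$n_het, x$n_total, x$percent, round(100 * x$conf_level),
    x$ci_percent[1L], x$ci_percent[2L], x$n_hom_alt))
  for (f in x$flags) cat("flag:", f, "\n")
  invisible(x)
}

#' Per-breed carrier summary
#'
#' One row per breed plus a Total row whose counts are the sums of the
#' breed counts. Percentages are heterozygote fractions rounded half-up
#' to one decimal.
#'
#' @param tab a `variant_table` with breed labels.
#' @return data.frame with breed, n_hom_ref, n_het, n_hom_alt, n_total,
#'   percent.
#' @export
panel_summary <- function(tab) {
  if (all(is.na(tab$breed))) stop_input("breed labels required")
  breeds <- unique(tab$breed)
  rows <- lapply(breeds, function(b) {
    cs <- carrier_frequency(tab[tab$breed == b, , drop = FALSE])
    data.frame(breed = b, n_hom_ref = cs$n_hom_ref, n_het = cs$n_het,
               n_hom_alt = cs$n_hom_alt, n_total = cs$n_total,
               percent = cs$percent, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tot <- data.frame(breed = "Total",
                    n_hom_ref = sum(out$n_hom_ref),
                    n_het = sum(out$n_het),
                    n_hom_alt = sum(out$n_hom_alt),
                    n_total = sum(out$n_total),
                    percent = round_half_up(
                      100 * sum(out$n_het) / sum(out$n_total), 1L),
                    stringsAsFactors = FALSE)
  rbind(out, tot)
}
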