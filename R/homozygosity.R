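#' Scan for homozygous regions shared by all affected individuals
#'
#' A marker is shared-homozygous when every affected individual with a
#' call there is homozygous for the same allele. Missing calls are
#' neutral — they neither support nor break a run — but a run may not
#' begin or end on a marker where any affected is missing, and any
#' stretch of more than `max_missing_run` consecutive missing calls in
#' one affected individual breaks the run. Maximal runs with at least
#' `min_markers` shared-homozygous markers are reported; runs on the
#' same chromosome separated by less than `merge_gap_bp` whose flanking
#' signature alleles agree are merged (a short interior break is then
#' treated as an artifact).
#'
#' @param gm a `genotype_matrix`.
#' @param affected_ids ids of the affected individuals (>= 1, all
#'   present in the matrix).
#' @param min_markers minimum shared-homozygous markers per segment.
#' @param max_missing_run longest tolerated consecutive-missing stretch
#'   per individual inside a segment.
#' @param merge_gap_bp gap below which compatible adjacent segments
#'   merge (0 disables merging).
#' @return a `shared_segments` data.frame (chrom, start_bp, end_bp,
#'   n_markers), sorted by chromosome label then start, with attributes
#'   `signatures` (per-segment named allele-symbol vectors),
#'   `marker_idx` (per-segment global marker indices of the signature
#'   markers) and `params`.
#' @export
shared_homozygosity_scan <- function(gm, affected_ids, min_markers = 20L,
                                     max_missing_run = 2L,
                                     merge_gap_bp = 1e6) {
  absent <- setdiff(affected_ids, rownames(gm$calls))
  if (length(absent)) {
    stop_input("affected ids absent from genotype matrix: ",
               paste(absent, collapse = ", "))
  }
  if (!length(affected_ids)) stop_input("need at least one affected id")
  map <- gm$map
  A <- gm$calls[affected_ids, , drop = FALSE]
  any_het <- colSums(A == 1L, na.rm = TRUE) > 0L
  has0 <- colSums(A == 0L, na.rm = TRUE) > 0L
  has2 <- colSums(A == 2L, na.rm = TRUE) > 0L
  brk <- any_het | (has0 & has2)
  # over-long per-individual missing stretches break runs
  for (i in seq_len(nrow(A))) {
    miss <- is.na(A[i, ])
    for (ch in unique(map$chrom)) {
      sel <- which(map$chrom == ch)
      rl <- rle(miss[sel])
      ends <- cumsum(rl$lengths)
      over <- which(rl$values & rl$lengths > max_missing_run)
      for (k in over) {
        brk[sel[(ends[k] - rl$lengths[k] + 1L):ends[k]]] <- TRUE
      }
    }
  }
  sig_idx <- rep(NA_integer_, ncol(A))
  sig_idx[!brk & has2] <- 2L
  sig_idx[!brk & has0] <- 1L
  counted <- !brk & !is.na(sig_idx)
  full <- counted & colSums(is.na(A)) == 0L

  segs <- list()
  for (ch in unique(map$chrom)) {
    sel <- which(map$chrom == ch)
    rl <- rle(!brk[sel])
    ends <- cumsum(rl$lengths)
    for (k in which(rl$values)) {
      run <- sel[(ends[k] - rl$lengths[k] + 1L):ends[k]]
      fulls <- run[full[run]]
      if (!length(fulls)) next
      run <- run[run >= fulls[1L] & run <= fulls[length(fulls)]]
      cm <- run[counted[run]]
      if (length(cm) < min_markers) next
      segs[[length(segs) + 1L]] <- list(
        chrom = ch, start_bp = map$bp[run[1L]],
        end_bp = map$bp[run[length(run)]], idx = cm)
    }
  }

  # merge close segments with agreeing flanking signature alleles
  seg_allele <- function(s, at) {
    i <- s$idx[at]
    if (sig_idx[i] == 1L) map$allele1[i] else map$allele2[i]
  }
  if (merge_gap_bp > 0 && length(segs) > 1L) {
    merged <- list(segs[[1L]])
    for (s in segs[-1L]) {
      last <- merged[[length(merged)]]
      if (identical(s$chrom, last$chrom) &&
          (s$start_bp - last$end_bp) < merge_gap_bp &&
          identical(seg_allele(last, length(last$idx)),
                    seg_allele(s, 1L))) {
        last$end_bp <- s$end_bp
        last$idx <- c(last$idx, s$idx)
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1L]] <- s
      }
    }
    segs <- merged
  }

  out <- data.frame(
    chrom = vapply(segs, `[[`, character(1L), "chrom"),
    start_bp = vapply(segs, `[[`, integer(1L), "start_bp"),
    end_bp = vapply(segs, `[[`, integer(1L), "end_bp"),
    n_markers = vapply(segs, function(s) length(s$idx), integer(1L)),
    stringsAsFactors = FALSE
  )
  ord <- order(out$chrom, out$start_bp)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  signatures <- lapply(segs[ord], function(s) {
    al <- ifelse(sig_idx[s$idx] == 1L, map$allele1[s$idx], map$allele2[s$idx])
    names(al) <- map$id[s$idx]
    al
  })
  structure(out,
            signatures = signatures,
            marker_idx = lapply(segs[ord], `[[`, "idx"),
            sig_allele_idx = lapply(segs[ord], function(s) sig_idx[s$idx]),
            params = list(min_markers = min_markers,
                          max_missing_run = max_missing_run,
                          merge_gap_bp = merge_gap_bp,
                          affected_ids = affected_ids),
            class = c("shared_segments", "data.frame"))
}

#' Build a consistency rule set for relatives
#'
#' Obligate and declared carriers must carry the shared allele at every
#' signature marker (up to `tolerance` violating markers) and must not
#' be homozygous for the whole signature (they would be affected).
#' Unaffected relatives must merely not be homozygous for the whole
#' signature. Missing calls are skipped.
#'
#' @param obligate_carriers,declared_carriers,unaffected_relatives
#'   individual id vectors; the three sets must be disjoint from each
#'   other and from the affected set of the scan.
#' @param tolerance number of violating markers forgiven per individual
#'   and segment (default 0).
#' @return a `consistency_rules` list.
#' @export
consistency_rules <- function(obligate_carriers = character(),
                              declared_carriers = character(),
                              unaffected_relatives = character(),
                              tolerance = 0L) {
  ids <- c(obligate_carriers, declared_carriers, unaffected_relatives)
  if (anyDuplicated(ids)) {
    stop_input("an individual appears under more than one rule")
  }
  structure(list(obligate_carriers = obligate_carriers,
                 declared_carriers = declared_carriers,
                 unaffected_relatives = unaffected_relatives,
                 tolerance = as.integer(tolerance)),
            class = "consistency_rules")
}

#' Filter shared segments by relative consistency
#'
#' Applies the carrier and unaffected-relative rules of a
#' [consistency_rules()] set to every shared segment: a carrier fails if
#' it lacks the shared allele entirely (is homozygous for the opposite
#' allele) at more than `tolerance` non-missing signature markers, or if
#' it is homozygous for the signature at every non-missing marker of the
#' segment; an unaffected relative fails only under the latter rule.
#'
#' @param segments a `shared_segments` object.
#' @param gm the `genotype_matrix` the scan ran on.
#' @param rules a `consistency_rules` set.
#' @return a `candidate_regions` object: the segment table plus a
#'   `status` column (consistent/excluded) and a `verdicts` attribute
#'   (per region and relative: rule, pass, n_violations, first failing
#'   marker).
#' @export
apply_consistency_filter <- function(segments, gm, rules) {
  ids <- c(rules$obligate_carriers, rules$declared_carriers,
           rules$unaffected_relatives)
  if (intersect_nonempty(ids, attr(segments, "params")$affected_ids)) {
    stop_input("rule individuals overlap the affected set")
  }
  absent <- setdiff(ids, rownames(gm$calls))
  if (length(absent)) {
    stop_input("rule individuals absent from matrix: ",
               paste(absent, collapse = ", "))
  }
  if (!length(ids)) {
    warning("empty rule set: all segments pass unfiltered", call. = FALSE)
  }
  rule_of <- c(stats::setNames(rep("obligate_carrier",
                                   length(rules$obligate_carriers)),
                               rules$obligate_carriers),
               stats::setNames(rep("declared_carrier",
                                   length(rules$declared_carriers)),
                               rules$declared_carriers),
               stats::setNames(rep("unaffected_relative",
                                   length(rules$unaffected_relatives)),
                               rules$unaffected_relatives))
  midx <- attr(segments, "marker_idx")
  sig_idx <- attr(segments, "sig_allele_idx")
  verdicts <- list()
  status <- character(nrow(segments))
  for (r in seq_len(nrow(segments))) {
    mi <- midx[[r]]
    hom_code <- ifelse(sig_idx[[r]] == 1L, 0L, 2L)
    all_pass <- TRUE
    for (id in ids) {
      g <- gm$calls[id, mi]
      typed <- !is.na(g)
      lacks <- typed & g != 1L & g != hom_code
      hom_all <- any(typed) && all(g[typed] == hom_code[typed])
      rule <- rule_of[[id]]
      if (rule == "unaffected_relative") {
        fail <- hom_all
        n_viol <- 0L
        first_fail <- if (fail) gm$map$id[mi[which(typed)[1L]]] else NA
      } else {
        n_viol <- sum(lacks)
        fail_a <- n_viol > rules$tolerance
        fail <- fail_a || hom_all
        first_fail <- if (fail_a) {
          gm$map$id[mi[which(lacks)[rules$tolerance + 1L]]]
        } else if (hom_all) gm$map$id[mi[which(typed)[1L]]] else NA
      }
      all_pass <- all_pass && !fail
      verdicts[[length(verdicts) + 1L]] <- data.frame(
        region = r, individual = id, rule = rule, pass = !fail,
        n_violations = n_viol,
        first_fail_marker = as.character(first_fail),
        stringsAsFactors = FALSE)
    }
    status[r] <- if (all_pass) "consistent" else "excluded"
  }
  out <- segments
  out$status <- status
  attr(out, "verdicts") <- if (length(verdicts)) {
    do.call(rbind, verdicts)
  } else {
    data.frame(region = integer(), individual = character(),
               rule = character(), pass = logical(),
               n_violations = integer(), first_fail_marker = character(),
               stringsAsFactors = FALSE)
  }
  attr(out, "rules") <- rules
  class(out) <- c("candidate_regions", class(segments))
  out
}

intersect_nonempty <- function(a, b) length(intersect(a, b)) > 0L

#' Tabulate candidate regions
#'
#' One row per region with its span in bp (end - start, the boundary
#' difference) and Mb (rounded half-up to one decimal), marker count,
#' status and a compact per-relative verdict summary.
#'
#' @param regions a `candidate_regions` or `shared_segments` object.
#' @return a data.frame report.
#' @export
region_report <- function(regions) {
  span_bp <- regions$end_bp - regions$start_bp
  rep <- data.frame(
    chrom = regions$chrom, start_bp = regions$start_bp,
    end_bp = regions$end_bp, span_bp = span_bp,
    span_mb = round_half_up(span_bp / 1e6, 1L),
    n_markers = regions$n_markers,
    status = if ("status" %in% names(regions)) regions$status else NA,
    stringsAsFactors = FALSE
  )
  v <- attr(regions, "verdicts")
  rep$verdicts <- if (!is.null(v) && nrow(v) && nrow(rep)) {
    vapply(seq_len(nrow(rep)), function(r) {
      vv <- v[v$region == r, ]
      paste(sprintf("%s:%s", vv$individual,
                    ifelse(vv$pass, "pass", "fail")), collapse = ";")
    }, character(1L))
  } else rep(NA_character_, nrow(rep))
  rep
}

#' Candidate genes overlapping or near regions
#'
#' Reports every gene that overlaps a region or lies within `slop_bp`
#' of its boundary; distances are boundary differences (gene start
#' minus region end, or region start minus gene end; 0 when
#' overlapping), the same arithmetic convention as the region spans.
#'
#' @param regions a region table with chrom, start_bp, end_bp columns.
#' @param gene_table data.frame with columns gene, chrom, start, end on
#'   the same coordinate system.
#' @param slop_bp maximum reported distance (default 0: overlaps only).
#' @return data.frame with gene, chrom, region_start, region_end and
#'   distance_bp, sorted by distance.
#' @export
gene_overlap <- function(regions, gene_table, slop_bp = 0) {
  hits <- list()
  for (r in seq_len(nrow(regions))) {
    g <- gene_table[gene_table$chrom == regions$chrom[r], , drop = FALSE]
    if (!nrow(g)) next
    d <- pmax(0L, g$start - regions$end_bp[r], regions$start_bp[r] - g$end)
    keep <- d <= slop_bp
    if (!any(keep)) next
    hits[[length(hits) + 1L]] <- data.frame(
      gene = g$gene[keep], chrom = g$chrom[keep],
      gene_start = g$start[keep], gene_end = g$end[keep],
      region_start = regions$start_bp[r], region_end = regions$end_bp[r],
      distance_bp = d[keep], stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    return(data.frame(gene = character(), chrom = character(),
                      gene_start = integer(), gene_end = integer(),
                      region_start = integer(), region_end = integer(),
                      distance_bp = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$distance_bp), , drop = FALSE]
}
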