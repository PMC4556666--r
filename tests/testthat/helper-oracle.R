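# Independent oracle for the shared-homozygosity scan: exhaustive window
# enumeration. A window [i, j] on one chromosome is valid iff both
# endpoints are markers where every affected is non-missing and
# homozygous for the shared allele, the window contains no marker where
# an affected is heterozygous or two affecteds are homozygous for
# opposite alleles, no affected has a complete stretch of more than
# max_missing_run consecutive missing calls inside it, and it holds at
# least min_markers markers with a defined shared allele. Maximal valid
# windows are reported.
brute_scan <- function(gm, affected_ids, min_markers = 20L,
                       max_missing_run = 2L) {
  map <- gm$map
  A <- gm$calls[affected_ids, , drop = FALSE]
  out <- list()
  for (ch in unique(map$chrom)) {
    sel <- which(map$chrom == ch)
    Ac <- A[, sel, drop = FALSE]
    n <- length(sel)
    nmiss <- colSums(is.na(Ac))
    het <- colSums(Ac == 1L, na.rm = TRUE) > 0L
    h0 <- colSums(Ac == 0L, na.rm = TRUE) > 0L
    h2 <- colSums(Ac == 2L, na.rm = TRUE) > 0L
    brk <- het | (h0 & h2)
    shared <- !brk & (h0 | h2)
    full <- shared & nmiss == 0L
    cb <- cumsum(brk)
    cs <- cumsum(shared)
    runs <- matrix(0L, 0L, 2L)
    for (r in seq_len(nrow(Ac))) {
      rl <- rle(is.na(Ac[r, ]))
      e <- cumsum(rl$lengths)
      s <- e - rl$lengths + 1L
      keep <- rl$values & rl$lengths > max_missing_run
      if (any(keep)) runs <- rbind(runs, cbind(s[keep], e[keep]))
    }
    V <- matrix(FALSE, n, n)
    fulls <- which(full)
    for (i in fulls) {
      j <- fulls[fulls >= i]
      base_b <- if (i > 1L) cb[i - 1L] else 0L
      base_s <- if (i > 1L) cs[i - 1L] else 0L
      ok <- (cb[j] - base_b) == 0L & (cs[j] - base_s) >= min_markers
      if (nrow(runs)) {
        for (k in seq_len(nrow(runs))) {
          if (runs[k, 1L] >= i) ok[j >= runs[k, 2L]] <- FALSE
        }
      }
      V[i, j[ok]] <- TRUE
    }
    if (!any(V)) next
    first_i <- apply(V, 2L, function(col) which(col)[1L])
    last_j <- apply(V, 1L, function(row) {
      w <- which(row)
      if (length(w)) w[length(w)] else NA_integer_
    })
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (V[i, j] && first_i[j] == i && last_j[i] == j) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = ch, start_bp = map$bp[sel[i]],
            end_bp = map$bp[sel[j]],
            n_markers = cs[j] - (if (i > 1L) cs[i - 1L] else 0L),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_markers = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Random genotype matrix with enough homozygosity for segments to arise.
random_gm <- function(n_ind, n_markers, n_chrom = 2L, miss = 0.1,
                      seed = 1L) {
  set.seed(seed)
  chrom <- sort(rep_len(paste0("chr", seq_len(n_chrom)), n_markers))
  bp <- unlist(lapply(split(seq_len(n_markers), chrom), function(ix) {
    sort(sample.int(1e8, length(ix)))
  }), use.names = FALSE)
  m <- marker_map(chrom, bp)
  calls <- matrix(
    sample(c(0L, 1L, 2L, NA), n_ind * n_markers, replace = TRUE,
           prob = c(0.4, 0.2, 0.3 - miss / 2, 0.1 + miss / 2)),
    nrow = n_ind, dimnames = list(paste0("I", seq_len(n_ind)), NULL))
  genotype_matrix(calls, m)
}

scan_as_df <- function(segs) {
  df <- data.frame(chrom = segs$chrom, start_bp = segs$start_bp,
                   end_bp = segs$end_bp, n_markers = segs$n_markers,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
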