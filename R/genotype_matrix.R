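#' Construct a genotype matrix
#'
#' Biallelic calls for a set of individuals on a marker map, coded as the
#' count of allele2 (0 = hom allele1, 1 = het, 2 = hom allele2, NA =
#' missing).
#'
#' @param calls integer matrix, individuals x markers; rownames are
#'   individual ids.
#' @param map the `marker_map` the columns refer to.
#' @return a `genotype_matrix` (list with elements calls, map).
#' @export
genotype_matrix <- function(calls, map) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(map)) {
    stop_input("call matrix has ", ncol(calls), " columns for ",
               nrow(map), " map markers")
  }
  if (is.null(rownames(calls))) stop_input("calls must have individual ids as rownames")
  if (anyDuplicated(rownames(calls))) stop_input("duplicate individual ids")
  if (any(calls < 0L | calls > 2L, na.rm = TRUE)) {
    stop_input("calls must be 0, 1, 2 or NA")
  }
  colnames(calls) <- map$id
  structure(list(calls = calls, map = map),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "individuals x",
      ncol(x$calls), "markers on",
      length(unique(x$map$chrom)), "chromosomes\n")
  cr <- round(100 * call_rate(x), 1)
  cat("call rates (%):", paste(sprintf("%s=%s", names(cr), cr), collapse = " "),
      "\n")
  invisible(x)
}

#' Per-individual call rate
#' @param gm a `genotype_matrix`.
#' @return named numeric vector, fraction of non-missing calls.
#' @export
call_rate <- function(gm) rowMeans(!is.na(gm$calls))

#' Resolve calls to allele-symbol genotypes
#'
#' @param gm a `genotype_matrix`.
#' @return character matrix of "X/Y" genotype strings (alleles in map
#'   allele1/allele2 order), NA where missing.
#' @export
genotype_symbols <- function(gm) {
  a1 <- gm$map$allele1
  a2 <- gm$map$allele2
  out <- matrix(NA_character_, nrow(gm$calls), ncol(gm$calls),
                dimnames = dimnames(gm$calls))
  for (code in 0:2) {
    idx <- which(gm$calls == code)
    if (!length(idx)) next
    col <- (idx - 1L) %/% nrow(gm$calls) + 1L
    out[idx] <- switch(as.character(code),
      "0" = paste(a1[col], a1[col], sep = "/"),
      "1" = paste(a1[col], a2[col], sep = "/"),
      "2" = paste(a2[col], a2[col], sep = "/"))
  }
  out
}

#' Subset a genotype matrix by marker index
#' @param gm a `genotype_matrix`.
#' @param idx integer or logical marker index.
#' @return a `genotype_matrix` on the subsetted map.
#' @export
gm_markers <- function(gm, idx) {
  sub <- gm$map[idx, , drop = FALSE]
  class(sub) <- class(gm$map)
  genotype_matrix(gm$calls[, idx, drop = FALSE], sub)
}

#' Subset a genotype matrix by individual id
#' @param gm a `genotype_matrix`.
#' @param ids individual ids to keep.
#' @return a `genotype_matrix`.
#' @export
gm_individuals <- function(gm, ids) {
  missing_ids <- setdiff(ids, rownames(gm$calls))
  if (length(missing_ids)) {
    stop_input("individuals absent from genotype matrix: ",
               paste(missing_ids, collapse = ", "))
  }
  genotype_matrix(gm$calls[ids, , drop = FALSE], gm$map)
}
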