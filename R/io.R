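#' Construct a single-variant genotype table
#'
#' Per-individual genotypes for one biallelic variant, with an optional
#' breed label. Genotype strings are unordered ("G/A" and "A/G" are the
#' same genotype) and normalized to ref-allele-first; strings that do
#' not resolve against the declared ref/alt alleles become missing with
#' a warning.
#'
#' @param individual individual ids (unique).
#' @param genotype genotype strings, e.g. "G/G", "G/A", "A/A"; "0/0",
#'   "./." or NA for missing.
#' @param breed optional breed labels.
#' @param ref,alt the declared reference and alternate allele symbols.
#' @param variant_id label for the variant.
#' @return a `variant_table` data.frame (individual, breed, genotype)
#'   with attributes ref, alt, variant_id.
#' @export
variant_table <- function(individual, genotype, breed = NA_character_,
                          ref = "G", alt = "A",
                          variant_id = "c.1190G>A") {
  individual <- as.character(individual)
  if (anyDuplicated(individual)) {
    stop_input("duplicate individual ids in variant table")
  }
  g <- normalize_genotypes(as.character(genotype), ref, alt)
  tab <- data.frame(individual = individual,
                    breed = rep_len(as.character(breed), length(individual)),
                    genotype = g, stringsAsFactors = FALSE)
  structure(tab, ref = ref, alt = alt, variant_id = variant_id,
            class = c("variant_table", "data.frame"))
}

normalize_genotypes <- function(g, ref, alt) {
  out <- rep(NA_character_, length(g))
  missing_tokens <- c(NA, "", "0/0", "./.", ".", "NA", "0")
  for (i in seq_along(g)) {
    if (g[i] %in% missing_tokens) next
    parts <- strsplit(g[i], "[/|]")[[1L]]
    if (length(parts) != 2L || !all(parts %in% c(ref, alt))) {
      warning("unrecognized genotype string '", g[i],
              "' treated as missing", call. = FALSE)
      next
    }
    out[i] <- if (all(parts == ref)) paste(ref, ref, sep = "/")
              else if (all(parts == alt)) paste(alt, alt, sep = "/")
              else paste(ref, alt, sep = "/")
  }
  out
}

#' Classify variant-table genotypes against ref/alt
#' @param tab a `variant_table`.
#' @return character vector: "hom_ref", "het", "hom_alt" or NA.
#' @export
genotype_class <- function(tab) {
  ref <- attr(tab, "ref"); alt <- attr(tab, "alt")
  cls <- rep(NA_character_, nrow(tab))
  cls[tab$genotype == paste(ref, ref, sep = "/")] <- "hom_ref"
  cls[tab$genotype == paste(ref, alt, sep = "/")] <- "het"
  cls[tab$genotype == paste(alt, alt, sep = "/")] <- "hom_alt"
  cls
}

#' Read PLINK-style .ped/.map text files
#'
#' White-space delimited; .map columns chrom, id, genetic distance
#' (ignored), bp; .ped columns FID IID PAT MAT SEX PHENO followed by two
#' allele columns per marker ("0" = missing allele). PHENO 2 = affected,
#' 1 = unaffected, 0/-9 = unknown; SEX 1 = male, 2 = female, 0 =
#' unknown. Allele symbols per marker are taken from the observed calls
#' (sorted, so allele1 < allele2); a marker with more than two observed
#' alleles is an error.
#'
#' @param ped_path,map_path file paths.
#' @param status_path optional side-car TSV (columns id, status) with
#'   declared carrier statuses, not representable in PLINK itself.
#' @return list with `ped` (a `pedigree`) and `genotypes` (a
#'   `genotype_matrix`).
#' @export
read_plink <- function(ped_path, map_path, status_path = NULL) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  if (!length(map_lines)) stop_input("empty marker map: ", map_path)
  map_f <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_f)
  if (any(nf != 4L)) {
    stop_input("map line ", which(nf != 4L)[1L], " has ",
               nf[nf != 4L][1L], " fields (expected 4)")
  }
  map_m <- do.call(rbind, map_f)
  n_mark <- nrow(map_m)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_f <- strsplit(trimws(ped_lines), "[ \t]+")
  want <- 6L + 2L * n_mark
  nf <- lengths(ped_f)
  if (any(nf != want)) {
    bad <- which(nf != want)[1L]
    stop_input("ped line ", bad, " has ", nf[bad],
               " fields (expected ", want, ")")
  }
  ped_m <- do.call(rbind, ped_f)
  ids <- ped_m[, 2L]
  if (anyDuplicated(ids)) {
    stop_input("duplicate individual id on ped line ",
               which(duplicated(ids))[1L])
  }
  sex <- c("0" = "unknown", "1" = "male", "2" = "female")[ped_m[, 5L]]
  sex[is.na(sex)] <- "unknown"
  ph <- c("2" = "affected", "1" = "unaffected", "0" = "unknown",
          "-9" = "unknown")[ped_m[, 6L]]
  ph[is.na(ph)] <- "unknown"
  status <- rep("none", length(ids))
  if (!is.null(status_path)) {
    st <- utils::read.delim(status_path, header = TRUE,
                            colClasses = "character")
    status[match(st$id, ids)] <- st$status
  }
  ped <- pedigree(id = ids,
                  sire = ifelse(ped_m[, 3L] == "0", NA, ped_m[, 3L]),
                  dam = ifelse(ped_m[, 4L] == "0", NA, ped_m[, 4L]),
                  sex = unname(sex), phenotype = unname(ph),
                  status = status)

  a_cols <- ped_m[, -(1:6), drop = FALSE]
  calls <- matrix(NA_integer_, length(ids), n_mark,
                  dimnames = list(ids, NULL))
  allele1 <- character(n_mark); allele2 <- character(n_mark)
  for (j in seq_len(n_mark)) {
    x1 <- a_cols[, 2L * j - 1L]; x2 <- a_cols[, 2L * j]
    half_missing <- xor(x1 == "0", x2 == "0")
    if (any(half_missing)) {
      stop_input("half-missing genotype for marker ", map_m[j, 2L],
                 ", individual ", ids[half_missing][1L])
    }
    obs <- sort(unique(c(x1, x2)))
    obs <- obs[obs != "0"]
    if (length(obs) > 2L) {
      stop_input("marker ", map_m[j, 2L], " has ", length(obs),
                 " observed alleles")
    }
    if (length(obs) == 0L) obs <- c("A", "B")
    if (length(obs) == 1L) obs <- c(obs, if (obs == "B") "b" else "B")
    allele1[j] <- obs[1L]; allele2[j] <- obs[2L]
    ok <- x1 != "0"
    calls[ok, j] <- (x1[ok] == obs[2L]) + (x2[ok] == obs[2L])
  }
  map <- marker_map(map_m[, 1L], as.integer(map_m[, 4L]), id = map_m[, 2L],
                    allele1 = allele1, allele2 = allele2)
  list(ped = ped, genotypes = genotype_matrix(calls, map))
}

#' Write PLINK-style .ped/.map text files
#'
#' Inverse of [read_plink()] up to allele ordering (the reader sorts
#' allele symbols) and the declared carrier status, which PLINK cannot
#' carry and goes to an optional side-car TSV.
#'
#' @param ped a `pedigree`.
#' @param gm a `genotype_matrix` for (a superset of) the pedigree.
#' @param out_prefix output path prefix; writes `<prefix>.ped`,
#'   `<prefix>.map` and, if any declared statuses, `<prefix>.status.tsv`.
#' @return invisibly, the paths written.
#' @export
write_plink <- function(ped, gm, out_prefix) {
  map_path <- paste0(out_prefix, ".map")
  ped_path <- paste0(out_prefix, ".ped")
  writeLines(paste(gm$map$chrom, gm$map$id, 0L, gm$map$bp, sep = "\t"),
             map_path)
  sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  ph <- c(affected = "2", unaffected = "1", unknown = "0")[ped$phenotype]
  n <- nrow(gm$map)
  lines <- vapply(seq_len(nrow(ped)), function(i) {
    id <- ped$id[i]
    g <- if (id %in% rownames(gm$calls)) gm$calls[id, ] else rep(NA_integer_, n)
    x1 <- ifelse(is.na(g), "0", ifelse(g == 2L, gm$map$allele2, gm$map$allele1))
    x2 <- ifelse(is.na(g), "0", ifelse(g >= 1L, gm$map$allele2, gm$map$allele1))
    paste(c("FAM1", id,
            ifelse(is.na(ped$sire[i]), "0", ped$sire[i]),
            ifelse(is.na(ped$dam[i]), "0", ped$dam[i]),
            sex[i], ph[i], rbind(x1, x2)), collapse = " ")
  }, character(1L))
  writeLines(lines, ped_path)
  paths <- c(ped_path, map_path)
  if (any(ped$status != "none")) {
    st_path <- paste0(out_prefix, ".status.tsv")
    keep <- ped$status != "none"
    utils::write.table(data.frame(id = ped$id[keep], status = ped$status[keep]),
                       st_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, st_path)
  }
  invisible(paths)
}

#' Read a single-variant genotype table
#'
#' Accepts either a TSV with columns `individual`, `genotype` and
#' optionally `breed`, or a minimal single-site VCF (v4.x, GT field);
#' the format is detected from the file content. Unrecognized genotype
#' strings become missing with a warning.
#'
#' @param path file path.
#' @param ref,alt allele symbols for a TSV input (a VCF carries its
#'   own REF/ALT).
#' @param variant_id variant label for a TSV input.
#' @return a `variant_table`.
#' @export
read_variant_table <- function(path, ref = "G", alt = "A",
                               variant_id = "c.1190G>A") {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    return(read_variant_vcf(path))
  }
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           comment.char = "#")
  if (!all(c("individual", "genotype") %in% names(tab))) {
    stop_input("no recognizable individual/genotype columns in ", path)
  }
  variant_table(tab$individual, tab$genotype,
                breed = if ("breed" %in% names(tab)) tab$breed else NA,
                ref = ref, alt = alt, variant_id = variant_id)
}

read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) != 1L) {
    stop_input("expected a single-site VCF, got ", nrow(v@fix), " records")
  }
  ref <- unname(v@fix[1L, "REF"]); alt <- unname(v@fix[1L, "ALT"])
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  alleles <- c("0" = ref, "1" = alt)
  geno <- vapply(gt[1L, ], function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_character_)
    idx <- strsplit(g, "[/|]")[[1L]]
    if (!all(idx %in% names(alleles))) return(NA_character_)
    paste(alleles[idx], collapse = "/")
  }, character(1L))
  variant_table(samples, unname(geno), ref = ref, alt = alt,
                variant_id = paste0(v@fix[1L, "CHROM"], ":",
                                    v@fix[1L, "POS"], ref, ">", alt))
}

#' Write a variant table as TSV
#' @param tab a `variant_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_variant_table <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# variant: %s\tref: %s\talt: %s",
                     attr(tab, "variant_id"), attr(tab, "ref"),
                     attr(tab, "alt")), con)
  utils::write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#' @param path FASTA file.
#' @return a [Biostrings::AAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readAAStringSet(path)

#' Read an aligned FASTA (equal-length sequences)
#'
#' @param path aligned FASTA file; '-' denotes gaps.
#' @return a [Biostrings::AAStringSet] with an attribute
#'   `gap_only_columns`: indices of columns that are gaps in every
#'   sequence.
#' @export
read_aligned_fasta <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  w <- Biostrings::width(s)
  if (length(unique(w)) > 1L) {
    stop_input("aligned FASTA has unequal sequence lengths: ",
               paste(unique(w), collapse = ", "))
  }
  m <- do.call(rbind, strsplit(as.character(s), ""))
  attr(s, "gap_only_columns") <- which(colSums(m != "-") == 0L)
  s
}

#' Write sequences as FASTA wrapped at 60 columns
#' @param seqs a [Biostrings::XStringSet].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}
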