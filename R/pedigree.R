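#' Construct a pedigree
#'
#' Individuals with optional parent links, sex, phenotype and a declared
#' carrier status. Parent links are both-or-none: an individual has
#' either two known parents (both present in the pedigree) or none.
#'
#' @param id character individual ids (unique).
#' @param sire,dam parent ids or NA.
#' @param sex "male", "female" or "unknown".
#' @param phenotype "affected", "unaffected" or "unknown".
#' @param status declared carrier status: "none", "obligate_carrier",
#'   "declared_carrier" or "declared_noncarrier". Obligate carriers are
#'   additionally inferred automatically (parents of affecteds) by the
#'   segregation functions.
#' @return a `pedigree` data.frame.
#' @export
pedigree <- function(id, sire = NA, dam = NA, sex = "unknown",
                     phenotype = "unknown", status = "none") {
  n <- length(id)
  p <- data.frame(
    id = as.character(id),
    sire = rep_len(as.character(sire), n),
    dam = rep_len(as.character(dam), n),
    sex = rep_len(as.character(sex), n),
    phenotype = rep_len(as.character(phenotype), n),
    status = rep_len(as.character(status), n),
    stringsAsFactors = FALSE
  )
  class(p) <- c("pedigree", "data.frame")
  validate_pedigree(p)
}

validate_pedigree <- function(p) {
  if (anyDuplicated(p$id)) stop_input("duplicate individual ids in pedigree")
  bad_sex <- !p$sex %in% c("male", "female", "unknown")
  if (any(bad_sex)) stop_input("invalid sex value: ", p$sex[bad_sex][1L])
  bad_ph <- !p$phenotype %in% c("affected", "unaffected", "unknown")
  if (any(bad_ph)) stop_input("invalid phenotype: ", p$phenotype[bad_ph][1L])
  bad_st <- !p$status %in% c("none", "obligate_carrier", "declared_carrier",
                             "declared_noncarrier")
  if (any(bad_st)) stop_input("invalid status: ", p$status[bad_st][1L])
  one_parent <- is.na(p$sire) != is.na(p$dam)
  if (any(one_parent)) {
    stop_input("individual with exactly one known parent: ",
               p$id[one_parent][1L], " (both or none required)")
  }
  for (col in c("sire", "dam")) {
    ref <- p[[col]][!is.na(p[[col]])]
    if (!all(ref %in% p$id)) {
      stop_input(col, " id not present in pedigree: ",
                 setdiff(ref, p$id)[1L])
    }
  }
  sire_sex <- p$sex[match(p$sire, p$id)]
  if (any(sire_sex == "female", na.rm = TRUE)) {
    stop_input("sire with female sex")
  }
  dam_sex <- p$sex[match(p$dam, p$id)]
  if (any(dam_sex == "male", na.rm = TRUE)) stop_input("dam with male sex")
  topo_order(p)  # errors on cycles
  p
}

#' Founders of a pedigree
#' @param ped a `pedigree`.
#' @return character vector of ids with no known parents.
#' @export
founders <- function(ped) ped$id[is.na(ped$sire)]

#' Topological order of a pedigree
#'
#' Parents before children; errors if the parent links contain a cycle
#' (an individual that is its own ancestor).
#'
#' @param ped a `pedigree`.
#' @return character vector of ids in dependency order.
#' @export
topo_order <- function(ped) {
  remaining <- ped$id
  placed <- character(0)
  while (length(remaining)) {
    idx <- match(remaining, ped$id)
    ready <- (is.na(ped$sire[idx]) | ped$sire[idx] %in% placed) &
      (is.na(ped$dam[idx]) | ped$dam[idx] %in% placed)
    if (!any(ready)) {
      stop_input("pedigree contains a cycle involving: ",
                 paste(remaining, collapse = ", "))
    }
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  placed
}

#' The seven-member mapping family
#'
#' The nuclear family used for homozygosity mapping: an affected sib-pair
#' (KIT1, KIT2), their healthy littermate (KIT3), the two healthy parents
#' (SIRE, DAM) and the paternal grandparents (PGF, PGM). The dam and the
#' paternal grandmother are the default mutation-introducing founders.
#'
#' @return a `pedigree` of 7 individuals.
#' @export
mapping_family_pedigree <- function() {
  pedigree(
    id = c("PGF", "PGM", "DAM", "SIRE", "KIT1", "KIT2", "KIT3"),
    sire = c(NA, NA, NA, "PGF", "SIRE", "SIRE", "SIRE"),
    dam = c(NA, NA, NA, "PGM", "DAM", "DAM", "DAM"),
    sex = c("male", "female", "female", "male", "male", "female", "male"),
    phenotype = c("unaffected", "unaffected", "unaffected", "unaffected",
                  "affected", "affected", "unaffected"),
    status = c("none", "declared_carrier", "none", "none",
               "none", "none", "none")
  )
}
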