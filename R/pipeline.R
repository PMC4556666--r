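#' Validate a pipeline configuration
#'
#' Assembles the end-to-end run configuration: stage toggles, stage
#' parameters and the output directory. Unknown keys are rejected.
#'
#' @param out_dir output directory.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param ... overrides for the default keys (see Details).
#' @details Recognized keys and defaults: simulate (TRUE), map_regions
#'   (TRUE), segregate (TRUE), conserve (TRUE); n_markers (12000),
#'   missing_rate (0.02), min_markers (8), max_missing_run (2),
#'   merge_gap_bp (1e6), tolerance (0), slop_bp (4e6), conf_level
#'   (0.95), domain_window (c(375, 451)), resume (FALSE). The demo
#'   simulation runs at roughly a fifth of a real array's marker
#'   density, so its min_markers default is scaled down accordingly
#'   from the scan's full-density default of 20.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, ...) {
  defaults <- list(
    simulate = TRUE, map_regions = TRUE, segregate = TRUE,
    conserve = TRUE, n_markers = 12000L, missing_rate = 0.02,
    min_markers = 8L, max_missing_run = 2L, merge_gap_bp = 1e6,
    tolerance = 0L, slop_bp = 4e6, conf_level = 0.95,
    domain_window = c(375L, 451L), resume = FALSE
  )
  extra <- list(...)
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown)) {
    stop_input("unknown configuration keys: ",
               paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, extra)
  cfg$seed <- as.integer(seed)
  cfg$version <- as.character(utils::packageVersion("autozyg"))
  # the hash covers the scientific settings, not the output location,
  # so identical analyses hash identically wherever they run
  cfg$hash <- rlang::hash(cfg[sort(names(cfg))])
  cfg$out_dir <- out_dir
  structure(cfg, class = "pipeline_config")
}

#' Read a key/value configuration file
#'
#' One `key = value` (or `key: value`) pair per line; `#` comments and
#' blank lines ignored. Values are parsed as logical, numeric or left
#' as character.
#'
#' @param path config file path.
#' @param out_dir,seed as in [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir, seed = 1L) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=:]", fixed = FALSE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop_input("malformed config line: ", lines[bad][1L])
  vals <- lapply(kv, function(p) {
    v <- trimws(p[2L])
    if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  })
  names(vals) <- trimws(vapply(kv, `[[`, character(1L), 1L))
  do.call(pipeline_config, c(list(out_dir = out_dir, seed = seed), vals))
}

write_tsv_report <- function(df, path, cfg, header_extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# autozyg %s\tconfig_hash: %s\tseed: %d",
                       cfg$version, cfg$hash, cfg$seed),
               header_extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the end-to-end analysis
#'
#' Executes the enabled stages in dependency order: simulate a family
#' dataset, map and filter shared homozygous regions, check segregation
#' and carrier frequency on the bundled cohort fixtures, and run the
#' conservation analysis on a synthetic ortholog bundle. Outputs are
#' tab-separated with `#`-prefixed headers naming the config hash;
#' machine-readable JSON sits next to each TSV. With `resume = TRUE`
#' a stage whose outputs already exist is skipped.
#'
#' @param cfg a `pipeline_config`.
#' @return a `run_manifest` list: per-stage outputs, warnings, config
#'   hash and a manifest hash that is identical for identical
#'   inputs + config + seed.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = cfg$hash, seed = cfg$seed,
                   stages = list(), files = character(),
                   warnings = character())

  fam <- NULL
  if (cfg$simulate) {
    sim_path <- file.path(cfg$out_dir, "synthetic_family")
    if (cfg$resume && file.exists(paste0(sim_path, ".ped"))) {
      manifest$stages$simulate <- list(skipped = "resume")
    } else {
      fam <- simulate_family_dataset(sim_config(
        n_markers = cfg$n_markers, missing_rate = cfg$missing_rate,
        seed = derive_seed(cfg$seed, "simulate")))
      paths <- write_plink(fam$ped, fam$genotypes, sim_path)
      manifest$files <- c(manifest$files, paths)
      manifest$stages$simulate <- list(
        n_markers = nrow(fam$map), n_individuals = nrow(fam$ped),
        causal = fam$causal,
        call_rates = round(call_rate(fam$genotypes), 4))
    }
  }

  if (cfg$map_regions) {
    if (is.null(fam)) {
      loaded <- read_plink(file.path(cfg$out_dir, "synthetic_family.ped"),
                           file.path(cfg$out_dir, "synthetic_family.map"))
      gm <- loaded$genotypes
      ped <- loaded$ped
      causal <- NULL
    } else {
      gm <- fam$genotypes; ped <- fam$ped; causal <- fam$causal
    }
    affected <- ped$id[ped$phenotype == "affected"]
    segs <- shared_homozygosity_scan(gm, affected,
                                     min_markers = cfg$min_markers,
                                     max_missing_run = cfg$max_missing_run,
                                     merge_gap_bp = cfg$merge_gap_bp)
    obligate <- setdiff(unique(stats::na.omit(
      c(ped$sire[ped$id %in% affected], ped$dam[ped$id %in% affected]))),
      affected)
    declared <- setdiff(ped$id[ped$status == "declared_carrier"],
                        c(obligate, affected))
    unaff <- setdiff(ped$id[ped$phenotype == "unaffected"],
                     c(obligate, declared))
    regions <- apply_consistency_filter(
      segs, gm, consistency_rules(obligate, declared, unaff,
                                  tolerance = cfg$tolerance))
    rep <- region_report(regions)
    p <- write_tsv_report(rep, file.path(cfg$out_dir, "regions.tsv"), cfg,
                          sprintf("# min_markers: %d\tmax_missing_run: %d\tmerge_gap_bp: %g\ttolerance: %d",
                                  cfg$min_markers, cfg$max_missing_run,
                                  cfg$merge_gap_bp, cfg$tolerance))
    jp <- file.path(cfg$out_dir, "regions.json")
    jsonlite::write_json(list(config_hash = cfg$hash, regions = rep),
                         jp, auto_unbox = TRUE, digits = NA)
    manifest$files <- c(manifest$files, p, jp)
    consistent <- rep[rep$status == "consistent", , drop = FALSE]
    causal_hit <- if (!is.null(causal)) {
      cb <- causal$marker_bp %||% causal$bp
      any(consistent$chrom == causal$chrom &
            consistent$start_bp <= cb &
            consistent$end_bp >= cb)
    } else NA
    manifest$stages$map_regions <- list(
      n_segments = nrow(segs), n_consistent = nrow(consistent),
      causal_in_consistent = causal_hit)
  }

  if (cfg$segregate) {
    ped <- segregation_family_pedigree()
    tab <- segregation_variant_table()
    verdicts <- classify_compatibility(ped, tab)
    conc <- concordance(verdicts)
    p <- write_tsv_report(verdicts,
                          file.path(cfg$out_dir, "segregation.tsv"), cfg,
                          sprintf("# concordance_percent: %.1f", conc$percent))
    panel <- panel_summary(breed_panel_table())
    p2 <- write_tsv_report(panel, file.path(cfg$out_dir, "panels.tsv"), cfg)
    sphynx <- carrier_frequency(
      breed_panel_table()[breed_panel_table()$breed == "Control Sphynx", ],
      conf_level = cfg$conf_level)
    manifest$files <- c(manifest$files, p, p2)
    manifest$stages$segregate <- list(
      concordance_percent = conc$percent, n_typed = conc$n_typed,
      sphynx_carrier_percent = sphynx$percent,
      sphynx_ci_percent = round(sphynx$ci_percent, 2))
  }

  if (cfg$conserve) {
    cys <- c(375L, 381L, 397L, 400L, 405L, 412L, 423L, 431L, 440L, 451L)
    orth <- generate_ortholog_set(
      reference_length = 455L, n_species = 8L, conserved_positions = cys,
      divergence = 0.13, seed = derive_seed(cfg$seed, "orthologs"),
      conserved_residue = "C",
      species_names = c("ref_species", paste0("ortholog_", 1:7)))
    fp <- file.path(cfg$out_dir, "synthetic_orthologs.fasta")
    write_fasta(orth, fp)
    mapping <- map_cdna_variant(1190L, "G", "A", synthetic_cds(455L, 397L))
    profile <- conserved_column_scan(orth, "ref_species",
                                     window = cfg$domain_window,
                                     residues = "C")
    ident <- pairwise_identity(orth[["ref_species"]], orth[["ortholog_1"]],
                               mode = "global")
    rep <- substitution_report(mapping, profile,
                               domain_window = cfg$domain_window)
    manifest$files <- c(manifest$files, fp)
    manifest$stages$conserve <- list(
      change = mapping$hgvs_p,
      conserved_cysteines = length(profile$matching_residues),
      residue_conserved = rep$conserved,
      classification = rep$classification,
      identity_percent = ident$percent)
  }

  manifest$files <- basename(manifest$files)
  manifest$manifest_hash <- rlang::hash(manifest[setdiff(names(manifest),
                                                         "manifest_hash")])
  mp <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  structure(manifest, class = "run_manifest")
}

#' @exportS3Method base::print
print.run_manifest <- function(x, ...) {
  cat("run_manifest", x$manifest_hash, "\n")
  for (s in names(x$stages)) {
    cat("stage", s, ":",
        paste(names(x$stages[[s]]),
              vapply(x$stages[[s]], function(v) paste(format(v), collapse = ","),
                     character(1L)),
              sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}
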