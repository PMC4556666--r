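# build a genotype matrix from a small integer matrix on one chromosome
gm_from <- function(calls, chrom = "1") {
  calls <- rbind(calls)
  genotype_matrix(calls, marker_map(rep(chrom, ncol(calls)),
                                    seq_len(ncol(calls)) * 1e5))
}

test_that("degenerate inputs yield no shared segments", {
  # a fully heterozygous affected individual
  gm <- gm_from(matrix(1L, 1, 50, dimnames = list("A", NULL)))
  expect_equal(nrow(shared_homozygosity_scan(gm, "A", min_markers = 5)), 0L)
  # two affecteds homozygous for opposite alleles everywhere
  gm2 <- gm_from(matrix(c(0L, 2L), 2, 50, dimnames = list(c("A", "B"), NULL)))
  expect_equal(nrow(shared_homozygosity_scan(gm2, c("A", "B"),
                                             min_markers = 5)), 0L)
  expect_error(shared_homozygosity_scan(gm, "nope"), "absent")
})

test_that("the scan equals exhaustive window enumeration on random matrices", {
  for (case in 1:12) {
    n_ind <- sample(2:6, 1)
    n_markers <- sample(c(80L, 150L, 300L), 1)
    gm <- random_gm(n_ind, n_markers, n_chrom = sample(1:3, 1),
                    seed = 500 + case)
    affected <- rownames(gm$calls)[seq_len(sample(1:2, 1))]
    mm <- sample(1:5, 1)
    mr <- sample(0:3, 1)
    got <- shared_homozygosity_scan(gm, affected, min_markers = mm,
                                    max_missing_run = mr,
                                    merge_gap_bp = 0)
    expect_equal(scan_as_df(got),
                 brute_scan(gm, affected, min_markers = mm,
                            max_missing_run = mr),
                 info = sprintf("case %d (mm=%d mr=%d)", case, mm, mr))
  }
})

test_that("scan output ignores individual order and marker-id relabelling", {
  gm <- random_gm(4, 200, seed = 77)
  segs <- shared_homozygosity_scan(gm, c("I1", "I2"), min_markers = 3,
                                   merge_gap_bp = 0)
  # permute individuals
  perm <- gm
  perm$calls <- gm$calls[c(3, 1, 4, 2), ]
  segs_p <- shared_homozygosity_scan(perm, c("I2", "I1"), min_markers = 3,
                                     merge_gap_bp = 0)
  expect_equal(scan_as_df(segs), scan_as_df(segs_p))
  # relabel marker ids
  rel <- gm
  rel$map$id <- paste0("renamed_", seq_len(nrow(rel$map)))
  colnames(rel$calls) <- rel$map$id
  segs_r <- shared_homozygosity_scan(rel, c("I1", "I2"), min_markers = 3,
                                     merge_gap_bp = 0)
  expect_equal(scan_as_df(segs), scan_as_df(segs_r))
})

test_that("runs neither begin nor end on missing calls", {
  calls <- matrix(c(NA, 0L, 0L, 0L, NA), 1, dimnames = list("A", NULL))
  gm <- gm_from(calls)
  segs <- shared_homozygosity_scan(gm, "A", min_markers = 2,
                                   max_missing_run = 3, merge_gap_bp = 0)
  expect_equal(segs$start_bp, 2e5)
  expect_equal(segs$end_bp, 4e5)
  expect_equal(segs$n_markers, 3L)
})

test_that("carrier rules exclude segments as specified, with tolerance boundaries", {
  # one segment of 10 markers, affecteds homozygous allele1 (code 0)
  aff <- matrix(0L, 2, 10, dimnames = list(c("A1", "A2"), NULL))
  # carrier het everywhere: passes; carrier hom-opposite at 1 marker:
  # fails at tolerance 0, passes at tolerance 1
  carrier <- rep(1L, 10)
  carrier_bad <- carrier; carrier_bad[5] <- 2L
  hom_carrier <- rep(0L, 10)
  gm <- gm_from(rbind(aff, CAR = carrier_bad, HOM = hom_carrier,
                      UNAFF = rep(1L, 10)))
  segs <- shared_homozygosity_scan(gm, c("A1", "A2"), min_markers = 5,
                                   merge_gap_bp = 0)
  expect_equal(nrow(segs), 1L)

  r0 <- apply_consistency_filter(segs, gm,
                                 consistency_rules("CAR", tolerance = 0))
  expect_equal(r0$status, "excluded")
  v <- attr(r0, "verdicts")
  expect_equal(v$n_violations, 1L)
  expect_equal(v$first_fail_marker, gm$map$id[5])

  r1 <- apply_consistency_filter(segs, gm,
                                 consistency_rules("CAR", tolerance = 1))
  expect_equal(r1$status, "consistent")

  # a carrier homozygous for the signature across the segment would be
  # affected: excluded even though it never lacks the shared allele
  rh <- apply_consistency_filter(segs, gm, consistency_rules("HOM"))
  expect_equal(rh$status, "excluded")
  # an unaffected relative fails only the homozygosity rule
  ru <- apply_consistency_filter(
    segs, gm, consistency_rules(unaffected_relatives = c("HOM", "UNAFF")))
  vu <- attr(ru, "verdicts")
  expect_equal(vu$pass[vu$individual == "HOM"], FALSE)
  expect_equal(vu$pass[vu$individual == "UNAFF"], TRUE)

  expect_warning(apply_consistency_filter(segs, gm, consistency_rules()),
                 "empty rule set")
})

test_that("six constructed segments reduce to the single consistent one", {
  # six chromosomes, one 12-marker shared-homozygous block each;
  # relatives violate a rule on five of them
  n <- 12L
  blocks <- lapply(1:6, function(k) {
    a <- matrix(0L, 2, n)
    sire <- rep(1L, n); dam <- rep(1L, n); sib <- rep(1L, n)
    if (k == 1) sire[4] <- 2L          # sire lacks the shared allele
    if (k == 2) dam[7] <- 2L           # dam lacks the shared allele
    if (k == 3) sib <- rep(0L, n)      # sib homozygous: would be affected
    if (k == 4) sire <- rep(0L, n)     # sire homozygous: would be affected
    if (k == 5) { sire[2] <- 2L; dam[9] <- 2L }
    rbind(a, sire, dam, sib)
  })
  calls <- do.call(cbind, blocks)
  rownames(calls) <- c("A1", "A2", "SIRE", "DAM", "SIB")
  m <- marker_map(rep(paste0("chr", 1:6), each = n),
                  rep(seq_len(n) * 1e5, 6))
  gm <- genotype_matrix(calls, m)
  segs <- shared_homozygosity_scan(gm, c("A1", "A2"), min_markers = 5,
                                   merge_gap_bp = 0)
  expect_equal(nrow(segs), 6L)
  regions <- apply_consistency_filter(
    segs, gm, consistency_rules(obligate_carriers = c("SIRE", "DAM"),
                                unaffected_relatives = "SIB"))
  expect_equal(sum(regions$status == "consistent"), 1L)
  expect_equal(regions$chrom[regions$status == "consistent"], "chr6")
  # the filter only removes: every consistent region is a scanned segment
  key <- function(df) paste(df$chrom, df$start_bp, df$end_bp)
  expect_true(all(key(regions[regions$status == "consistent", ]) %in%
                    key(segs)))
})

test_that("nearby segments with agreeing signatures merge across small gaps", {
  # two 6-marker blocks separated by one heterozygous marker
  calls <- matrix(c(rep(0L, 6), 1L, rep(0L, 6)), 1,
                  dimnames = list("A", NULL))
  gm <- gm_from(calls)
  apart <- shared_homozygosity_scan(gm, "A", min_markers = 3,
                                    merge_gap_bp = 0)
  expect_equal(nrow(apart), 2L)
  merged <- shared_homozygosity_scan(gm, "A", min_markers = 3,
                                     merge_gap_bp = 1e6)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_markers, 12L)
  expect_equal(merged$start_bp, 1e5)
  expect_equal(merged$end_bp, 13e5)
})

test_that("region reports use boundary-difference spans in Mb", {
  r <- data.frame(chrom = "C2", start_bp = 137108027L,
                  end_bp = 140984522L, n_markers = 60L)
  rep <- region_report(r)
  expect_equal(rep$span_bp, 3876495L)
  expect_equal(rep$span_mb, 3.9)
  # degenerate zero-length region
  r0 <- data.frame(chrom = "1", start_bp = 5L, end_bp = 5L, n_markers = 1L)
  expect_equal(region_report(r0)$span_mb, 0)
  # random intervals: span equals independent subtraction
  set.seed(42)
  s <- sample.int(1e8, 50)
  e <- s + sample.int(1e7, 50)
  rr <- region_report(data.frame(chrom = "1", start_bp = s, end_bp = e,
                                 n_markers = 1L))
  expect_equal(rr$span_bp, e - s)
})

test_that("gene overlap honours the vicinity rule with exact distances", {
  regions <- data.frame(chrom = "C2", start_bp = 137108027L,
                        end_bp = 140984522L)
  genes <- data.frame(
    gene = c("inside", "nearby", "far", "other_chrom"),
    chrom = c("C2", "C2", "C2", "A1"),
    start = c(138000000L, 140984522L + 3900000L, 160000000L, 138000000L),
    end = c(138050000L, 140984522L + 3977168L, 160050000L, 138050000L))
  hit0 <- gene_overlap(regions, genes, slop_bp = 0)
  expect_equal(hit0$gene, "inside")
  expect_equal(hit0$distance_bp, 0L)
  hit4 <- gene_overlap(regions, genes, slop_bp = 4e6)
  expect_equal(hit4$gene, c("inside", "nearby"))
  expect_equal(hit4$distance_bp, c(0L, 3900000L))
  # brute-force distance check on random tables
  set.seed(9)
  rg <- data.frame(chrom = "z", start_bp = 5e6, end_bp = 6e6)
  gs <- sort(sample.int(1.2e7, 30))
  tab <- data.frame(gene = paste0("g", 1:30), chrom = "z",
                    start = gs, end = gs + 1e4)
  got <- gene_overlap(rg, tab, slop_bp = 1.2e7)
  ref_d <- vapply(seq_len(nrow(tab)), function(i) {
    if (tab$end[i] < rg$start_bp) rg$start_bp - tab$end[i]
    else if (tab$start[i] > rg$end_bp) tab$start[i] - rg$end_bp
    else 0
  }, numeric(1))
  expect_equal(got$distance_bp[match(tab$gene, got$gene)], ref_d)
})
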