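small_map <- function(n, chrom = "1", spacing = 1e5) {
  marker_map(rep(chrom, n), seq_len(n) * spacing)
}

test_that("founder haplotypes follow the stated allele frequencies", {
  m <- small_map(50)
  # degenerate frequency: allele1 everywhere
  h <- simulate_founder_haplotypes(m, freqs = 1, n_founders = 2, seed = 1)
  expect_true(all(h == 1L))
  # frequency 0.5: mean allele1 fraction within 3 binomial SD
  m2 <- small_map(1000)
  h2 <- simulate_founder_haplotypes(m2, freqs = 0.5, n_founders = 4,
                                    seed = 5)
  n_draws <- length(h2)
  frac <- mean(h2 == 1L)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_draws))
  # determinism
  h3 <- simulate_founder_haplotypes(m2, freqs = 0.5, n_founders = 4,
                                    seed = 5)
  expect_identical(h2, h3)
  expect_error(simulate_founder_haplotypes(m, freqs = 0, n_founders = 2),
               "frequencies")
})

test_that("gene dropping without recombination transmits whole haplotypes", {
  m <- small_map(200)
  ped <- pedigree(id = c("F1", "F2", "C"), sire = c(NA, NA, "F1"),
                  dam = c(NA, NA, "F2"),
                  sex = c("male", "female", "unknown"))
  h <- simulate_founder_haplotypes(m, 0.5, ids = c("F1", "F2"), seed = 2)
  res <- drop_genes(ped, h, m, recomb_rate = 0, seed = 3)
  o <- res$truth$origins[["C"]]
  # each gamete carries a single founder haplotype across the chromosome
  expect_equal(length(unique(o[1, ])), 1L)
  expect_equal(length(unique(o[2, ])), 1L)
  expect_true(res$truth$hap_labels[o[1, 1]] %in% c("F1.1", "F1.2"))
  expect_true(res$truth$hap_labels[o[2, 1]] %in% c("F2.1", "F2.2"))
})

mendel_ok <- function(child, p1, p2) {
  # genotype codes are allele2 counts; a child must receive one allele
  # from each parent
  lo <- pmax(0L, p1 - 1L, na.rm = TRUE) + pmax(0L, p2 - 1L, na.rm = TRUE)
  hi <- pmin(1L, p1) + pmin(1L, p2)
  child >= lo & child <= hi
}

test_that("every simulated trio is Mendelian-consistent at every marker", {
  m <- small_map(2000, spacing = 5e4)
  ped <- mapping_family_pedigree()
  for (rep in 1:100) {
    h <- simulate_founder_haplotypes(m, 0.5, ids = founders(ped),
                                     seed = 1000 + rep)
    res <- drop_genes(ped, h, m, recomb_rate = 1, seed = NULL)
    g <- res$genotypes$calls
    for (i in which(!is.na(ped$sire))) {
      expect_true(all(mendel_ok(g[ped$id[i], ], g[ped$sire[i], ],
                                g[ped$dam[i], ])))
    }
  }
})

test_that("full sibs share both parental origins at about a quarter of markers", {
  n_per_chrom <- 1000L
  chroms <- paste0("c", 1:5)
  m <- marker_map(rep(chroms, each = n_per_chrom),
                  rep(seq_len(n_per_chrom) * 1e5, 5))
  ped <- pedigree(id = c("F1", "F2", "S1", "S2"),
                  sire = c(NA, NA, "F1", "F1"), dam = c(NA, NA, "F2", "F2"),
                  sex = c("male", "female", "unknown", "unknown"))
  ibd2 <- numeric(60)
  for (rep in seq_along(ibd2)) {
    h <- simulate_founder_haplotypes(m, 0.5, ids = c("F1", "F2"),
                                     seed = 400 + rep)
    res <- drop_genes(ped, h, m, recomb_rate = 1, seed = NULL)
    o1 <- res$truth$origins[["S1"]]
    o2 <- res$truth$origins[["S2"]]
    ibd2[rep] <- mean(o1[1, ] == o2[1, ] & o1[2, ] == o2[2, ])
  }
  expect_lt(abs(mean(ibd2) - 0.25), 0.03)
})

test_that("recessive phenotype assignment follows descent at the causal locus", {
  m <- small_map(100)
  causal <- list(chrom = "1", bp = 5e6)
  # no carrier founders: nobody affected
  ped <- pedigree(id = c("F1", "F2", "C1", "C2"),
                  sire = c(NA, NA, "F1", "F1"), dam = c(NA, NA, "F2", "F2"),
                  sex = c("male", "female", "unknown", "unknown"))
  h <- simulate_founder_haplotypes(m, 0.5, ids = c("F1", "F2"), seed = 1)
  res <- drop_genes(ped, h, m, seed = 2)
  ph <- implant_recessive_disease(res$truth, causal,
                                  carrier_founders = character(0))
  expect_true(all(ph$phenotype == "unaffected"))
  # carrier x noncarrier: children can carry but never be affected
  ph2 <- implant_recessive_disease(res$truth, causal,
                                   carrier_founders = "F1")
  expect_true(all(ph2$phenotype[ph2$id %in% c("C1", "C2")] == "unaffected"))
  expect_true(all(ph2$n_mutant[ph2$id %in% c("C1", "C2")] <= 1L))
})

test_that("carrier x carrier matings produce about a quarter affected", {
  n_kids <- 600L
  kids <- paste0("K", seq_len(n_kids))
  ped <- pedigree(id = c("F1", "F2", kids),
                  sire = c(NA, NA, rep("F1", n_kids)),
                  dam = c(NA, NA, rep("F2", n_kids)),
                  sex = c("male", "female", rep("unknown", n_kids)))
  m <- small_map(20)
  h <- simulate_founder_haplotypes(m, 0.5, ids = c("F1", "F2"), seed = 7)
  res <- drop_genes(ped, h, m, recomb_rate = 0, seed = 8)
  ph <- implant_recessive_disease(res$truth, list(chrom = "1", bp = 1e6),
                                  carrier_founders = c("F1", "F2"))
  frac <- mean(ph$phenotype[ph$id %in% kids] == "affected")
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / n_kids))
})

test_that("missingness masks calls at the stated rate and spares call rates", {
  m <- small_map(500)
  calls <- matrix(0L, 4, 500, dimnames = list(paste0("I", 1:4), NULL))
  gm <- genotype_matrix(calls, m)
  expect_identical(apply_missingness(gm, 0)$calls, gm$calls)
  # aggregate missing count across replicates near rate * n_calls
  n_miss <- vapply(1:50, function(s) {
    sum(is.na(apply_missingness(gm, 0.1, seed = s)$calls))
  }, numeric(1))
  n_calls <- length(calls)
  expect_lt(abs(mean(n_miss) - 0.1 * n_calls),
            3 * sqrt(0.1 * 0.9 * n_calls / 50))
  # at the array's missing rate, per-individual call rates stay > 95%
  big <- genotype_matrix(matrix(0L, 5, 61705,
                                dimnames = list(paste0("I", 1:5), NULL)),
                         cat_marker_map(61705, seed = 1))
  cr <- call_rate(apply_missingness(big, 0.04, seed = 9))
  expect_true(all(cr > 0.95))
  expect_error(apply_missingness(gm, 1), "rate")
})

test_that("control panels carry the requested heterozygote fraction and no hom-alt", {
  p0 <- simulate_panel(211, 0, seed = 1)
  expect_true(all(p0$genotype == "G/G"))
  p1 <- simulate_panel(50, 1, seed = 1)
  expect_true(all(p1$genotype == "G/A"))
  p <- simulate_panel(10000, 0.037, seed = 2)
  frac <- mean(p$genotype == "G/A")
  expect_lt(abs(frac - 0.037), 3 * sqrt(0.037 * 0.963 / 10000))
  for (s in 1:5) {
    f <- runif(1)
    expect_false(any(simulate_panel(200, f, seed = s)$genotype == "A/A"))
  }
})

test_that("ortholog sets respect conserved positions and divergence", {
  o0 <- generate_ortholog_set(100, 5, divergence = 0, seed = 1)
  expect_true(all(as.character(o0) == as.character(o0)[1]))
  # divergence without conserved positions: identity about 1 - d
  o <- generate_ortholog_set(800, 2, divergence = 0.13, seed = 3)
  ident <- mean(strsplit(as.character(o)[1], "")[[1]] ==
                  strsplit(as.character(o)[2], "")[[1]])
  expect_lt(abs(ident - 0.87), 3 * sqrt(0.13 * 0.87 / 800))
  # conserved positions never mutate
  cons <- c(10L, 40L, 70L)
  oc <- generate_ortholog_set(80, 6, conserved_positions = cons,
                              divergence = 0.9, seed = 4,
                              conserved_residue = "C")
  chars <- do.call(rbind, strsplit(as.character(oc), ""))
  expect_true(all(chars[, cons] == "C"))
  expect_false(any(apply(chars[, -cons, drop = FALSE], 2,
                         function(col) all(col == "C"))))
  expect_error(generate_ortholog_set(10, 3, conserved_positions = 11L),
               "outside")
})

test_that("family datasets are deterministic and honest about the truth", {
  cfg <- sim_config(n_markers = 4000, seed = 11)
  fam1 <- simulate_family_dataset(cfg)
  fam2 <- simulate_family_dataset(cfg)
  expect_identical(fam1$genotypes$calls, fam2$genotypes$calls)
  expect_identical(fam1$ped, fam2$ped)
  # ascertainment delivered the affected sib-pair and nobody else
  expect_setequal(fam1$ped$id[fam1$ped$phenotype == "affected"],
                  c("KIT1", "KIT2"))
  # affected individuals are homozygous-by-descent at the causal marker
  expect_true(all(fam1$phenos$n_mutant[fam1$phenos$phenotype ==
                                         "affected"] == 2L))
  expect_true(all(call_rate(fam1$genotypes) > 0.95))
})

test_that("every simulated dataset passes a trio consistency sweep", {
  fam <- simulate_family_dataset(sim_config(n_markers = 3000, seed = 21))
  g <- fam$genotypes$calls
  ped <- fam$ped
  for (i in which(!is.na(ped$sire))) {
    ok <- mendel_ok(g[ped$id[i], ], g[ped$sire[i], ], g[ped$dam[i], ])
    expect_true(all(ok, na.rm = TRUE))
  }
})
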