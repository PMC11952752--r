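test_that("MAC-stratified Bonferroni thresholds follow the closed form", {
  assoc <- data.frame(snp_id = paste0("s", 1:1000), mac = 50)
  tt <- mac_bonferroni(assoc, alpha = 0.05, mac_cutoffs = 5)
  expect_equal(tt$n_snps, 1000L)
  expect_equal(tt$threshold_neglog10p, -log10(0.05 / 1000))
  expect_equal(round(tt$threshold_neglog10p, 4), 4.3010)

  one <- mac_bonferroni(data.frame(snp_id = "s1", mac = 9), 0.05, 5)
  expect_equal(round(one$threshold_neglog10p, 4), 1.3010)

  # macs {3, 6, 12}, cutoffs {5, 10}: n = {2, 1}
  tri <- mac_bonferroni(data.frame(snp_id = c("a", "b", "c"),
                                   mac = c(3, 6, 12)),
                        alpha = 0.05, mac_cutoffs = c(5, 10))
  expect_equal(tri$n_snps, c(2L, 1L))
  expect_equal(tri$threshold_neglog10p,
               c(-log10(0.05 / 2), -log10(0.05 / 1)))

  # a cutoff with no qualifying SNP is undefined, not an error
  none <- mac_bonferroni(data.frame(snp_id = "a", mac = 2), 0.05, c(1, 10))
  expect_true(is.na(none$threshold_neglog10p[2]))

  # SNPs repeated across traits are counted once
  dup <- data.frame(snp_id = c("a", "a", "b"), mac = c(8, 8, 8))
  expect_equal(mac_bonferroni(dup, 0.05, 5)$n_snps, 2L)
})

test_that("threshold table is monotone: counts down, bars up with cutoff", {
  set.seed(14)
  for (i in 1:10) {
    assoc <- data.frame(snp_id = paste0("s", 1:200),
                        mac = sample(1:60, 200, TRUE))
    tt <- mac_bonferroni(assoc, 0.05, c(3, 5, 10, 20, 40))
    expect_true(all(diff(tt$n_snps) <= 0))
    ok <- !is.na(tt$threshold_neglog10p)
    expect_true(all(diff(tt$threshold_neglog10p[ok]) <= 0))
    # threshold strictly increases with n_snps
    expect_true(all(order(tt$n_snps[ok]) ==
                    order(tt$threshold_neglog10p[ok])))
  }
})

test_that("MAC-matched significance filtering uses the stratum threshold", {
  tt <- mac_bonferroni(data.frame(snp_id = paste0("s", 1:100),
                                  mac = rep(c(6, 20), 50)),
                       alpha = 0.05, mac_cutoffs = c(5, 10))
  assoc <- data.frame(snp_id = c("x1", "x2", "x3"),
                      chrom = "1", pos = c(100, 200, 300),
                      mac = c(3, 6, 20),
                      pvalue = c(1e-9, 1e-9, 1e-3), trait = "t")
  sig <- filter_significant(assoc, tt)
  # mac 3 is below the smallest cutoff: never significant
  expect_false("x1" %in% sig$snp_id)
  # mac 6 judged against the mac>=5 bar
  expect_true("x2" %in% sig$snp_id)
  # mac 20 judged against the mac>=10 bar; 3 < -log10(0.05/50)
  expect_false("x3" %in% sig$snp_id)
})

test_that("cluster_loci merges SNPs by single linkage within the window", {
  assoc <- data.frame(snp_id = c("a", "b", "c"), chrom = "1",
                      pos = c(100, 5000, 50000),
                      pvalue = c(1e-6, 1e-8, 1e-7), trait = "t1")
  loci <- cluster_loci(assoc, window_bp = 10000)
  expect_equal(nrow(loci), 2L)
  two <- loci[loci$n_snps == 2L, ]
  expect_equal(c(two$start, two$end), c(100, 5000))
  one <- loci[loci$n_snps == 1L, ]
  expect_equal(c(one$start, one$end), c(50000, 50000))

  # single SNP -> span-0 locus; empty input -> empty table
  s1 <- cluster_loci(assoc[1, ], 10000)
  expect_equal(s1$start, s1$end)
  expect_equal(nrow(cluster_loci(assoc[0, ], 10000)), 0L)
})

test_that("cluster_loci is order-invariant and conserves SNPs", {
  set.seed(27)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    assoc <- data.frame(
      snp_id = paste0("s", 1:n),
      chrom = sample(c("1", "2"), n, TRUE),
      pos = sample(1:200000, n),
      pvalue = 10^-runif(n, 2, 10),
      trait = sample(c("root", "shoot"), n, TRUE))
    loci <- cluster_loci(assoc, window_bp = 10000)
    shuffled <- cluster_loci(assoc[sample(n), ], window_bp = 10000)
    expect_equal(loci, shuffled)
    members <- unlist(strsplit(loci$snp_ids, ";", fixed = TRUE))
    expect_setequal(members, assoc$snp_id)
    expect_equal(sum(loci$n_snps), n)
    expect_true(all(loci$start <= loci$end))
  }
})

test_that("haplotype grouping tallies patterns and excludes small groups", {
  gm <- data.frame(accession = paste0("a", 1:6),
                   s1 = c(0, 0, 0, 1, 1, 0),
                   s2 = c(0, 0, 0, 1, 1, 1))
  hap <- haplotype_group(gm, c("s1", "s2"), min_accessions = 3)
  expect_equal(nrow(hap$haplotypes), 1L)
  expect_equal(hap$haplotypes$pattern, "00")
  expect_equal(hap$haplotypes$n, 3L)
  expect_setequal(hap$excluded$accession, c("a4", "a5", "a6"))

  # all identical -> a single haplotype holding everyone
  gm2 <- data.frame(accession = paste0("a", 1:4), s1 = 1, s2 = 0)
  hap2 <- haplotype_group(gm2, c("s1", "s2"))
  expect_equal(hap2$haplotypes$n, 4L)
  expect_equal(unique(hap2$assignment$haplotype), "H1")

  # all unique patterns -> zero retained haplotypes, with a warning
  gm3 <- data.frame(accession = paste0("a", 1:3),
                    s1 = c(0, 0, 1), s2 = c(0, 1, 1))
  expect_warning(hap3 <- haplotype_group(gm3, c("s1", "s2")), "min_accessions")
  expect_equal(nrow(hap3$haplotypes), 0L)

  expect_error(haplotype_group(gm, character(0)), "non-empty")
  expect_error(haplotype_group(gm, "nope"), "absent")
})

test_that("haplotype grouping matches a brute-force tally on random matrices", {
  set.seed(33)
  for (i in 1:15) {
    n <- sample(8:40, 1); m <- sample(2:6, 1)
    mat <- matrix(sample(c(0L, 1L), n * m, TRUE), n, m)
    mat[runif(n * m) < 0.05] <- NA
    gm <- data.frame(accession = paste0("a", seq_len(n)), mat)
    snps <- names(gm)[-1]
    hap <- suppressWarnings(haplotype_group(gm, snps, min_accessions = 3))
    orc <- oracle_haplotypes(gm, snps, 3L)
    expect_setequal(hap$assignment$accession, orc$retained)
    expect_equal(sort(hap$haplotypes$n, decreasing = TRUE), orc$sizes)
    expect_setequal(hap$missing, orc$missing)
    # labels follow descending size
    expect_true(all(diff(hap$haplotypes$n) <= 0))
    # partition: retained + excluded + missing = all accessions
    expect_setequal(c(hap$assignment$accession, hap$excluded$accession,
                      hap$missing), gm$accession)
  }
})

test_that("haplotype phenotype test separates near-degenerate groups", {
  gm <- data.frame(accession = paste0("a", 1:8),
                   s1 = rep(c(0, 1), each = 4))
  hap <- haplotype_group(gm, "s1", min_accessions = 3)
  set.seed(6)
  ph <- data.frame(accession = paste0("a", 1:8),
                   value = rep(c(0, 5), each = 4) + rnorm(8, 0, 0.01))
  tst <- haplotype_phenotype_test(hap, ph)
  expect_lt(tst$anova$p_value, 1e-6)
  expect_equal(length(unique(tst$groups$letters)), 2L)
  # letter sets of the two groups are disjoint
  l <- strsplit(tst$groups$letters, "")
  expect_length(intersect(l[[1]], l[[2]]), 0L)
})

test_that("all-equal phenotypes give F = 0 and one shared letter", {
  gm <- data.frame(accession = paste0("a", 1:9),
                   s1 = rep(c(0, 1, NA), each = 3))
  hap <- haplotype_group(gm, "s1", min_accessions = 3)
  ph <- data.frame(accession = paste0("a", 1:9), value = 4.2)
  tst <- haplotype_phenotype_test(hap, ph)
  expect_equal(tst$anova$F, 0)
  expect_equal(unique(tst$groups$letters), "a")

  # one group only -> error
  gm1 <- data.frame(accession = paste0("a", 1:4), s1 = 0)
  hap1 <- haplotype_group(gm1, "s1")
  expect_error(haplotype_phenotype_test(hap1, ph), ">= 2 haplotype groups")
})

test_that("compact letters reproduce Tukey pairwise significance exactly", {
  set.seed(17)
  for (i in 1:12) {
    k <- sample(3:5, 1)
    n_per <- sample(4:8, 1)
    effects <- rnorm(k, sd = sample(c(0.2, 1, 3), 1))
    acc <- paste0("a", seq_len(k * n_per))
    # force k distinct patterns via three binary SNP columns
    idx <- rep(seq_len(k), each = n_per)
    gm <- data.frame(accession = acc, s1 = idx %% 2,
                     s2 = (idx %/% 2) %% 2, s3 = (idx %/% 4) %% 2)
    snps <- c("s1", "s2", "s3")
    hap <- haplotype_group(gm, snps, min_accessions = 2)
    ph <- data.frame(accession = acc,
                     value = effects[idx] + rnorm(length(idx), 0, 0.5))
    tst <- haplotype_phenotype_test(hap, ph)
    tk <- tst$tukey
    letters_of <- setNames(strsplit(tst$groups$letters, ""),
                           tst$groups$haplotype)
    for (p in seq_len(nrow(tk))) {
      ab <- strsplit(tk$pair[p], "-", fixed = TRUE)[[1]]
      share <- length(intersect(letters_of[[ab[1]]],
                                letters_of[[ab[2]]])) > 0
      signif <- tk$`p adj`[p] < tst$alpha
      expect_identical(share, !signif,
                       label = sprintf("pair %s seed-iter %d", tk$pair[p], i))
    }
  }
})
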