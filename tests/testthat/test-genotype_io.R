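# PLINK binary input, quality control and cohort merging

test_that("hand-decoded PLINK bed bytes are read back as major-allele dosages", {
  stem <- withr::local_tempfile()
  write_tiny_plink(stem)
  panel <- read_plink(paste0(stem, ".bed"))
  # SNP1: AA/AB/BB with freq(A) = 0.5; the tie designates the second bim
  # allele (A) as major, so the column counts A: (1, 0.5, 0)
  expect_equal(unname(panel$genotypes[, "rs1"]), c(1, 0.5, 0))
  expect_identical(panel$map$major[panel$map$snp_id == "rs1"], "A")
  # SNP2: CC/CC/CT, freq(C) = 5/6 -> C major -> (1, 1, 0.5)
  expect_equal(unname(panel$genotypes[, "rs2"]), c(1, 1, 0.5))
  expect_identical(panel$map$major[panel$map$snp_id == "rs2"], "C")
  expect_identical(panel$individual_ids, c("id1", "id2", "id3"))
})

test_that("malformed bed files are rejected", {
  stem <- withr::local_tempfile()
  write_tiny_plink(stem)
  con <- file(paste0(stem, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1c, 0x01, 11, 32)), con); close(con)
  expect_error(read_plink(paste0(stem, ".bed")), "magic")

  con <- file(paste0(stem, ".bed"), "wb")  # one genotype byte missing
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 11)), con); close(con)
  expect_error(read_plink(paste0(stem, ".bed")), "mismatch")
})

test_that("an all-missing SNP keeps NA dosages and an undefined major allele", {
  stem <- withr::local_tempfile()
  con <- file(paste0(stem, ".bed"), "wb")
  # codes 1 (missing) for all 3 individuals: byte 1 + 1*4 + 1*16 = 21
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 21, 32)), con); close(con)
  writeLines(c("1\trs1\t0\t100\tB\tA",
               "1\trs2\t0\t200\tC\tT"), paste0(stem, ".bim"))
  writeLines(c("F1\tid1\t0\t0\t1\t-9", "F2\tid2\t0\t0\t2\t-9",
               "F3\tid3\t0\t0\t1\t-9"), paste0(stem, ".fam"))
  panel <- read_plink(paste0(stem, ".bed"))
  expect_true(all(is.na(panel$genotypes[, "rs1"])))
  expect_true(is.na(panel$map$major[panel$map$snp_id == "rs1"]))
})

test_that("write_plink / read_plink round-trips genotypes exactly", {
  withr::local_seed(1)
  for (n in c(3, 4, 9)) {       # exercise all byte paddings
    panel <- random_panel(n = n, m = 7, missing_rate = 0.15,
                          chromosome = rep(c(1L, 2L), c(4, 3)))
    stem <- withr::local_tempfile()
    write_plink(panel, stem)
    back <- read_plink(paste0(stem, ".bed"))
    expect_equal(back$genotypes, panel$genotypes)
    expect_identical(back$map$snp_id, panel$map$snp_id)
    expect_equal(back$map$major, panel$map$major)
  }
})

test_that("QC filters match a hand-enumerated toy and is idempotent", {
  withr::local_seed(42)
  n_good <- 30
  m <- 40
  base <- matrix(rep(c(0, 0.5, 0.5, 1), length.out = n_good * m),
                 n_good, m)
  # snp1: missing for individuals 1-5 -> call rate 25/30 < 0.98
  base[1:5, 1] <- NA
  # snp2: monomorphic -> MAF 0 < 0.02
  base[, 2] <- 1
  # snp3: all heterozygous -> HWE chi-square = n = 30, p ~ 4e-8 < 1e-6
  base[, 3] <- 0.5
  # extra individual with 10 missing calls -> call rate 30/40 < 0.97
  bad_ind <- c(rep(NA, 10), rep(1, 10), rep(0.5, 10), rep(0, 10))
  g <- rbind(base, bad_ind)
  panel <- tiny_panel(g)

  res <- apply_qc(panel)
  expect_equal(res$report$ind_removed_callrate, 1)
  expect_equal(res$report$snp_removed_callrate, 1)
  expect_equal(res$report$snp_removed_maf, 1)
  expect_equal(res$report$snp_removed_hwe, 1)
  expect_equal(dim(res$panel), c(30L, 37L))
  expect_false("i31" %in% res$panel$individual_ids)

  # idempotence: a second application removes nothing
  res2 <- apply_qc(res$panel)
  expect_equal(dim(res2$panel), dim(res$panel))
  expect_equal(res2$report$snp_removed_maf +
                 res2$report$snp_removed_hwe +
                 res2$report$snp_removed_callrate +
                 res2$report$ind_removed_callrate, 0)

  # every retained SNP respects the MAF floor
  p <- major_allele_freqs(res$panel)
  expect_true(all(1 - p >= 0.02 - 1e-12))
})

test_that("a SNP at MAF 0.015 is removed under default thresholds", {
  withr::local_seed(7)
  n <- 1000
  g <- matrix(rbinom(n * 2, 2, 0.6) / 2, n, 2)   # HWE-consistent filler
  # 30 heterozygotes in 1000 individuals: 30 minor alleles of 2000 = 0.015
  g[, 1] <- c(rep(0.5, 30), rep(1, n - 30))
  panel <- tiny_panel(g)
  res <- apply_qc(panel)
  expect_equal(res$report$snp_removed_maf, 1)
  expect_identical(res$panel$map$snp_id, "s2")
})

test_that("a clean panel passes QC unchanged", {
  withr::local_seed(3)
  panel <- random_panel(n = 40, m = 10, missing_rate = 0)
  res <- apply_qc(panel)
  expect_equal(res$panel$genotypes, panel$genotypes)
})

test_that("panel merging intersects SNPs, resolves strand flips and drops ambiguous conflicts", {
  g1 <- matrix(c(1, 0.5, 0, 1,
                 0.5, 0.5, 1, 0,
                 1, 1, 0.5, 0.5,
                 0, 0.5, 1, 1,
                 1, 0.5, 1, 0.5), 4, 5)
  map1 <- data.frame(snp_id = paste0("m", 1:5), chromosome = 1L,
                     position_bp = (1:5) * 100L,
                     allele_a = c("A", "A", "A", "A", "A"),
                     allele_b = c("G", "G", "G", "T", "G"),
                     major = c("G", "G", "G", "T", "G"))
  p1 <- genotype_panel(g1, paste0("a", 1:4), map1)

  # p2 shares m1 (same alleles), m2 (strand-flipped T/C vs A/G), m4
  # (ambiguous A/T vs T/A conflict) and m5 (incompatible alleles A/C)
  g2 <- matrix(c(1, 0.5, 1, 0.5, 0, 1, 1, 0.5, 1, 0.5, 1, 1), 3, 4)
  map2 <- data.frame(snp_id = c("m1", "m2", "m4", "m5"), chromosome = 1L,
                     position_bp = c(100L, 200L, 400L, 500L),
                     allele_a = c("A", "T", "T", "A"),
                     allele_b = c("G", "C", "A", "C"),
                     major = c("G", "C", "A", "C"))
  p2 <- genotype_panel(g2, paste0("b", 1:3), map2)

  expect_warning(merged <- intersect_panels(list(p1, p2)), "conflict")
  expect_setequal(merged$map$snp_id, c("m1", "m2"))
  expect_equal(length(merged$individual_ids), 7)
  # m2 in p2 counts C (flip of G): dosages agree after flipping
  j <- match("m2", merged$map$snp_id)
  expect_true(all(merged$genotypes[, j] %in% c(0, 0.5, 1)))

  # identical SNP lists concatenate individuals
  p3 <- genotype_panel(g1, paste0("c", 1:4), map1)
  both <- intersect_panels(list(p1, p3))
  expect_equal(dim(both), c(8L, 5L))
  expect_identical(both$map$snp_id, map1$snp_id)
})

test_that("merged dosages stay consistent across strand flips", {
  # one SNP typed as (A,G) in cohort 1 and (T,C) in cohort 2; identical
  # samples must produce identical dosage columns after merging
  g <- matrix(c(1, 0.5, 0, 1, 0.5, 0.5), 6, 1)
  mapA <- data.frame(snp_id = "x", chromosome = 1L, position_bp = 100L,
                     allele_a = "A", allele_b = "G", major = "G")
  mapB <- data.frame(snp_id = "x", chromosome = 1L, position_bp = 100L,
                     allele_a = "T", allele_b = "C", major = "C")
  pA <- genotype_panel(g, paste0("a", 1:6), mapA)
  pB <- genotype_panel(g, paste0("b", 1:6), mapB)
  merged <- intersect_panels(list(pA, pB))
  expect_equal(unname(merged$genotypes[1:6, 1]),
               unname(merged$genotypes[7:12, 1]))
})
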