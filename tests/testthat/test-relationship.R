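# IBS kinship, GRMs, sliding windows and PCA covariates

test_that("major-allele frequencies equal the mean coded genotype", {
  panel <- tiny_panel(cbind(c(1, 1, 0.5, 0), c(1, 1, 1, 1),
                            c(0.5, 0.5, 0.5, 0.5)))
  p <- major_allele_freqs(panel)
  expect_equal(unname(p), c(0.625, 1, 0.5))
  panel$genotypes[, 2] <- NA
  expect_error(major_allele_freqs(panel), "non-missing")
})

test_that("kinship matches hand evaluation of the weighted-IBS formula", {
  # single SNP, p = 0.75, both individuals common hom:
  # (1-0.75)^2 / (0.75*0.25) = 1/3
  panel <- tiny_panel(cbind(c(1, 1, 0.5, 0.5)))   # p = 0.75
  k <- genomic_kinship(panel)
  expect_equal(k$values[1, 2], 1 / 3)
  # heterozygote at p = 0.5: centred genotype zero, self-term 0
  panel2 <- tiny_panel(cbind(c(0.5, 0.5)))
  k2 <- genomic_kinship(panel2)
  expect_equal(k2$values[1, 1], 0)
})

test_that("vectorized kinship equals a scalar-loop oracle", {
  withr::local_seed(5)
  panel <- random_panel(n = 6, m = 9, missing_rate = 0.15)
  p <- unname(major_allele_freqs(panel))
  k <- genomic_kinship(panel)
  g <- panel$genotypes
  poly <- p > 0 & p < 1
  for (i in 1:6) for (j in 1:6) {
    s <- 0; cnt <- 0
    for (m in which(poly)) {
      if (!is.na(g[i, m]) && !is.na(g[j, m])) {
        s <- s + (g[i, m] - p[m]) * (g[j, m] - p[m]) / (p[m] * (1 - p[m]))
        cnt <- cnt + 1
      }
    }
    expect_equal(k$values[i, j], s / cnt, tolerance = 1e-12)
    expect_equal(k$snp_count_used[i, j], cnt)
  }
})

test_that("relationship doubles kinship and is flagged by kind", {
  withr::local_seed(8)
  panel <- random_panel(n = 5, m = 6, missing_rate = 0)
  k <- genomic_kinship(panel)
  A <- to_relationship(k, kind = "regional")
  expect_equal(A$values, 2 * k$values)
  expect_identical(A$kind, "regional")
  # f_ij = 0.125 -> A_ij = 0.25 under the doubling contract
  expect_equal(2 * 0.125, 0.25)
})

test_that("a pair sharing no usable SNPs is an error, not a silent zero", {
  g <- cbind(c(1, NA, 0.5), c(NA, 0.5, 1), c(0.5, NA, 0))
  panel <- tiny_panel(g)
  expect_error(genomic_kinship(panel), "share no usable SNPs")
})

test_that("windows follow the documented tiling including truncation", {
  # 200 SNPs -> exactly [1-100], [51-150], [101-200]
  panel <- random_panel(n = 4, m = 200, missing_rate = 0)
  w <- make_windows(panel, 100, 50)
  expect_equal(nrow(w), 3)
  expect_equal(w$first_snp_index, c(1, 51, 101))
  expect_equal(w$last_snp_index, c(100, 150, 200))

  # exactly 100 SNPs -> one window
  w1 <- make_windows(random_panel(n = 4, m = 100, missing_rate = 0), 100, 50)
  expect_equal(nrow(w1), 1)

  # 275 SNPs -> starts 1, 51, 101, 151 plus trailing [201-275]
  w2 <- make_windows(random_panel(n = 4, m = 275, missing_rate = 0), 100, 50)
  expect_equal(nrow(w2), 5)
  expect_equal(w2$first_snp_index, c(1, 51, 101, 151, 201))
  expect_equal(w2$last_snp_index[5], 275)

  # short chromosome: no window, with a warning
  expect_warning(
    w3 <- make_windows(random_panel(n = 4, m = 249, missing_rate = 0,
                                    chromosome = rep(c(1L, 2L), c(200, 49))),
                       100, 50),
    "no window")
  expect_true(all(w3$chromosome == 1))

  # genome-wide ordinals are contiguous and windows never span chromosomes
  panel4 <- random_panel(n = 4, m = 400, missing_rate = 0,
                         chromosome = rep(c(1L, 2L), each = 200))
  w4 <- make_windows(panel4, 100, 50)
  expect_equal(w4$ordinal, seq_len(nrow(w4)))
  for (i in seq_len(nrow(w4)))
    expect_equal(panel4$map$chromosome[w4$first_snp_index[i]],
                 panel4$map$chromosome[w4$last_snp_index[i]])
})

test_that("whole-genome kinship is the count-weighted average of a window partition", {
  withr::local_seed(11)
  panel <- random_panel(n = 8, m = 120, missing_rate = 0.1)
  p <- major_allele_freqs(panel)
  whole <- genomic_kinship(panel, freqs = p)
  w <- make_windows(panel, 40, 40)        # non-overlapping partition
  num <- matrix(0, 8, 8); cnt <- matrix(0, 8, 8)
  for (i in seq_len(nrow(w))) {
    kw <- genomic_kinship(panel, seq(w$first_snp_index[i],
                                     w$last_snp_index[i]), freqs = p)
    num <- num + kw$values * kw$snp_count_used
    cnt <- cnt + kw$snp_count_used
  }
  expect_equal(whole$values, num / cnt, tolerance = 1e-10)
})

test_that("kinship is equivariant under individual permutation", {
  withr::local_seed(13)
  panel <- random_panel(n = 7, m = 30, missing_rate = 0.05)
  k <- genomic_kinship(panel)
  perm <- sample(7)
  panel_p <- subset_panel(panel, individuals = perm)
  k_p <- genomic_kinship(panel_p)
  expect_equal(unname(k_p$values), unname(k$values[perm, perm]),
               tolerance = 1e-12)
})

test_that("simulated full sibs have mean relationship near 0.5", {
  pop <- shared_pop()
  ped <- pop$pedigree
  key <- paste(ped$father, ped$mother)
  fams <- split(seq_len(nrow(ped)), key)
  fams <- fams[!grepl("NA", names(fams)) & lengths(fams) >= 2]
  pairs <- do.call(rbind, lapply(fams, function(ix) t(utils::combn(ix, 2))))
  expect_gt(nrow(pairs), 200)
  A <- make_grm(pop$panel)$values
  sib_rel <- A[pairs]
  expect_equal(mean(sib_rel), 0.5, tolerance = 0.05)
  expect_equal(mean(diag(A)), 1, tolerance = 0.05)
})

test_that("principal components match a dense eigendecomposition", {
  withr::local_seed(17)
  M <- crossprod(matrix(rnorm(25), 5, 5))
  pcs <- pca_covariates(M, 3)
  e <- eigen(M, symmetric = TRUE)
  for (j in 1:3) {
    v <- e$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(pcs[, j]), v, tolerance = 1e-10)
  }
  expect_equal(attr(pcs, "eigenvalues"), e$values[1:3], tolerance = 1e-10)
  # rank-1 matrix: first component proportional to the generating vector
  v1 <- c(3, 1, -2, 0.5)
  p1 <- pca_covariates(tcrossprod(v1), 1)
  expect_equal(unname(abs(drop(crossprod(p1, v1 / sqrt(sum(v1^2)))))), 1,
               tolerance = 1e-10)
  expect_error(pca_covariates(M, 6), "exceeds")
})

test_that("GRMs round-trip through TSV and GCTA binary formats", {
  withr::local_seed(19)
  panel <- random_panel(n = 6, m = 12, missing_rate = 0.05)
  G <- make_grm(panel)
  tsv <- withr::local_tempfile()
  write_grm(G, tsv, "tsv")
  G2 <- read_grm(tsv, "tsv")
  expect_equal(G2$values, G$values, tolerance = 1e-9)
  stem <- withr::local_tempfile()
  write_grm(G, stem, "gcta")
  G3 <- read_grm(stem, "gcta")
  expect_equal(unname(G3$values), unname(G$values), tolerance = 1e-6)
  expect_equal(unname(G3$snp_count_used), unname(G$snp_count_used),
               tolerance = 1e-6)
})
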