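# Shared fixtures, generated in code.  The cached population amortizes the
# gene-drop simulation across test files.

tiny_panel <- function(g, chromosome = NULL, alleles = c("A", "G")) {
  g <- as.matrix(g)
  m <- ncol(g)
  if (is.null(chromosome)) chromosome <- rep(1L, m)
  pos <- stats::ave(chromosome, chromosome, FUN = seq_along) * 1000L
  map <- data.frame(snp_id = paste0("s", seq_len(m)),
                    chromosome = chromosome, position_bp = pos,
                    allele_a = alleles[1], allele_b = alleles[2],
                    major = alleles[2], stringsAsFactors = FALSE)
  genotype_panel(g, paste0("i", seq_len(nrow(g))), map)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# medium population-isolate sample: ~700 individuals, 2000 SNPs, 4 chromosomes
shared_pop <- function() cached("pop", {
  spec <- population_spec(n_founders = 150, n_generations = 3,
                          mean_offspring = 2.6, n_snps = 2000,
                          n_chromosomes = 4)
  withr::with_seed(20240901, sim_population(spec))
})

# small scanned dataset: ~250 individuals, 600 SNPs, planted window
shared_scan <- function() cached("scan", {
  spec <- population_spec(n_founders = 90, n_generations = 2,
                          mean_offspring = 2.6, n_snps = 600,
                          n_chromosomes = 2)
  withr::with_seed(20240902, {
    pop <- sim_population(spec)
    ts <- trait_spec(background_h2 = 0.3,
                     regional_qtl = list(list(first_snp_index = 101,
                                              last_snp_index = 200,
                                              fraction = 0.15,
                                              n_causal = 5)))
    sim <- simulate_phenotype(pop$panel, ts, pop$pedigree)
    cfg <- scan_config(window_size = 100, shift = 50,
                       fixed_spec = fixed_effects_spec(
                         factors = c("sex", "village"),
                         covariates = "age"))
    list(pop = pop, sim = sim, cfg = cfg,
         scan = scan_genome(pop$panel, sim$pheno, cfg))
  })
})

# hand-written PLINK triplet: 3 individuals, 2 SNPs (see test-genotype_io)
write_tiny_plink <- function(stem) {
  # SNP1 bim alleles (B=allele1, A=allele2); genotypes AA, AB, BB
  #   -> codes 3, 2, 0 -> byte 3*1 + 2*4 + 0*16 = 11
  # SNP2 bim alleles (C, T); genotypes CC, CC, CT
  #   -> codes 0, 0, 2 -> byte 0 + 0 + 2*16 = 32
  con <- file(paste0(stem, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 11, 32)), con)
  close(con)
  writeLines(c("1\trs1\t0\t100\tB\tA",
               "1\trs2\t0\t200\tC\tT"), paste0(stem, ".bim"))
  writeLines(c("F1\tid1\t0\t0\t1\t-9",
               "F2\tid2\t0\t0\t2\t-9",
               "F3\tid3\t0\t0\t1\t-9"), paste0(stem, ".fam"))
  invisible(stem)
}

random_panel <- function(n = 12, m = 8, missing_rate = 0.1,
                         chromosome = NULL) {
  g <- matrix(sample(c(0, 0.5, 1), n * m, replace = TRUE,
                     prob = c(0.2, 0.4, 0.4)), n, m)
  if (missing_rate > 0)
    g[sample(length(g), round(missing_rate * length(g)))] <- NA
  # keep at least one call per SNP
  for (j in seq_len(m)) if (all(is.na(g[, j]))) g[1, j] <- 1
  rhm:::recode_major(tiny_panel(g, chromosome))
}
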