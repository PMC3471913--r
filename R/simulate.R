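#' Specification of a simulated population isolate
#'
#' Parameters of the gene-dropping simulator: founder haplotypes with
#' first-order Markov linkage disequilibrium are transmitted through a
#' village-structured pedigree with limited migration, producing a sample
#' that, like a population isolate, combines recorded close relationships
#' with deeper unrecorded ones.
#'
#' @param n_founders number of founder individuals (split over villages).
#' @param n_generations generations of gene dropping after the founders.
#' @param mean_offspring mean number of children per couple (Poisson).
#' @param n_villages number of villages.
#' @param migration_rate probability that a mate is drawn from another
#'   village.
#' @param n_snps total SNPs (split evenly over chromosomes).
#' @param n_chromosomes number of chromosomes.
#' @param rho adjacent-site haplotype correlation in `[0, 1)`; LD decays
#'   geometrically with SNP distance.
#' @param maf_range range of target allele frequencies (uniform).
#' @param cm_per_snp genetic map density; adjacent-SNP recombination
#'   fraction follows Haldane's map function.
#' @param maf_blocks optional list
#'   `list(size =, low =, high =, rho_low =, high_block =, rho_high =,
#'   jitter =)` replacing the uniform frequency draw with alternating
#'   classes of `size` SNPs whose minor-allele frequencies are drawn from
#'   the `low` and `high` ranges.  Sites in low-MAF classes copy their
#'   neighbour with probability `rho_low` (default 0) instead of `rho`:
#'   rare alleles then arise on essentially independent founder
#'   haplotypes and are poorly tagged by surrounding markers, as in real
#'   data.  High-MAF classes are built as LD blocks of `high_block` SNPs
#'   (default `size`, i.e. one block): within a block the target
#'   frequency is shared up to `jitter` and neighbours copy with
#'   probability `rho_high` (default `rho`), while the first site of each
#'   block falls back to `rho`, so common variants are well tagged
#'   locally but blocks are nearly independent of each other.  This gives
#'   each 50-SNP window a well-tagged high-MAF class and a poorly tagged
#'   low-MAF class, the structure the embedded-QTL power design sorts on.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n_founders = 120, n_generations = 3,
                            mean_offspring = 2.5, n_villages = 3,
                            migration_rate = 0.1, n_snps = 2000,
                            n_chromosomes = 4, rho = 0.9,
                            maf_range = c(0.02, 0.5), cm_per_snp = 0.1,
                            maf_blocks = NULL) {
  stopifnot(rho >= 0, rho < 1, migration_rate >= 0, migration_rate <= 1,
            n_snps %% n_chromosomes == 0)
  structure(as.list(environment()), class = "population_spec")
}

#' Simulate founder haplotypes with Markov linkage disequilibrium
#'
#' Binary haplotypes with per-site target allele frequencies and
#' first-order dependence: each site copies the previous site's latent
#' uniform with probability `rho`, otherwise redraws it.  When adjacent
#' sites share a target frequency the adjacent-allele correlation is
#' exactly `rho`, and correlation decays as `rho^d` with distance d.
#'
#' @param spec a [population_spec()].
#' @param n_haplotypes number of haplotypes to draw.
#' @param freqs optional vector of target frequencies (length `n_snps`);
#'   drawn uniformly from `spec$maf_range` when `NULL`.
#' @return A list: `haplotypes` (n_haplotypes x n_snps 0/1 matrix),
#'   `freqs`, `chromosome` (per-SNP chromosome index).
#' @export
simulate_haplotypes <- function(spec, n_haplotypes, freqs = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  m <- spec$n_snps
  rho_site <- rep(spec$rho, m)
  if (is.null(freqs)) {
    if (is.null(spec$maf_blocks)) {
      freqs <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
    } else {
      b <- spec$maf_blocks
      rho_low <- if (is.null(b$rho_low)) 0 else b$rho_low
      high_block <- if (is.null(b$high_block)) b$size else b$high_block
      rho_high <- if (is.null(b$rho_high)) spec$rho else b$rho_high
      jitter <- if (is.null(b$jitter)) 0 else b$jitter
      nb <- ceiling(m / b$size)
      lo <- rep(c(TRUE, FALSE), length.out = nb)
      freqs <- numeric(nb * b$size)
      rho_cls <- numeric(nb * b$size)
      for (i in seq_len(nb)) {
        at <- (i - 1) * b$size + seq_len(b$size)
        if (lo[i]) {
          freqs[at] <- stats::runif(b$size, b$low[1], b$low[2])
          rho_cls[at] <- rho_low
        } else {
          nsub <- ceiling(b$size / high_block)
          base <- rep(stats::runif(nsub, b$high[1], b$high[2]),
                      each = high_block)[seq_len(b$size)]
          freqs[at] <- pmin(pmax(
            base + stats::runif(b$size, -jitter, jitter), 0.01), 0.5)
          r <- rep(rho_high, b$size)
          r[seq(1, b$size, by = high_block)] <- spec$rho
          rho_cls[at] <- r
        }
      }
      freqs <- freqs[seq_len(m)]
      rho_site <- rho_cls[seq_len(m)]
    }
  }
  chrom <- rep(seq_len(spec$n_chromosomes), each = m / spec$n_chromosomes)
  H <- matrix(0L, n_haplotypes, m)
  u <- numeric(n_haplotypes)
  for (k in seq_len(m)) {
    if (k == 1 || chrom[k] != chrom[k - 1]) {
      u <- stats::runif(n_haplotypes)
    } else {
      redraw <- stats::runif(n_haplotypes) >= rho_site[k]
      if (any(redraw)) u[redraw] <- stats::runif(sum(redraw))
    }
    H[, k] <- as.integer(u < freqs[k])
  }
  list(haplotypes = H, freqs = freqs, chromosome = chrom)
}

# one gamete from a parent's two haplotype rows (Haldane crossovers,
# chromosomes independent)
.meiosis <- function(hapA, hapB, chrom, r_adj) {
  m <- length(hapA)
  sw <- stats::runif(m) < r_adj
  newchr <- c(TRUE, chrom[-1] != chrom[-m])
  sw[newchr] <- stats::runif(sum(newchr)) < 0.5    # fresh start per chromosome
  choice <- cumsum(sw) %% 2L
  ifelse(choice == 1L, hapB, hapA)
}

#' Gene-drop a pedigree from founder haplotypes
#'
#' Founders are split over villages; each generation, males and females
#' within a village are paired (mates drawn from another village with
#' probability `migration_rate`) and each couple has a Poisson number of
#' children.  Gametes recombine with adjacent-SNP recombination fraction
#' from Haldane's map function at `cm_per_snp`.  All individuals of all
#' generations are genotyped.  The pedigree is returned for validation
#' only; analysis functions never see it.
#'
#' @param founders result of [simulate_haplotypes()] with
#'   `2 * spec$n_founders` haplotypes.
#' @param spec a [population_spec()].
#' @return A list: `panel` (a [genotype_panel()], dosages oriented to the
#'   empirical major allele), `pedigree` (data frame: `id`, `father`,
#'   `mother`, `generation`, `village`, `sex`), `haplotypes` (list of the
#'   two n x m haplotype matrices).
#' @export
gene_drop <- function(founders, spec) {
  stopifnot(inherits(spec, "population_spec"))
  nf <- spec$n_founders
  if (nrow(founders$haplotypes) != 2 * nf)
    stop("founders must provide 2 * n_founders haplotypes")
  m <- ncol(founders$haplotypes)
  chrom <- founders$chromosome
  r_adj <- 0.5 * (1 - exp(-2 * spec$cm_per_snp / 100))

  hapA <- founders$haplotypes[seq(1, 2 * nf, by = 2), , drop = FALSE]
  hapB <- founders$haplotypes[seq(2, 2 * nf, by = 2), , drop = FALSE]
  ped <- data.frame(id = sprintf("I%05d", seq_len(nf)),
                    father = NA_character_, mother = NA_character_,
                    generation = 0L,
                    village = rep_len(seq_len(spec$n_villages), nf),
                    sex = rep_len(c("M", "F"), nf),
                    stringsAsFactors = FALSE)
  next_id <- nf + 1L
  cur <- seq_len(nf)                      # indices of current generation
  for (gen in seq_len(spec$n_generations)) {
    kids_A <- list(); kids_B <- list(); kids_ped <- list()
    for (v in seq_len(spec$n_villages)) {
      males <- cur[ped$village[cur] == v & ped$sex[cur] == "M"]
      females <- cur[ped$village[cur] == v & ped$sex[cur] == "F"]
      nc <- min(length(males), length(females))
      if (nc == 0) next
      males <- sample(males); females <- sample(females)
      for (ci in seq_len(nc)) {
        f <- males[ci]; mo <- females[ci]
        if (stats::runif(1) < spec$migration_rate) {
          other <- cur[ped$village[cur] != v & ped$sex[cur] == "F"]
          if (length(other)) mo <- other[sample.int(length(other), 1)]
        }
        nk <- stats::rpois(1, spec$mean_offspring)
        for (k in seq_len(nk)) {
          kids_A[[length(kids_A) + 1L]] <-
            .meiosis(hapA[f, ], hapB[f, ], chrom, r_adj)
          kids_B[[length(kids_B) + 1L]] <-
            .meiosis(hapA[mo, ], hapB[mo, ], chrom, r_adj)
          kids_ped[[length(kids_ped) + 1L]] <- data.frame(
            id = sprintf("I%05d", next_id), father = ped$id[f],
            mother = ped$id[mo], generation = gen, village = v,
            sex = sample(c("M", "F"), 1), stringsAsFactors = FALSE)
          next_id <- next_id + 1L
        }
      }
    }
    if (!length(kids_A)) stop("lineage extinct: no couples produced children")
    hapA <- rbind(hapA, do.call(rbind, kids_A))
    hapB <- rbind(hapB, do.call(rbind, kids_B))
    ped <- rbind(ped, do.call(rbind, kids_ped))
    cur <- seq.int(nrow(hapA) - length(kids_A) + 1L, nrow(hapA))
  }

  g <- (hapA + hapB) / 2                  # dosage of the "1" allele
  map <- data.frame(
    snp_id = sprintf("snp%d_%d", chrom, stats::ave(chrom, chrom,
                                                   FUN = seq_along)),
    chromosome = chrom,
    position_bp = 50000L * as.integer(stats::ave(chrom, chrom,
                                                 FUN = seq_along)),
    allele_a = "A", allele_b = "B", major = "B",
    stringsAsFactors = FALSE)
  panel <- genotype_panel(g, ped$id, map)
  panel <- recode_major(panel)
  list(panel = panel, pedigree = ped,
       haplotypes = list(A = hapA, B = hapB))
}

#' Trait specification for simulated phenotypes
#'
#' @param background_h2 fraction of phenotypic variance from a polygenic
#'   term spread over all non-QTL SNPs (presets of interest: 0.3 for a
#'   moderate-heritability trait, 0.8 for a high-heritability one).
#' @param regional_qtl list of regional effects, each a list with
#'   `first_snp_index`, `last_snp_index`, `fraction` (of phenotypic
#'   variance) and `n_causal`.
#' @param sex_effect additive fixed effect of sex (trait SD units).
#' @param age_slope fixed regression on age (trait SD per year).
#' @param village_sd SD of random village means (trait SD units).
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(background_h2 = 0.3, regional_qtl = list(),
                       sex_effect = 0.25, age_slope = 0.005,
                       village_sd = 0.1) {
  tot <- background_h2 + sum(vapply(regional_qtl,
                                    function(q) q$fraction, numeric(1)))
  if (tot > 1) stop("variance budget exceeds 1: background_h2 + regional ",
                    "fractions = ", tot)
  structure(as.list(environment()), class = "trait_spec")
}

# scale a vector to have exactly the target sample variance (0 stays 0)
.scale_var <- function(x, target_var) {
  x <- x - mean(x)
  v <- stats::var(x)
  if (v <= 0) {
    if (target_var > 0) stop("degenerate genetic values: zero variance")
    return(x)
  }
  x * sqrt(target_var / v)
}

#' Simulate a phenotype on a genotype panel
#'
#' Builds `trait = fixed effects + polygenic value + regional QTL values +
#' residual noise` on a phenotypic-variance scale of 1.  The polygenic
#' value sums small normal effects over all non-QTL SNPs and is rescaled
#' so its realized sample variance equals `background_h2`; each regional
#' QTL block is likewise rescaled to its target fraction, so realized
#' variance fractions match their targets exactly in the simulated sample.
#'
#' @param panel a [genotype_panel()].
#' @param spec a [trait_spec()].
#' @param pedigree optional pedigree from [gene_drop()] supplying sex and
#'   village; otherwise both are drawn at random.
#' @return A list: `pheno` (data frame `id`, `trait`, `sex`, `age`,
#'   `population`, `village`) and `truth` (QTL indices, per-component
#'   values and realized variances).
#' @export
simulate_phenotype <- function(panel, spec = trait_spec(),
                               pedigree = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(spec, "trait_spec"))
  n <- length(panel$individual_ids)
  m <- nrow(panel$map)
  qtl_idx <- integer(0)
  qtl_values <- matrix(0, n, length(spec$regional_qtl))
  causal <- vector("list", length(spec$regional_qtl))
  for (qi in seq_along(spec$regional_qtl)) {
    q <- spec$regional_qtl[[qi]]
    win <- seq(q$first_snp_index, q$last_snp_index)
    poly <- win[apply(panel$genotypes[, win, drop = FALSE], 2,
                      function(g) stats::var(g, na.rm = TRUE) > 0)]
    if (length(poly) < q$n_causal)
      stop("window has fewer polymorphic SNPs than n_causal")
    cs <- sample(poly, q$n_causal)
    causal[[qi]] <- cs
    val <- rowSums(vapply(cs, function(j) {
      g <- panel$genotypes[, j]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      .scale_var(g, 1 / q$n_causal) * sample(c(-1, 1), 1)
    }, numeric(n)))
    qtl_values[, qi] <- .scale_var(val, q$fraction)
    qtl_idx <- c(qtl_idx, cs)
  }
  bg_idx <- setdiff(seq_len(m), qtl_idx)
  polygenic <- rep(0, n)
  if (spec$background_h2 > 0) {
    Z <- panel$genotypes[, bg_idx, drop = FALSE]
    Z[is.na(Z)] <- 0.5
    Z <- scale(Z, center = TRUE, scale = FALSE)
    polygenic <- .scale_var(drop(Z %*% stats::rnorm(length(bg_idx))),
                            spec$background_h2)
  }
  resid_var <- 1 - spec$background_h2 -
    sum(vapply(spec$regional_qtl, function(q) q$fraction, numeric(1)))
  noise <- .scale_var(stats::rnorm(n), resid_var)

  if (!is.null(pedigree)) {
    sex <- pedigree$sex[match(panel$individual_ids, pedigree$id)]
    village <- pedigree$village[match(panel$individual_ids, pedigree$id)]
  } else {
    sex <- sample(c("M", "F"), n, replace = TRUE)
    village <- sample(3, n, replace = TRUE)
  }
  age <- stats::runif(n, 18, 98)
  veff <- stats::rnorm(length(unique(village)), 0, spec$village_sd)
  fixed <- spec$sex_effect * (sex == "M") + spec$age_slope * age +
    veff[match(village, unique(village))]
  genetic <- polygenic + rowSums(qtl_values)
  y <- fixed + genetic + noise
  pheno <- data.frame(id = panel$individual_ids, trait = y,
                      sex = factor(sex), age = age,
                      population = factor("POP1"),
                      village = factor(paste0("V", village)),
                      stringsAsFactors = FALSE)
  truth <- list(causal_snps = causal,
                polygenic = polygenic, qtl_values = qtl_values,
                noise = noise, fixed = fixed,
                realized = c(background = stats::var(polygenic),
                             regional = if (ncol(qtl_values))
                               apply(qtl_values, 2, stats::var) else NULL,
                             residual = stats::var(noise)),
                phenotypic_var = stats::var(y - fixed))
  list(pheno = pheno, truth = truth)
}

#' Simulate a complete population sample
#'
#' Convenience wrapper: founder haplotypes, gene dropping, and (optionally)
#' trimming to a target sample size by keeping the most recent
#' generations.
#'
#' @param spec a [population_spec()].
#' @param n_target optional number of individuals to keep (most recent
#'   first); `NULL` keeps everyone.
#' @param seed optional integer seed.
#' @return As [gene_drop()], with the panel possibly trimmed.
#' @export
sim_population <- function(spec = population_spec(), n_target = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  founders <- simulate_haplotypes(spec, 2 * spec$n_founders)
  pop <- gene_drop(founders, spec)
  if (!is.null(n_target)) {
    n <- nrow(pop$pedigree)
    if (n < n_target)
      stop("population of ", n, " smaller than n_target; increase ",
           "n_founders, mean_offspring or n_generations")
    keep <- order(pop$pedigree$generation, decreasing = TRUE)[seq_len(n_target)]
    keep <- sort(keep)
    pop$panel <- subset_panel(pop$panel, individuals = keep)
    pop$panel <- recode_major(pop$panel)
    pop$pedigree <- pop$pedigree[keep, ]
    pop$haplotypes <- lapply(pop$haplotypes,
                             function(h) h[keep, , drop = FALSE])
  }
  pop
}
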