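#' Quality-control thresholds
#'
#' Defaults follow common practice for array genotypes in population-isolate
#' association samples: SNPs are discarded when the minor allele frequency is
#' below 2%, the Hardy-Weinberg equilibrium test gives p below 1e-6 or the
#' call rate is below 98%; individuals are discarded at call rate below 97%.
#'
#' @param maf_min minimum minor-allele frequency.
#' @param hwe_p_min minimum Hardy-Weinberg p-value (1-df chi-square test).
#' @param snp_call_min minimum per-SNP call rate.
#' @param ind_call_min minimum per-individual call rate.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.02, hwe_p_min = 1e-6,
                          snp_call_min = 0.98, ind_call_min = 0.97) {
  vals <- c(maf_min, hwe_p_min, snp_call_min, ind_call_min)
  if (any(vals < 0 | vals > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 snp_call_min = snp_call_min, ind_call_min = ind_call_min),
            class = "qc_thresholds")
}

# 1-df Pearson chi-square HWE test on observed genotype class counts
# (n0 = rare hom, n1 = het, n2 = common hom).  Returns the p-value; 1 when
# the SNP is monomorphic (expected het count 0).
hwe_pvalue <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(NA_real_)
  p <- (2 * n2 + n1) / (2 * n)          # common-allele frequency
  q <- 1 - p
  e <- n * c(q^2, 2 * p * q, p^2)
  if (any(e == 0)) return(1)
  x2 <- sum((c(n0, n1, n2) - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Apply genotype quality control
#'
#' Individuals are filtered first on call rate; SNP statistics (call rate,
#' minor allele frequency, Hardy-Weinberg) are then computed on the retained
#' individuals, so SNP filters reflect the analysed sample.  The major
#' allele is recomputed after filtering.  Missing genotypes are retained
#' (no imputation).
#'
#' @param panel a [genotype_panel()].
#' @param thresholds a [qc_thresholds()].
#' @return A list with elements `panel` (the filtered panel) and `report`,
#'   a list counting removals per criterion.
#' @export
apply_qc <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!inherits(thresholds, "qc_thresholds"))
    thresholds <- do.call(qc_thresholds, as.list(thresholds))
  g <- panel$genotypes
  ind_call <- rowMeans(!is.na(g))
  keep_ind <- ind_call >= thresholds$ind_call_min
  if (!any(keep_ind)) stop("all individuals removed by call-rate filter")

  g <- g[keep_ind, , drop = FALSE]
  snp_call <- colMeans(!is.na(g))
  n0 <- colSums(g == 0,   na.rm = TRUE)
  n1 <- colSums(g == 0.5, na.rm = TRUE)
  n2 <- colSums(g == 1,   na.rm = TRUE)
  p_major <- (n2 + 0.5 * n1) / pmax(n0 + n1 + n2, 1)
  maf <- pmin(p_major, 1 - p_major)
  hwe <- vapply(seq_len(ncol(g)),
                function(j) hwe_pvalue(n0[j], n1[j], n2[j]), numeric(1))

  fail_call <- snp_call < thresholds$snp_call_min
  fail_maf  <- !fail_call & maf < thresholds$maf_min
  fail_hwe  <- !fail_call & !fail_maf &
    (!is.na(hwe) & hwe < thresholds$hwe_p_min)
  all_missing <- snp_call == 0
  keep_snp <- !(fail_call | fail_maf | fail_hwe | all_missing)
  if (!any(keep_snp)) stop("all SNPs removed by QC")

  out <- subset_panel(panel, individuals = which(keep_ind),
                      snps = which(keep_snp))
  out <- recode_major(out)
  report <- list(
    n_ind_in = nrow(panel$genotypes),
    n_snp_in = ncol(panel$genotypes),
    ind_removed_callrate = sum(!keep_ind),
    snp_removed_callrate = sum(fail_call | (all_missing & !fail_call)),
    snp_removed_maf = sum(fail_maf),
    snp_removed_hwe = sum(fail_hwe),
    n_ind_out = sum(keep_ind),
    n_snp_out = sum(keep_snp),
    thresholds = thresholds)
  list(panel = out, report = report)
}

# complement map used to resolve strand flips between cohorts
.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Merge genotype panels on shared SNPs
#'
#' Restricts to SNPs present in every panel (matched by snp id) whose allele
#' pairs agree, resolving strand flips for unambiguous pairs (A/C, A/G, T/C,
#' T/G).  Shared SNPs with ambiguous (A/T or C/G) conflicting alleles, or
#' genuinely different alleles, are dropped with a warning.  Individuals are
#' concatenated and the major allele recomputed on the merged sample.
#'
#' @param panels list of two or more [genotype_panel()] objects.
#' @return The merged `genotype_panel`.
#' @export
intersect_panels <- function(panels) {
  stopifnot(is.list(panels), length(panels) >= 2)
  for (p in panels) stopifnot(inherits(p, "genotype_panel"))
  ids <- Reduce(intersect, lapply(panels, function(p) p$map$snp_id))
  if (!length(ids)) stop("no shared SNPs")
  ref <- panels[[1]]$map[match(ids, panels[[1]]$map$snp_id), ]
  keep <- rep(TRUE, length(ids))
  aligned <- vector("list", length(panels))
  aligned[[1]] <- subset_panel(panels[[1]], snps = ids)
  for (k in seq_along(panels)[-1]) {
    pk <- subset_panel(panels[[k]], snps = ids)
    mk <- pk$map
    exact <- mk$allele_a == ref$allele_a & mk$allele_b == ref$allele_b
    swapped <- !exact &
      mk$allele_a == ref$allele_b & mk$allele_b == ref$allele_a
    fa <- unname(.complement[mk$allele_a]); fb <- unname(.complement[mk$allele_b])
    flipped <- !exact & !swapped & !is.na(fa) & !is.na(fb) &
      ((fa == ref$allele_a & fb == ref$allele_b) |
       (fa == ref$allele_b & fb == ref$allele_a))
    ambiguous <- !is.na(.complement[mk$allele_b]) &
      mk$allele_a == unname(.complement[mk$allele_b])
    # for A/T and C/G pairs a swap cannot be told from a strand flip
    ok <- exact | ((swapped | flipped) & !ambiguous)
    if (any(!ok)) keep <- keep & ok
    if (any(flipped & !ambiguous)) {
      i <- which(flipped & !ambiguous)
      mk$allele_a[i] <- unname(.complement[mk$allele_a[i]])
      mk$allele_b[i] <- unname(.complement[mk$allele_b[i]])
      if (!is.null(mk$major))
        mk$major[i] <- unname(.complement[mk$major[i]])
      pk$map <- mk
    }
    aligned[[k]] <- pk
  }
  if (any(!keep)) {
    warning(sum(!keep), " shared SNP(s) dropped for allele conflicts: ",
            paste(utils::head(ids[!keep], 5), collapse = ", "),
            if (sum(!keep) > 5) ", ..." else "")
    ids <- ids[keep]
    if (!length(ids)) stop("no shared SNPs after allele reconciliation")
    aligned <- lapply(aligned, subset_panel, snps = ids)
    ref <- ref[keep, ]
  }
  # express every panel's dosage as dosage of the reference panel's
  # allele_b (arbitrary fixed orientation), then concatenate
  gmats <- lapply(aligned, function(pk) {
    mk <- pk$map[match(ids, pk$map$snp_id), ]
    g <- pk$genotypes[, ids, drop = FALSE]
    counts_b <- !is.na(mk$major) & mk$major == ref$allele_b
    g[, !counts_b] <- 1 - g[, !counts_b, drop = FALSE]
    g
  })
  all_ids <- unlist(lapply(aligned, function(p) p$individual_ids))
  if (anyDuplicated(all_ids)) stop("duplicated individual ids across panels")
  map <- ref
  map$major <- map$allele_b
  merged <- genotype_panel(do.call(rbind, gmats), all_ids, map)
  recode_major(merged)
}
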