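#' Select QTL SNPs from a 50-SNP window
#'
#' Ranks the window's SNPs by minor allele frequency (ties broken by map
#' position), splits them into the 25 highest-MAF and 25 lowest-MAF SNPs,
#' and samples `n_qtl` uniformly without replacement from the designated
#' half.
#'
#' @param panel a [genotype_panel()].
#' @param window one-row window data frame with `first_snp_index`,
#'   `last_snp_index` delimiting exactly 50 SNPs.
#' @param n_qtl number of QTL (1, 5 or 10; at most 25).
#' @param maf_group `"high"` or `"low"`.
#' @return Integer vector of panel SNP indices.
#' @export
select_qtl <- function(panel, window, n_qtl, maf_group = c("high", "low")) {
  maf_group <- match.arg(maf_group)
  idx <- seq(window$first_snp_index, window$last_snp_index)
  if (length(idx) != 50) stop("power-study windows must have exactly 50 SNPs")
  if (n_qtl > 25) stop("n_qtl must be <= 25")
  p <- colMeans(panel$genotypes[, idx, drop = FALSE], na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  o <- order(maf, panel$map$position_bp[idx])   # ascending MAF, ties by bp
  half <- if (maf_group == "low") idx[o[1:25]] else idx[o[26:50]]
  sort(sample(half, n_qtl))
}

#' Embed regional QTL effects into an observed trait
#'
#' Adds additive per-genotype effects at the selected QTL to the trait
#' values, with equal variance share per QTL and a random sign each, then
#' rescales the summed (mean-centred) genetic values so the realized added
#' variance equals `variance_fraction` of the original trait variance.
#' The QTL SNPs are removed from the returned marker panel, so analysis
#' windows keep 49/45/40 markers for 1/5/10 QTL.  A QTL monomorphic in the
#' sample is re-selected (seeded by the ongoing RNG stream) and noted in
#' the result.
#'
#' @param panel a [genotype_panel()].
#' @param pheno phenotype data frame aligned to the panel (column
#'   `trait`).
#' @param qtl_idx panel SNP indices of the QTL, e.g. from [select_qtl()].
#' @param variance_fraction added variance as a fraction of the original
#'   trait variance.
#' @param window window data frame row used for re-selection when a QTL is
#'   monomorphic (optional).
#' @param maf_group passed to re-selection.
#' @return A list: `panel` (QTL removed), `pheno` (trait augmented),
#'   `qtl_idx`, `qtl_snp_ids`, `added_values`, `realized_fraction`,
#'   `reselected`.
#' @export
embed_effects <- function(panel, pheno, qtl_idx, variance_fraction = 0.025,
                          window = NULL, maf_group = "high") {
  stopifnot(inherits(panel, "genotype_panel"))
  ids <- as.character(pheno$id)
  if (!identical(ids, panel$individual_ids))
    stop("pheno rows must align with panel individuals")
  reselected <- 0L
  repeat {
    mono <- vapply(qtl_idx, function(j) {
      g <- panel$genotypes[, j]
      stats::var(g, na.rm = TRUE) == 0 || all(is.na(g))
    }, logical(1))
    if (!any(mono)) break
    if (is.null(window))
      stop("monomorphic QTL and no window given for re-selection")
    reselected <- reselected + sum(mono)
    qtl_idx <- select_qtl(panel, window, length(qtl_idx), maf_group)
  }
  n <- nrow(panel$genotypes)
  if (variance_fraction == 0) {
    added <- rep(0, n)
  } else {
    per <- vapply(qtl_idx, function(j) {
      g <- panel$genotypes[, j]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      .scale_var(g, 1 / length(qtl_idx)) * sample(c(-1, 1), 1)
    }, numeric(n))
    added <- .scale_var(rowSums(per),
                        variance_fraction * stats::var(pheno$trait))
  }
  out_pheno <- pheno
  out_pheno$trait <- pheno$trait + added
  keep <- setdiff(seq_len(ncol(panel$genotypes)), qtl_idx)
  list(panel = subset_panel(panel, snps = keep),
       pheno = out_pheno,
       qtl_idx = qtl_idx,
       qtl_snp_ids = panel$map$snp_id[qtl_idx],
       added_values = added,
       realized_fraction = stats::var(added) / stats::var(pheno$trait),
       reselected = reselected)
}

# projection matrix of the null polygenic model at fixed variance
# components (used so the power experiment needs one REML fit per cell)
.null_projection <- function(fit, Gmat) {
  n <- fit$n
  V <- fit$sigma2[["genomic"]] * Gmat + diag(fit$sigma2[["residual"]], n)
  Vinv <- chol2inv(chol(V))
  W <- Vinv %*% fit$X
  P <- Vinv - W %*% solve(crossprod(fit$X, W), t(W))
  list(P = P, Py = drop(P %*% fit$y))
}

#' Run the embedded-QTL power experiment
#'
#' For each window and scenario (`n_qtl` x `maf_group`), QTL are selected,
#' 2.5% additional trait variance embedded, the QTL removed from the
#' marker set, and the augmented data analysed both ways: the regional
#' heritability model (whole-genome GRM from all remaining markers plus
#' the reduced-window regional GRM; LRT against the genomic-only null) and
#' single-marker score tests of the remaining window markers against the
#' same null.  A window counts as detected when its LRT (respectively its
#' best marker -log10 p) exceeds the supplied threshold; power is the
#' detected fraction over windows.
#'
#' @param panel QC'd [genotype_panel()] (complete genotypes recommended).
#' @param pheno phenotype data frame aligned by `id`.
#' @param windows window table of 50-SNP windows to use as replicates
#'   (e.g. `make_windows(panel, 50, 50)` or a subset).
#' @param n_qtl_set numbers of QTL per region.
#' @param maf_groups MAF groups to simulate.
#' @param variance_fraction added regional variance fraction.
#' @param lrt_threshold regional detection threshold on the LRT scale;
#'   default Bonferroni for the panel's own 50-SNP overlapping scan.
#' @param gwas_threshold single-marker detection threshold on the -log10 p
#'   scale; default Bonferroni for the panel's SNP count.
#' @param config a [scan_config()] (fixed effects and trait name).
#' @param seed integer seed.
#' @return A list of class `power_result`: `detail` (one row per window x
#'   scenario) and `power` (aggregated per scenario), with the thresholds
#'   used.
#' @export
run_power_experiment <- function(panel, pheno, windows,
                                 n_qtl_set = c(1, 5, 10),
                                 maf_groups = c("high", "low"),
                                 variance_fraction = 0.025,
                                 lrt_threshold = NULL,
                                 gwas_threshold = NULL,
                                 config = scan_config(window_size = 50,
                                                      shift = 25),
                                 seed = 1) {
  set.seed(seed)
  if (is.null(lrt_threshold)) {
    n50 <- 2 * floor(nrow(panel$map) / 50)   # overlapping 50-SNP windows
    lrt_threshold <- scan_thresholds(max(n50, 2))$lrt_genomewide
  }
  if (is.null(gwas_threshold))
    gwas_threshold <- gwas_bonferroni(nrow(panel$map))
  detail <- list()
  for (w in seq_len(nrow(windows))) {
    win <- windows[w, ]
    for (grp in maf_groups) for (nq in n_qtl_set) {
      qtl <- select_qtl(panel, win, nq, grp)
      emb <- embed_effects(panel, pheno, qtl, variance_fraction,
                           window = win, maf_group = grp)
      prep <- prepare_scan(emb$panel, emb$pheno, config,
                           windows = data.frame(
                             chromosome = win$chromosome,
                             first_snp_index = NA, last_snp_index = NA))
      # reduced window in the QTL-free panel
      win_ids <- setdiff(
        panel$map$snp_id[seq(win$first_snp_index, win$last_snp_index)],
        emb$qtl_snp_ids)
      widx <- match(win_ids, prep$panel$map$snp_id)
      Q <- make_grm(prep$panel, snp_subset = widx, freqs = prep$freqs,
                    kind = "regional")
      fit1 <- reml_fit(prep$y, prep$X,
                       kernels = list(genomic = prep$G,
                                      regional = Q$values),
                       keep_kernels = FALSE)
      lrt_w <- lrt(prep$null_fit, fit1)
      pr <- .null_projection(prep$null_fit, prep$G)
      null_obj <- structure(list(fit = prep$null_fit, P = pr$P,
                                 Py = pr$Py, V = NULL, y = prep$y,
                                 X = prep$X), class = "gblup_null")
      mlp <- vapply(widx, function(j) {
        r <- snp_score_test(null_obj, prep$panel$genotypes[, j],
                            missing = "mean")
        if (r$excluded) NA_real_ else r$minus_log10_p
      }, numeric(1))
      best <- suppressWarnings(max(mlp, na.rm = TRUE))
      detail[[length(detail) + 1L]] <- data.frame(
        window = win$ordinal, maf_group = grp, n_qtl = nq,
        n_markers = length(widx), lrt_regional = lrt_w,
        best_snp_minus_log10_p = best,
        detected_regional = is.finite(lrt_w) & lrt_w > lrt_threshold,
        detected_gwas = is.finite(best) & best > gwas_threshold,
        realized_fraction = emb$realized_fraction,
        converged = fit1$converged)
    }
  }
  detail <- do.call(rbind, detail)
  power <- stats::aggregate(
    cbind(power_regional = detected_regional,
          power_gwas = detected_gwas) ~ maf_group + n_qtl,
    data = detail, FUN = mean)
  structure(list(detail = detail, power = power,
                 lrt_threshold = lrt_threshold,
                 gwas_threshold = gwas_threshold, seed = seed),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(paste0("Power experiment: thresholds LRT %.2f (regional), ",
                     "-log10 p %.2f (GWAS)\n"),
              x$lrt_threshold, x$gwas_threshold))
  print(x$power, row.names = FALSE, digits = 3)
  invisible(x)
}
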