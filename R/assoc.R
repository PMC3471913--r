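#' Null polygenic fit and projection for score tests
#'
#' Fits the genomic-only model \eqn{y = X\beta + u + e},
#' \eqn{u \sim N(0, \sigma^2_u G)}, by REML and returns the estimated
#' covariance \eqn{\hat V = \hat\sigma^2_u G + \hat\sigma^2_e I} together
#' with the projection
#' \eqn{\hat P = \hat V^{-1} - \hat V^{-1}X(X'\hat V^{-1}X)^{-1}X'\hat
#' V^{-1}}, which annihilates the fixed effects and is reused unchanged
#' for every SNP (GRAMMAR/mmscore convention: variance parameters are
#' estimated once under the null and held fixed across SNPs).
#'
#' @param y trait vector.
#' @param X fixed-effect design matrix.
#' @param G whole-genome `grm` or matrix.
#' @return A list of class `gblup_null`: `fit` (the [reml_fit()]), `P`,
#'   `Py`, `V`, `y`, `X`.
#' @export
fit_null_gblup <- function(y, X = NULL, G) {
  Gv <- kernel_values(G)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- reml_fit(y, X, kernels = list(genomic = Gv), keep_kernels = FALSE)
  if (!fit$converged) stop("null polygenic fit did not converge")
  V <- fit$sigma2[["genomic"]] * Gv + diag(fit$sigma2[["residual"]], n)
  Vinv <- chol2inv(chol(V))
  W <- Vinv %*% X
  P <- Vinv - W %*% solve(crossprod(X, W), t(W))
  structure(list(fit = fit, P = P, Py = drop(P %*% y), V = V,
                 y = y, X = X),
            class = "gblup_null")
}

#' Single-SNP mixed-model score test
#'
#' Score statistic for a SNP genotype vector `g` against the null
#' polygenic model: \eqn{T = (g'\hat P y)^2 / (g'\hat P g)}, referred to
#' \eqn{\chi^2_1}, with effect estimate \eqn{g'\hat P y / (g'\hat P g)}
#' (trait units per coded-genotype unit).  Individuals with a missing
#' genotype are dropped and the projection recomputed on the complete
#' subset with variance parameters held fixed (or, with
#' `missing = "mean"`, missing genotypes are replaced by the SNP mean and
#' the full projection reused).
#'
#' @param null a [fit_null_gblup()] result.
#' @param g genotype vector (any affine coding; 0/0.5/1 by convention).
#' @param snp_id optional identifier carried into the result.
#' @param missing `"drop"` or `"mean"`.
#' @return One-row data frame: `snp_id`, `effect_estimate`,
#'   `score_statistic`, `p_value`, `minus_log10_p`, `n_used`, `excluded`,
#'   `reason`.
#' @export
snp_score_test <- function(null, g, snp_id = NA_character_,
                           missing = c("drop", "mean")) {
  stopifnot(inherits(null, "gblup_null"))
  missing <- match.arg(missing)
  g <- as.numeric(g)
  if (length(g) != length(null$y)) stop("genotype length mismatch")
  obs <- !is.na(g)
  if (length(unique(g[obs])) < 2)
    return(data.frame(snp_id = snp_id, effect_estimate = NA_real_,
                      score_statistic = NA_real_, p_value = NA_real_,
                      minus_log10_p = NA_real_, n_used = sum(obs),
                      excluded = TRUE, reason = "constant genotype"))
  if (all(obs)) {
    P <- null$P; Py <- null$Py
  } else if (missing == "mean") {
    g[!obs] <- mean(g[obs])
    P <- null$P; Py <- null$Py
  } else {
    V <- null$V[obs, obs]
    X <- null$X[obs, , drop = FALSE]
    Vinv <- chol2inv(chol(V))
    W <- Vinv %*% X
    P <- Vinv - W %*% solve(crossprod(X, W), t(W))
    Py <- drop(P %*% null$y[obs])
    g <- g[obs]
  }
  gPg <- sum(g * (P %*% g))
  gPy <- sum(g * Py)
  stat <- gPy^2 / gPg
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  data.frame(snp_id = snp_id, effect_estimate = gPy / gPg,
             score_statistic = stat, p_value = p,
             minus_log10_p = -log10(p), n_used = length(Py),
             excluded = FALSE, reason = NA_character_)
}

#' Genome-wide single-SNP association scan
#'
#' Runs [snp_score_test()] over every SNP of a panel.
#'
#' @param panel QC'd [genotype_panel()].
#' @param pheno phenotype data frame with `id` and trait.
#' @param config a [scan_config()] (its `fixed_spec` and `trait` are
#'   used).
#' @param missing missing-genotype mode, see [snp_score_test()].
#' @return Data frame with one row per SNP: map columns plus the score
#'   test columns.
#' @export
assoc_scan <- function(panel, pheno, config = scan_config(),
                       missing = c("drop", "mean")) {
  missing <- match.arg(missing)
  prep <- prepare_scan(panel, pheno, config,
                       windows = data.frame(chromosome = NA,
                                            first_snp_index = 1,
                                            last_snp_index = 1),
                       fit_null = FALSE)
  null <- fit_null_gblup(prep$y, prep$X, prep$G)
  map <- prep$panel$map
  rows <- lapply(seq_len(nrow(map)), function(j)
    snp_score_test(null, prep$panel$genotypes[, j],
                   snp_id = map$snp_id[j], missing = missing))
  cbind(map[, c("snp_id", "chromosome", "position_bp")],
        do.call(rbind, rows)[, -1])
}

#' Bonferroni GWAS threshold on the -log10 p scale
#'
#' @param n_snps number of SNPs tested.
#' @param alpha genome-wide type-I error rate.
#' @return `-log10(alpha / n_snps)`; e.g. 6.7 (to 1 d.p.) for 275,564
#'   SNPs at alpha 0.05.
#' @export
gwas_bonferroni <- function(n_snps, alpha = 0.05) {
  stopifnot(n_snps >= 1)
  -log10(alpha / n_snps)
}
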