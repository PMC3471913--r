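#' Boundary-mixture p-value for a regional-variance LRT
#'
#' Under the null hypothesis the regional variance sits on the zero
#' boundary of the parameter space, so the likelihood-ratio statistic is
#' asymptotically distributed as the mixture
#' \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1}: a point mass of one half at
#' zero plus half a 1-df chi-square.  The survival function is 1 for
#' `lrt <= 0` and \eqn{\tfrac12 \Pr(\chi^2_1 \ge t)} otherwise.
#'
#' @param lrt likelihood-ratio statistic(s); finite.
#' @return p-value(s).
#' @export
mixture_pvalue <- function(lrt) {
  if (any(!is.finite(lrt))) stop("non-finite LRT")
  ifelse(lrt <= 0, 1,
         0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE))
}

# inverse of the mixture survival function: t with 0.5*P(chi2_1 >= t) = p
mixture_quantile <- function(p) {
  ifelse(p >= 0.5, 0,
         stats::qchisq(2 * p, df = 1, lower.tail = FALSE))
}

#' Significance thresholds for a regional heritability scan
#'
#' Windows overlap by half their length, so the scan of `n_windows` tests
#' is treated as `m_eff = n_windows / 2` effectively independent tests.
#' The genome-wide threshold is the Bonferroni level `alpha / m_eff`; the
#' suggestive threshold is the per-test level `1 / m_eff`, at which one
#' false positive per genome scan is expected.  Both are converted to the
#' LRT scale through the boundary-mixture null.  For a 5511-window scan
#' these evaluate to LRT 17.1 and 11.4.
#'
#' @param n_windows number of (overlapping) windows tested.
#' @param alpha genome-wide type-I error rate.
#' @return A list of class `threshold_set`: `n_windows`, `m_eff`,
#'   `alpha_genomewide`, `alpha_suggestive` (per-test levels),
#'   `lrt_genomewide`, `lrt_suggestive`.
#' @export
scan_thresholds <- function(n_windows, alpha = 0.05) {
  stopifnot(n_windows >= 2)
  m_eff <- n_windows / 2
  ag <- alpha / m_eff
  as_ <- min(1 / m_eff, 1)
  structure(list(n_windows = n_windows, m_eff = m_eff,
                 alpha_genomewide = ag, alpha_suggestive = as_,
                 lrt_genomewide = mixture_quantile(ag),
                 lrt_suggestive = mixture_quantile(as_)),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(paste0("scan thresholds: %d windows (m_eff = %.1f)\n",
                     "  genome-wide: LRT %.2f (per-test alpha %.3g)\n",
                     "  suggestive:  LRT %.2f (per-test alpha %.3g)\n"),
              x$n_windows, x$m_eff, x$lrt_genomewide, x$alpha_genomewide,
              x$lrt_suggestive, x$alpha_suggestive))
  invisible(x)
}

#' Permute a regional relationship matrix
#'
#' Applies one random permutation to rows and columns of the regional
#' matrix, breaking the correspondence between individuals and their
#' regional relationships while leaving phenotypes, fixed effects and the
#' whole-genome matrix untouched.  A similarity transform, so the spectrum
#' is preserved.
#'
#' @param Q a `grm` or square matrix.
#' @param seed integer seed making the permutation reproducible.
#' @param perm optional explicit permutation (overrides `seed`).
#' @return An object of the same type with permuted rows/columns; the
#'   permutation used is attached as attribute `"perm"`.
#' @export
permute_regional <- function(Q, seed = NULL, perm = NULL) {
  v <- if (inherits(Q, "grm")) Q$values else as.matrix(Q)
  n <- nrow(v)
  if (is.null(perm)) {
    if (!is.null(seed)) set.seed(seed)
    perm <- sample.int(n)
  }
  vp <- v[perm, perm, drop = FALSE]
  dimnames(vp) <- dimnames(v)
  if (inherits(Q, "grm")) {
    out <- Q
    out$values <- vp
    if (!is.null(Q$snp_count_used))
      out$snp_count_used <- Q$snp_count_used[perm, perm, drop = FALSE]
  } else out <- vp
  attr(out, "perm") <- perm
  out
}

#' Permutation null distribution for a regional scan
#'
#' For each window and replicate, the window's regional matrix is
#' independently row/column-permuted against the individuals and the
#' window model refitted, giving the distribution of the LRT under no true
#' regional effect while the trait's overall heritability structure (y, X,
#' G) is left intact.  Because each window is permuted separately, all
#' permuted tests are mutually uncorrelated.
#'
#' @param panel QC'd [genotype_panel()].
#' @param pheno phenotype data frame aligned to the panel (see
#'   [scan_genome()]).
#' @param config a [scan_config()].
#' @param n_replicates permutation replicates (each is one genome scan).
#' @param seed integer seed.
#' @return A list of class `permutation_null`: `lrt` (matrix windows x
#'   replicates), `pvalues`, `qq` (data frame of expected vs observed
#'   -log10 p, pooled), `seed`, `n_replicates`, `thresholds`.
#' @export
permutation_scan <- function(panel, pheno, config = scan_config(),
                             n_replicates = 10, seed = 1) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  prep <- prepare_scan(panel, pheno, config)
  windows <- prep$windows
  nw <- nrow(windows)
  set.seed(seed)
  lrt_mat <- matrix(NA_real_, nw, n_replicates)
  for (r in seq_len(n_replicates)) {
    for (w in seq_len(nw)) {
      Q <- regional_grm_for_window(prep, w)
      Qp <- permute_regional(Q)
      fit1 <- reml_fit(prep$y, prep$X,
                       kernels = list(genomic = prep$G, regional = Qp),
                       keep_kernels = FALSE)
      if (fit1$converged)
        lrt_mat[w, r] <- lrt(prep$null_fit, fit1)
    }
  }
  pv <- mixture_pvalue(lrt_mat[is.finite(lrt_mat)])
  m <- length(pv)
  qq <- data.frame(
    expected = -log10((seq_len(m) - 0.5) / m),
    observed = -log10(sort(pv)))
  structure(list(lrt = lrt_mat, pvalues = pv, qq = qq, seed = seed,
                 n_replicates = n_replicates,
                 thresholds = scan_thresholds(nw)),
            class = "permutation_null")
}

#' Probability of locus overlap by chance
#'
#' Exact binomial tail for the chance that at least `k_min` of `n_loci`
#' independently placed loci fall into a region set spanning `span_bp` of a
#' `genome_bp` genome: \eqn{\Pr(X \ge k_{min})} with
#' \eqn{X \sim \mathrm{Bin}(n_{loci}, span/genome)}.  Used to test whether
#' scan regions are enriched for loci reported by external meta-analyses.
#'
#' @param n_loci number of external loci.
#' @param span_bp total base pairs spanned by the regions.
#' @param genome_bp genome size in base pairs.
#' @param k_min minimum number of overlapping loci observed.
#' @return The enrichment probability.
#' @export
locus_overlap_pvalue <- function(n_loci, span_bp, genome_bp = 3e9,
                                 k_min) {
  if (span_bp <= 0 || span_bp >= genome_bp)
    stop("span_bp must lie strictly between 0 and genome_bp")
  if (k_min < 0 || k_min > n_loci)
    stop("k_min must lie in [0, n_loci]")
  if (k_min == 0) return(1)
  stats::pbinom(k_min - 1, size = n_loci, prob = span_bp / genome_bp,
                lower.tail = FALSE)
}
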