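#' Scan configuration
#'
#' @param window_size window size in SNPs.
#' @param shift shift between window starts in SNPs.
#' @param fixed_spec a [fixed_effects_spec()] for the trait.
#' @param trait name of the trait column in the phenotype table.
#' @param two_step if `TRUE`, fix the genomic variance at its genome-only
#'   estimate and estimate only the regional variance per window (speed
#'   mode); default is the full joint REML per window.
#' @param omit_snps_from_Q snp ids excluded from every regional matrix.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(window_size = 100, shift = 50,
                        fixed_spec = fixed_effects_spec(),
                        trait = "trait", two_step = FALSE,
                        omit_snps_from_Q = NULL) {
  stopifnot(shift <= window_size, shift >= 1)
  structure(list(window_size = window_size, shift = shift,
                 fixed_spec = fixed_spec, trait = trait,
                 two_step = two_step,
                 omit_snps_from_Q = omit_snps_from_Q),
            class = "scan_config")
}

# Align panel and phenotypes, build the design matrix, the whole-genome
# GRM (computed once, reused identically for every window) and the
# genomic-only null fit.
prepare_scan <- function(panel, pheno, config = scan_config(),
                         windows = NULL, fit_null = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(pheno$id)) stop("phenotype table needs an 'id' column")
  trait <- config$trait
  if (is.null(pheno[[trait]])) stop("no trait column '", trait, "'")
  ids <- intersect(panel$individual_ids, as.character(pheno$id))
  if (!length(ids)) stop("no shared individuals between panel and phenotypes")
  ph <- pheno[match(ids, as.character(pheno$id)), , drop = FALSE]
  ok <- !is.na(ph[[trait]])
  ph <- ph[ok, , drop = FALSE]; ids <- ids[ok]
  dm <- build_design_matrix(ph, config$fixed_spec)
  ids <- ids[dm$rows]; ph <- ph[dm$rows, , drop = FALSE]
  pan <- subset_panel(panel, individuals = ids)
  y <- as.numeric(ph[[trait]])
  freqs <- major_allele_freqs(pan)
  G <- make_grm(pan, kind = "whole_genome")
  if (is.null(windows))
    windows <- make_windows(pan, config$window_size, config$shift)
  null_fit <- if (fit_null)
    reml_fit(y, dm$X, kernels = list(genomic = G$values),
             keep_kernels = FALSE) else NULL
  list(panel = pan, pheno = ph, y = y, X = dm$X, freqs = freqs, G = G$values,
       G_grm = G, windows = windows, null_fit = null_fit, config = config)
}

# Regional GRM for window w of a prepared scan; whole-sample allele
# frequencies are used so regional and genomic matrices share a scale.
regional_grm_for_window <- function(prep, w, omit_snps = NULL) {
  win <- prep$windows[w, ]
  idx <- seq(win$first_snp_index, win$last_snp_index)
  omit <- unique(c(omit_snps, prep$config$omit_snps_from_Q))
  if (length(omit))
    idx <- idx[!(prep$panel$map$snp_id[idx] %in% omit)]
  make_grm(prep$panel, snp_subset = idx, freqs = prep$freqs,
           kind = "regional")
}

window_fit_row <- function(prep, w, Q) {
  kn <- list(genomic = prep$G, regional = Q$values)
  fs <- if (isTRUE(prep$config$two_step))
    c(genomic = unname(prep$null_fit$sigma2["genomic"])) else NULL
  fit1 <- reml_fit(prep$y, prep$X, kernels = kn, fixed_sigma2 = fs,
                   keep_kernels = FALSE)
  h <- heritabilities(fit1)
  data.frame(
    lrt = if (fit1$converged) lrt(prep$null_fit, fit1) else NA_real_,
    h2_regional = unname(h["regional"]),
    h2_genomic = unname(h["genomic"]),
    h2_total = unname(attr(h, "total_genetic")),
    logL0 = prep$null_fit$logL_reml, logL1 = fit1$logL_reml,
    converged = fit1$converged)
}

#' Genome scan for regional heritability
#'
#' Slides windows of `window_size` SNPs (shifted by `shift`) across each
#' chromosome.  The whole-genome relationship matrix is computed once from
#' all SNPs (markers of the window under test are not removed) and reused
#' for every window, as is the genomic-only null fit.  For each window the
#' two-kernel model adds the regional relationship matrix and the
#' likelihood-ratio statistic for regional variance is recorded, with
#' regional, residual genomic and total heritability estimates.
#'
#' @param panel QC'd [genotype_panel()].
#' @param pheno phenotype data frame with `id` and the trait column.
#' @param config a [scan_config()].
#' @return An object of class `rhm_scan`: `windows` (per-window results
#'   merged with the window table), `n_windows`, `thresholds`
#'   ([scan_thresholds()]), `null_fit`, `config`.
#' @export
scan_genome <- function(panel, pheno, config = scan_config()) {
  prep <- prepare_scan(panel, pheno, config)
  nw <- nrow(prep$windows)
  rows <- vector("list", nw)
  for (w in seq_len(nw)) {
    Q <- regional_grm_for_window(prep, w)
    rows[[w]] <- window_fit_row(prep, w, Q)
  }
  res <- cbind(prep$windows, do.call(rbind, rows))
  res$mixture_p <- ifelse(is.na(res$lrt), NA, mixture_pvalue(res$lrt))
  res$minus_log10_p <- -log10(res$mixture_p)
  structure(list(windows = res, n_windows = nw,
                 thresholds = scan_thresholds(nw),
                 null_fit = prep$null_fit, config = config,
                 prep = prep),
            class = "rhm_scan")
}

#' @export
print.rhm_scan <- function(x, ...) {
  cat("Regional heritability scan:", x$n_windows, "windows\n")
  th <- x$thresholds
  ok <- x$windows$converged & !is.na(x$windows$lrt)
  cat(sprintf("  genome-wide LRT threshold %.2f: %d window(s) exceed\n",
              th$lrt_genomewide, sum(x$windows$lrt[ok] > th$lrt_genomewide)))
  cat(sprintf("  suggestive  LRT threshold %.2f: %d window(s) exceed\n",
              th$lrt_suggestive, sum(x$windows$lrt[ok] > th$lrt_suggestive)))
  if (any(!ok)) cat("  ", sum(!ok), "window(s) did not converge\n")
  cat(sprintf("  null (genomic-only) h2: %.3f\n",
              x$null_fit$h2[["genomic"]]))
  invisible(x)
}

# Among overlapping runs of windows exceeding a threshold, keep only the
# single highest-LRT window per run.
prune_overlapping_hits <- function(windows, threshold) {
  hit <- which(!is.na(windows$lrt) & windows$converged &
               windows$lrt > threshold)
  if (!length(hit)) return(windows[integer(0), ])
  keep <- integer(0)
  run <- hit[1]
  for (i in hit[-1]) {
    prev <- run[length(run)]
    overlaps <- windows$chromosome[i] == windows$chromosome[prev] &&
      windows$first_snp_index[i] <= windows$last_snp_index[prev]
    if (overlaps) run <- c(run, i)
    else { keep <- c(keep, run[which.max(windows$lrt[run])]); run <- i }
  }
  keep <- c(keep, run[which.max(windows$lrt[run])])
  windows[keep, ]
}

#' Summarize a regional heritability scan
#'
#' Reports windows exceeding the suggestive and genome-wide thresholds;
#' where adjacent overlapping windows both exceed a threshold only the
#' highest-LRT window of the run is listed.
#'
#' @param object an `rhm_scan`.
#' @param ... unused.
#' @return A list of class `summary.rhm_scan`.
#' @export
summary.rhm_scan <- function(object, ...) {
  th <- object$thresholds
  w <- object$windows
  structure(list(
    n_windows = object$n_windows, thresholds = th,
    genomewide_hits = prune_overlapping_hits(w, th$lrt_genomewide),
    suggestive_hits = prune_overlapping_hits(w, th$lrt_suggestive),
    mean_h2 = c(regional = mean(w$h2_regional, na.rm = TRUE),
                genomic = mean(w$h2_genomic, na.rm = TRUE),
                total = mean(w$h2_total, na.rm = TRUE)),
    null_h2_genomic = object$null_fit$h2[["genomic"]]),
    class = "summary.rhm_scan")
}

#' @export
print.summary.rhm_scan <- function(x, ...) {
  cat("Scan of", x$n_windows, "windows; mean h2:",
      sprintf("regional %.4f, genomic %.4f, total %.4f\n",
              x$mean_h2["regional"], x$mean_h2["genomic"],
              x$mean_h2["total"]))
  print(x$thresholds)
  cols <- c("chromosome", "ordinal", "bp_start", "bp_end", "lrt",
            "h2_regional", "h2_genomic", "h2_total")
  cat("Genome-wide significant regions:",
      nrow(x$genomewide_hits), "\n")
  if (nrow(x$genomewide_hits))
    print(x$genomewide_hits[, cols], row.names = FALSE, digits = 4)
  cat("Suggestive regions:", nrow(x$suggestive_hits), "\n")
  if (nrow(x$suggestive_hits))
    print(x$suggestive_hits[, cols], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a regional heritability scan
#'
#' LRT against genome-wide window ordinal with the genome-wide (solid) and
#' suggestive (dashed) thresholds.
#'
#' @param x an `rhm_scan`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rhm_scan <- function(x, ...) {
  w <- x$windows
  graphics::plot(w$ordinal, w$lrt, pch = 16, cex = 0.6,
                 col = 1 + w$chromosome %% 2,
                 xlab = "window", ylab = "LRT", ...)
  graphics::abline(h = x$thresholds$lrt_genomewide, lty = 1)
  graphics::abline(h = x$thresholds$lrt_suggestive, lty = 2)
  invisible(x)
}

#' Write scan results as TSV
#'
#' @param scan an `rhm_scan` (or its `windows` data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  w <- if (inherits(scan, "rhm_scan")) scan$windows else scan
  cols <- intersect(c("chromosome", "ordinal", "snp_id_first",
                      "snp_id_last", "bp_start", "bp_end", "lrt",
                      "minus_log10_p", "h2_regional", "h2_genomic",
                      "h2_total", "converged"), names(w))
  utils::write.table(w[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Joint models over multiple candidate regions
#'
#' Fits each region singly (genomic + one regional matrix), in sliding
#' batches of up to `batch_size` regions simultaneously, and in one fully
#' joint model containing every region.  Batches are formed by sliding a
#' window of `batch_size` regions one region at a time through the given
#' order, so each region appears in several batches; its minimum, maximum
#' and mean estimate across those batches is reported next to the single
#' fit.
#'
#' @param panel QC'd [genotype_panel()].
#' @param pheno phenotype data frame.
#' @param regions data frame of windows (rows of a [make_windows()] table
#'   or of `rhm_scan$windows`), in report order; must not overlap.
#' @param batch_size regions per batch (1-10).
#' @param config a [scan_config()].
#' @return A list of class `rhm_jointfit`: `regions` (data frame with
#'   `h2_single`, `h2_multi_min`, `h2_multi_max`, `h2_multi_mean`),
#'   `joint_total_regional_h2` (summed regional variance of the fully
#'   joint model), `sum_single_h2`.
#' @export
joint_fit_regions <- function(panel, pheno, regions, batch_size = 5,
                              config = scan_config()) {
  stopifnot(batch_size >= 1, batch_size <= 10)
  nr <- nrow(regions)
  if (!nr) stop("no regions")
  for (i in seq_len(nr)) for (j in seq_len(nr)) if (i < j) {
    if (regions$chromosome[i] == regions$chromosome[j] &&
        regions$first_snp_index[i] <= regions$last_snp_index[j] &&
        regions$first_snp_index[j] <= regions$last_snp_index[i])
      stop("regions ", i, " and ", j, " overlap: shared SNPs make ",
           "regional kernels collinear")
  }
  prep <- prepare_scan(panel, pheno, config, windows = regions)
  Qs <- lapply(seq_len(nr), function(w) regional_grm_for_window(prep, w))

  fit_set <- function(which_regions) {
    kn <- c(list(genomic = prep$G),
            stats::setNames(lapply(Qs[which_regions], `[[`, "values"),
                            paste0("region", which_regions)))
    fit <- reml_fit(prep$y, prep$X, kernels = kn, keep_kernels = FALSE)
    h <- heritabilities(fit)
    stats::setNames(as.numeric(h[paste0("region", which_regions)]),
                    which_regions)
  }

  h_single <- vapply(seq_len(nr), function(i) fit_set(i), numeric(1))
  bs <- min(batch_size, nr)
  starts <- if (nr == bs) 1L else seq_len(nr - bs + 1L)
  batch_est <- vector("list", length(starts))
  for (b in seq_along(starts))
    batch_est[[b]] <- fit_set(seq(starts[b], length.out = bs))
  per_region <- lapply(seq_len(nr), function(i) {
    unlist(lapply(batch_est, function(e) e[as.character(i)]), use.names = FALSE)
  })
  per_region <- lapply(per_region, function(v) v[!is.na(v)])

  joint <- fit_set(seq_len(nr))
  out <- cbind(regions,
               h2_single = h_single,
               h2_multi_min = vapply(per_region, min, numeric(1)),
               h2_multi_max = vapply(per_region, max, numeric(1)),
               h2_multi_mean = vapply(per_region, mean, numeric(1)),
               h2_joint = as.numeric(joint))
  structure(list(regions = out,
                 joint_total_regional_h2 = sum(joint),
                 sum_single_h2 = sum(h_single),
                 batch_size = bs),
            class = "rhm_jointfit")
}

#' @export
print.rhm_jointfit <- function(x, digits = 4, ...) {
  cat("Joint regional fits (batch size ", x$batch_size, "):\n", sep = "")
  cols <- c("chromosome", "ordinal", "h2_single", "h2_multi_min",
            "h2_multi_max", "h2_multi_mean", "h2_joint")
  print(format(x$regions[, intersect(cols, names(x$regions))],
               digits = digits), row.names = FALSE)
  cat(sprintf("Sum of single-region h2: %.4f; fully joint total: %.4f\n",
              x$sum_single_h2, x$joint_total_regional_h2))
  invisible(x)
}

#' Window fit with SNP genotypes as fixed covariates
#'
#' Re-estimates a window's regional heritability after adding named SNP
#' genotypes (coded 0/0.5/1) to the fixed-effect design, so the regional
#' estimate is net of those SNPs and of anything in LD with them.
#' Individuals missing a covariate genotype are dropped for this fit;
#' monomorphic covariate SNPs are dropped with a warning.  With an empty
#' `snp_ids` the result equals the plain window fit.
#'
#' @param panel QC'd [genotype_panel()].
#' @param pheno phenotype data frame.
#' @param window one-row window data frame (e.g. a row of
#'   `rhm_scan$windows`).
#' @param snp_ids character vector of covariate SNPs within the window.
#' @param config a [scan_config()].
#' @return One-row data frame like a scan row, with `n_used` and
#'   `snp_covariates` attached.
#' @export
scan_with_snp_covariates <- function(panel, pheno, window,
                                     snp_ids = character(),
                                     config = scan_config()) {
  prep <- prepare_scan(panel, pheno, config, windows = window)
  idx_win <- seq(window$first_snp_index, window$last_snp_index)
  if (length(snp_ids)) {
    pos <- match(snp_ids, prep$panel$map$snp_id)
    if (anyNA(pos)) stop("unknown covariate snp id(s)")
    if (!all(pos %in% idx_win))
      stop("covariate SNPs must lie within the window")
    gcov <- prep$panel$genotypes[, pos, drop = FALSE]
    mono <- apply(gcov, 2, function(v) length(unique(v[!is.na(v)])) < 2)
    if (any(mono)) {
      warning("monomorphic covariate SNP(s) dropped: ",
              paste(snp_ids[mono], collapse = ", "))
      gcov <- gcov[, !mono, drop = FALSE]
    }
    keep <- !apply(gcov, 1, anyNA)
    prep$y <- prep$y[keep]
    prep$X <- cbind(prep$X[keep, , drop = FALSE],
                    gcov[keep, , drop = FALSE])
    prep$G <- prep$G[keep, keep]
    prep$panel <- subset_panel(prep$panel, individuals = which(keep))
    used <- colnames(gcov)
  } else used <- character()
  prep$null_fit <- reml_fit(prep$y, prep$X,
                            kernels = list(genomic = prep$G),
                            keep_kernels = FALSE)
  Q <- regional_grm_for_window(prep, 1)
  wcols <- intersect(c("chromosome", "ordinal", "first_snp_index",
                       "last_snp_index", "bp_start", "bp_end",
                       "snp_id_first", "snp_id_last", "n_snps"),
                     names(prep$windows))
  row <- cbind(prep$windows[1, wcols], window_fit_row(prep, 1, Q))
  row$n_used <- length(prep$y)
  attr(row, "snp_covariates") <- used
  row
}

#' Multi-resolution window fits
#'
#' Re-analyses one region with sub-windows of several sizes (shift =
#' size/2), optionally recomputing every regional matrix with named SNPs
#' omitted, to localise signal within a significant window.
#'
#' @param panel QC'd [genotype_panel()].
#' @param pheno phenotype data frame.
#' @param region one-row window data frame (single chromosome).
#' @param sizes sub-window sizes in SNPs.
#' @param omit_snps snp ids omitted from every regional matrix (e.g. the
#'   most significant single SNPs); `NULL` or empty for none.
#' @param config a [scan_config()].
#' @return Data frame of per-sub-window results keyed by `size` and
#'   `sub_ordinal`.
#' @export
multiresolution_scan <- function(panel, pheno, region,
                                 sizes = c(10, 20, 100),
                                 omit_snps = NULL,
                                 config = scan_config()) {
  prep <- prepare_scan(panel, pheno, config, windows = region)
  first <- region$first_snp_index; last <- region$last_snp_index
  m <- last - first + 1
  out <- list()
  for (size in sizes) {
    if (size > m) {
      warning("sub-window size ", size, " exceeds region (", m,
              " SNPs): skipped")
      next
    }
    shift <- max(1, floor(size / 2))
    starts <- seq(first, last - size + 1, by = shift)
    if (starts[length(starts)] + size - 1 < last &&
        last - (starts[length(starts)] + shift) + 1 >= size / 2)
      starts <- c(starts, starts[length(starts)] + shift)
    for (si in seq_along(starts)) {
      s <- starts[si]; e <- min(s + size - 1, last)
      sub <- data.frame(chromosome = region$chromosome, ordinal = si,
                        first_snp_index = s, last_snp_index = e)
      prep$windows <- sub
      Q <- regional_grm_for_window(prep, 1, omit_snps = omit_snps)
      row <- window_fit_row(prep, 1, Q)
      out[[length(out) + 1L]] <- cbind(
        data.frame(size = size, sub_ordinal = si,
                   first_snp_index = s, last_snp_index = e,
                   bp_start = prep$panel$map$position_bp[s],
                   bp_end = prep$panel$map$position_bp[e]),
        row)
    }
  }
  if (!length(out)) stop("no sub-windows could be formed")
  do.call(rbind, out)
}
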