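#' Major-allele frequencies
#'
#' Under the `{0, 0.5, 1}` dosage-class coding the mean coded genotype over
#' non-missing individuals equals the major-allele frequency, so
#' `p_k >= 0.5` for every SNP oriented to its major allele.
#'
#' @param panel a [genotype_panel()].
#' @return Named numeric vector of frequencies, one per SNP.
#' @export
major_allele_freqs <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  nn <- colSums(!is.na(panel$genotypes))
  if (any(nn == 0))
    stop("SNP(s) with no non-missing calls: ",
         paste(utils::head(panel$map$snp_id[nn == 0], 5), collapse = ", "))
  colMeans(panel$genotypes, na.rm = TRUE)
}

#' Genomic kinship by allele-frequency-weighted IBS
#'
#' Pairwise kinship between individuals i and j:
#' \deqn{f_{ij} = \frac{1}{n} \sum_k \frac{(g_{ik}-p_k)(g_{jk}-p_k)}
#'   {p_k (1-p_k)}}
#' with genotypes \eqn{g \in \{0, 1/2, 1\}} and \eqn{p_k} the major-allele
#' frequency.  The sum runs over SNPs where both individuals are non-missing
#' and n is that pairwise count, so estimates stay unbiased under
#' missing-at-random without imputation.  Monomorphic SNPs
#' (\eqn{p_k(1-p_k)=0}) are skipped.
#'
#' @param panel a [genotype_panel()].
#' @param snp_subset integer indices (or snp ids) of the SNPs to use;
#'   default all.
#' @param freqs optional precomputed frequencies for *all* panel SNPs, so
#'   regional kinships can be weighted by whole-sample frequencies.
#' @return A list of class `kinship_matrix`: `values` (n x n symmetric
#'   kinship matrix) and `snp_count_used` (n x n pairwise non-missing SNP
#'   counts).
#' @export
genomic_kinship <- function(panel, snp_subset = NULL, freqs = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(freqs)) freqs <- major_allele_freqs(panel)
  if (is.null(snp_subset)) snp_subset <- seq_len(nrow(panel$map))
  if (is.character(snp_subset))
    snp_subset <- match(snp_subset, panel$map$snp_id)
  if (!length(snp_subset) || anyNA(snp_subset))
    stop("invalid snp subset")
  g <- panel$genotypes[, snp_subset, drop = FALSE]
  p <- freqs[snp_subset]
  poly <- p * (1 - p) > 0
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  if (!ncol(g)) stop("no polymorphic SNPs in subset")

  w <- 1 / sqrt(p * (1 - p))
  z <- sweep(g, 2, p, "-")
  z <- sweep(z, 2, w, "*")
  obs <- !is.na(z)
  z[!obs] <- 0
  num <- tcrossprod(z)                        # sum over shared SNPs
  cnt <- tcrossprod(obs * 1)                  # pairwise non-missing counts
  if (any(cnt == 0))
    stop("individual pair(s) share no usable SNPs in this region")
  f <- num / cnt
  ids <- panel$individual_ids
  dimnames(f) <- list(ids, ids)
  structure(list(values = f, snp_count_used = cnt,
                 snp_ids = panel$map$snp_id[snp_subset][poly]),
            class = "kinship_matrix")
}

#' Relationship (GRM) from kinship
#'
#' Doubles the kinship elementwise: off-diagonals become \eqn{2 f_{ij}} and
#' diagonals \eqn{2 f_{ii}}, interpretable as one plus the genomic
#' inbreeding coefficient.
#'
#' @param kinship a `kinship_matrix` from [genomic_kinship()].
#' @param kind `"whole_genome"` or `"regional"`.
#' @return A list of class `grm`: `values` (n x n), `snp_ids`, `kind`,
#'   `snp_count_used`.
#' @export
to_relationship <- function(kinship, kind = c("whole_genome", "regional")) {
  stopifnot(inherits(kinship, "kinship_matrix"))
  kind <- match.arg(kind)
  structure(list(values = 2 * kinship$values,
                 snp_ids = kinship$snp_ids, kind = kind,
                 snp_count_used = kinship$snp_count_used),
            class = "grm")
}

#' Build a GRM in one call
#'
#' Convenience wrapper: [genomic_kinship()] followed by
#' [to_relationship()].
#'
#' @inheritParams genomic_kinship
#' @inheritParams to_relationship
#' @return A `grm`.
#' @export
make_grm <- function(panel, snp_subset = NULL, freqs = NULL,
                     kind = if (is.null(snp_subset)) "whole_genome"
                            else "regional") {
  to_relationship(genomic_kinship(panel, snp_subset, freqs), kind = kind)
}

#' @export
print.grm <- function(x, ...) {
  cat("grm (", x$kind, "): ", nrow(x$values), " individuals, ",
      length(x$snp_ids), " SNPs\n", sep = "")
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.5f\n",
              mean(diag(x$values)),
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Sliding SNP windows
#'
#' Tiles each chromosome with windows of `size` SNPs shifted by `shift`
#' SNPs, e.g. SNPs 1-100, 51-150, 101-200 for the defaults.  Windows never
#' span chromosome boundaries.  After the last full window, a truncated
#' trailing window starting at the next regular offset is emitted when it
#' covers additional SNPs and contains at least `size/2` of them; a
#' chromosome with fewer than `size/2` SNPs yields no window (with a
#' warning).  Ordinals are assigned genome-wide in order.
#'
#' @param panel a [genotype_panel()].
#' @param size window size in SNPs.
#' @param shift shift between consecutive windows in SNPs.
#' @return Data frame of class `window_table` with columns `chromosome`,
#'   `ordinal`, `first_snp_index`, `last_snp_index` (panel-wide, inclusive),
#'   `bp_start`, `bp_end`, `snp_id_first`, `snp_id_last`, `n_snps`.
#' @export
make_windows <- function(panel, size = 100, shift = 50) {
  stopifnot(inherits(panel, "genotype_panel"), size >= 2,
            shift >= 1, shift <= size)
  map <- panel$map
  out <- list()
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    m <- length(idx)
    if (m < size / 2) {
      warning("chromosome ", chr, " has ", m, " SNPs (< size/2): no window")
      next
    }
    starts <- integer(0)
    s <- 1L
    while (s + size - 1 <= m) { starts <- c(starts, s); s <- s + shift }
    if (length(starts)) {
      last_end <- starts[length(starts)] + size - 1L
      nxt <- starts[length(starts)] + shift
      if (m > last_end && m - nxt + 1 >= size / 2)
        starts <- c(starts, nxt)
    } else starts <- 1L                      # size/2 <= m < size
    ends <- pmin(starts + size - 1L, m)
    out[[length(out) + 1L]] <- data.frame(
      chromosome = chr,
      first_snp_index = idx[starts],
      last_snp_index = idx[ends])
  }
  if (!length(out)) stop("no windows could be formed")
  w <- do.call(rbind, out)
  w <- w[order(w$chromosome, w$first_snp_index), ]
  w$ordinal <- seq_len(nrow(w))
  w$bp_start <- map$position_bp[w$first_snp_index]
  w$bp_end <- map$position_bp[w$last_snp_index]
  w$snp_id_first <- map$snp_id[w$first_snp_index]
  w$snp_id_last <- map$snp_id[w$last_snp_index]
  w$n_snps <- w$last_snp_index - w$first_snp_index + 1L
  rownames(w) <- NULL
  class(w) <- c("window_table", "data.frame")
  w[, c("chromosome", "ordinal", "first_snp_index", "last_snp_index",
        "bp_start", "bp_end", "snp_id_first", "snp_id_last", "n_snps")]
}

#' Principal-component covariates from a GRM
#'
#' Leading eigenvectors of the relationship matrix, for use as fixed-effect
#' covariates controlling residual stratification.  Eigenvectors are unit
#' norm with the sign fixed so the largest-magnitude entry is positive.
#'
#' @param G a `grm` or symmetric matrix.
#' @param n_components number of components.
#' @return n x n_components matrix, columns ordered by descending
#'   eigenvalue, with the eigenvalues in attribute `"eigenvalues"`.
#' @export
pca_covariates <- function(G, n_components = 10) {
  v <- if (inherits(G, "grm")) G$values else as.matrix(G)
  if (n_components > nrow(v))
    stop("n_components exceeds matrix dimension")
  e <- eigen((v + t(v)) / 2, symmetric = TRUE)
  vec <- e$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  colnames(vec) <- paste0("PC", seq_len(n_components))
  attr(vec, "eigenvalues") <- e$values[seq_len(n_components)]
  vec
}

#' Write / read a GRM
#'
#' Two formats: plain TSV (`format = "tsv"`, a full matrix with ids as
#' header) and the GCTA binary triplet (`format = "gcta"`: `<stem>.grm.bin`
#' lower-triangle single-precision values, `<stem>.grm.N.bin` SNP counts,
#' `<stem>.grm.id`).
#'
#' @param grm a `grm`.
#' @param stem output stem (gcta) or file path (tsv).
#' @param format `"tsv"` or `"gcta"`.
#' @return `stem`, invisibly.
#' @export
write_grm <- function(grm, stem, format = c("tsv", "gcta")) {
  format <- match.arg(format)
  v <- grm$values
  ids <- rownames(v)
  if (format == "tsv") {
    df <- as.data.frame(v)
    utils::write.table(cbind(id = ids, df), stem, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(stem))
  }
  n <- nrow(v)
  lt <- which(lower.tri(v, diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(lt[, 1], lt[, 2]), ]        # GCTA order: by row, j<=i
  con <- file(paste0(stem, ".grm.bin"), "wb")
  writeBin(as.numeric(v[lt]), con, size = 4); close(con)
  con <- file(paste0(stem, ".grm.N.bin"), "wb")
  writeBin(as.numeric(grm$snp_count_used[lt]), con, size = 4); close(con)
  utils::write.table(data.frame(ids, ids), paste0(stem, ".grm.id"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(stem)
}

#' @rdname write_grm
#' @param kind stored on the result (`read_grm` cannot infer it).
#' @export
read_grm <- function(stem, format = c("tsv", "gcta"),
                     kind = "whole_genome") {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(stem, header = TRUE, sep = "\t",
                            check.names = FALSE)
    ids <- as.character(df[[1]])
    v <- as.matrix(df[, -1, drop = FALSE])
    dimnames(v) <- list(ids, ids)
    return(structure(list(values = v, snp_ids = NULL, kind = kind,
                          snp_count_used = NULL), class = "grm"))
  }
  ids <- utils::read.table(paste0(stem, ".grm.id"), header = FALSE)[[2]]
  n <- length(ids)
  m <- n * (n + 1) / 2
  vals <- readBin(paste0(stem, ".grm.bin"), what = "numeric", n = m,
                  size = 4)
  cnts <- readBin(paste0(stem, ".grm.N.bin"), what = "numeric", n = m,
                  size = 4)
  v <- matrix(0, n, n); cnt <- matrix(0, n, n)
  lt <- which(lower.tri(v, diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(lt[, 1], lt[, 2]), ]
  v[lt] <- vals; cnt[lt] <- cnts
  v <- v + t(v) - diag(diag(v)); cnt <- cnt + t(cnt) - diag(diag(cnt))
  dimnames(v) <- list(ids, ids)
  structure(list(values = v, snp_ids = NULL, kind = kind,
                 snp_count_used = cnt), class = "grm")
}
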