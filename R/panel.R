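#' Genotype panel
#'
#' Container for a set of genotyped individuals.  Genotypes are stored as the
#' dosage class of the major allele: 0 = rare-allele homozygote, 0.5 =
#' heterozygote, 1 = common-allele homozygote, `NA` = missing.  Under this
#' coding the mean of a SNP column over non-missing individuals equals the
#' major-allele frequency.
#'
#' @param genotypes numeric matrix, individuals x SNPs, values in
#'   `{0, 0.5, 1, NA}`.
#' @param individual_ids character vector of unique individual identifiers.
#' @param map data frame with columns `snp_id`, `chromosome` (integer 1-22),
#'   `position_bp` (1-based), `allele_a`, `allele_b` (the two observed
#'   alleles; `allele_a` corresponds to the first .bim allele) and `major`
#'   (the allele the dosage counts; `NA` when undefined, e.g. an all-missing
#'   SNP).
#' @return An object of class `genotype_panel`: a list with elements
#'   `genotypes`, `individual_ids`, `map`.
#' @export
genotype_panel <- function(genotypes, individual_ids, map) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  individual_ids <- as.character(individual_ids)
  if (nrow(genotypes) != length(individual_ids))
    stop("genotypes has ", nrow(genotypes), " rows but ",
         length(individual_ids), " individual ids")
  if (ncol(genotypes) != nrow(map))
    stop("genotypes has ", ncol(genotypes), " columns but map has ",
         nrow(map), " SNPs")
  if (anyDuplicated(individual_ids))
    stop("duplicated individual ids")
  need <- c("snp_id", "chromosome", "position_bp", "allele_a", "allele_b")
  miss <- setdiff(need, names(map))
  if (length(miss)) stop("map lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(map$major)) map$major <- NA_character_
  map$snp_id <- as.character(map$snp_id)
  if (anyDuplicated(map$snp_id)) stop("duplicated snp ids in map")
  if (any(map$position_bp < 1, na.rm = TRUE)) stop("position_bp must be >= 1")
  o <- order(map$chromosome, map$position_bp)
  if (any(o != seq_len(nrow(map)))) {
    map <- map[o, , drop = FALSE]
    genotypes <- genotypes[, o, drop = FALSE]
  }
  rownames(map) <- NULL
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% c(0, 0.5, 1)))
    stop("genotype values must be 0, 0.5, 1 or NA")
  dimnames(genotypes) <- list(individual_ids, map$snp_id)
  structure(list(genotypes = genotypes, individual_ids = individual_ids,
                 map = map),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$individual_ids), "individuals x",
      nrow(x$map), "SNPs on",
      length(unique(x$map$chromosome)), "chromosome(s)\n")
  mr <- mean(is.na(x$genotypes))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mr))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$genotypes)

#' Subset a genotype panel
#'
#' @param panel a [genotype_panel()].
#' @param individuals indices or ids of individuals to keep (default all).
#' @param snps indices or snp ids to keep (default all).
#' @return A `genotype_panel` restricted to the selection.
#' @export
subset_panel <- function(panel, individuals = NULL, snps = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  ii <- if (is.null(individuals)) seq_along(panel$individual_ids) else {
    if (is.character(individuals))
      match(individuals, panel$individual_ids) else individuals
  }
  jj <- if (is.null(snps)) seq_len(nrow(panel$map)) else {
    if (is.character(snps)) match(snps, panel$map$snp_id) else snps
  }
  if (anyNA(ii)) stop("unknown individual id(s)")
  if (anyNA(jj)) stop("unknown snp id(s)")
  genotype_panel(panel$genotypes[ii, jj, drop = FALSE],
                 panel$individual_ids[ii],
                 panel$map[jj, , drop = FALSE])
}

# Recompute the major allele per SNP from the current genotype matrix and
# re-express dosages relative to it.  Frequency ties (0.5) designate
# allele_b as major, so the orientation is deterministic.
recode_major <- function(panel) {
  g <- panel$genotypes
  p <- colMeans(g, na.rm = TRUE)          # freq of currently-counted allele
  flip <- !is.na(p) & p < 0.5
  if (any(flip)) {
    g[, flip] <- 1 - g[, flip]
    map <- panel$map
    cur <- ifelse(is.na(map$major) | map$major == map$allele_b,
                  "b", "a")
    cur[flip] <- ifelse(cur[flip] == "b", "a", "b")
    map$major <- ifelse(cur == "b", map$allele_b, map$allele_a)
    panel$map <- map
    panel$genotypes <- g
  }
  # ties: ensure allele_b is the designated major
  p2 <- colMeans(panel$genotypes, na.rm = TRUE)
  tie <- !is.na(p2) & abs(p2 - 0.5) < .Machine$double.eps^0.5
  if (any(tie)) {
    map <- panel$map
    to_b <- tie & !is.na(map$major) & map$major == map$allele_a
    if (any(to_b)) {
      panel$genotypes[, to_b] <- 1 - panel$genotypes[, to_b]
      map$major[to_b] <- map$allele_b[to_b]
      panel$map <- map
    }
  }
  panel
}
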