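#' Read PLINK 1 binary genotypes
#'
#' Reads a SNP-major .bed/.bim/.fam triplet and recodes genotypes to major
#' allele dosage classes `{0, 0.5, 1}`.  The major allele of each SNP is the
#' allele with frequency >= 0.5 among non-missing calls (ties designate the
#' second .bim allele).  Missing calls are preserved as `NA`; an all-missing
#' SNP keeps `major = NA` in the map.
#'
#' @param bed_path,bim_path,fam_path paths to the three PLINK files.  If
#'   `bim_path`/`fam_path` are missing they are derived from `bed_path` by
#'   extension substitution.
#' @return A [genotype_panel()].
#' @export
read_plink <- function(bed_path, bim_path = NULL, fam_path = NULL) {
  stem <- sub("\\.bed$", "", bed_path)
  if (is.null(bim_path)) bim_path <- paste0(stem, ".bim")
  if (is.null(fam_path)) fam_path <- paste0(stem, ".fam")
  for (f in c(bed_path, bim_path, fam_path))
    if (!file.exists(f)) stop("file not found: ", f)

  bim <- utils::read.table(bim_path, header = FALSE,
                           col.names = c("chromosome", "snp_id", "cm",
                                         "position_bp", "allele_a",
                                         "allele_b"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character",
                                          "character"))
  fam <- utils::read.table(fam_path, header = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex",
                                         "phe"),
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "character", "character"))
  n <- nrow(fam); m <- nrow(bim)

  raw <- readBin(bed_path, what = "raw", n = file.info(bed_path)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed layout is supported")
  bps <- ceiling(n / 4)                 # bytes per SNP
  if (length(raw) - 3L != bps * m)
    stop("bed/bim/fam dimension mismatch: expected ", bps * m,
         " genotype bytes for ", n, " individuals x ", m, " SNPs, found ",
         length(raw) - 3L)

  body <- matrix(as.integer(raw[-(1:3)]), nrow = bps, ncol = m)
  # unpack 2-bit codes, individuals within byte are in the low bits first
  codes <- matrix(NA_integer_, nrow = 4 * bps, ncol = m)
  shift <- c(1L, 4L, 16L, 64L)
  for (k in 1:4)
    codes[seq(k, by = 4, length.out = bps), ] <- (body %/% shift[k]) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> hom allele_a (2 copies), 10 (=2) -> het, 11 (=3) -> hom allele_b,
  # 01 (=1) -> missing
  dose_a <- matrix(NA_real_, n, m)
  dose_a[codes == 0L] <- 1
  dose_a[codes == 2L] <- 0.5
  dose_a[codes == 3L] <- 0

  p_a <- colMeans(dose_a, na.rm = TRUE)         # frequency of allele_a
  major_is_a <- !is.nan(p_a) & p_a > 0.5        # tie -> allele_b
  g <- dose_a
  g[, !major_is_a] <- 1 - g[, !major_is_a, drop = FALSE]
  bim$major <- ifelse(is.nan(p_a), NA_character_,
                      ifelse(major_is_a, bim$allele_a, bim$allele_b))
  ids <- if (anyDuplicated(fam$iid)) paste(fam$fid, fam$iid, sep = "_")
         else fam$iid
  genotype_panel(g, ids,
                 bim[, c("snp_id", "chromosome", "position_bp", "allele_a",
                         "allele_b", "major")])
}

#' Write PLINK 1 binary genotypes
#'
#' Inverse of [read_plink()]: writes a SNP-major .bed/.bim/.fam triplet such
#' that re-reading reproduces the panel's genotype matrix exactly.
#'
#' @param panel a [genotype_panel()].
#' @param stem output path stem; `<stem>.bed`, `.bim`, `.fam` are written.
#' @return `stem`, invisibly.
#' @export
write_plink <- function(panel, stem) {
  stopifnot(inherits(panel, "genotype_panel"))
  map <- panel$map
  n <- length(panel$individual_ids); m <- nrow(map)

  # dosage of allele_a (0, .5, 1 scale)
  major_is_a <- !is.na(map$major) & map$major == map$allele_a
  dose_a <- panel$genotypes
  dose_a[, !major_is_a] <- 1 - dose_a[, !major_is_a, drop = FALSE]
  codes <- matrix(1L, n, m)                       # 01 = missing
  codes[!is.na(dose_a) & dose_a == 1]   <- 0L     # hom allele_a
  codes[!is.na(dose_a) & dose_a == 0.5] <- 2L     # het
  codes[!is.na(dose_a) & dose_a == 0]   <- 3L     # hom allele_b

  bps <- ceiling(n / 4)
  padded <- matrix(0L, 4 * bps, m)
  padded[seq_len(n), ] <- codes
  shift <- c(1L, 4L, 16L, 64L)
  body <- matrix(0L, bps, m)
  for (k in 1:4)
    body <- body + padded[seq(k, by = 4, length.out = bps), , drop = FALSE] *
      shift[k]
  con <- file(paste0(stem, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.integer(body)), con)

  bim <- data.frame(map$chromosome, map$snp_id, 0, map$position_bp,
                    map$allele_a, map$allele_b)
  utils::write.table(bim, paste0(stem, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(panel$individual_ids, panel$individual_ids,
                    0, 0, 0, -9)
  utils::write.table(fam, paste0(stem, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(stem)
}

#' Read a phenotype/covariate table
#'
#' Tab-separated with header columns `id`, `trait`, `sex`, `age`,
#' `population`, `village`; missing values coded `NA`.
#'
#' @param path file path.
#' @return A data frame with `id` as character, `trait`/`age` numeric and
#'   `sex`/`population`/`village` as factors.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = "NA", stringsAsFactors = FALSE)
  need <- c("id", "trait")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("phenotype table lacks columns: ",
                         paste(miss, collapse = ", "))
  ph$id <- as.character(ph$id)
  if (anyDuplicated(ph$id)) stop("duplicated individual ids in phenotypes")
  ph$trait <- as.numeric(ph$trait)
  for (f in intersect(c("sex", "population", "village"), names(ph)))
    ph[[f]] <- factor(ph[[f]])
  if ("age" %in% names(ph)) ph$age <- as.numeric(ph$age)
  ph
}

#' Write a phenotype/covariate table
#'
#' @param pheno data frame as returned by [read_phenotypes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
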