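GT_VCF <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1", MISSING = "./.")

#' Write pseudo-diploid genotypes to VCF
#'
#' Emits a minimal VCF 4.2 with GT and DP fields, one record per
#' palindrome-arm site.
#'
#' @param geno a [pseudo_geno()] object.
#' @param file output path.
#' @param chrom chromosome/contig name to write.
#' @export
write_pseudodiploid_vcf <- function(geno, file, chrom = "palindrome") {
  stopifnot(inherits(geno, "pseudo_geno"))
  samples <- rownames(geno$gt)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", chrom),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  ns <- ncol(geno$gt)
  body <- vapply(seq_len(ns), function(j) {
    gts <- GT_VCF[geno$gt[, j]]
    dps <- if (is.null(geno$dp)) rep(".", length(samples)) else geno$dp[, j]
    paste(c(chrom, geno$sites$pos[j], ".", geno$sites$ref[j],
            geno$sites$alt[j], ".", "PASS", ".", "GT:DP",
            paste(gts, dps, sep = ":")), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Read pseudo-diploid genotypes from VCF
#'
#' Reads a biallelic VCF with GT (and optionally DP) fields into a
#' [pseudo_geno()] matrix; any unphased or phased diploid genotype code
#' is accepted, everything else becomes `MISSING`.
#'
#' @param file VCF path.
#' @return a [pseudo_geno()] object.
#' @export
read_pseudodiploid_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  sites <- data.frame(pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  raw_gt <- vcfR::extract.gt(v, element = "GT")
  map <- c("0/0" = "HOM_REF", "0|0" = "HOM_REF",
           "0/1" = "HET", "1/0" = "HET", "0|1" = "HET", "1|0" = "HET",
           "1/1" = "HOM_ALT", "1|1" = "HOM_ALT")
  gt <- matrix(unname(map[raw_gt]), nrow = nrow(raw_gt))
  gt[is.na(gt)] <- "MISSING"
  gt <- t(gt)                              # samples x sites
  rownames(gt) <- colnames(raw_gt)
  dp <- NULL
  if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    dp <- t(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    rownames(dp) <- colnames(raw_gt)
  }
  pseudo_geno(sites, gt, dp)
}

#' Write / read a haploid SNV matrix as TSV
#'
#' Samples in rows, sites in columns (column names are 1-based
#' positions); missing alleles are empty fields.
#'
#' @param mat character matrix (or an `"xdeg_sim"` object).
#' @param file path.
#' @export
write_snv_matrix <- function(mat, file) {
  if (inherits(mat, "xdeg_sim")) mat <- mat$matrix
  df <- data.frame(sample = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_snv_matrix
#' @export
read_snv_matrix <- function(file) {
  df <- read.table(file, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m[m == ""] <- NA
  m
}

#' Read / write BED intervals (0-based half-open)
#'
#' @param file BED path; the first three columns are `chrom`, `start`,
#'   `end`, an optional fourth is `name`.
#' @export
read_bed <- function(file) {
  df <- read.table(file, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df
}

#' @rdname read_bed
#' @param df data frame with columns `chrom`, `start`, `end` (and
#'   optionally more).
#' @export
write_bed <- function(df, file) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Write classified events to TSV
#'
#' @param events events data frame.
#' @param file path.
#' @export
write_events_tsv <- function(events, file) {
  write.table(events, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a sample-to-family map
#'
#' @param file TSV with header columns `sample` and `family`.
#' @export
read_family_map <- function(file) {
  df <- read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "family") %in% names(df)))
  df
}
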