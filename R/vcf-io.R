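#' Write a genotype matrix as minimal VCF v4.2
#'
#' One biallelic SNV record per site with a GT-only FORMAT; genotypes are
#' serialized unphased (`0/0`, `0/1`, `1/1`, `./.`). Output is deterministic:
#' the same matrix always produces byte-identical files (no timestamps).
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  gt_str <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=founderhap",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(gm$sites)), function(j) {
    codes <- gm$geno[, j]
    gts <- ifelse(is.na(codes), "./.", gt_str[codes + 1L])
    paste(c(gm$sites$chrom[j], gm$sites$pos[j],
            sprintf("site_%s_%d", gm$sites$chrom[j], gm$sites$pos[j]),
            gm$sites$ref[j], gm$sites$alt[j], ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal VCF into a genotype matrix
#'
#' Parses a VCF v4.2 with a GT field into a [genotype_matrix()]. Only
#' biallelic SNV records are retained; multiallelic records (comma in ALT) are
#' skipped with a single counted warning (count in the `"n_skipped"`
#' attribute). `|`-separated genotypes are accepted and treated as unphased;
#' any genotype containing a missing allele becomes the missing code.
#'
#' @param path VCF file path.
#' @return a [genotype_matrix()] with attribute `n_skipped`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_invalid("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_skipped <- sum(multi)
  if (n_skipped > 0)
    warning(sprintf("skipped %d multiallelic record(s)", n_skipped))
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  geno <- t(matrix(code(as.character(gt)), nrow = nrow(gt), ncol = ncol(gt)))
  samples <- colnames(gt)
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  gm <- genotype_matrix(samples, sites[ord, , drop = FALSE],
                        geno[, ord, drop = FALSE])
  attr(gm, "n_skipped") <- n_skipped
  gm
}
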