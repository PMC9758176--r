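#' Construct a genotype matrix
#'
#' Container for unphased diploid genotypes at biallelic SNVs: a sample x site
#' matrix of allele-dosage codes (0 hom-ref, 1 het, 2 hom-alt, `NA` missing)
#' together with site coordinates and alleles. Sites must be strictly sorted by
#' (chromosome, position) with no duplicate positions per chromosome — the IBD
#' streak scan depends on adjacency in genomic order.
#'
#' @param samples character vector of sample identifiers.
#' @param sites data.frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt` (single bases).
#' @param geno integer matrix, `length(samples)` rows x `nrow(sites)` columns,
#'   values in `{0, 1, 2, NA}`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, sites, geno) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop_invalid("duplicate sample identifiers")
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
    stop_invalid("sites needs columns chrom, pos, ref, alt")
  if (nrow(geno) != length(samples) || ncol(geno) != nrow(sites))
    stop_invalid("geno dimensions must be samples x sites")
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    stop_invalid("sites must be sorted by (chromosome, position)")
  if (any(stats::ave(sites$pos, sites$chrom, FUN = function(p) duplicated(p)) == 1))
    stop_invalid("duplicate positions within a chromosome")
  bad <- !(geno %in% c(0L, 1L, 2L)) & !is.na(geno)
  if (any(bad)) stop_invalid("genotype codes must be 0, 1, 2 or NA")
  storage.mode(geno) <- "integer"
  rownames(geno) <- samples
  structure(list(samples = samples,
                 sites = as.data.frame(sites, stringsAsFactors = FALSE),
                 geno = geno),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites on chromosome(s) %s\n",
              length(x$samples), nrow(x$sites),
              paste(unique(x$sites$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

# internal: genotype row for one sample, validating membership
gm_row <- function(gm, sample) {
  i <- match(sample, gm$samples)
  if (is.na(i)) stop_invalid("unknown sample: ", sample)
  gm$geno[i, ]
}
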