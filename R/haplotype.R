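#' Founder-haplotype discrimination rule
#'
#' A rule panel for assigning risk-allele-bearing chromosomes to one of two
#' founder haplotypes (alpha/beta) from a small set of discriminating tag SNPs
#' flanking the risk locus. The default is the published panel for the GNE
#' c.620A>T founder analysis: four tag SNPs on chromosome 9 whose alleles are
#' `G,G,G,C` on the alpha background and `A,A,A,T` on the beta background,
#' with non-risk chromosomes carrying `G,G,G,T`; the risk locus at 36,246,117
#' has reference `T` and risk allele `A` (plus strand — the cDNA A>T name maps
#' to genomic T>A because the gene is on the minus strand).
#'
#' Alpha and beta must differ at every discriminating site.
#'
#' @param positions discriminating-site positions (bp), same order as patterns.
#' @param alpha,beta,background single-base allele vectors per discriminating site.
#' @param risk_pos risk-locus position (bp).
#' @param risk_ref,risk_alt risk-locus reference and risk alleles.
#' @param chrom chromosome name.
#' @return object of class `haplotype_rule`.
#' @export
haplotype_rule <- function(positions = c(36214971, 36216426, 36217798, 36220134),
                           alpha = c("G", "G", "G", "C"),
                           beta = c("A", "A", "A", "T"),
                           background = c("G", "G", "G", "T"),
                           risk_pos = 36246117,
                           risk_ref = "T", risk_alt = "A",
                           chrom = "9") {
  n <- length(positions)
  if (length(alpha) != n || length(beta) != n || length(background) != n)
    stop_invalid("patterns must match the number of discriminating sites")
  if (any(alpha == beta))
    stop_invalid("alpha and beta must differ at every discriminating site")
  structure(list(positions = as.numeric(positions), alpha = alpha, beta = beta,
                 background = background, risk_pos = as.numeric(risk_pos),
                 risk_ref = risk_ref, risk_alt = risk_alt, chrom = chrom),
            class = "haplotype_rule")
}

# internal: canonical unordered genotype string, e.g. "TC" -> "CT"
canon_gt <- function(g) {
  vapply(g, function(x) {
    if (is.na(x)) return(NA_character_)
    paste(sort(strsplit(x, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

hom <- function(a) paste0(a, a)
het <- function(a, b) paste(sort(c(a, b)), collapse = "")

#' Classify one sample's diplotype at the rule panel
#'
#' Assigns a founder diplotype from unphased genotypes at the discriminating
#' sites and the risk locus. With a homozygous risk genotype the sample is
#' `alpha/alpha`, `beta/beta` or `alpha/beta` according to whether the panel is
#' homozygous alpha, homozygous beta or heterozygous alpha/beta throughout.
#' With a heterozygous risk genotype the risk chromosome is resolved against
#' the non-risk background haplotype: homozygous-alpha tag sites at the first
#' three positions with the alpha allele present at the fourth give `alpha/-`;
#' the beta-specific pattern (tag sites heterozygous at the first three,
#' homozygous at the fourth, matching beta over background) gives `beta/-`.
#' Any other configuration is `unknown` — the rule never forces a call.
#'
#' @param genotypes named character vector or list: names are site positions
#'   (discriminating sites and risk locus), values two-letter unphased
#'   genotypes such as `"GG"`, `"CT"` (order of letters irrelevant).
#' @param rule a [haplotype_rule()].
#' @return list of class `haplotype_call` with `diplotype` (one of
#'   `"alpha/alpha"`, `"beta/beta"`, `"alpha/beta"`, `"alpha/-"`, `"beta/-"`,
#'   `"none"`, `"unknown"`), `reason`, and `evidence` (the canonicalized
#'   per-site genotypes, panel order).
#' @examples
#' rule <- haplotype_rule()
#' g <- c("36214971" = "GG", "36216426" = "GG", "36217798" = "GG",
#'        "36220134" = "CT", "36246117" = "AT")
#' classify_diplotype(g, rule)$diplotype   # "alpha/-"
#' @export
classify_diplotype <- function(genotypes, rule = haplotype_rule()) {
  genotypes <- unlist(genotypes)
  key <- as.character(rule$positions)
  risk_key <- as.character(rule$risk_pos)
  if (!risk_key %in% names(genotypes) || is.na(genotypes[[risk_key]]))
    stop_invalid("risk-locus genotype missing")
  risk <- canon_gt(genotypes[[risk_key]])
  disc <- canon_gt(genotypes[key])
  call <- function(d, reason = "") {
    structure(list(diplotype = d, reason = reason,
                   evidence = c(disc, risk = risk)),
              class = "haplotype_call")
  }
  if (risk == hom(rule$risk_ref)) return(call("none"))
  known_risk <- c(hom(rule$risk_alt), het(rule$risk_ref, rule$risk_alt))
  if (!risk %in% known_risk) return(call("unknown", "unrecognized risk genotype"))
  if (any(is.na(disc))) return(call("unknown", "insufficient markers"))

  a_hom <- hom(rule$alpha); b_hom <- hom(rule$beta)
  ab_het <- mapply(het, rule$alpha, rule$beta)
  if (risk == hom(rule$risk_alt)) {
    if (all(disc == a_hom)) return(call("alpha/alpha"))
    if (all(disc == b_hom)) return(call("beta/beta"))
    if (all(disc == ab_het)) return(call("alpha/beta"))
    return(call("unknown", "pattern conflict"))
  }
  # heterozygous risk: resolve against the background haplotype
  n <- length(key)
  first3 <- seq_len(n - 1)
  alpha_letter_last <- grepl(rule$alpha[n], disc[n], fixed = TRUE)
  if (all(disc[first3] == a_hom[first3]) && alpha_letter_last)
    return(call("alpha/-"))
  bb_het <- mapply(het, rule$beta, rule$background)
  if (all(disc[first3] == bb_het[first3]) && disc[n] == hom(rule$beta[n]))
    return(call("beta/-"))
  call("unknown", "pattern conflict")
}

#' Classify all samples of a genotype matrix
#'
#' Looks up the rule-panel sites in a [genotype_matrix()], converts dosage
#' codes to allele-letter genotypes and classifies every sample. Classification
#' is independent of input site order (sites are matched by position).
#'
#' @param gm a [genotype_matrix()] containing the panel sites.
#' @param rule a [haplotype_rule()].
#' @param strata optional named character vector mapping sample -> stratum.
#' @return data.frame with `sample`, `diplotype`, `reason` and optional `stratum`.
#' @export
classify_samples <- function(gm, rule = haplotype_rule(), strata = NULL) {
  pos_all <- c(rule$positions, rule$risk_pos)
  idx <- match(pos_all, gm$sites$pos[gm$sites$chrom == rule$chrom])
  site_rows <- which(gm$sites$chrom == rule$chrom)[idx]
  if (is.na(idx[length(idx)])) stop_invalid("risk locus absent from genotype matrix")
  calls <- lapply(gm$samples, function(s) {
    g <- vapply(seq_along(pos_all), function(k) {
      r <- site_rows[k]
      if (is.na(r)) return(NA_character_)
      code <- gm$geno[match(s, gm$samples), r]
      if (is.na(code)) return(NA_character_)
      ref <- gm$sites$ref[r]; alt <- gm$sites$alt[r]
      c(hom(ref), het(ref, alt), hom(alt))[code + 1L]
    }, character(1))
    names(g) <- as.character(pos_all)
    classify_diplotype(g, rule)
  })
  out <- data.frame(
    sample = gm$samples,
    diplotype = vapply(calls, `[[`, character(1), "diplotype"),
    reason = vapply(calls, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
  if (!is.null(strata)) out$stratum <- unname(strata[out$sample])
  out
}

#' Founder-haplotype frequencies per stratum
#'
#' Fractions of alpha-bearing and beta-bearing calls among informative carrier
#' calls (calls of `none` and `unknown` are excluded; an `alpha/beta` double
#' carrier counts toward both haplotypes).
#'
#' @param calls data.frame with columns `diplotype` and optionally `stratum`.
#' @return data.frame with per-stratum `haplotype`, `count`, `n_carriers`,
#'   `pct` (exact) and `pct_display` (1 dp half-up).
#' @examples
#' calls <- data.frame(diplotype = c(rep("alpha/-", 19), rep("beta/-", 7)))
#' haplotype_frequencies(calls)
#' @export
haplotype_frequencies <- function(calls) {
  if (!"stratum" %in% names(calls)) calls$stratum <- "all"
  keep <- !(calls$diplotype %in% c("none", "unknown"))
  if (!any(keep)) {
    warning("no informative carrier calls")
    return(data.frame(stratum = character(), haplotype = character(),
                      count = integer(), n_carriers = integer(),
                      pct = numeric(), pct_display = numeric()))
  }
  calls <- calls[keep, , drop = FALSE]
  do.call(rbind, lapply(split(calls, calls$stratum), function(d) {
    n <- nrow(d)
    n_a <- sum(grepl("alpha", d$diplotype))
    n_b <- sum(grepl("beta", d$diplotype))
    data.frame(stratum = d$stratum[1], haplotype = c("alpha", "beta"),
               count = c(n_a, n_b), n_carriers = n,
               pct = c(n_a, n_b) / n * 100,
               pct_display = round_half_up(c(n_a, n_b) / n * 100, 1),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Published panel genotypes of the c.620A>T carrier series
#'
#' The discriminating-marker and risk-locus genotypes reported for the carrier
#' series: four c.620A>T homozygotes (two per founder haplotype), 26 compound
#' heterozygous c.620A>T/c.1807G>C patients (19 alpha, 7 beta) and 9 general
#' population heterozygous carriers (7 alpha, 2 beta). One row per individual,
#' genotypes as two-letter strings at the five panel positions.
#'
#' @return data.frame with `sample`, `stratum` (`"homozygote"`,
#'   `"compound_het"`, `"population"`) and one genotype column per panel site.
#' @export
carrier_reference_genotypes <- function() {
  row_block <- function(prefix, n, stratum, g) {
    df <- as.data.frame(matrix(rep(g, each = n), nrow = n), stringsAsFactors = FALSE)
    names(df) <- c("g36214971", "g36216426", "g36217798", "g36220134", "g36246117")
    cbind(data.frame(sample = paste0(prefix, seq_len(n)), stratum = stratum,
                     stringsAsFactors = FALSE), df)
  }
  rbind(
    row_block("Palpha", 2, "homozygote",   c("GG", "GG", "GG", "CC", "AA")),
    row_block("Pbeta",  2, "homozygote",   c("AA", "AA", "AA", "TT", "AA")),
    row_block("CHa",   19, "compound_het", c("GG", "GG", "GG", "CT", "AT")),
    row_block("CHb",    7, "compound_het", c("AG", "AG", "AG", "TT", "AT")),
    row_block("Ua",     7, "population",   c("GG", "GG", "GG", "CT", "AT")),
    row_block("Ub",     2, "population",   c("AG", "AG", "AG", "TT", "AT"))
  )
}

#' Classify the published carrier series
#'
#' Convenience wrapper running [classify_diplotype()] over
#' [carrier_reference_genotypes()].
#'
#' @param rule a [haplotype_rule()].
#' @return data.frame of calls with `sample`, `stratum`, `diplotype`, `reason`.
#' @export
classify_reference_carriers <- function(rule = haplotype_rule()) {
  ref <- carrier_reference_genotypes()
  pos <- as.character(c(rule$positions, rule$risk_pos))
  calls <- lapply(seq_len(nrow(ref)), function(i) {
    g <- as.character(ref[i, 3:7])
    names(g) <- pos
    classify_diplotype(g, rule)
  })
  data.frame(sample = ref$sample, stratum = ref$stratum,
             diplotype = vapply(calls, `[[`, character(1), "diplotype"),
             reason = vapply(calls, `[[`, character(1), "reason"),
             stringsAsFactors = FALSE)
}
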