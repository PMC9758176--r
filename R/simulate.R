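#' Simulation configuration for synthetic genotype panels
#'
#' Describes a synthetic biallelic SNP panel with optional planted founder
#' haplotypes. Background haplotypes are drawn site-wise independently
#' (linkage equilibrium) at per-site alt-allele frequencies; each founder is a
#' single fixed haplotype that carriers copy inside its planted span (and at
#' its named marker-pattern positions), truncated to fresh background outside.
#' Genotype errors and missingness are applied last, so planted alleles are
#' never altered except by the explicit error process. All randomness flows
#' from `seed`.
#'
#' @param seed integer seed recorded in all outputs.
#' @param chrom chromosome name.
#' @param region numeric `c(start, end)` in bp.
#' @param n_sites number of background marker sites (evenly spaced over the
#'   region unless `positions` is given).
#' @param positions optional explicit site positions (bp).
#' @param background_alt_freqs `NULL` (uniform on `[0.05, 0.95]`), a scalar, or
#'   a per-site vector of alt-allele frequencies.
#' @param site_alleles optional data.frame (`pos`, `ref`, `alt`) overriding the
#'   default `A`/`G` alleles at given positions.
#' @param founders list of founders, each
#'   `list(label =, pattern = named allele codes (position -> 0/1), span = c(start, end))`.
#' @param samples list of samples, each `list(id =, haps = c(spec, spec))`
#'   where a spec is a founder label or `"background"`.
#' @param error_rate,missing_rate per-genotype rates in `[0, 1)`.
#' @param overrides optional data.frame (`sample`, `pos`, `code`) of forced
#'   genotype codes applied after assembly (before the error process).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, chrom = "9", region = c(1e6, 3e6), n_sites = 400,
                       positions = NULL, background_alt_freqs = NULL,
                       site_alleles = NULL, founders = list(), samples = list(),
                       error_rate = 0, missing_rate = 0, overrides = NULL) {
  if (error_rate < 0 || error_rate >= 1 || missing_rate < 0 || missing_rate >= 1)
    stop_invalid("error/missing rates must lie in [0, 1)")
  for (f in founders) {
    if (!is.null(f$span) && (f$span[1] < region[1] || f$span[2] > region[2]))
      stop_invalid("planted span outside region for founder ", f$label)
    if (!is.null(f$pattern)) {
      p <- as.numeric(names(f$pattern))
      if (any(p < region[1] | p > region[2]))
        stop_invalid("pattern position outside region for founder ", f$label)
    }
  }
  structure(list(seed = as.integer(seed), chrom = chrom, region = region,
                 n_sites = n_sites, positions = positions,
                 background_alt_freqs = background_alt_freqs,
                 site_alleles = site_alleles, founders = founders,
                 samples = samples, error_rate = error_rate,
                 missing_rate = missing_rate, overrides = overrides),
            class = "sim_config")
}

#' Simulate a genotype panel with planted founder haplotypes
#'
#' Realizes a [sim_config()] into a [genotype_matrix()]. Deterministic given
#' the config seed; the seed and the planted truth (founder spans and sample
#' haplotype assignments) are attached as the `"truth"` attribute for oracle
#' comparison.
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()] with attribute `truth`.
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  pos <- cfg$positions
  if (is.null(pos)) pos <- round(seq(cfg$region[1], cfg$region[2], length.out = cfg$n_sites))
  extra <- unlist(lapply(cfg$founders, function(f)
    c(if (!is.null(f$pattern)) as.numeric(names(f$pattern)), f$span)))
  pos <- sort(unique(c(pos, extra)))
  n <- length(pos)

  freqs <- cfg$background_alt_freqs
  if (is.null(freqs)) freqs <- stats::runif(n, 0.05, 0.95)
  if (length(freqs) == 1) freqs <- rep(freqs, n)
  if (length(freqs) != n) stop_invalid("background_alt_freqs length mismatch")

  founder_vecs <- lapply(cfg$founders, function(f) {
    v <- stats::rbinom(n, 1, freqs)
    if (!is.null(f$pattern))
      v[match(as.numeric(names(f$pattern)), pos)] <- as.integer(f$pattern)
    v
  })
  names(founder_vecs) <- vapply(cfg$founders, `[[`, character(1), "label")
  founder_span <- lapply(cfg$founders, `[[`, "span")
  names(founder_span) <- names(founder_vecs)
  founder_pat_pos <- lapply(cfg$founders, function(f)
    if (is.null(f$pattern)) numeric(0) else as.numeric(names(f$pattern)))
  names(founder_pat_pos) <- names(founder_vecs)

  draw_hap <- function(spec) {
    bg <- stats::rbinom(n, 1, freqs)
    if (identical(spec, "background")) return(bg)
    if (!spec %in% names(founder_vecs)) stop_invalid("unknown haplotype spec: ", spec)
    keep <- rep(FALSE, n)
    sp <- founder_span[[spec]]
    if (!is.null(sp)) keep <- pos >= sp[1] & pos <= sp[2]
    keep[pos %in% founder_pat_pos[[spec]]] <- TRUE
    ifelse(keep, founder_vecs[[spec]], bg)
  }

  ids <- vapply(cfg$samples, `[[`, character(1), "id")
  geno <- t(vapply(cfg$samples, function(s) {
    draw_hap(s$haps[1]) + draw_hap(s$haps[2])
  }, integer(n)))

  if (!is.null(cfg$overrides)) {
    for (i in seq_len(nrow(cfg$overrides))) {
      r <- match(cfg$overrides$sample[i], ids)
      cidx <- match(cfg$overrides$pos[i], pos)
      if (is.na(r) || is.na(cidx)) stop_invalid("override references unknown sample/position")
      geno[r, cidx] <- as.integer(cfg$overrides$code[i])
    }
  }

  if (cfg$error_rate > 0) {
    err <- matrix(stats::rbinom(length(geno), 1, cfg$error_rate), nrow = nrow(geno)) == 1
    flips <- which(err)
    if (length(flips)) {
      cur <- geno[flips]
      up <- stats::rbinom(length(flips), 1, 0.5) == 1   # direction for hets
      geno[flips] <- ifelse(cur == 0L, 1L, ifelse(cur == 2L, 1L, ifelse(up, 2L, 0L)))
    }
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::rbinom(length(geno), 1, cfg$missing_rate), nrow = nrow(geno)) == 1
    geno[miss] <- NA_integer_
  }

  sites <- data.frame(chrom = cfg$chrom, pos = pos, ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  if (!is.null(cfg$site_alleles)) {
    m <- match(cfg$site_alleles$pos, pos)
    sites$ref[m] <- cfg$site_alleles$ref
    sites$alt[m] <- cfg$site_alleles$alt
  }
  gm <- genotype_matrix(ids, sites, geno)
  attr(gm, "truth") <- list(seed = cfg$seed,
                            founders = lapply(cfg$founders, function(f)
                              list(label = f$label, span = f$span)),
                            samples = lapply(cfg$samples, function(s)
                              list(id = s$id, haps = s$haps)))
  gm
}

# internal: guard-block overrides forcing opposite homozygotes just outside a
# planted span between one carrier pair, so the streak terminates at the span
guard_overrides <- function(pair, span, n_guard, guard_spacing) {
  gpos <- c(span[1] - guard_spacing * seq_len(n_guard),
            span[2] + guard_spacing * seq_len(n_guard))
  rbind(
    data.frame(sample = pair[1], pos = gpos, code = 0L, stringsAsFactors = FALSE),
    data.frame(sample = pair[2], pos = gpos, code = 2L, stringsAsFactors = FALSE)
  )
}

#' Simulate a sample pair sharing one planted IBD segment
#'
#' Two diploid samples each carry one copy of a shared founder haplotype over
#' `span`, on otherwise independent backgrounds. Short dense blocks of forced
#' opposite-homozygote guard markers immediately flank the span, so the
#' detectable streak terminates exactly at the planted boundaries (without
#' them, chance-compatible background markers would extend any streak by a
#' geometric tail). Genotype errors may corrupt guards like any other site.
#'
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @param region `c(start, end)` bp.
#' @param span planted segment `c(start, end)` bp, inside `region`.
#' @param spacing background marker spacing in bp.
#' @param background_freq alt-allele frequency of background sites.
#' @param error_rate,missing_rate per-genotype rates.
#' @param n_guard,guard_spacing guard-block size and spacing (bp).
#' @return list with `gm` (a [genotype_matrix()] of samples `S1`, `S2`) and
#'   `truth` (the planted span).
#' @export
simulate_ibd_pair <- function(seed, chrom = "9", region = c(35e6, 39e6),
                              span = c(36118198, 37898880), spacing = 5000,
                              background_freq = 0.5, error_rate = 0,
                              missing_rate = 0, n_guard = 6, guard_spacing = 200) {
  pos <- sort(unique(c(seq(region[1], region[2], by = spacing), span)))
  ov <- guard_overrides(c("S1", "S2"), span, n_guard, guard_spacing)
  pos <- sort(unique(c(pos, ov$pos)))
  cfg <- sim_config(seed, chrom = chrom, region = region, positions = pos,
                    background_alt_freqs = background_freq,
                    founders = list(list(label = "shared", span = span)),
                    samples = list(list(id = "S1", haps = c("shared", "background")),
                                   list(id = "S2", haps = c("shared", "background"))),
                    error_rate = error_rate, missing_rate = missing_rate,
                    overrides = ov)
  list(gm = simulate_genotypes(cfg), truth = list(span = span))
}

#' Simulate the two-founder homozygote quartet
#'
#' The synthetic counterpart of the founder-homozygote analysis: four samples
#' on chromosome 9, two (`P1`, `P2`) homozygous for founder haplotype alpha
#' with a planted shared segment at 36,118,198-37,898,880 (1780 kb) and two
#' (`P3`, `H1`) homozygous for founder beta with a planted segment at
#' 36,137,298-36,818,382 (680 kb). Both founders carry the risk allele and
#' their published discriminating-marker patterns, so the same panel exercises
#' the IBD detector and the haplotype classifier. Guard blocks flank each span
#' for its carrier pair.
#'
#' @param seed integer seed.
#' @param spacing background marker spacing in bp.
#' @param error_rate,missing_rate per-genotype rates.
#' @param rule a [haplotype_rule()] supplying panel positions and alleles.
#' @return list with `gm` (a [genotype_matrix()]) and `truth` (planted spans
#'   and carrier pairs).
#' @export
simulate_founder_quartet <- function(seed, spacing = 5000, error_rate = 0,
                                     missing_rate = 0, rule = haplotype_rule()) {
  region <- c(35.9e6, 38.1e6)
  span_a <- c(36118198, 37898880)
  span_b <- c(36137298, 36818382)
  panel_pos <- c(rule$positions, rule$risk_pos)
  panel_ref <- c(rule$background, rule$risk_ref)
  panel_alt <- c(ifelse(rule$alpha == rule$background, rule$beta, rule$alpha),
                 rule$risk_alt)
  code_of <- function(letters) as.integer(letters != panel_ref)
  alpha_pattern <- stats::setNames(code_of(c(rule$alpha, rule$risk_alt)), panel_pos)
  beta_pattern  <- stats::setNames(code_of(c(rule$beta, rule$risk_alt)), panel_pos)
  ov <- rbind(guard_overrides(c("P1", "P2"), span_a, 6, 200),
              guard_overrides(c("P3", "H1"), span_b, 6, 200))
  pos <- sort(unique(c(seq(region[1], region[2], by = spacing),
                       span_a, span_b, panel_pos, ov$pos)))
  cfg <- sim_config(seed, chrom = rule$chrom, region = region, positions = pos,
                    background_alt_freqs = 0.5,
                    site_alleles = data.frame(pos = panel_pos, ref = panel_ref,
                                              alt = panel_alt,
                                              stringsAsFactors = FALSE),
                    founders = list(
                      list(label = "alpha", pattern = alpha_pattern, span = span_a),
                      list(label = "beta",  pattern = beta_pattern,  span = span_b)),
                    samples = list(
                      list(id = "P1", haps = c("alpha", "alpha")),
                      list(id = "P2", haps = c("alpha", "alpha")),
                      list(id = "P3", haps = c("beta", "beta")),
                      list(id = "H1", haps = c("beta", "beta"))),
                    error_rate = error_rate, missing_rate = missing_rate,
                    overrides = ov)
  list(gm = simulate_genotypes(cfg),
       truth = list(span_alpha = span_a, span_beta = span_b,
                    pairs = list(alpha = c("P1", "P2"), beta = c("P3", "H1"))))
}

#' Simulate Hardy-Weinberg cohort genotype counts
#'
#' Draws genotype counts for `replicates` cohorts of `n_population` diploid
#' individuals with genotype probabilities `((1-q)^2, 2q(1-q), q^2)`.
#'
#' @param n_population cohort size (persons).
#' @param q alt-allele frequency in `[0, 1]`.
#' @param replicates number of replicate cohorts.
#' @param seed optional integer seed.
#' @return data.frame with `replicate`, `hom_ref`, `het`, `hom_alt`.
#' @export
simulate_cohort <- function(n_population, q, replicates = 1, seed = NULL) {
  if (q < 0 || q > 1) stop_invalid("q must lie in [0, 1]")
  if (n_population <= 0) stop_invalid("n_population must be positive")
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  draws <- stats::rmultinom(replicates, n_population, p)
  data.frame(replicate = seq_len(replicates),
             hom_ref = draws[1, ], het = draws[2, ], hom_alt = draws[3, ])
}

#' Simulate normally distributed group measurements
#'
#' Independent normal draws per group, e.g. onset ages per haplotype class.
#' The defaults are not set here: pass the group parameters observed in the
#' cohort being emulated (for the onset-age comparison these are mean 34.8,
#' sd 8.8, n 19 versus mean 36.7, sd 12.2, n 7).
#'
#' @param groups data.frame with columns `label`, `mean`, `sd`, `n`.
#' @param seed optional integer seed.
#' @return named list of numeric vectors, one per group.
#' @export
simulate_measurements <- function(groups, seed = NULL) {
  if (any(groups$sd < 0) || any(groups$n < 1))
    stop_invalid("group sd must be >= 0 and n >= 1")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nrow(groups)), function(i)
    stats::rnorm(groups$n[i], groups$mean[i], groups$sd[i]))
  stats::setNames(out, groups$label)
}
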