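panel_gt <- function(g1, g2, g3, g4, risk, rule = haplotype_rule()) {
  stats::setNames(c(g1, g2, g3, g4, risk),
                  as.character(c(rule$positions, rule$risk_pos)))
}

test_that("published diplotype patterns are classified as reported", {
  expect_equal(classify_diplotype(panel_gt("GG", "GG", "GG", "CC", "AA"))$diplotype,
               "alpha/alpha")
  expect_equal(classify_diplotype(panel_gt("AA", "AA", "AA", "TT", "AA"))$diplotype,
               "beta/beta")
  expect_equal(classify_diplotype(panel_gt("GG", "GG", "GG", "CT", "AT"))$diplotype,
               "alpha/-")
  expect_equal(classify_diplotype(panel_gt("AG", "AG", "AG", "TT", "AT"))$diplotype,
               "beta/-")
  ab <- classify_diplotype(panel_gt("AG", "AG", "AG", "CT", "AA"))
  expect_equal(ab$diplotype, "alpha/beta")
  conflict <- classify_diplotype(panel_gt("AG", "GG", "GG", "CT", "AT"))
  expect_equal(conflict$diplotype, "unknown")
  expect_equal(conflict$reason, "pattern conflict")
  expect_equal(classify_diplotype(panel_gt("GG", "GG", "GG", "TT", "TT"))$diplotype,
               "none")
})

test_that("missing inputs degrade as specified", {
  g <- panel_gt("GG", "GG", "GG", "CT", "AT")
  expect_error(classify_diplotype(g[1:4]), class = "founderhap_invalid_input")
  g_na <- g; g_na[2] <- NA
  call <- classify_diplotype(g_na)
  expect_equal(call$diplotype, "unknown")
  expect_equal(call$reason, "insufficient markers")
})

test_that("classification is invariant to genotype letter order and site order", {
  a <- classify_diplotype(panel_gt("GG", "GG", "GG", "TC", "TA"))
  expect_equal(a$diplotype, "alpha/-")
  g <- panel_gt("AG", "AG", "AG", "TT", "AT")
  expect_equal(classify_diplotype(g[c(5, 3, 1, 4, 2)])$diplotype, "beta/-")
})

test_that("every call is one of the seven labels and corruption of one site never swaps founders", {
  rule <- haplotype_rule()
  labels <- c("alpha/alpha", "beta/beta", "alpha/beta", "alpha/-", "beta/-",
              "none", "unknown")
  base <- list(
    panel_gt("GG", "GG", "GG", "CC", "AA"),
    panel_gt("AA", "AA", "AA", "TT", "AA"),
    panel_gt("AG", "AG", "AG", "CT", "AA"),
    panel_gt("GG", "GG", "GG", "CT", "AT"),
    panel_gt("AG", "AG", "AG", "TT", "AT")
  )
  gts_for_site <- function(i) {
    alleles <- unique(c(rule$alpha[i], rule$beta[i], rule$background[i]))
    unique(c(paste0(alleles, alleles),
             apply(utils::combn(alleles, 2), 2, function(p) het(p[1], p[2]))))
  }
  het <- function(a, b) paste(sort(c(a, b)), collapse = "")
  for (g in base) {
    orig <- classify_diplotype(g, rule)$diplotype
    other <- setdiff(c("alpha/alpha", "beta/beta", "alpha/beta", "alpha/-", "beta/-"),
                     orig)
    for (i in seq_along(rule$positions)) {
      for (repl in gts_for_site(i)) {
        gg <- g
        gg[i] <- repl
        got <- classify_diplotype(gg, rule)$diplotype
        expect_true(got %in% labels)
        # one corrupted discriminating site may only keep the call or void it
        expect_true(got %in% c(orig, "unknown"),
                    info = sprintf("base %s, site %d -> %s gave %s",
                                   orig, i, repl, got))
      }
    }
  }
})

test_that("synthesized founder carriers round-trip through the classifier without error", {
  rule <- haplotype_rule()
  panel_pos <- c(rule$positions, rule$risk_pos)
  pats <- list(
    alpha = stats::setNames(c(0, 0, 0, 1, 1), panel_pos),
    beta  = stats::setNames(c(1, 1, 1, 0, 1), panel_pos),
    bg    = stats::setNames(c(0, 0, 0, 0, 0), panel_pos)
  )
  n <- 1000
  samples <- lapply(seq_len(n), function(i)
    list(id = sprintf("s%04d", i),
         haps = c(if (i %% 2) "alpha" else "beta", "bg")))
  cfg <- sim_config(77, chrom = rule$chrom, region = c(36.2e6, 36.25e6),
                    positions = panel_pos,
                    site_alleles = data.frame(
                      pos = panel_pos,
                      ref = c(rule$background, rule$risk_ref),
                      alt = c("A", "A", "A", "C", rule$risk_alt)),
                    founders = list(list(label = "alpha", pattern = pats$alpha),
                                    list(label = "beta", pattern = pats$beta),
                                    list(label = "bg", pattern = pats$bg)),
                    samples = samples)
  gm <- simulate_genotypes(cfg)
  calls <- classify_samples(gm, rule)
  want <- ifelse(seq_len(n) %% 2 == 1, "alpha/-", "beta/-")
  expect_equal(calls$diplotype, want)
})

test_that("haplotype frequencies reproduce the carrier-series percentages", {
  calls <- data.frame(diplotype = c(rep("alpha/-", 19), rep("beta/-", 7)))
  f <- haplotype_frequencies(calls)
  expect_equal(f$pct_display[f$haplotype == "alpha"], 73.1)
  expect_equal(f$pct_display[f$haplotype == "beta"], 26.9)

  f2 <- haplotype_frequencies(data.frame(diplotype = c(rep("alpha/-", 7),
                                                       rep("beta/-", 2))))
  expect_equal(f2$pct_display, c(77.8, 22.2))

  f3 <- haplotype_frequencies(data.frame(diplotype = rep("alpha/-", 5)))
  expect_equal(f3$pct_display, c(100.0, 0.0))

  expect_warning(haplotype_frequencies(data.frame(diplotype = c("none", "unknown"))),
                 "no informative")
})

test_that("the full published carrier series reproduces the reported founder split", {
  calls <- classify_reference_carriers()
  expect_true(all(calls$reason == ""))
  f <- haplotype_frequencies(calls)
  get <- function(stratum, hap) f$pct_display[f$stratum == stratum & f$haplotype == hap]
  expect_equal(get("compound_het", "alpha"), 73.1)
  expect_equal(get("compound_het", "beta"), 26.9)
  expect_equal(get("population", "alpha"), 77.8)
  expect_equal(get("population", "beta"), 22.2)
  expect_equal(sort(calls$diplotype[calls$stratum == "homozygote"]),
               c("alpha/alpha", "alpha/alpha", "beta/beta", "beta/beta"))
})
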