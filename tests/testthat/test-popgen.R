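test_that("allele frequency, HWE expectation, detection rate and shares reproduce cohort arithmetic", {
  expect_equal(allele_frequency(22, 13686)$display, 0.00161)
  expect_equal(allele_frequency(0, 100)$display, 0)
  # 12/13686 = 0.000877 rounds to 0.00088 under half-up at 5 dp
  expect_equal(allele_frequency(12, 13686)$display, 0.00088)

  expect_equal(round_half_up(expected_homozygotes(0.00161, 91.8e6)), 238)
  expect_equal(round_half_up(expected_homozygotes(0.00089, 91.8e6)), 73)
  expect_equal(expected_homozygotes(0, 5e7), 0)

  expect_equal(detection_rate(3, 238)$display, 0.013)
  expect_equal(detection_rate(92, 73)$display, 1.260)
  expect_equal(detection_rate(0, 50)$display, 0)

  tab <- data.frame(variant_label = c("v1807", "v620"),
                    patient_alleles = c(318L, 185L),
                    homozygous_alleles = c(184L, 6L),
                    compound_het_alleles = c(134L, 179L))
  sh <- allele_shares(tab, 730)
  expect_equal(sh$share_pct_display, c(43.6, 25.3))
  expect_equal(sh$hom_rate_pct_display, c(57.9, 3.2))
  sh2 <- allele_shares(data.frame(variant_label = "v", patient_alleles = 10L,
                                  homozygous_alleles = 10L,
                                  compound_het_alleles = 0L), 10)
  expect_equal(sh2$share_pct_display, 100.0)
  expect_equal(sh2$hom_rate_pct_display, 100.0)
})

test_that("invalid popgen inputs are rejected", {
  expect_error(allele_frequency(1, 0), class = "founderhap_invalid_input")
  expect_error(expected_homozygotes(1.2, 1e6), class = "founderhap_invalid_input")
  expect_error(expected_homozygotes(0.1, 0), class = "founderhap_invalid_input")
  expect_error(detection_rate(3, 0), class = "founderhap_invalid_input")
  expect_error(compare_groups(1, c(2, 3)), class = "founderhap_invalid_input")
  bad <- data.frame(variant_label = "v", patient_alleles = 10L,
                    homozygous_alleles = 3L, compound_het_alleles = 7L)
  expect_error(allele_shares(bad, 100), class = "founderhap_invalid_input")
})

test_that("HWE expectation is monotone and quadratic in q; detection rate of itself is 1", {
  qs <- c(0.0005, 0.001, 0.01, 0.2, 0.9)
  e <- expected_homozygotes(qs, 1e6)
  expect_true(all(diff(e) > 0))
  expect_true(all(diff(expected_homozygotes(0.01, c(1e4, 1e5, 1e6))) > 0))
  expect_equal(expected_homozygotes(qs / 2, 1e6), e / 4)
  for (E in c(0.5, 7, 238)) expect_equal(detection_rate(E, E)$rate, 1)
})

test_that("allele shares of a closed table sum to 100 within rounding", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    alleles <- as.vector(stats::rmultinom(1, 500, runif(k) + 0.1))
    alleles <- pmax(alleles, 2L)
    hom <- vapply(alleles, function(a) 2L * sample.int(a %/% 2, 1), integer(1))
    tab <- data.frame(variant_label = paste0("v", seq_len(k)),
                      patient_alleles = alleles, homozygous_alleles = hom,
                      compound_het_alleles = alleles - hom)
    sh <- allele_shares(tab, sum(alleles))
    expect_equal(sum(sh$share_pct), 100, tolerance = 1e-12)
    expect_lte(abs(sum(sh$share_pct_display) - 100), 0.1 * k)
  }
})

test_that("simulated HWE cohorts recover the expected homozygote count", {
  # per-replicate P(count within 20% of N*q^2) is ~0.96 for Poisson(100), so
  # the 95% bound needs enough replicates to push Monte-Carlo noise below the
  # ~1% margin; 2000 replicates give a standard error of ~0.4%
  coh <- simulate_cohort(1e6, 0.01, replicates = 2000, seed = 11)
  ratio <- coh$hom_alt / (1e6 * 0.01^2)
  expect_gte(mean(ratio >= 0.8 & ratio <= 1.2), 0.95)
})

test_that("rank test agrees with the exhaustive permutation oracle on small groups", {
  set.seed(21)
  sizes <- list(c(4, 4), c(5, 4), c(3, 5), c(5, 5))
  for (s in sizes) for (rep in 1:5) {
    x <- rnorm(s[1]); y <- rnorm(s[2], mean = rep / 2)
    got <- compare_groups(x, y, method = "rank_test")$p_value
    expect_equal(got, perm_ranksum_p(x, y), tolerance = 1e-12)
  }
})

test_that("group comparisons behave at the null, under near-null parameters, and under large shifts", {
  x <- c(12, 15.5, 19, 22, 30, 41)
  expect_gt(compare_groups(x, x, method = "rank_test")$p_value, 0.9)
  expect_gt(compare_groups(x, x, method = "t_test")$p_value, 0.9)

  # onset-age parameters of the two founder-haplotype carrier groups: the
  # separation is far below one pooled SD, so rejections should stay near alpha
  set.seed(33)
  rej <- mean(vapply(1:1000, function(i) {
    m <- simulate_measurements(data.frame(label = c("A", "B"),
                                          mean = c(34.8, 36.7),
                                          sd = c(8.8, 12.2), n = c(19L, 7L)))
    compare_groups(m$A, m$B, method = "rank_test")$p_value < 0.05
  }, logical(1)))
  expect_lt(rej, 0.15)

  set.seed(34)
  a <- rnorm(20); b <- rnorm(20) + 5
  expect_lt(compare_groups(a, b, method = "rank_test")$p_value, 0.001)
  expect_lt(compare_groups(a, b, method = "t_test")$p_value, 0.001)
})

test_that("popgen_report assembles estimates and shares from a cohort table", {
  counts <- read_cohort_table(system.file("extdata", "cohort_counts.tsv",
                                          package = "founderhap"))
  rep <- popgen_report(counts, 91800000)
  est <- rep$estimates
  expect_equal(est$expected_display[est$variant_label == "c.620A>T"], 238)
  expect_equal(est$expected_display[est$variant_label == "c.1807G>C"], 73)
  expect_equal(est$rate_display, c(0.013, 1.260))
  # exact mode propagates the unrounded fraction instead of the printed one
  rep2 <- popgen_report(counts, 91800000, freq_mode = "exact")
  expect_equal(rep2$estimates$q, counts$alt_alleles / counts$total_alleles)
})
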