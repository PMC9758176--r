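#' Allele frequency from cohort allele counts
#'
#' Computes the variant allele frequency `alt / total` from chromosome-level
#' counts (for a diploid cohort, `total` is twice the number of genotyped
#' individuals). The raw fraction is kept at full precision; the display value
#' is rounded half-up to five decimal places, the precision at which population
#' screening frequencies are conventionally reported.
#'
#' @param alt_alleles non-negative integer count of variant alleles.
#' @param total_alleles positive integer count of all genotyped alleles.
#' @param variant_label optional label carried into the result.
#' @return list with `variant_label`, `alt_alleles`, `total_alleles`,
#'   `freq` (exact), `display` (numeric, 5 dp half-up) and `display_str`.
#' @examples
#' allele_frequency(22, 13686)$display   # 0.00161
#' @export
allele_frequency <- function(alt_alleles, total_alleles, variant_label = NA_character_) {
  if (length(total_alleles) != 1L || is.na(total_alleles) || total_alleles <= 0)
    stop_invalid("total_alleles must be a positive count")
  if (is.na(alt_alleles) || alt_alleles < 0 || alt_alleles > total_alleles)
    stop_invalid("alt_alleles must lie in [0, total_alleles]")
  freq <- alt_alleles / total_alleles
  list(
    variant_label = variant_label,
    alt_alleles   = as.integer(alt_alleles),
    total_alleles = as.integer(total_alleles),
    freq          = freq,
    display       = round_half_up(freq, 5),
    display_str   = fmt_fixed(freq, 5)
  )
}

#' Hardy-Weinberg expected homozygote count
#'
#' Under random mating an allele at frequency `q` is carried homozygously by a
#' fraction `q^2` of the population, so a population of `n_population` persons
#' is expected to contain `n_population * q^2` homozygotes. This is the
#' reference number against which the count of actually identified homozygous
#' patients is compared.
#'
#' @param q allele frequency in `[0, 1]`.
#' @param n_population positive population size (persons).
#' @return expected homozygote count (real, persons). Use
#'   `round_half_up(expected_homozygotes(q, N))` for the integer display value.
#' @examples
#' round_half_up(expected_homozygotes(0.00161, 91.8e6))  # 238
#' @export
expected_homozygotes <- function(q, n_population) {
  if (any(is.na(q)) || any(q < 0) || any(q > 1))
    stop_invalid("allele frequency q must lie in [0, 1]")
  if (any(is.na(n_population)) || any(n_population <= 0))
    stop_invalid("n_population must be positive")
  n_population * q^2
}

#' Homozygote detection rate
#'
#' Ratio of identified homozygous patients to the Hardy-Weinberg expected
#' homozygote count. Values far below 1 indicate that most homozygotes never
#' present as patients; values near or above 1 indicate near-complete (or
#' excess, e.g. through ascertainment) detection.
#'
#' @param observed non-negative integer count of identified homozygotes.
#' @param expected positive expected homozygote count.
#' @return list with `rate` (exact), `display` (3 dp half-up) and `display_str`.
#' @examples
#' detection_rate(3, 238)$display    # 0.013
#' detection_rate(92, 73)$display    # 1.260
#' @export
detection_rate <- function(observed, expected) {
  if (is.na(expected) || expected <= 0)
    stop_invalid("expected homozygote count must be positive")
  if (is.na(observed) || observed < 0)
    stop_invalid("observed count must be non-negative")
  rate <- observed / expected
  list(rate = rate, display = round_half_up(rate, 3), display_str = fmt_fixed(rate, 3))
}

#' Per-variant allele shares and homozygous rates in a patient cohort
#'
#' For each variant row the share of all patient alleles it accounts for, and
#' the homozygous rate by allele (alleles found in homozygotes divided by all
#' alleles of that variant). Counting is by allele, not by person: a homozygote
#' contributes two alleles to `homozygous_alleles`.
#'
#' @param table data.frame with columns `variant_label`, `patient_alleles`,
#'   `homozygous_alleles`, `compound_het_alleles`.
#' @param total_patient_alleles total allele count across the patient cohort
#'   (denominator of the share).
#' @return data.frame with exact and 1-dp half-up display columns
#'   `share_pct`, `hom_rate_pct` (display columns suffixed `_display`);
#'   `hom_rate_pct` is `NA` where a variant has zero patient alleles.
#' @examples
#' tab <- data.frame(variant_label = c("v1", "v2"),
#'                   patient_alleles = c(318L, 185L),
#'                   homozygous_alleles = c(184L, 6L),
#'                   compound_het_alleles = c(134L, 179L))
#' allele_shares(tab, 730)
#' @export
allele_shares <- function(table, total_patient_alleles) {
  req <- c("variant_label", "patient_alleles", "homozygous_alleles", "compound_het_alleles")
  if (!all(req %in% names(table)))
    stop_invalid("cohort table must have columns: ", paste(req, collapse = ", "))
  if (is.na(total_patient_alleles) || total_patient_alleles <= 0)
    stop_invalid("total_patient_alleles must be positive")
  with(table, {
    if (any(homozygous_alleles + compound_het_alleles != patient_alleles))
      stop_invalid("homozygous_alleles + compound_het_alleles must equal patient_alleles")
    if (any(homozygous_alleles %% 2 != 0))
      stop_invalid("homozygous_alleles must be even (two alleles per homozygote)")
  })
  if (sum(table$patient_alleles) > total_patient_alleles)
    stop_invalid("per-variant patient alleles exceed total_patient_alleles")
  share <- table$patient_alleles / total_patient_alleles * 100
  hom_rate <- ifelse(table$patient_alleles > 0,
                     table$homozygous_alleles / table$patient_alleles * 100, NA_real_)
  data.frame(
    variant_label        = table$variant_label,
    patient_alleles      = table$patient_alleles,
    homozygous_alleles   = table$homozygous_alleles,
    share_pct            = share,
    share_pct_display    = round_half_up(share, 1),
    hom_rate_pct         = hom_rate,
    hom_rate_pct_display = round_half_up(hom_rate, 1),
    stringsAsFactors = FALSE
  )
}

#' Full homozygote-deficit estimate for one variant
#'
#' Convenience wrapper combining [expected_homozygotes()] and
#' [detection_rate()]. Following the reporting convention of cohort screens,
#' the expectation is computed from the frequency as printed (rounded) and the
#' detection rate from the integer-rounded expectation; set
#' `use_rounded = FALSE` to propagate full precision instead.
#'
#' @param q allele frequency (typically the 5-dp display frequency).
#' @param n_population population size (persons).
#' @param observed identified homozygote count.
#' @param variant_label optional label.
#' @param use_rounded logical; if `TRUE` (default) the detection rate divides by
#'   the integer-rounded expectation.
#' @return one-row data.frame with `q`, `expected`, `expected_display`,
#'   `observed`, `rate`, `rate_display`.
#' @export
homozygote_estimate <- function(q, n_population, observed,
                                variant_label = NA_character_, use_rounded = TRUE) {
  expected <- expected_homozygotes(q, n_population)
  expected_display <- round_half_up(expected, 0)
  denom <- if (use_rounded) expected_display else expected
  dr <- detection_rate(observed, denom)
  data.frame(
    variant_label = variant_label, q = q,
    n_population = n_population,
    expected = expected, expected_display = expected_display,
    observed = as.integer(observed),
    rate = dr$rate, rate_display = dr$display,
    stringsAsFactors = FALSE
  )
}

#' Two-group comparison of measurement sets
#'
#' Compares two independent groups of measurements (e.g. ages at disease onset
#' across haplotype classes, or sialylation levels across genotype groups) with
#' either the unpaired Wilcoxon rank-sum test or Student's t-test, two-sided.
#' A paired variant of the rank test is available for matched designs.
#'
#' @param a,b numeric vectors, each of length >= 2 (equal lengths if `paired`).
#' @param method `"rank_test"` (Wilcoxon) or `"t_test"`.
#' @param paired logical; paired signed-rank / paired t variant.
#' @return list with `statistic`, `p_value`, `method`, `paired`.
#' @examples
#' compare_groups(rnorm(10), rnorm(10) + 5)$p_value
#' @export
compare_groups <- function(a, b, method = c("rank_test", "t_test"), paired = FALSE) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop_invalid("each group needs at least 2 values")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop_invalid("measurement values must be finite")
  ht <- if (method == "rank_test") {
    suppressWarnings(stats::wilcox.test(a, b, paired = paired, alternative = "two.sided"))
  } else {
    stats::t.test(a, b, paired = paired, alternative = "two.sided")
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = method, paired = paired)
}

#' Read a cohort count table
#'
#' Tab-separated with header; expected columns `variant_label`,
#' `patient_alleles`, `homozygous_alleles`, `compound_het_alleles` and
#' optionally `alt_alleles`, `total_alleles`, `observed_homozygotes`,
#' `printed_freq`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop_invalid("cohort table not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read measurement sets from a two-column TSV (group, value)
#'
#' @param path file path.
#' @return named list of numeric vectors, one per group label.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop_invalid("measurement file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("group", "value") %in% names(df)))
    stop_invalid("measurement file needs columns: group, value")
  split(as.numeric(df$value), df$group)
}

#' Cohort homozygote-deficit report
#'
#' Runs the full population-genetics summary over a cohort count table:
#' allele frequencies, expected homozygotes at the given population size,
#' detection rates, allele shares and homozygous rates.
#'
#' @param counts data.frame as from [read_cohort_table()]; rows are variants.
#' @param n_population population size for the Hardy-Weinberg expectation.
#' @param total_patient_alleles denominator for allele shares (defaults to the
#'   `total_patient_alleles` attribute or the per-table maximum supplied in a
#'   `total_patient_alleles` column).
#' @param freq_mode `"printed"` uses the `printed_freq` column where present
#'   (falling back to the 5-dp display frequency), `"display"` always rounds the
#'   exact fraction to 5 dp, `"exact"` uses the raw fraction.
#' @return list with `estimates` (data.frame) and `shares` (data.frame).
#' @export
popgen_report <- function(counts, n_population,
                          total_patient_alleles = NULL,
                          freq_mode = c("printed", "display", "exact")) {
  freq_mode <- match.arg(freq_mode)
  if (is.null(total_patient_alleles)) {
    if (!"total_patient_alleles" %in% names(counts))
      stop_invalid("total_patient_alleles must be given or present as a column")
    total_patient_alleles <- counts$total_patient_alleles[1]
  }
  est <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    row <- counts[i, ]
    af <- allele_frequency(row$alt_alleles, row$total_alleles, row$variant_label)
    q <- switch(freq_mode,
      printed = if (!is.null(row$printed_freq) && !is.na(row$printed_freq))
                  row$printed_freq else af$display,
      display = af$display,
      exact   = af$freq)
    he <- homozygote_estimate(q, n_population, row$observed_homozygotes,
                              variant_label = row$variant_label,
                              use_rounded = freq_mode != "exact")
    cbind(data.frame(freq = af$freq, freq_display = af$display), he)
  }))
  shares <- allele_shares(counts, total_patient_alleles)
  list(estimates = est, shares = shares)
}
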