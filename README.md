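# founderhap

Analysis toolkit for recessive founder variants that show a **homozygote
deficit** — alleles common enough that many homozygotes must exist, yet
almost none present as patients, while compound heterozygotes carrying the
same allele do. The motivating case is the *GNE* missense variant c.620A>T
(p.D207V) behind a distal myopathy caused by defective sialic-acid
biosynthesis.

The package implements the full computational chain as reusable, tested
functions, plus a seeded synthetic-genotype generator so every stage runs
without access to restricted patient genomes:

| stage | what it computes |
|---|---|
| `popgen` | allele frequencies, Hardy-Weinberg expected homozygotes `N·q²`, detection rates (observed/expected), per-variant allele shares, rank/t group comparisons |
| `ibdstreak` | identity-by-descent segments between carrier pairs as maximal *SNP streaks* — runs of consecutive unphased genotypes free of opposite-homozygote conflicts — with multiway intersection across carrier groups |
| `haplotyper` | rule-based assignment of risk chromosomes to founder haplotypes alpha/beta from a four-SNP discriminating panel, and per-stratum haplotype frequencies |
| `fluxmodel` | interval-valued multiplicative route scores for ManNAc 6-phosphate production in the enzyme dimer (each route = source epimerase × transfer × destination kinase, summed over the four routes) |
| `synthdata` | seeded genotype panels with planted founder haplotypes, IBD segments and guard markers; HWE cohort draws; normal group measurements |

## Worked example

```r
library(founderhap)

# Hardy-Weinberg expectation and detection rate: 22/13,686 alleles, 91.8 M persons
af <- allele_frequency(22, 13686)
af$display
#> [1] 0.00161
round_half_up(expected_homozygotes(af$display, 91.8e6))
#> [1] 238
detection_rate(3, 238)$display
#> [1] 0.013

# simulate the four founder homozygotes with planted IBD segments, then map them
q <- simulate_founder_quartet(seed = 1)
seg <- multiway_shared_segments(q$gm, c("P1", "P2"), streak_params(0, 100, 1e5))
seg[, c("start", "end", "n_markers")]
#>      start      end n_markers
#> 1 36118198 37898880       377
segment_span_kb(segment = seg)
#> [1] 1780

# classify the published carrier panel and tabulate founder frequencies
f <- haplotype_frequencies(classify_reference_carriers())
f[f$stratum == "compound_het", c("haplotype", "count", "pct_display")]
#>   haplotype count pct_display
#> 1     alpha    19        73.1
#> 2      beta     7        26.9

# dimer route-flux prediction: mild homodimer vs severe compound heterodimer
dimer_production(dimer_flux_model("D207V", "D207V"))$total
#> [1] 1.6 2.0
dimer_production(dimer_flux_model("D207V", "catalytic"))$total
#> [1] 0.57 0.61
```

Only 3 of an expected 238 c.620A>T homozygotes present as patients
(detection rate 0.013), the four known homozygotes split onto two distinct
founder segments (1780 kb and 680 kb), and the flux model predicts the
homodimer retains 40–50% of wild-type production capacity while the
compound heterodimer with a catalytic variant drops to ~15% — a consistent
mechanistic account of the homozygote deficit.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the study
end-to-end on synthetic data and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # quartet VCF with planted founder segments
Rscript analysis/02_ibd.R        # SNP-streak mapping: 1780 kb + 680 kb segments
Rscript analysis/03_classify.R   # founder-haplotype calls and frequencies
Rscript analysis/04_popgen.R     # homozygote-deficit statistics
Rscript analysis/05_flux.R       # dimer route-flux grid
```

`run_pipeline()` performs the same chain from a single YAML config (see
`inst/extdata/demo_config.yaml`).

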