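---
title: "Methods: founder-haplotype mapping and the homozygote deficit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: founder-haplotype mapping and the homozygote deficit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderhap)
```

## The scientific problem

Some recessive disease alleles show a striking *homozygote deficit*: the
allele is common enough that many homozygotes must exist in the population,
yet almost none present as patients, while compound heterozygotes carrying
the same allele regularly do. The motivating case is a missense variant
(p.D207V, cDNA c.620A>T) in *GNE*, the bifunctional UDP-GlcNAc
2-epimerase/ManNAc kinase that commits the sialic-acid biosynthesis pathway.
`founderhap` implements the computational chain needed to characterize such a
variant:

1. **popgen** — how many homozygotes does Hardy-Weinberg predict, and what
   fraction of them surface as patients?
2. **ibdstreak** — do the few observed homozygotes descend from a common
   ancestor? Identity-by-descent (IBD) segments shared between carriers are
   mapped as *SNP streaks* on unphased genotypes.
3. **haplotyper** — which founder haplotype does each carrier chromosome
   ride on, classified from a small discriminating tag-SNP panel?
4. **fluxmodel** — a mechanistic toy model of why the homozygote is mild:
   multiplicative route scores for ManNAc 6-phosphate production in the
   enzyme dimer, with interval arithmetic for uncertain scores.
5. **synthdata** — a seeded generator producing genotype panels with planted
   founder haplotypes and IBD segments, HWE cohorts, and group measurements,
   so every stage runs and is testable without the restricted patient
   genomes.

## Hardy-Weinberg expectations and the detection rate

For an allele at frequency $q$ in a randomly mating population of $N$
persons, the expected homozygote count is $N q^2$. The *detection rate* is
the ratio of identified homozygous patients to that expectation; values far
below one mean homozygotes exist but rarely present clinically.

Numeric conventions, chosen to reproduce printed cohort summaries
deterministically:

* **Half-up decimal rounding** (`round_half_up()`) at the precision each
  quantity is conventionally printed with: frequencies 5 dp, percentages
  1 dp, rates 3 dp. Base R's round-half-even would print 0.5-boundary cases
  differently.
* **Printed-frequency mode.** `popgen_report()` computes the expectation
  from the frequency *as printed* by default and divides the observed count
  by the integer-rounded expectation (`freq_mode = "printed"`,
  `use_rounded = TRUE`), because that is how such tables are assembled;
  `freq_mode = "exact"` propagates full precision instead. The bundled count
  table carries one frequency (0.00089 for 12/13,686) whose final digit
  cannot be recovered from the raw fraction under any standard rounding
  (12/13,686 = 0.000877); it is therefore treated as an *input*, and the
  package's own display rounding of the fraction gives 0.00088.
* The default population size, 91.8 million, is the national population
  above the cohort's mean onset age; it is an explicit argument everywhere.
* **Allele counting.** "Homozygous rate by allele" counts both alleles of a
  homozygote: 92 homozygous patients contribute 184 of 318 alleles (57.9%).

Group comparisons (`compare_groups()`) default to the *unpaired* Wilcoxon
rank-sum test: the groups compared (onset ages across haplotype or genotype
classes) are unrelated individuals, so a matched-pairs signed-rank test is
not applicable; the paired form is exposed behind `paired = TRUE` for
matched designs. The test suite checks the rank test against an exhaustive
permutation enumeration on small groups.

## SNP-streak IBD mapping

On unphased diploid genotypes, two samples sharing one haplotype copy can
show any genotype combination at a site *except* opposite homozygotes.
A streak is a maximal run of consecutive markers free of opposite-homozygote
conflicts:

* `max_mismatches` incompatible sites are tolerated per streak (default 0);
  the windows reported cannot be extended in either direction without
  exceeding the budget, and each is trimmed so both boundary markers are
  informative and compatible.
* Missing genotypes are neutral: they never terminate a streak and never
  count toward `n_markers`. A streak can therefore bridge no-call gaps, but
  its evidence is measured in observed compatible markers only.
* When mismatch budgets make maximal windows overlap, a greedy
  non-overlapping selection keeps windows with more informative markers
  first (ties to the leftmost); the brute-force oracle in the tests applies
  the same definition by exhaustive enumeration.
* Defaults `min_markers = 100`, `min_span_bp = 1e5` suppress chance streaks:
  between unrelated samples at 50% allele frequency the per-site
  compatibility probability is $1 - 2 p^2 q^2 = 0.875$, so runs of
  100 informative markers essentially never occur by chance.
* Coordinates are 1-based inclusive internally (VCF convention); BED export
  converts to 0-based half-open. Spans are quoted in kb rounded half-up at
  the 10-kb level, matching how founder segments are conventionally cited.

`multiway_shared_segments()` intersects pairwise streaks over all pairs of a
carrier group, which is how the two founder segments (1780 kb shared by the
alpha pair, 680 kb by the beta pair, nothing by all four) are mapped.

## Founder-haplotype classification

The rule panel (`haplotype_rule()`) encodes the published discrimination
table: four tag SNPs with alleles `G,G,G,C` on founder alpha, `A,A,A,T` on
founder beta, and `G,G,G,T` on non-risk background chromosomes, plus the
risk locus (reference `T`, risk allele `A` on the genomic plus strand).
Design choices:

* **Unphased carrier resolution** leans on the background haplotype: a
  heterozygous carrier whose tag sites read `GG,GG,GG,CT` can only be
  alpha-over-background, and `AG,AG,AG,TT` only beta-over-background. This
  is the unique configuration consistent with the published heterozygote
  rows.
* **Conflicts are never forced.** Any panel configuration outside the
  enumerated patterns yields `unknown` with a reason (`pattern conflict`,
  `insufficient markers`). Because alpha and beta differ at *every*
  discriminating site, corrupting a single site can only void a call, never
  flip alpha to beta — the tests verify this exhaustively over all
  single-site corruptions.
* The alpha/beta double carrier (risk homozygote with fully heterozygous
  tags) is allowed as `alpha/beta`, a logically forced extension never
  observed in the published series.

`carrier_reference_genotypes()` ships the published panel of 39 carriers
(4 homozygotes, 26 compound heterozygotes, 9 population carriers) so the
frequency summary (73.1%/26.9% and 77.8%/22.2%) is recomputed from genotype
patterns, not hard-coded.

## The dimer route-flux model

ManNAc 6-phosphate production by the enzyme dimer is scored as the sum of
four routes; each route multiplies the source monomer's epimerase score, a
transfer score (intramolecular within one monomer, or intermonomer), and the
destination monomer's kinase score. Presets: wild type scores 1 everywhere
(total 4); D207V halves intramolecular transfer (0.5) and renders
intermonomer transfer variable (0.3–0.5) through partial oligomerization
failure; catalytic-site variants and V603L score 0.1 and 0.2 on both
enzymatic reactions, transfer intact.

* Ranged scores propagate by **interval arithmetic** (endpoint-wise products
  and sums, valid because all scores are non-negative), never collapsed to
  midpoints; Monte-Carlo sampling within component intervals always lands
  inside the computed totals.
* Intermonomer impairment is a *dimer-level* property triggered by at least
  one D207V monomer, with an explicit override. D207V's epimerase score is 1
  as modeled — the 18% in vitro epimerase activity reported for the
  corresponding short-isoform mutant is available as the non-default
  `D207V_invitro` preset.
* Totals are reported absolute (WT = 4) and relative (WT = 1), since a
  per-route "score 1" convention and a normalized-total reading are both
  defensible; both are emitted so either is inspectable.

The model's key qualitative output — the D207V homodimer (1.6–2.0) sits far
above the D207V/catalytic heterodimer (0.57–0.61) — mirrors the clinical
asymmetry between mild homozygotes and affected compound heterozygotes.

## What the generator emulates — and what it does not

`simulate_genotypes()` draws background haplotypes site-wise independently
(linkage equilibrium) at configurable alt-allele frequencies, copies each
founder's fixed haplotype inside its planted span (and its tag-SNP pattern at
panel positions), assembles diploids from two haplotype specs, and applies a
symmetric single-step genotype error (0↔1↔2) and missingness last. All
randomness flows from one seed; the same seed yields byte-identical VCF.

Two deliberate simplifications matter for interpreting test results:

* **No linkage disequilibrium and no recombination model.** Planted founder
  segments are truncated deterministically at configured endpoints rather
  than through simulated meioses. This keeps every planted boundary exactly
  known, which the boundary-recovery tests require.
* **Guard blocks.** Outside a planted span, background genotypes are
  *chance*-compatible with probability ~0.875 per site, so a streak would
  overrun a planted boundary by a geometric tail of markers (mean ~7 at 50%
  frequency, i.e. tens of kb at realistic density). Exact boundary recovery
  is therefore only a well-posed expectation when the flanking markers are
  forced incompatible; `simulate_ibd_pair()` and `simulate_founder_quartet()`
  plant short dense blocks of opposite-homozygote guard markers just outside
  each span end (six sites at 200 bp spacing, sized to exceed any mismatch
  budget used in testing). Real data offer no such guarantee: on real
  genotypes, reported boundaries are first/last-conflict boundaries and carry
  the corresponding uncertainty.

Passing the planted-recovery tests therefore shows the detector is correct
*given* conflict-delimited segments, not that real founder boundaries are
recoverable to the base pair.

Problem sizes used by the test-suite and analysis drivers — a ~2.2 Mb region
at 5 kb marker spacing (~470 sites) for the quartet, 3 Mb at 4 kb spacing for
error-rate replicates, 150–200-site panels for the brute-force oracle grid,
10^6-person cohorts for HWE recovery, and 1000-draw Monte-Carlo checks — were
chosen so each property is measured well clear of its noise floor while the
whole suite stays quick to run.

## Known limitations

* The streak compatibility rule is the standard unphased IBD1 relaxation
  ("not opposite homozygotes"); it cannot distinguish IBD from long
  stretches of identity by state in regions of low diversity, and no
  probabilistic (HMM) scoring or LD modeling is attempted.
* Detection-rate estimates inherit whatever ascertainment biases produced
  the observed patient counts; a rate above 1 (as for the comparison
  variant) signals exactly such a bias, not super-complete detection.
* The flux model is a scoring heuristic, not kinetics: no ODEs, no
  tetramer/hexamer route graphs, and no fitting of scores to sialylation
  measurements.
* The cohort table's person-versus-allele bookkeeping follows the published
  convention; tables whose counts violate it (odd homozygous-allele counts,
  shares exceeding the total) are rejected rather than repaired.
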