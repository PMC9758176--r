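Package: founderhap
Title: Founder-Haplotype and Homozygote-Deficit Analysis for a Recessive Myopathy Variant
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studying founder variants that show a deficit of
    affected homozygotes. Implements Hardy-Weinberg homozygote expectations and
    detection-rate estimation from cohort allele counts, identity-by-descent (IBD)
    segment mapping on unphased genotypes by the SNP-streak approach, rule-based
    classification of risk haplotypes from a discriminating tag-SNP panel, and a
    multiplicative route-flux score for a dimeric bifunctional enzyme with interval
    arithmetic for ranged component scores. A seeded synthetic-genotype generator
    with planted founder haplotypes and IBD segments lets every stage of the
    pipeline run without access to restricted patient genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
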