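Package: assocpower
Title: Power of Single-SNP Score Tests with Multiple Causal Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analytical and simulation-based power analysis for
    covariate-adjusted single-SNP (and collapsed rare-variant) score tests
    of quantitative-trait association when the trait is driven by multiple
    causal variants. The noncentrality parameter of the 1-df score test is
    decomposed into per-causal-SNP contributions r*h (adjusted genotype
    correlation times direct effect), which quantifies the "hyper-LD"
    effect: power at a test SNP arising from many weak, possibly long-range
    or purely chance, correlations with causal SNPs. Includes genotype,
    covariate and replicate-trait simulators, Hardy-Weinberg equilibrium
    filtering, genome-scale adjusted-correlation scans with distance
    exclusion, and a matched linkage-equilibrium null comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
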