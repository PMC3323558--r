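Package: apmlink
Title: Affected Pedigree Member Linkage Analysis with Gene-Dropping Nulls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric genome-wide linkage analysis of familial
    exceptional longevity in extended pedigrees.  Implements excess
    longevity (EL) and kinship-weighted familial excess longevity (FEL)
    phenotyping, affected-relative-pair enumeration from recursive kinship
    coefficients, the simplified affected-pedigree-member (APM)
    identity-by-state sharing statistic with allele-frequency weights, a
    Mendelian gene-dropping Monte Carlo null (unlinked markers and linked
    chromosomes under Haldane recombination), singlepoint and multipoint
    scans with a 1-cM interpolation grid, genome-wide empirical p-value
    adjustment, cross-study Z-score meta-analysis, and a synthetic-data
    generator for multigenerational pedigrees, microsatellite panels and
    Gompertz lifespans with a carrier hazard-ratio effect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
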