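Package: pgxposure
Title: Pharmacogenetic Drug Exposure and Actionable-Genotype Burden Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Translates population genotype data into predicted drug-response
    phenotypes using star-allele definitions and DPWG-style
    diplotype-to-phenotype rules, then combines predicted phenotype
    frequencies with drug-utilization tables to estimate risky exposures
    (exposures of actionable-genotype carriers to pharmacogenetic drugs),
    per-gene shares of those exposures, preemptive panel coverage, and
    demographic stratification of drug use. Includes a reference catalog of
    14 pharmacogenes and haplo-groups transcribed at printed precision, a
    Hardy-Weinberg cohort simulator for end-to-end testing without private
    cohort data, VCF input/output for cohort genotypes, allele-frequency
    estimation and two-cohort comparison tests, and a reproducible pipeline
    runner that emits the full set of report tables with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
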