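---
title: "Methods: from population genotypes to risky drug exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from population genotypes to risky drug exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxposure)
```

## The question the package answers

Many commonly prescribed drugs are *pharmacogenetic* (PGX) drugs: their
efficacy or toxicity depends on the patient's genotype at one or a few
pharmacogenes, and clinical guidelines (DPWG-style) define *actionable*
genotypes for which a dose change or an alternative drug is recommended.
Given (i) allele frequencies of the guideline variants in a population and
(ii) drug-utilization statistics for that population, one can estimate how
many drug exposures land on patients who carry an actionable genotype —
the *risky exposures* — and therefore which small panel of genes a
preemptive genotyping program should target.

The estimate for one drug–gene row is deliberately simple:

> risky exposures = (fraction of the population with an actionable
> phenotype for the gene) x (exposures of all patients to the drug),

where an *exposure* is one user of one drug over the study window
(repeat prescriptions of the same drug by the same user count once), and
the user base is first reduced to the ancestry stratum the genotype
reference describes (85% by default). Everything else in the package
exists to produce, check and stratify the two factors of that product.

## Data model

* **Catalog** (`load_catalog()`): for each of 14 genes/haplo-groups, the
  star-allele definitions (defining variants, risk alleles, functional
  status, haplotype frequency), a diplotype-to-phenotype rule table, and
  the drug–gene interaction map with per-interaction actionable phenotype
  sets. Everything is plain TSV and re-validated on load; validation
  reports *all* violations, not the first.
* **Cohort** (`pgx_cohort`): a samples x variants risk-allele dosage
  matrix keyed by rsID (never by genomic position, so no genome build is
  assumed), per-haplotype matrices for phased variants, and a per-gene
  copy-number side channel fed by a sidecar TSV rather than VCF CNV
  records.
* **Utilization tables**: per-drug issuance with therapeutic areas, the
  per-gene exposure table, and users stratified by year, sex and seven
  age bands.

## Phenotype conventions

The catalog encodes one rule table per gene because the guideline
conventions genuinely differ between genes:

* **CYP2C9, CYP2B6, SLCO1B1, DPYD, TPMT**: any single reduced-function
  allele makes an intermediate; two make a poor
  metabolizer/transporter. This reproduces the published predicted
  phenotype frequencies from the published allele frequencies under
  Hardy–Weinberg equilibrium (CYP2C9: 0.64/0.32/0.04 against the
  published 0.649/0.309/0.042).
* **CYP2D6** uses the activity-score convention: a decreased allele next
  to a functional one still scores as a normal metabolizer (score 1.5);
  intermediates are scores 0.5–1; poor is 0. This is the only convention
  consistent with the published actionable fraction for the gene:
  I+P+U = 0.401 printed, and the closed form gives 0.408 under this rule
  versus 0.518 if heterozygous decreased alleles were intermediate.
* **CYP2C19**: the increased-activity promoter allele only yields an
  ultrarapid phenotype when homozygous; heterozygotes fold into normal
  (rapid) metabolizers, and a null allele in trans makes an
  intermediate. Again this is the only reading consistent with the
  published phenotype table (U = 0.066 printed; the closed form gives
  0.053 for homozygotes versus 0.343 if heterozygotes were ultrarapid).
* **CYP3A5** is an expresser gene: the majority allele is non-functional,
  so the *reference* allele of the gene model is inactive and the
  actionable categories for its substrate drug are the expressers (N+I).
* **Carrier genes** (factor V Leiden, the four HLA tag haplo-groups) use
  non-carrier/Het/Hom, with carriers (Het+Hom) actionable. The
  anticoagulant-sensitivity gene VKORC1 is genotype-coded (GG/GA/AA to
  N/I/P) with only the homozygous-sensitive category actionable.

### Nested haplotype frequencies

Published per-variant minor allele frequencies are marginals, not
haplotype frequencies. The CYP2D6 inactive allele carries both its own
SNP and the decreased allele's SNP, so the decreased haplotype's own
frequency is 0.23 − 0.21 = 0.02; similarly the TPMT double-variant
haplotype (frequency 0.021) leaves 0.017 and 0.063 for the two
single-variant haplotypes. The allele fixture stores haplotype
frequencies; tests verify that the marginals reproduce the published
per-SNP values exactly.

### CYP2D6 duplication fraction

Copy number is not inferable from a dosage matrix, so the simulator
assigns a third gene copy with probability 0.0327, chosen once so that
P(ultrarapid) = P(functional diplotype) x dup = 0.612 x 0.0327 = 0.02,
the published ultrarapid frequency (itself taken by the source study from
an external database for the same reason). Duplication of an inactive
diplotype does not create an ultrarapid phenotype.

## Star-allele calling

On phased data the caller is exact: each haplotype's set of observed risk
alleles must equal a catalog allele's defining set (the empty set is the
reference allele); anything else is a no-call. On unphased data every
allele pair consistent with the dosages is enumerated and a fixed
precedence picks one: fewest distinct non-reference alleles, then lowest
combined functional activity (conservative: ambiguity resolves toward
flagging carriers), then lexicographic order. Two-SNP haplotype tags
require both SNPs; unbalanced dosages across a tag (2 and 0, or 2 and 1)
are unexplainable and yield a no-call. Missing genotypes at any defining
variant propagate to a no-call — no imputation. At the catalog's allele
frequencies, ambiguity is rare: the only structurally ambiguous pattern
is the TPMT trans/cis configuration of its two SNPs (probability about
0.2% under HWE), which the precedence rule resolves to the cis
double-variant haplotype and flags `resolved-unphased`.

## Exposure arithmetic and its documented anomalies

All reported counts use round-half-away-from-zero. Under that rule three
published risky-exposure rows (TPMT, CYP2C9, the HLA-B\*57:01 row)
reproduce exactly from the printed factors; the factor V Leiden row
prints one more than the product (92,226 vs 92,225.484), which the
acceptance suite pins as a discrepancy rather than reproducing. The
published grand total of risky exposures (12,380,754) differs from the
sum of the published column (12,456,611); `exposure_report()` computes
both and uses the computed sum as the share denominator unless
`use_fixture_total = TRUE`.

Two published actionable percentages are not derivable from the published
phenotype table at all: the carbamazepine HLA row (38.54%, versus about
8% of carriers of either tag haplotype) and the CYP2C19 row (9.88%
labelled I+P+U, versus 32.5% from the phenotype table — plausibly only
P+U was intended). The catalog stores the printed values verbatim, and a
regression test asserts that cohort-derived fractions *remain* discrepant
with them, so the inconsistency cannot silently disappear. Two further
sub-0.1-point rounding slips in the source (the psychiatry/neurology
class share and the combined women's share) are asserted at their
recomputed values.

## Allele-frequency comparison test

The two-cohort comparison is a two-proportion chi-square on allele counts
(2n chromosomes per cohort) without continuity correction, falling back
to Fisher's exact test when a count is zero; the comparison cohort
defaults to 349 individuals. The source study does not name its test, and
several of its printed p-values cannot be reproduced from any standard
two-proportion test at the printed frequencies (e.g. about 0.39
recomputed versus 0.43 printed for one CYP2D6 variant), so printed
p-values are carried as reference metadata only and never asserted. The
chosen test's calibration is what the suite checks: type-I error 0.05 ±
0.02 and approximately uniform null p-values over 2,000 replicates.

## What the simulator does and does not emulate

`simulate_cohort()` draws two haplotypes per individual per gene from the
star-allele frequency vector, independently across genes — Hardy–Weinberg
equilibrium and linkage equilibrium between genes by construction, with
within-gene allele exclusivity and multi-SNP haplotypes consistent by
design. It does **not** emulate: linkage disequilibrium beyond
defining-variant nesting, trio/family structure, genotyping error, or
departures from HWE present in real cohorts. The published phenotype
table shows exactly such departures for some genes (the HLA haplo-groups
and VKORC1 deviate a few percent from the HWE closed form at the
published allele frequencies), so passing simulation-based tests
demonstrates internal consistency of the pipeline, not that a real cohort
would reproduce the published table — the individual-level source data
are not public, and the package does not pretend otherwise.

## Numerical choices and problem sizes

* Rounding of counts: half away from zero (`round_half_away()`); shares
  reported unrounded and rounded only for display.
* HWE triple closes to 1 exactly (the homozygote-alt term is computed as
  the complement).
* Ties in unphased calling are broken deterministically (see above);
  degenerate inputs (all-missing columns, empty catalogs, zero users)
  are hard errors with named offenders.
* Test problem sizes, chosen to make binomial noise negligible relative
  to the tolerances: phased/unphased concordance at n = 500; closed-form
  convergence at n = 50,000 (3 standard errors per gene and label);
  actionable-fraction recovery at the study's own n = 498; test
  calibration at 2,000 replicates. Fixed seeds make every run
  reproducible; the pipeline writes a manifest with checksums so
  re-runs can be verified byte-for-byte.

## Known limitations

The gene list and variant set are exactly the catalog's 14 rows — no
full PharmVar/CPIC allele tables, no CYP2D6 structural-variant calling
beyond the copy-number side channel, no HLA imputation (tag SNPs are
taken at face value), no phasing algorithm, and no de-duplication of
multi-gene drugs in the exposure table (a drug listed under two genes
contributes to both rows, as in the source tables). Exposure counts are
taken as given integers; whether they are drug–user pairs per period or
distinct users is an ambiguity of the source the package documents but
cannot resolve.
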