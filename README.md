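# pgxposure

Pharmacogenetic (PGX) drugs are drugs whose efficacy or toxicity depends
on the patient's genotype at a small number of pharmacogenes; for many of
them, guideline bodies such as the Dutch Pharmacogenetics Working Group
(DPWG) define *actionable* genotypes that warrant a dose change or an
alternative drug. `pgxposure` is for pharmacoepidemiologists and
implementation-science groups who want to answer, from population allele
frequencies and drug-utilization statistics: **how many drug exposures
land on patients with an actionable genotype, and which small gene panel
would a preemptive genotyping program need to cover most of them?**

The central quantity, per drug–gene row, is the count of *risky
exposures*

```
risky = round( a_g  x  E_d )
```

where `a_g` is the fraction of the population with an actionable
phenotype for gene *g* (from star-allele diplotype frequencies translated
through DPWG-style diplotype-to-phenotype rules) and `E_d` is the number
of exposures of all patients to the interacting drug(s) over the study
window (one user of one drug counts once, after restricting the user base
to the ancestry stratum the genotype reference describes). Per-gene
shares of the total risky exposures then rank the genes, and the summed
share of a candidate panel is its *coverage*.

The package provides, as separately usable modules:

* a validated reference **catalog** of 14 pharmacogenes/HLA haplo-groups
  (allele definitions, per-gene phenotype rules, drug–gene interactions)
  plus Dutch drug-consumption, exposure and sex/age stratification
  reference tables, all transcribed at printed precision;
* **VCF I/O** for cohort genotypes (rsID-keyed, GT-only, with a
  copy-number sidecar);
* a **star-allele caller** (exact on phased data; deterministic,
  conservatively tie-broken resolution on unphased data);
* a **phenotype translator** and actionable-genotype carriage statistics;
* **population-genetics utilities** (allele-frequency estimation,
  Hardy–Weinberg expectations, two-cohort frequency tests);
* the **exposure model** (risky exposures, gene/class shares, panel
  coverage, per-user averages, stratification);
* a **Hardy–Weinberg cohort simulator** so the whole chain is testable
  without private cohort data, and a **pipeline runner**
  (`run_pipeline()`, plus a thin CLI at `inst/cli/pgx-exposure`) that
  emits the full report bundle with a checksummed manifest.

## Worked example

```r
library(pgxposure)
cat14 <- load_catalog()

# a 498-individual cohort under HWE at the catalog's allele frequencies
sim   <- simulate_cohort(simulation_config(498, seed = 1), cat14)
calls <- translate_diplotypes(call_all_diplotypes(sim$cohort, cat14), cat14)

round(phenotype_frequencies(calls, "CYP2C9"), 3)
#>     I     N     P
#> 0.303 0.655 0.042
```

65.5% of the simulated cohort are CYP2C9 normal metabolizers, 30.3%
intermediate and 4.2% poor — the intermediate and poor categories
(34.5%) are the actionable ones for phenytoin. Counting actionable genes
per individual:

```r
carriage_distribution(calls, cat14)
#> <pgx_carriage> n = 498
#>   k count  pct
#> 1 0    15  3.0
#> 2 1    90 18.1
#> 3 2   139 27.9
#> 4 3   134 26.9
#> ...
```

Only 3% of individuals carry no actionable genotype at all. The exposure
side uses the packaged utilization tables:

```r
rep <- exposure_report()
rep
#> Risky-exposure report: 13 gene rows
#>   total exposures:         51,304,829
#>   total risky (computed):  12,462,238
#>   total risky (printed):   12,380,754
#>   exposures per user:      5.3 over 9,690,000 users
#>
#>  gene_label exposures actionable_pct   risky risky_printed share_pct
#>      CYP3A5    261514          11.85   30989         30983      0.25
#>      ...
#>      CYP2D6  18638754          40.10 7474140       7467420     59.97
#>     SLCO1B1   9226089          29.52 2723541       2723364     21.85
#>      ...
```

51.3 million exposures over the period, 5.3 per user; about a quarter of
them are risky, and CYP2D6 alone accounts for ~60% of the risky ones.
A three-gene preemptive panel covers almost everything:

```r
shares <- gene_shares(setNames(rep$risky_printed, rep$gene_label), 12380754)
panel_coverage(shares, c("CYP2D6", "SLCO1B1", "CYP2C19"))
#> [1] 94.66
```

The methods vignette (`vignettes/pgx-exposure-methods.Rmd`) documents the
phenotype conventions, the calling precedence rules, the simulator's
assumptions and the documented inconsistencies of the source tables that
the test suite pins rather than smooths over.

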