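# End-to-end orchestration: catalog -> cohort (VCF or simulation) ->
# diplotypes -> phenotypes -> frequency/carriage tables -> allele-frequency
# comparison -> exposure report -> stratification, with a run manifest.
# Every stage failure aborts with the stage name; outputs are plain TSV and
# JSON so re-runs on identical inputs are byte-identical (the manifest's
# timestamp aside).

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Cohort-derived actionable fractions per exposure-table row
#'
#' For each gene row of the exposure table, the fraction of cohort samples
#' whose predicted phenotype at any of the row's genes lies in the row's
#' actionable set. This is the cohort-based replacement for the published
#' Column A percentages.
#'
#' @param calls translated diplotype calls over all genes.
#' @param exposure_table data frame from [read_exposure_table()].
#' @param denominator `"non_missing"` (default) divides by samples with at
#'   least one non-missing phenotype among the row's genes; `"all"` divides
#'   by the full cohort.
#' @return named vector of fractions (names = `gene_label`).
#' @export
cohort_actionable_fractions <- function(calls, exposure_table,
                                        denominator = c("non_missing",
                                                        "all")) {
  denominator <- match.arg(denominator)
  samples <- unique(calls$sample_id)
  out <- setNames(numeric(nrow(exposure_table)), exposure_table$gene_label)
  for (i in seq_len(nrow(exposure_table))) {
    genes <- strsplit(exposure_table$genes[i], ";", fixed = TRUE)[[1]]
    set <- strsplit(exposure_table$actionable_label[i], "+",
                    fixed = TRUE)[[1]]
    hit <- setNames(rep(FALSE, length(samples)), samples)
    seen <- setNames(rep(FALSE, length(samples)), samples)
    for (g in genes) {
      sub <- calls[calls$gene == g, ]
      idx <- match(sub$sample_id, samples)
      hit[idx] <- hit[idx] | (!is.na(sub$phenotype) & sub$phenotype %in% set)
      seen[idx] <- seen[idx] | !is.na(sub$phenotype)
    }
    out[i] <- if (denominator == "all") mean(hit)
              else sum(hit) / max(1L, sum(seen))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Produces the complete report bundle in `out_dir`: per-sample diplotypes
#' and phenotypes, per-gene phenotype frequencies, the actionable-genotype
#' carriage histogram, the cohort-versus-reference allele-frequency
#' comparison, the per-gene risky-exposure report, therapeutic-class
#' shares, the sex/age stratification summary, and a JSON manifest with
#' checksums of every output.
#'
#' @param out_dir output directory (created if needed).
#' @param catalog_path catalog directory (`NULL` = packaged catalog).
#' @param vcf optional cohort VCF; when `NULL` a cohort of `n` individuals
#'   is simulated with `seed`.
#' @param copy_number optional copy-number sidecar TSV (used with `vcf`).
#' @param n,seed simulated cohort size and RNG seed (ignored with `vcf`).
#' @param consumption_path,strata_path,exposure_path,totals_path
#'   drug-utilization inputs (`NULL` = packaged reference tables).
#' @param column_a `"fixture"` uses the published actionable percentages in
#'   the exposure table; `"cohort"` replaces them with fractions computed
#'   from the cohort's predicted phenotypes.
#' @param use_fixture_total passed to [exposure_report()].
#' @return invisibly, a list with every computed object plus the manifest.
#' @export
run_pipeline <- function(out_dir, catalog_path = NULL, vcf = NULL,
                         copy_number = NULL, n = 498, seed = 1,
                         consumption_path = NULL, strata_path = NULL,
                         exposure_path = NULL, totals_path = NULL,
                         column_a = c("fixture", "cohort"),
                         use_fixture_total = FALSE) {
  column_a <- match.arg(column_a)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    write_tsv(x, path)
    files <<- c(files, path)
    path
  }

  catalog <- run_stage("catalog", load_catalog(catalog_path))

  truth <- NULL
  cohort <- run_stage("cohort", {
    if (!is.null(vcf)) {
      wanted <- unique(unlist(lapply(catalog$genes, gene_rsids)))
      read_vcf(vcf, wanted, variants = catalog$variants,
               copy_number = copy_number)
    } else {
      sim <- simulate_cohort(simulation_config(n, seed), catalog)
      truth <- sim$truth
      sim$cohort
    }
  })
  if (!is.null(truth)) emit(truth, "truth.tsv")

  calls <- run_stage("star_caller", call_all_diplotypes(cohort, catalog))
  emit(calls, "diplotypes.tsv")

  calls <- run_stage("phenotyper", translate_diplotypes(calls, catalog))
  emit(calls[, c("sample_id", "gene", "phenotype")], "phenotypes.tsv")

  freq_tab <- run_stage("phenotyper", {
    do.call(rbind, lapply(names(catalog$genes), function(g) {
      f <- phenotype_frequencies(calls, g)
      data.frame(gene = g, phenotype = names(f), freq = as.numeric(f),
                 n_missing = attr(f, "n_missing"), stringsAsFactors = FALSE)
    }))
  })
  emit(freq_tab, "phenotype_frequencies.tsv")

  carriage <- run_stage("phenotyper", carriage_distribution(calls, catalog))
  emit(data.frame(k = names(carriage$counts),
                  count = as.integer(carriage$counts),
                  fraction = as.numeric(carriage$fraction)), "carriage.tsv")

  maf_cmp <- run_stage("popgen", compare_cohort_frequencies(cohort))
  emit(maf_cmp, "maf_comparison.tsv")

  consumption <- run_stage("consumption", read_consumption(consumption_path))
  exposure_tab <- run_stage("exposure", read_exposure_table(exposure_path))
  totals <- run_stage("exposure", read_totals(totals_path))
  fractions <- NULL
  if (column_a == "cohort") {
    fractions <- run_stage("exposure",
                           cohort_actionable_fractions(calls, exposure_tab))
  }
  report <- run_stage("exposure", {
    exposure_report(exposure_tab, actionable_fractions = fractions,
                    use_fixture_total = use_fixture_total, totals = totals)
  })
  emit(as.data.frame(report), "exposures_report.tsv")

  cls <- run_stage("exposure", class_shares(consumption))
  emit(data.frame(therapeutic_area = names(cls),
                  share_pct = as.numeric(cls)), "class_shares.tsv")

  strata <- run_stage("strata", read_strata(strata_path))
  usage <- run_stage("strata", stratify_usage(strata))
  emit(usage$by_sex, "usage_by_sex.tsv")
  emit(usage$by_age, "usage_by_age.tsv")

  shares <- setNames(report$share_pct, report$gene_label)
  top3 <- names(sort(shares, decreasing = TRUE))[1:3]
  summary <- list(
    total_exposures = attr(report, "total_exposures"),
    total_risky_computed = attr(report, "total_risky_computed"),
    total_risky_printed = attr(report, "total_risky_printed"),
    exposures_per_user = attr(report, "exposures_per_user"),
    n_users = attr(report, "n_users"),
    panel_top3 = top3,
    panel_top3_coverage_pct = panel_coverage(shares, top3),
    pgx_item_share_pct = 100 * totals[["total_pgx_items_thousands"]] /
      totals[["total_all_items_thousands"]],
    women_share_pct = unname(usage$combined_sex["women"]),
    age_45plus_pct = usage$age_45plus_pct,
    pct_one_or_more_actionable =
      100 * mean(carriage$per_sample$k >= 1)
  )
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, summary_path)

  manifest <- list(
    package = "pgxposure",
    version = as.character(packageVersion("pgxposure")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = if (is.null(vcf)) seed else NA,
    cohort = list(n_samples = length(cohort$sample_ids),
                  n_variants = nrow(cohort$variants),
                  source = if (is.null(vcf)) "simulated" else vcf),
    row_counts = list(diplotypes = nrow(calls),
                      phenotype_frequencies = nrow(freq_tab),
                      interactions = nrow(catalog$interactions),
                      exposure_rows = nrow(report)),
    outputs = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(catalog = catalog, cohort = cohort, truth = truth,
                 calls = calls, phenotype_frequencies = freq_tab,
                 carriage = carriage, maf_comparison = maf_cmp,
                 report = report, class_shares = cls, usage = usage,
                 summary = summary, manifest = manifest,
                 files = c(files, manifest_path)))
}
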