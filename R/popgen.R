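# Allele-frequency estimation, Hardy-Weinberg expectations and two-cohort
# frequency comparison. The comparison test operates on allele counts
# (2n chromosomes per diploid cohort); the default is a two-proportion
# chi-square without continuity correction, with Fisher's exact test as an
# option and as the automatic fall-back when a margin is empty.

#' Allele-frequency record
#'
#' @param maf minor (risk) allele frequency in `[0, 1]`.
#' @param n_chromosomes number of chromosomes sampled (2n for a diploid
#'   cohort); must be positive and even.
#' @param rsid,gene,star_name,source optional annotation.
#' @return object of class `pgx_maf`.
#' @export
allele_frequency_record <- function(maf, n_chromosomes, rsid = NA_character_,
                                    gene = NA_character_,
                                    star_name = NA_character_,
                                    source = NA_character_) {
  if (is.na(maf) || maf < 0 || maf > 1) stop("maf must be in [0, 1]")
  if (n_chromosomes <= 0 || n_chromosomes %% 2 != 0) {
    stop("n_chromosomes must be positive and even for a diploid cohort")
  }
  structure(
    list(maf = maf, n_chromosomes = as.integer(n_chromosomes), rsid = rsid,
         gene = gene, star_name = star_name, source = source),
    class = "pgx_maf"
  )
}

#' @export
print.pgx_maf <- function(x, ...) {
  cat("<pgx_maf>", x$rsid, "maf =", format(x$maf, digits = 4),
      "on", x$n_chromosomes, "chromosomes",
      if (!is.na(x$source)) paste0("[", x$source, "]") else "", "\n")
  invisible(x)
}

#' Estimate the risk-allele frequency of one variant in a cohort
#'
#' `maf = sum of risk-allele dosages / (2 x non-missing samples)`.
#'
#' @param cohort a `pgx_cohort`.
#' @param rsid variant to estimate; must be a column of the cohort.
#' @param source cohort label carried into the record.
#' @return a `pgx_maf` record.
#' @export
estimate_maf <- function(cohort, rsid, source = "cohort") {
  if (!rsid %in% colnames(cohort$dosage)) {
    stop("rsid not in cohort: ", rsid)
  }
  d <- cohort$dosage[, rsid]
  n_ok <- sum(!is.na(d))
  if (n_ok == 0) stop("all genotypes missing for ", rsid)
  allele_frequency_record(
    maf = sum(d, na.rm = TRUE) / (2 * n_ok),
    n_chromosomes = 2L * n_ok, rsid = rsid, source = source
  )
}

#' Hardy-Weinberg genotype frequencies from an allele frequency
#'
#' @param maf allele frequency q in `[0, 1]`.
#' @return numeric vector `(hom_ref, het, hom_alt)` =
#'   `((1-q)^2, 2q(1-q), q^2)`; sums to 1 exactly.
#' @examples
#' hwe_genotype_freqs(0.373)
#' @export
hwe_genotype_freqs <- function(maf) {
  if (any(is.na(maf)) || any(maf < 0 | maf > 1)) {
    stop("maf must be in [0, 1]")
  }
  hom_ref <- (1 - maf)^2
  het <- 2 * maf * (1 - maf)
  # complement rather than maf^2 so the triple closes to 1 exactly in
  # floating point (difference from maf^2 is below 1e-16)
  c(hom_ref = hom_ref, het = het, hom_alt = 1 - hom_ref - het)
}

#' Compare allele frequencies between two cohorts
#'
#' Two-proportion test on allele counts. The chi-square variant uses no
#' continuity correction; when any cell of the 2x2 allele-count table is
#' zero it automatically falls back to Fisher's exact test, noted in the
#' result. The test is symmetric in its arguments.
#'
#' @param rec_a,rec_b `pgx_maf` records (see [allele_frequency_record()]).
#' @param method `"chi-square"` (default) or `"fisher"`.
#' @return list with `p_value`, `method` (the method actually used),
#'   `maf_a`, `maf_b`, and `fallback` (TRUE when chi-square fell back to
#'   Fisher).
#' @export
compare_maf <- function(rec_a, rec_b, method = c("chi-square", "fisher")) {
  method <- match.arg(method)
  counts <- function(r) {
    x <- round(r$maf * r$n_chromosomes)
    c(x, r$n_chromosomes - x)
  }
  tab <- rbind(counts(rec_a), counts(rec_b))
  fallback <- FALSE
  if (method == "chi-square" && any(tab == 0)) {
    method <- "fisher"
    fallback <- TRUE
  }
  p <- if (method == "chi-square") {
    suppressWarnings(
      prop.test(tab[, 1], rowSums(tab), correct = FALSE)$p.value
    )
  } else {
    fisher.test(tab)$p.value
  }
  list(p_value = min(1, p), method = method,
       maf_a = rec_a$maf, maf_b = rec_b$maf, fallback = fallback)
}

#' Compare every cohort variant against published reference frequencies
#'
#' Runs [estimate_maf()] + [compare_maf()] for each single-variant row of
#' the packaged reference table that has a comparison-cohort frequency,
#' producing the cohort-versus-reference comparison report.
#'
#' @param cohort a `pgx_cohort`.
#' @param reference data frame as returned by
#'   [reference_variant_frequencies()].
#' @param n_other number of individuals in the comparison cohort used to
#'   form allele counts when the source did not publish them (default 349).
#' @param method passed to [compare_maf()].
#' @return data frame: gene, star_name, rsid, maf_cohort, maf_other, p,
#'   method, p_printed.
#' @export
compare_cohort_frequencies <- function(cohort,
                                       reference =
                                         reference_variant_frequencies(),
                                       n_other = 349,
                                       method = "chi-square") {
  rows <- lapply(seq_len(nrow(reference)), function(i) {
    ref <- reference[i, ]
    rsids <- strsplit(ref$rsids, ";", fixed = TRUE)[[1]]
    if (length(rsids) != 1 || !rsids %in% colnames(cohort$dosage)) {
      return(NULL)
    }
    if (is.na(ref$maf_other)) return(NULL)
    rec_a <- estimate_maf(cohort, rsids, source = "cohort")
    rec_b <- allele_frequency_record(ref$maf_other, 2 * n_other,
                                     rsid = rsids, source = "reference")
    cmp <- compare_maf(rec_a, rec_b, method = method)
    data.frame(gene = ref$gene, star_name = ref$star_name, rsid = rsids,
               maf_cohort = rec_a$maf, maf_other = ref$maf_other,
               p = cmp$p_value, method = cmp$method,
               p_printed = ref$p_printed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
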