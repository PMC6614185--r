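# Synthetic-data generator. Cohorts are drawn gene by gene under
# Hardy-Weinberg equilibrium: each individual receives two haplotypes drawn
# independently from the gene's star-allele frequency vector (alleles are
# mutually exclusive within a gene, the reference allele takes the residual
# mass), and haplotypes are rendered into per-variant genotypes. Because
# star-allele frequencies, not per-SNP frequencies, drive the draw,
# multi-SNP haplotype tags and nested definitions (e.g. the inactive allele
# carrying the decreased allele's SNP) come out consistent, and the per-SNP
# minor allele frequencies emerge as marginals.

#' Simulation configuration
#'
#' @param n_individuals cohort size (>= 1).
#' @param seed RNG seed; identical config + seed gives identical output.
#' @param maf_overrides optional named vector, rsid -> haplotype frequency.
#'   An override applies to every catalog allele whose defining-variant set
#'   contains the rsid (a multi-SNP allele takes the smallest override among
#'   its variants).
#' @param cyp2d6_dup_fraction probability of a third CYP2D6 gene copy
#'   (default 0.0327, calibrated so the ultrarapid phenotype frequency is
#'   0.02 under the packaged allele frequencies).
#' @param phased_output emit phased haplotypes (TRUE) or unphased dosages.
#' @param missing_rate per-genotype missingness probability.
#' @return list of class `pgx_sim_config`.
#' @export
simulation_config <- function(n_individuals, seed, maf_overrides = NULL,
                              cyp2d6_dup_fraction = 0.0327,
                              phased_output = TRUE, missing_rate = 0) {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  stopifnot(cyp2d6_dup_fraction >= 0, cyp2d6_dup_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (!is.null(maf_overrides)) {
    if (is.null(names(maf_overrides)) ||
        any(maf_overrides < 0 | maf_overrides > 1)) {
      stop("maf_overrides must be a named vector of fractions in [0, 1]")
    }
  }
  structure(
    list(n_individuals = as.integer(n_individuals), seed = as.integer(seed),
         maf_overrides = maf_overrides,
         cyp2d6_dup_fraction = cyp2d6_dup_fraction,
         phased_output = isTRUE(phased_output),
         missing_rate = missing_rate),
    class = "pgx_sim_config"
  )
}

# Apply rsid-keyed overrides to one gene's non-reference allele frequencies.
override_freqs <- function(gene, overrides) {
  al <- gene$alleles
  freq <- al$freq
  if (!is.null(overrides)) {
    for (i in which(!al$is_reference)) {
      hit <- intersect(al$rsids[[i]], names(overrides))
      if (length(hit) > 0) freq[i] <- min(overrides[hit])
    }
  }
  freq[al$is_reference] <- 1 - sum(freq[!al$is_reference])
  if (freq[al$is_reference] < -1e-9) {
    stop(gene$gene, ": allele frequencies sum to more than 1")
  }
  pmax(freq, 0)
}

#' Simulate a diploid cohort under Hardy-Weinberg equilibrium
#'
#' @param config a `pgx_sim_config` (see [simulation_config()]).
#' @param catalog a `pgx_catalog`; defaults to the packaged catalog.
#' @return list with `cohort` (a `pgx_cohort`) and `truth` (data frame of
#'   the drawn diplotypes: sample_id, gene, allele_1, allele_2,
#'   copy_number).
#' @examples
#' sim <- simulate_cohort(simulation_config(50, seed = 1))
#' sim$cohort
#' head(sim$truth)
#' @export
simulate_cohort <- function(config, catalog = load_catalog()) {
  stopifnot(inherits(config, "pgx_sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  sample_ids <- sprintf("S%04d", seq_len(n))
  variants <- catalog$variants
  m <- nrow(variants)
  A1 <- matrix(0L, n, m, dimnames = list(sample_ids, variants$rsid))
  A2 <- matrix(0L, n, m, dimnames = list(sample_ids, variants$rsid))
  truth <- vector("list", length(catalog$genes))
  copy_number <- list()

  for (gi in seq_along(catalog$genes)) {
    gene <- catalog$genes[[gi]]
    al <- gene$alleles
    freq <- override_freqs(gene, config$maf_overrides)
    i1 <- sample.int(nrow(al), n, replace = TRUE, prob = freq)
    i2 <- sample.int(nrow(al), n, replace = TRUE, prob = freq)
    for (k in seq_len(nrow(al))) {
      rs <- al$rsids[[k]]
      if (length(rs) == 0) next
      A1[i1 == k, rs] <- 1L
      A2[i2 == k, rs] <- 1L
    }
    cn <- rep(2L, n)
    if (gene$gene == "CYP2D6" && config$cyp2d6_dup_fraction > 0) {
      cn <- cn + rbinom(n, 1, config$cyp2d6_dup_fraction)
      copy_number[[gene$gene]] <- cn
    }
    ref <- reference_allele(gene)
    pairs <- mapply(function(x, y) order_allele_pair(x, y, ref),
                    al$star_name[i1], al$star_name[i2])
    truth[[gi]] <- data.frame(
      sample_id = sample_ids, gene = gene$gene,
      allele_1 = pairs[1, ], allele_2 = pairs[2, ], copy_number = cn,
      stringsAsFactors = FALSE
    )
  }

  dosage <- A1 + A2
  if (config$missing_rate > 0) {
    mask <- matrix(runif(n * m) < config$missing_rate, n, m)
    dosage[mask] <- NA_integer_
    A1[mask] <- NA_integer_
    A2[mask] <- NA_integer_
  }
  cohort <- if (config$phased_output) {
    new_cohort(sample_ids, variants, dosage, A1, A2,
               phased = rep(TRUE, m), copy_number = copy_number)
  } else {
    new_cohort(sample_ids, variants, dosage,
               phased = rep(FALSE, m), copy_number = copy_number)
  }
  list(cohort = cohort, truth = do.call(rbind, c(truth,
                                                 make.row.names = FALSE)))
}

#' Simulate drug-consumption and stratification tables
#'
#' Generates schema-valid stand-ins for the drug-utilization inputs: drugs
#' with log-uniform issuance, therapeutic areas drawn from the packaged
#' table's empirical class distribution, and sex/age strata with the
#' packaged table's marginal shape.
#'
#' @param seed RNG seed.
#' @param n_drugs number of drugs to generate.
#' @param scale issuance scale (thousands of items for the largest drugs).
#' @return list with `consumption` and `strata` data frames matching the
#'   schemas of [read_consumption()] and [read_strata()].
#' @export
simulate_consumption <- function(seed, n_drugs = 20, scale = 1e5) {
  stopifnot(scale > 0, n_drugs >= 0)
  set.seed(seed)
  ref_cons <- read_consumption()
  area_share <- class_shares(ref_cons)
  if (n_drugs == 0) {
    consumption <- ref_cons[0, ]
  } else {
    items <- exp(runif(n_drugs, log(scale * 1e-3), log(scale)))
    users <- round_half_away(items * 1000 * runif(n_drugs, 0.05, 0.5))
    consumption <- data.frame(
      drug = sprintf("drug_%02d", seq_len(n_drugs)),
      therapeutic_area = sample(names(area_share), n_drugs, replace = TRUE,
                                prob = area_share),
      year = "2011-2017",
      items_thousands = round(items, 3),
      users = users,
      stringsAsFactors = FALSE
    )
  }
  ref_strata <- read_strata()
  shape <- ref_strata$users / sum(ref_strata$users)
  total_users <- max(1, round(sum(consumption$users) %||% 0))
  if (nrow(consumption) == 0) total_users <- round(scale * 100)
  counts <- as.vector(rmultinom(1, total_users, shape))
  strata <- data.frame(
    year = ref_strata$year, sex = ref_strata$sex,
    age_band = ref_strata$age_band, users = counts,
    stringsAsFactors = FALSE
  )
  list(consumption = consumption, strata = strata)
}

#' Write a simulated cohort to disk
#'
#' Emits the VCF, the copy-number sidecar and the truth table for a
#' simulated cohort.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return named vector of the paths written, invisibly.
#' @export
write_simulated_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             copy_number = file.path(dir, "copy_number.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_vcf(sim$cohort, paths["vcf"])
  write_copy_number(sim$cohort, paths["copy_number"])
  write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}

#' @export
print.pgx_sim_config <- function(x, ...) {
  cat("<pgx_sim_config> n =", x$n_individuals, "seed =", x$seed,
      if (x$phased_output) "phased" else "unphased",
      "dup =", x$cyp2d6_dup_fraction,
      "missing =", x$missing_rate, "\n")
  invisible(x)
}
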