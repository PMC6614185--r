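# Drug-utilization ingestion and the headline exposure arithmetic: risky
# exposures per gene (actionable fraction x exposures), gene shares of the
# total risky burden, therapeutic-class shares, exposures per user,
# ancestry adjustment and sex/age stratification.

#' Read a drug-consumption table
#'
#' @param path TSV with columns `drug`, `therapeutic_area`, `year`,
#'   `items_thousands`, `users`; `NULL` for the packaged 2011-2017
#'   reference table.
#' @return validated data frame.
#' @export
read_consumption <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("gip", "consumption.tsv")
  if (!file.exists(path)) stop("consumption table not found: ", path)
  x <- read_tsv(path)
  needed <- c("drug", "therapeutic_area", "year", "items_thousands", "users")
  if (!all(needed %in% names(x))) {
    stop("consumption table must have columns: ",
         paste(needed, collapse = ", "))
  }
  if (any(!is.na(x$items_thousands) & x$items_thousands < 0)) {
    stop("negative issuance in consumption table")
  }
  x$therapeutic_area <- normalize_area(x$therapeutic_area)
  x
}

# Published tables mix capitalisations of the same class label.
normalize_area <- function(x) {
  x <- trimws(tolower(x))
  x
}

#' Read the per-gene exposure table
#'
#' One row per drug-gene interaction group: the published actionable
#' percentage ("Column A"), the total exposures of all users to the group's
#' drugs over the study period ("Column B"), and the published risky
#' exposures and shares, stored verbatim for comparison.
#'
#' @param path TSV; `NULL` for the packaged reference table.
#' @return data frame.
#' @export
read_exposure_table <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("gip", "exposures.tsv")
  if (!file.exists(path)) stop("exposure table not found: ", path)
  x <- read_tsv(path)
  needed <- c("gene_label", "genes", "drugs", "col_a_pct", "actionable_label",
              "exposures", "risky_printed")
  if (!all(needed %in% names(x))) {
    stop("exposure table must have columns: ", paste(needed, collapse = ", "))
  }
  if (any(x$exposures < 0)) stop("negative exposures")
  x
}

#' Read the sex/age stratification table
#'
#' @param path TSV with columns `year`, `sex`, `age_band`, `users`; `NULL`
#'   for the packaged table (2015 and 2017).
#' @return validated data frame.
#' @export
read_strata <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("gip", "strata.tsv")
  if (!file.exists(path)) stop("strata table not found: ", path)
  x <- read_tsv(path)
  needed <- c("year", "sex", "age_band", "users")
  if (!all(needed %in% names(x))) {
    stop("strata table must have columns: ", paste(needed, collapse = ", "))
  }
  bands <- c("0-4", "5-14", "15-24", "25-44", "45-64", "65-74", "75+")
  bad <- setdiff(unique(x$age_band), bands)
  if (length(bad) > 0) {
    stop("unknown age band(s): ", paste(bad, collapse = ", "))
  }
  if (!all(x$sex %in% c("men", "women"))) {
    stop("sex must be 'men' or 'women'")
  }
  if (any(x$users < 0)) stop("negative user counts")
  x
}

#' Read study-level totals
#'
#' @param path key/value TSV; `NULL` for the packaged totals.
#' @return named numeric vector.
#' @export
read_totals <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("gip", "totals.tsv")
  x <- read_tsv(path)
  setNames(as.numeric(x$value), x$key)
}

#' Risky exposures: actionable fraction times exposures
#'
#' The product is rounded half away from zero, the convention under which
#' the reproducible published rows come out exactly.
#'
#' @param actionable_fraction fraction in `[0, 1]`.
#' @param exposures non-negative exposure count.
#' @return integer count of risky exposures.
#' @examples
#' risky_exposures(0.205, 193641)  # 39696
#' @export
risky_exposures <- function(actionable_fraction, exposures) {
  if (any(actionable_fraction < 0 | actionable_fraction > 1)) {
    stop("actionable_fraction must be in [0, 1]")
  }
  if (any(exposures < 0)) stop("exposures must be >= 0")
  round_half_away(actionable_fraction * exposures)
}

#' Per-gene shares of total risky exposures
#'
#' @param risky named vector of per-gene risky exposures.
#' @param total_risky denominator; defaults to `sum(risky)`.
#' @return named vector of percentages.
#' @export
gene_shares <- function(risky, total_risky = sum(risky)) {
  if (total_risky <= 0) stop("total_risky must be positive")
  100 * risky / total_risky
}

#' Panel coverage: share of risky exposures a gene panel accounts for
#'
#' @param shares named vector of per-gene share percentages
#'   (see [gene_shares()]).
#' @param panel character vector of gene (row) names; must be a subset of
#'   `names(shares)`.
#' @return summed percentage.
#' @examples
#' panel_coverage(c(CYP2D6 = 60.31, SLCO1B1 = 22.00, CYP2C19 = 12.35,
#'                  TPMT = 0.32), c("CYP2D6", "SLCO1B1", "CYP2C19"))
#' @export
panel_coverage <- function(shares, panel) {
  bad <- setdiff(panel, names(shares))
  if (length(bad) > 0) {
    stop("panel gene(s) not present: ", paste(bad, collapse = ", "))
  }
  sum(shares[panel])
}

#' Therapeutic-class shares of issuance
#'
#' Percentages of total items issued per therapeutic area, computed from
#' raw issuance (thousands of items), never from pre-rounded percentages.
#'
#' @param consumption data frame from [read_consumption()].
#' @return named vector of percentages, descending.
#' @export
class_shares <- function(consumption) {
  if (nrow(consumption) == 0) stop("empty consumption table")
  by_area <- tapply(consumption$items_thousands,
                    normalize_area(consumption$therapeutic_area), sum)
  sort(100 * by_area / sum(consumption$items_thousands), decreasing = TRUE)
}

#' Per-drug shares of issuance
#'
#' @param consumption data frame from [read_consumption()].
#' @param total_items_thousands denominator; defaults to the table sum.
#' @return named vector of percentages, descending.
#' @export
drug_shares <- function(consumption,
                        total_items_thousands =
                          sum(consumption$items_thousands)) {
  sort(setNames(100 * consumption$items_thousands / total_items_thousands,
                consumption$drug), decreasing = TRUE)
}

#' Average exposures per drug user
#'
#' @param total_exposures total exposures over the period.
#' @param n_users number of distinct drug users.
#' @param digits rounding used for reporting (default 1 decimal place).
#' @return the ratio.
#' @examples
#' exposures_per_user(51304829, 9.69e6)  # 5.3
#' @export
exposures_per_user <- function(total_exposures, n_users, digits = 1) {
  if (n_users <= 0) stop("n_users must be positive")
  round(total_exposures / n_users, digits)
}

#' Ancestry adjustment of a population count
#'
#' Scales a count by the fraction of the population the genotype reference
#' panel represents (the catalog's frequencies describe the European-
#' ancestry majority only), rounding half away from zero.
#'
#' @param count population or user count.
#' @param fraction_kept fraction retained (default 0.85).
#' @return adjusted count.
#' @export
ancestry_adjust <- function(count, fraction_kept = 0.85) {
  if (fraction_kept < 0 || fraction_kept > 1) {
    stop("fraction_kept must be in [0, 1]")
  }
  round_half_away(count * fraction_kept)
}

#' Sex and age stratification of drug users
#'
#' Row/column margins of the users-by-stratum table: per-year and combined
#' sex shares, age-band shares, and the share of users aged 45 or older
#' (the three oldest bands).
#'
#' @param strata data frame from [read_strata()].
#' @param years years to combine; default all years present.
#' @return list with `by_sex` (data frame: year, sex, users, share_pct),
#'   `combined_sex` (sex shares over the selected years), `by_age`
#'   (combined age-band users and shares), `age_45plus_pct`, and `table`
#'   (users by year x sex x band, wide).
#' @export
stratify_usage <- function(strata, years = NULL) {
  if (is.null(years)) years <- sort(unique(strata$year))
  miss <- setdiff(years, unique(strata$year))
  if (length(miss) > 0) {
    stop("strata incomplete for year(s): ", paste(miss, collapse = ", "))
  }
  x <- strata[strata$year %in% years, ]
  by_sex <- aggregate(users ~ year + sex, x, sum)
  tot_year <- tapply(by_sex$users, by_sex$year, sum)
  by_sex$share_pct <- 100 * by_sex$users / tot_year[as.character(by_sex$year)]

  comb_sex <- tapply(x$users, x$sex, sum)
  combined_sex <- 100 * comb_sex / sum(comb_sex)

  bands <- c("0-4", "5-14", "15-24", "25-44", "45-64", "65-74", "75+")
  by_age_users <- tapply(x$users, factor(x$age_band, levels = bands), sum)
  by_age_users[is.na(by_age_users)] <- 0
  by_age <- data.frame(age_band = bands, users = as.numeric(by_age_users),
                       share_pct = 100 * as.numeric(by_age_users) /
                         sum(by_age_users))
  age_45plus <- sum(by_age$share_pct[by_age$age_band %in%
                                       c("45-64", "65-74", "75+")])
  wide <- reshape(aggregate(users ~ year + sex + age_band, x, sum),
                  idvar = c("year", "sex"), timevar = "age_band",
                  direction = "wide")
  names(wide) <- sub("^users\\.", "", names(wide))
  list(by_sex = by_sex, combined_sex = combined_sex, by_age = by_age,
       age_45plus_pct = age_45plus, table = wide)
}

#' Risky-exposure report over all genes
#'
#' The central estimate: per gene row, risky exposures = actionable
#' fraction x exposures, plus shares of the total. By default the
#' actionable fractions are the table's published Column A percentages and
#' the share denominator is the computed sum of risky exposures; the
#' published (fixture) grand total, which differs from the printed column's
#' sum, can be substituted with `use_fixture_total = TRUE`. Alternatively,
#' cohort-derived actionable fractions (e.g. from a simulated or genotyped
#' cohort) can be supplied per gene label.
#'
#' @param exposure_table data frame from [read_exposure_table()].
#' @param actionable_fractions optional named vector (by `gene_label`) of
#'   fractions in `[0, 1]` replacing the published Column A.
#' @param use_fixture_total use the published grand total of risky
#'   exposures as the share denominator instead of the computed sum.
#' @param totals named totals vector (see [read_totals()]); used for the
#'   fixture grand total and the user base.
#' @return object of class `pgx_exposure_report`: the per-gene data frame
#'   with columns `gene_label`, `exposures`, `actionable_pct`, `risky`,
#'   `risky_printed`, `share_pct`, plus attributes `total_exposures`,
#'   `total_risky_computed`, `total_risky_printed`, `exposures_per_user`
#'   and `n_users`.
#' @export
exposure_report <- function(exposure_table = read_exposure_table(),
                            actionable_fractions = NULL,
                            use_fixture_total = FALSE,
                            totals = read_totals()) {
  tab <- exposure_table
  frac <- tab$col_a_pct / 100
  if (!is.null(actionable_fractions)) {
    idx <- match(names(actionable_fractions), tab$gene_label)
    if (any(is.na(idx))) {
      stop("unknown gene_label(s): ",
           paste(names(actionable_fractions)[is.na(idx)], collapse = ", "))
    }
    frac[idx] <- actionable_fractions
  }
  risky <- risky_exposures(frac, tab$exposures)
  total_computed <- sum(risky)
  total_printed <- unname(totals["printed_total_risky"])
  denom <- if (use_fixture_total) total_printed else total_computed
  out <- data.frame(
    gene_label = tab$gene_label, exposures = tab$exposures,
    actionable_pct = 100 * frac, risky = risky,
    risky_printed = tab$risky_printed,
    share_pct = as.numeric(gene_shares(risky, denom)),
    stringsAsFactors = FALSE
  )
  n_users <- ancestry_adjust(unname(totals["insured_population"]),
                             unname(totals["european_ancestry_fraction"]))
  structure(out,
            total_exposures = sum(tab$exposures),
            total_risky_computed = total_computed,
            total_risky_printed = total_printed,
            n_users = n_users,
            exposures_per_user = exposures_per_user(sum(tab$exposures),
                                                    n_users),
            class = c("pgx_exposure_report", "data.frame"))
}

#' @export
print.pgx_exposure_report <- function(x, ...) {
  cat("Risky-exposure report:", nrow(x), "gene rows\n")
  cat("  total exposures:        ",
      format(attr(x, "total_exposures"), big.mark = ","), "\n")
  cat("  total risky (computed): ",
      format(attr(x, "total_risky_computed"), big.mark = ","), "\n")
  cat("  total risky (printed):  ",
      format(attr(x, "total_risky_printed"), big.mark = ","), "\n")
  cat("  exposures per user:     ", attr(x, "exposures_per_user"),
      "over", format(attr(x, "n_users"), big.mark = ","), "users\n\n")
  df <- as.data.frame(x)
  df$actionable_pct <- round(df$actionable_pct, 2)
  df$share_pct <- round(df$share_pct, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
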