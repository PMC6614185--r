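# Cohort genotype container and VCF I/O. Variants are keyed by rsID
# throughout; chromosome/position are carried along for output but never
# used for matching, so the container is genome-build agnostic. Only the GT
# subfield of a VCF is consumed.

#' Construct a cohort genotype container
#'
#' Holds a samples-by-variants dosage matrix of the catalog risk (ALT)
#' allele, per-haplotype allele matrices for phased variants, a per-variant
#' phase flag and an optional per-gene copy-number side channel.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param variants data frame with columns `rsid`, `chrom`, `pos`, `ref`,
#'   `alt` (one row per variant column).
#' @param dosage integer matrix (`samples x variants`) of risk-allele
#'   dosages 0/1/2, `NA` for missing.
#' @param a1,a2 optional integer matrices of per-haplotype risk-allele
#'   counts (0/1/`NA`); required for variants flagged phased.
#' @param phased logical vector, one flag per variant.
#' @param copy_number optional named list, gene -> integer vector of
#'   per-sample copy numbers (default 2 everywhere).
#' @return an object of class `pgx_cohort`.
#' @export
new_cohort <- function(sample_ids, variants, dosage, a1 = NULL, a2 = NULL,
                       phased = NULL, copy_number = list()) {
  n <- length(sample_ids)
  m <- nrow(variants)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (anyDuplicated(variants$rsid)) {
    stop("rsid collision in variant table: ",
         paste(unique(variants$rsid[duplicated(variants$rsid)]),
               collapse = ", "))
  }
  dosage <- matrix(as.integer(dosage), n, m,
                   dimnames = list(sample_ids, variants$rsid))
  if (any(!is.na(dosage) & (dosage < 0L | dosage > 2L))) {
    stop("dosages must be 0, 1, 2 or missing")
  }
  if (is.null(phased)) phased <- rep(FALSE, m)
  names(phased) <- variants$rsid
  empty <- matrix(NA_integer_, n, m,
                  dimnames = list(sample_ids, variants$rsid))
  a1 <- if (is.null(a1)) empty else {
    dimnames(a1) <- dimnames(empty); a1
  }
  a2 <- if (is.null(a2)) empty else {
    dimnames(a2) <- dimnames(empty); a2
  }
  if (any(!is.na(a1) & !(a1 %in% 0:1)) || any(!is.na(a2) & !(a2 %in% 0:1))) {
    stop("haplotype entries must be 0, 1 or missing")
  }
  for (g in names(copy_number)) {
    cn <- copy_number[[g]]
    if (length(cn) != n || any(!is.na(cn) & cn < 0)) {
      stop("copy_number[['", g, "']] must give one value >= 0 per sample")
    }
  }
  structure(
    list(sample_ids = sample_ids, variants = variants, dosage = dosage,
         a1 = a1, a2 = a2, phased = phased, copy_number = copy_number),
    class = "pgx_cohort"
  )
}

#' @export
print.pgx_cohort <- function(x, ...) {
  cat("<pgx_cohort> ", length(x$sample_ids), " samples x ",
      nrow(x$variants), " variants (",
      sum(x$phased), " phased)\n", sep = "")
  miss <- sum(is.na(x$dosage))
  cat("  missing genotypes: ", miss, " (",
      round(100 * miss / max(1, length(x$dosage)), 2), "%)\n", sep = "")
  if (length(x$copy_number) > 0) {
    cat("  copy-number side channel:",
        paste(names(x$copy_number), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read cohort genotypes from a VCF
#'
#' Reads a VCF (4.x, plain or gzipped) and returns the risk-allele dosage
#' matrix restricted to the requested rsIDs. Phase is taken from the GT
#' separator (`|` phased, `/` unphased); a variant is flagged phased only
#' when every non-missing genotype is phased. rsIDs absent from the file
#' become all-missing columns and are reported with a warning.
#'
#' @param path VCF file.
#' @param wanted_rsids character vector of rsIDs to extract.
#' @param variants optional variant annotation (as in [new_cohort()]) used
#'   to fill chrom/pos/ref/alt for absent rsIDs; defaults to the packaged
#'   catalog's variant table.
#' @param copy_number optional path to a copy-number sidecar TSV with
#'   columns `sample_id`, `gene`, `copy_number`.
#' @return a `pgx_cohort`.
#' @export
read_vcf <- function(path, wanted_rsids, variants = NULL,
                     copy_number = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) > 0 && anyDuplicated(stats::na.omit(fix$ID))) {
    stop("rsid collision in VCF: ",
         paste(unique(fix$ID[duplicated(fix$ID)]), collapse = ", "))
  }
  multi <- !is.na(fix$ALT) & grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    stop("multi-allelic record(s) not supported (record ",
         paste(which(multi), collapse = ", "), ": ",
         paste(fix$ID[multi], collapse = ", "), ")")
  }
  sample_ids <- colnames(vcf@gt)[-1]
  if (is.null(sample_ids)) sample_ids <- character(0)
  n <- length(sample_ids)

  if (is.null(variants)) {
    variants <- read_tsv(pkg_extdata("catalog", "variants.tsv"))
  }
  vtab <- data.frame(rsid = wanted_rsids, stringsAsFactors = FALSE)
  idx_fix <- match(wanted_rsids, fix$ID)
  idx_ann <- match(wanted_rsids, variants$rsid)
  vtab$chrom <- ifelse(!is.na(idx_fix), fix$CHROM[idx_fix],
                       variants$chrom[idx_ann])
  vtab$pos <- as.integer(ifelse(!is.na(idx_fix), fix$POS[idx_fix],
                                variants$pos[idx_ann]))
  vtab$ref <- ifelse(!is.na(idx_fix), fix$REF[idx_fix],
                     variants$ref[idx_ann])
  vtab$alt <- ifelse(!is.na(idx_fix), fix$ALT[idx_fix],
                     variants$alt[idx_ann])

  absent <- wanted_rsids[is.na(idx_fix)]
  if (length(absent) > 0) {
    warning("rsID(s) absent from VCF, recorded as all-missing: ",
            paste(absent, collapse = ", "))
  }

  m <- length(wanted_rsids)
  dos <- matrix(NA_integer_, n, m)
  h1 <- matrix(NA_integer_, n, m)
  h2 <- matrix(NA_integer_, n, m)
  phased <- rep(FALSE, m)
  if (n > 0 && nrow(fix) > 0) {
    gt_field <- vcfR::extract.gt(vcf, element = "GT")
    for (j in seq_len(m)) {
      i <- idx_fix[j]
      if (is.na(i)) next
      gt <- gt_field[i, sample_ids]
      parsed <- parse_gt(gt, record = i)
      dos[, j] <- parsed$dosage
      h1[, j] <- parsed$a1
      h2[, j] <- parsed$a2
      phased[j] <- parsed$phased
    }
  }
  cohort <- new_cohort(sample_ids, vtab, dos, h1, h2, phased)
  if (!is.null(copy_number)) {
    cohort <- attach_copy_number(cohort, copy_number)
  }
  cohort
}

# Decode a vector of GT strings for one record. Accepts "0/1", "0|1", ".",
# "./.", ".|."; anything else is a hard error naming the record.
parse_gt <- function(gt, record) {
  gt <- sub(":.*$", "", gt)
  miss <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  ok <- miss | grepl("^[01][/|][01]$", gt)
  if (!all(ok)) {
    stop("malformed GT at VCF record ", record, ": ",
         paste(unique(gt[!ok]), collapse = ", "))
  }
  a1 <- ifelse(miss, NA_integer_, as.integer(substr(gt, 1, 1)))
  a2 <- ifelse(miss, NA_integer_, as.integer(substr(gt, 3, 3)))
  is_phased <- !miss & substr(gt, 2, 2) == "|"
  all_phased <- length(gt[!miss]) > 0 && all(is_phased[!miss])
  list(dosage = a1 + a2,
       a1 = if (all_phased) a1 else rep(NA_integer_, length(gt)),
       a2 = if (all_phased) a2 else rep(NA_integer_, length(gt)),
       phased = all_phased)
}

#' Attach a copy-number sidecar to a cohort
#'
#' @param cohort a `pgx_cohort`.
#' @param path TSV with columns `sample_id`, `gene`, `copy_number`; samples
#'   not listed default to copy number 2.
#' @return the cohort with its `copy_number` channel filled.
#' @export
attach_copy_number <- function(cohort, path) {
  side <- if (is.data.frame(path)) path else read_tsv(path)
  needed <- c("sample_id", "gene", "copy_number")
  if (!all(needed %in% names(side))) {
    stop("copy-number sidecar must have columns: ",
         paste(needed, collapse = ", "))
  }
  unknown <- setdiff(side$sample_id, cohort$sample_ids)
  if (length(unknown) > 0) {
    stop("copy-number sidecar names unknown sample(s): ",
         paste(unknown, collapse = ", "))
  }
  for (g in unique(side$gene)) {
    cn <- rep(2L, length(cohort$sample_ids))
    rows <- side[side$gene == g, ]
    cn[match(rows$sample_id, cohort$sample_ids)] <- as.integer(rows$copy_number)
    cohort$copy_number[[g]] <- cn
  }
  cohort
}

#' Write a cohort to a VCF file
#'
#' Emits a minimal VCF 4.2 with GT-only genotypes. Phased variants are
#' written with `|` separators from the haplotype matrices; unphased ones
#' with `/` from the dosage. `read_vcf(write_vcf(x))` is the identity on
#' dosages, phase flags and missingness.
#'
#' @param cohort a `pgx_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path) {
  v <- cohort$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pgxposure",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$sample_ids), collapse = "\t")
  )
  lines <- character(nrow(v))
  for (j in seq_len(nrow(v))) {
    if (cohort$phased[j]) {
      gt <- ifelse(is.na(cohort$a1[, j]) | is.na(cohort$a2[, j]), ".|.",
                   paste0(cohort$a1[, j], "|", cohort$a2[, j]))
    } else {
      d <- cohort$dosage[, j]
      gt <- c("0/0", "0/1", "1/1")[d + 1L]
      gt[is.na(d)] <- "./."
    }
    lines[j] <- paste(c(v$chrom[j], v$pos[j], v$rsid[j], v$ref[j], v$alt[j],
                        ".", "PASS", ".", "GT", gt), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write the copy-number side channel to a sidecar TSV
#'
#' @param cohort a `pgx_cohort`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_copy_number <- function(cohort, path) {
  rows <- do.call(rbind, lapply(names(cohort$copy_number), function(g) {
    data.frame(sample_id = cohort$sample_ids, gene = g,
               copy_number = cohort$copy_number[[g]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(sample_id = character(0), gene = character(0),
                       copy_number = integer(0))
  }
  write_tsv(rows, path)
}
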