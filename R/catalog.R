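# Reference catalog: allele definitions, diplotype-to-phenotype rules and
# drug-gene interactions for the 14 pharmacogenes / HLA haplo-groups covered
# by the analysis. The packaged fixture transcribes the published reference
# tables at printed precision; load_catalog() validates any user-supplied
# directory against the same schema.

.allele_functions <- c("normal", "decreased", "inactive", "increased",
                       "risk-tag", "non-carrier")

# Relative activity used by the conservative tie-break in unphased calling:
# lower combined activity is preferred so ambiguous samples are flagged as
# carriers rather than silently normalized.
.function_activity <- c(inactive = 0, decreased = 0.5, `risk-tag` = 0.5,
                        normal = 1, `non-carrier` = 1, increased = 1.5)

.catalog_files <- c("alleles.tsv", "phenotype_rules.tsv", "interactions.tsv",
                    "variants.tsv")

#' Load a pharmacogene catalog
#'
#' Reads and validates the allele-definition, phenotype-rule, variant and
#' drug-gene-interaction tables that drive star-allele calling, phenotype
#' translation and exposure attribution. With `path = NULL` the packaged
#' reference catalog (14 genes/haplo-groups, 13 drug-gene interaction rows)
#' is loaded.
#'
#' Validation is exhaustive: every schema violation found is reported, not
#' only the first.
#'
#' @param path directory containing `alleles.tsv`, `phenotype_rules.tsv`,
#'   `interactions.tsv` and `variants.tsv`; `NULL` for the packaged catalog.
#' @return an object of class `pgx_catalog`: a list with `genes` (named list
#'   of `pgx_gene_model`), `interactions` (data frame) and `variants`
#'   (data frame of rsid, chrom, pos, ref, alt).
#' @examples
#' cat14 <- load_catalog()
#' names(cat14$genes)
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("catalog")
  if (!dir.exists(path)) {
    stop("catalog directory does not exist: ", path)
  }
  missing <- .catalog_files[!file.exists(file.path(path, .catalog_files))]
  if (length(missing) > 0) {
    stop("catalog directory ", path, " is missing required files: ",
         paste(missing, collapse = ", "))
  }

  alleles <- read_tsv(file.path(path, "alleles.tsv"))
  rules <- read_tsv(file.path(path, "phenotype_rules.tsv"))
  interactions <- read_tsv(file.path(path, "interactions.tsv"))
  variants <- read_tsv(file.path(path, "variants.tsv"))

  genes <- lapply(unique(alleles$gene), function(g) {
    ga <- alleles[alleles$gene == g, , drop = FALSE]
    gr <- rules[rules$gene == g, , drop = FALSE]
    new_gene_model(
      gene = g,
      category = ga$category[1],
      alleles = data.frame(
        star_name = ga$star_name,
        fun = ga$`function`,
        freq = suppressWarnings(as.numeric(ga$maf)),
        stringsAsFactors = FALSE
      ),
      rsids = split_field(ga$rsids),
      risk_alleles = split_field(ga$risk_alleles),
      rules = data.frame(
        function_pair = gr$function_pair,
        copy_number = gr$copy_number,
        phenotype = gr$phenotype,
        stringsAsFactors = FALSE
      )
    )
  })
  names(genes) <- unique(alleles$gene)

  interactions$genes <- split_field(interactions$gene)
  interactions$drugs <- split_field(interactions$drug)
  interactions$actionable <- split_field(interactions$actionable_set, "+")

  catalog <- structure(
    list(genes = genes, interactions = interactions, variants = variants),
    class = "pgx_catalog"
  )
  problems <- validate_catalog(catalog)
  if (length(problems) > 0) {
    stop("invalid catalog (", length(problems), " problem(s)):\n  ",
         paste(problems, collapse = "\n  "))
  }
  catalog
}

# Construct a single gene model. The reference allele is the row with no
# defining variants; its frequency is the residual haplotype mass.
new_gene_model <- function(gene, category, alleles, rsids, risk_alleles,
                           rules) {
  alleles$rsids <- I(rsids)
  alleles$risk_alleles <- I(risk_alleles)
  alleles$is_reference <- lengths(rsids) == 0
  defined <- alleles[!alleles$is_reference, , drop = FALSE]
  if (any(alleles$is_reference)) {
    alleles$freq[alleles$is_reference] <-
      1 - sum(defined$freq, na.rm = TRUE)
  }
  structure(
    list(gene = gene, category = category, alleles = alleles, rules = rules,
         labels = unique(rules$phenotype)),
    class = "pgx_gene_model"
  )
}

#' Validate a catalog, collecting every violation
#'
#' @param catalog a `pgx_catalog`.
#' @return character vector of problems (empty when valid).
#' @export
validate_catalog <- function(catalog) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))

  known_rsids <- catalog$variants$rsid
  if (anyDuplicated(known_rsids)) {
    note("duplicated rsids in variants.tsv: ",
         paste(unique(known_rsids[duplicated(known_rsids)]), collapse = ", "))
  }
  for (g in catalog$genes) {
    al <- g$alleles
    if (sum(al$is_reference) != 1) {
      note(g$gene, ": expected exactly one reference allele (row with no ",
           "defining variants), found ", sum(al$is_reference))
    }
    if (anyDuplicated(al$star_name)) {
      note(g$gene, ": duplicated star_name")
    }
    bad_fun <- setdiff(unique(al$fun), .allele_functions)
    if (length(bad_fun) > 0) {
      note(g$gene, ": unknown allele function(s): ",
           paste(bad_fun, collapse = ", "))
    }
    defined <- al[!al$is_reference, , drop = FALSE]
    if (any(is.na(defined$freq)) || any(defined$freq < 0 | defined$freq > 1)) {
      note(g$gene, ": allele frequencies must be in [0, 1]")
    } else if (sum(defined$freq) > 1 + 1e-9) {
      note(g$gene, ": defined allele frequencies sum to ",
           format(sum(defined$freq)), " > 1")
    }
    for (i in seq_len(nrow(al))) {
      rs <- al$rsids[[i]]
      ra <- al$risk_alleles[[i]]
      if (length(rs) != length(ra)) {
        note(g$gene, " ", al$star_name[i],
             ": rsids and risk_alleles differ in length")
      }
      if (anyDuplicated(rs)) {
        note(g$gene, " ", al$star_name[i], ": duplicated defining rsid")
      }
      unknown <- setdiff(rs, known_rsids)
      if (length(unknown) > 0) {
        note(g$gene, " ", al$star_name[i], ": rsid(s) not in variants.tsv: ",
             paste(unknown, collapse = ", "))
      }
      bad <- setdiff(ra, c("A", "C", "G", "T", "del", "ins"))
      if (length(bad) > 0) {
        note(g$gene, " ", al$star_name[i], ": risk allele must be a base or ",
             "a del/ins token, got ", paste(bad, collapse = ", "))
      }
    }
    # phenotype rule must be total over unordered pairs of defined functions
    funs <- unique(al$fun)
    pairs <- outer(funs, funs, function(a, b) {
      mapply(function(x, y) paste(sort(c(x, y)), collapse = "+"), a, b)
    })
    needed <- unique(as.character(pairs))
    covered <- g$rules$function_pair[g$rules$copy_number == "any"]
    absent <- setdiff(needed, covered)
    if (length(absent) > 0) {
      note(g$gene, ": phenotype rule not total; missing function pair(s): ",
           paste(absent, collapse = ", "))
    }
    bad_cn <- setdiff(unique(g$rules$copy_number), c("any", "gt2"))
    if (length(bad_cn) > 0) {
      note(g$gene, ": unknown copy_number condition: ",
           paste(bad_cn, collapse = ", "))
    }
  }

  for (i in seq_len(nrow(catalog$interactions))) {
    row <- catalog$interactions[i, ]
    for (gn in row$genes[[1]]) {
      if (!gn %in% names(catalog$genes)) {
        note("interaction '", row$drug, "': unknown gene ", gn)
      } else {
        bad <- setdiff(row$actionable[[1]], catalog$genes[[gn]]$labels)
        if (length(bad) > 0) {
          note("interaction '", row$drug, "' (", gn,
               "): actionable label(s) outside the gene's phenotype set: ",
               paste(bad, collapse = ", "))
        }
      }
    }
    if (length(row$actionable[[1]]) == 0) {
      note("interaction '", row$drug, "': empty actionable set")
    }
  }
  problems
}

#' Write a catalog back to a directory of TSV files
#'
#' Inverse of [load_catalog()]: `load_catalog(write_catalog(x, dir))`
#' reproduces `x` field for field.
#'
#' @param catalog a `pgx_catalog`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  allele_rows <- do.call(rbind, lapply(catalog$genes, function(g) {
    al <- g$alleles
    data.frame(
      gene = g$gene, category = g$category, star_name = al$star_name,
      rsids = join_field(al$rsids), risk_alleles = join_field(al$risk_alleles),
      `function` = al$fun,
      maf = ifelse(al$is_reference, NA, al$freq),
      stringsAsFactors = FALSE, check.names = FALSE
    )
  }))
  write_tsv(allele_rows, file.path(path, "alleles.tsv"))
  rule_rows <- do.call(rbind, lapply(catalog$genes, function(g) {
    cbind(gene = g$gene, g$rules)
  }))
  write_tsv(rule_rows, file.path(path, "phenotype_rules.tsv"))
  ints <- catalog$interactions
  write_tsv(data.frame(
    drug = join_field(ints$drugs),
    gene = join_field(ints$genes),
    actionable_set = join_field(ints$actionable, "+"),
    therapeutic_area = ints$therapeutic_area,
    stringsAsFactors = FALSE
  ), file.path(path, "interactions.tsv"))
  write_tsv(catalog$variants, file.path(path, "variants.tsv"))
  invisible(path)
}

#' Fraction of a cohort carrying an actionable phenotype
#'
#' Sums phenotype frequencies over an actionable-phenotype set; this is the
#' "Column A" quantity that, multiplied by drug exposures, yields risky
#' exposures.
#'
#' @param phenotype_freqs named numeric vector of phenotype fractions
#'   (values in `[0, 1]`, summing to at most 1 plus tolerance).
#' @param actionable_set character vector of phenotype labels; must be
#'   non-empty and present in `phenotype_freqs`.
#' @return the summed fraction.
#' @examples
#' actionable_fraction(c(N = 0.649, I = 0.309, P = 0.042), c("I", "P"))
#' @export
actionable_fraction <- function(phenotype_freqs, actionable_set) {
  if (length(actionable_set) == 0) {
    stop("actionable_set must be non-empty")
  }
  if (any(phenotype_freqs < -1e-12 | phenotype_freqs > 1 + 1e-12)) {
    stop("phenotype frequencies must lie in [0, 1]")
  }
  if (sum(phenotype_freqs) > 1 + 0.005) {
    stop("phenotype frequencies sum to more than 1")
  }
  absent <- setdiff(actionable_set, names(phenotype_freqs))
  if (length(absent) > 0) {
    stop("actionable label(s) absent from phenotype frequencies: ",
         paste(absent, collapse = ", "))
  }
  sum(phenotype_freqs[actionable_set])
}

#' Published per-gene predicted phenotype frequencies
#'
#' The reference table of predicted phenotype frequencies for the 498-parent
#' Dutch cohort, transcribed at printed precision (long format: gene,
#' phenotype, freq). Carrier genes use `Het`/`Hom` in place of the
#' intermediate/poor columns.
#'
#' @return data frame with columns `gene`, `phenotype`, `freq`.
#' @export
reference_phenotype_frequencies <- function() {
  read_tsv(pkg_extdata("gonl", "phenotype_frequencies.tsv"))
}

#' Published per-variant allele frequencies and cohort comparison
#'
#' Reference metadata: per-variant minor allele frequencies in the
#' 498-parent cohort, the comparison cohort's frequencies, and the published
#' p-values (stored verbatim; several cannot be reproduced exactly because
#' the original counts and test are unpublished).
#'
#' @return data frame, one row per published variant row.
#' @export
reference_variant_frequencies <- function() {
  read_tsv(pkg_extdata("gonl", "table1_frequencies.tsv"))
}

#' @export
print.pgx_catalog <- function(x, ...) {
  cat("<pgx_catalog> ", length(x$genes), " genes, ",
      nrow(x$interactions), " drug-gene interactions, ",
      nrow(x$variants), " variants\n", sep = "")
  cat("  genes:", paste(names(x$genes), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.pgx_gene_model <- function(x, ...) {
  cat("<pgx_gene_model> ", x$gene, " (", x$category, ")\n", sep = "")
  ref <- x$alleles$star_name[x$alleles$is_reference]
  cat("  alleles: ",
      paste0(x$alleles$star_name, " [", x$alleles$fun, "]", collapse = ", "),
      "\n  reference: ", ref,
      "\n  phenotypes: ", paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}
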