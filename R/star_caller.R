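# Star-allele diplotype calling. Each sample's observed risk-allele dosages
# (or phased haplotypes) over a gene's defining variants are matched against
# the catalog's allele definitions. Defining-variant sets are treated as
# exhaustive: an observed pattern no allele pair can explain is a no-call,
# never a guess.

gene_rsids <- function(gene) {
  unique(unlist(gene$alleles$rsids))
}

# star -> function lookup for one gene
allele_fun_map <- function(gene) {
  setNames(gene$alleles$fun, gene$alleles$star_name)
}

reference_allele <- function(gene) {
  gene$alleles$star_name[gene$alleles$is_reference]
}

#' Resolve an unphased dosage pattern to a deterministic allele pair
#'
#' Enumerates every allele pair (including the reference allele) whose
#' combined risk-allele contributions reproduce the observed dosages
#' exactly, then applies a fixed precedence: (1) fewest distinct
#' non-reference alleles; (2) among ties, the pair with lower combined
#' functional activity (conservative: ambiguity flags more actionable
#' carriers); (3) lexicographic order of the pair label. An inconsistent
#' pattern (e.g. dosage 2 at one SNP of a two-SNP haplotype tag and 0 at the
#' other) yields a no-call.
#'
#' @param dosages named vector of risk-allele dosages (0/1/2), complete
#'   over the gene's defining rsIDs.
#' @param gene a `pgx_gene_model`.
#' @return list with `allele_1`, `allele_2` (NA for no-call) and
#'   `call_quality` (`"exact"`, `"resolved-unphased"` or `"no-call"`).
#' @examples
#' cat14 <- load_catalog()
#' resolve_unphased(
#'   c(rs16947 = 0, rs3892097 = 1, rs1065852 = 1, rs28371706 = 0,
#'     rs28371725 = 0, rs72549346 = 0),
#'   cat14$genes$CYP2D6
#' )
#' @export
resolve_unphased <- function(dosages, gene) {
  rs <- gene_rsids(gene)
  if (!all(rs %in% names(dosages))) {
    stop("dosage map incomplete for ", gene$gene, ": missing ",
         paste(setdiff(rs, names(dosages)), collapse = ", "))
  }
  obs <- as.integer(dosages[rs])
  if (any(is.na(obs))) {
    return(list(allele_1 = NA_character_, allele_2 = NA_character_,
                call_quality = "no-call"))
  }
  al <- gene$alleles
  memb <- vapply(al$rsids, function(r) as.integer(rs %in% r),
                 integer(length(rs)))
  memb <- matrix(memb, nrow = length(rs))  # rs x alleles
  k <- nrow(al)
  cand <- list()
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (all(memb[, i] + memb[, j] == obs)) {
        cand[[length(cand) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(cand) == 0) {
    return(list(allele_1 = NA_character_, allele_2 = NA_character_,
                call_quality = "no-call"))
  }
  n_nonref <- vapply(cand, function(p) sum(!al$is_reference[p]), numeric(1))
  activity <- vapply(cand, function(p) {
    sum(.function_activity[al$fun[p]])
  }, numeric(1))
  label <- vapply(cand, function(p) {
    paste(sort(al$star_name[p]), collapse = "/")
  }, character(1))
  best <- cand[[order(n_nonref, activity, label)[1]]]
  pair <- order_allele_pair(al$star_name[best[1]], al$star_name[best[2]],
                            reference_allele(gene))
  list(allele_1 = pair[1], allele_2 = pair[2],
       call_quality = if (length(cand) == 1) "exact" else "resolved-unphased")
}

# Report non-reference allele first, then lexicographic.
order_allele_pair <- function(a, b, ref) {
  pair <- c(a, b)
  is_ref <- pair == ref
  pair[order(is_ref, pair)]
}

#' Call per-sample diplotypes for one gene
#'
#' For variants phased across the cohort the caller is exact: each
#' haplotype's risk-allele set must equal a catalog allele's defining set
#' (the empty set being the reference allele). Otherwise dosage patterns are
#' resolved by [resolve_unphased()]. A sample with a missing genotype at any
#' defining variant is a no-call; no imputation is attempted. Copy number is
#' taken from the cohort's side channel (default 2) and attached to the call
#' without altering allele assignment.
#'
#' @param cohort a `pgx_cohort`.
#' @param gene a `pgx_gene_model`.
#' @return data frame: `sample_id`, `gene`, `allele_1`, `allele_2`,
#'   `copy_number`, `call_quality`.
#' @export
call_diplotypes <- function(cohort, gene) {
  rs <- gene_rsids(gene)
  n <- length(cohort$sample_ids)
  have <- intersect(rs, colnames(cohort$dosage))
  D <- matrix(NA_integer_, n, length(rs),
              dimnames = list(cohort$sample_ids, rs))
  if (length(have) > 0) D[, have] <- cohort$dosage[, have, drop = FALSE]
  cn <- cohort$copy_number[[gene$gene]] %||% rep(2L, n)

  fully_phased <- length(have) == length(rs) && all(cohort$phased[rs])
  if (fully_phased) {
    res <- call_phased(cohort, gene, rs)
  } else {
    res <- call_from_dosage(D, gene, rs)
  }
  data.frame(sample_id = cohort$sample_ids, gene = gene$gene,
             allele_1 = res$allele_1, allele_2 = res$allele_2,
             copy_number = cn, call_quality = res$call_quality,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Exact per-haplotype matching on phased data. Haplotype patterns are
# encoded as bit codes over the gene's defining variants so matching is a
# single lookup rather than per-sample set comparison.
call_phased <- function(cohort, gene, rs) {
  al <- gene$alleles
  w <- 2^(seq_along(rs) - 1)
  allele_code <- vapply(al$rsids, function(r) sum(w[rs %in% r]), numeric(1))
  if (anyDuplicated(allele_code)) {
    stop(gene$gene, ": allele definitions are not distinguishable")
  }
  code_of <- function(H) as.vector(H %*% w)
  H1 <- cohort$a1[, rs, drop = FALSE]
  H2 <- cohort$a2[, rs, drop = FALSE]
  miss <- rowSums(is.na(H1)) > 0 | rowSums(is.na(H2)) > 0
  H1[is.na(H1)] <- 0L; H2[is.na(H2)] <- 0L
  i1 <- match(code_of(H1), allele_code)
  i2 <- match(code_of(H2), allele_code)
  ok <- !miss & !is.na(i1) & !is.na(i2)
  a1 <- a2 <- rep(NA_character_, nrow(H1))
  ref <- reference_allele(gene)
  if (any(ok)) {
    pairs <- mapply(function(x, y) order_allele_pair(x, y, ref),
                    al$star_name[i1[ok]], al$star_name[i2[ok]])
    a1[ok] <- pairs[1, ]
    a2[ok] <- pairs[2, ]
  }
  list(allele_1 = a1, allele_2 = a2,
       call_quality = ifelse(ok, "exact", "no-call"))
}

# Unphased path: resolve each distinct dosage pattern once, then map back.
call_from_dosage <- function(D, gene, rs) {
  key <- apply(D, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  resolved <- lapply(which(uniq), function(i) {
    resolve_unphased(setNames(D[i, ], rs), gene)
  })
  names(resolved) <- key[uniq]
  a1 <- vapply(resolved[key], `[[`, character(1), "allele_1")
  a2 <- vapply(resolved[key], `[[`, character(1), "allele_2")
  q <- vapply(resolved[key], `[[`, character(1), "call_quality")
  list(allele_1 = unname(a1), allele_2 = unname(a2),
       call_quality = unname(q))
}

#' Call diplotypes for every catalog gene
#'
#' @param cohort a `pgx_cohort`.
#' @param catalog a `pgx_catalog`.
#' @return row-bound data frame of [call_diplotypes()] results.
#' @export
call_all_diplotypes <- function(cohort, catalog) {
  do.call(rbind, lapply(catalog$genes, function(g) {
    call_diplotypes(cohort, g)
  }))
}
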