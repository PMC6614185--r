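# Diplotype-to-phenotype translation and actionable-genotype aggregation.
# Each gene carries its own rule table mapping unordered pairs of allele
# functions (optionally conditioned on copy number > 2) to a phenotype
# label: metabolizer categories N/I/P/U for enzyme-like genes, carrier
# categories N/Het/Hom for risk-tag genes.

#' Translate diplotypes into predicted phenotypes
#'
#' @param allele_1,allele_2 star-allele names (vectors); `NA` for no-call.
#' @param copy_number integer vector of gene copy numbers (default 2).
#' @param gene a `pgx_gene_model`.
#' @return character vector of phenotype labels; `NA` where the diplotype
#'   is a no-call.
#' @examples
#' cat14 <- load_catalog()
#' translate_phenotype("*4", "*4", 2, cat14$genes$CYP2D6)   # "P"
#' translate_phenotype("*1", "*1", 3, cat14$genes$CYP2D6)   # "U"
#' @export
translate_phenotype <- function(allele_1, allele_2, copy_number = 2L, gene) {
  allele_1 <- as.character(allele_1)
  allele_2 <- as.character(allele_2)
  fun_of <- allele_fun_map(gene)
  bad <- setdiff(stats::na.omit(c(allele_1, allele_2)), names(fun_of))
  if (length(bad) > 0) {
    stop(gene$gene, ": unknown allele(s): ", paste(bad, collapse = ", "))
  }
  n <- max(length(allele_1), length(allele_2))
  copy_number <- rep_len(copy_number, n)
  f1 <- fun_of[allele_1]
  f2 <- fun_of[allele_2]
  key <- ifelse(is.na(f1) | is.na(f2), NA_character_,
                paste(pmin(f1, f2), pmax(f1, f2), sep = "+"))
  rules <- gene$rules
  any_map <- setNames(rules$phenotype[rules$copy_number == "any"],
                      rules$function_pair[rules$copy_number == "any"])
  gt2_map <- setNames(rules$phenotype[rules$copy_number == "gt2"],
                      rules$function_pair[rules$copy_number == "gt2"])
  out <- unname(any_map[key])
  amplified <- !is.na(key) & copy_number > 2L & key %in% names(gt2_map)
  out[amplified] <- unname(gt2_map[key[amplified]])
  if (any(!is.na(key) & is.na(out))) {
    stop(gene$gene, ": no phenotype rule for function pair(s): ",
         paste(unique(key[!is.na(key) & is.na(out)]), collapse = ", "))
  }
  out
}

#' Translate a table of diplotype calls
#'
#' Adds a `phenotype` column to the output of [call_diplotypes()] /
#' [call_all_diplotypes()].
#'
#' @param calls data frame with `gene`, `allele_1`, `allele_2`,
#'   `copy_number` columns.
#' @param catalog a `pgx_catalog`.
#' @return `calls` with a `phenotype` column appended.
#' @export
translate_diplotypes <- function(calls, catalog) {
  calls$phenotype <- NA_character_
  for (g in unique(calls$gene)) {
    idx <- calls$gene == g
    gm <- catalog$genes[[g]]
    if (is.null(gm)) stop("gene not in catalog: ", g)
    calls$phenotype[idx] <- translate_phenotype(
      calls$allele_1[idx], calls$allele_2[idx], calls$copy_number[idx], gm)
  }
  calls
}

#' Cohort phenotype frequencies for one gene
#'
#' Fractions are taken over non-missing calls; the number of no-calls is
#' reported as an attribute.
#'
#' @param calls data frame with `gene` and `phenotype` columns.
#' @param gene gene symbol.
#' @return named numeric vector of fractions summing to 1, with attribute
#'   `n_missing`.
#' @export
phenotype_frequencies <- function(calls, gene) {
  ph <- calls$phenotype[calls$gene == gene]
  n_missing <- sum(is.na(ph))
  ph <- ph[!is.na(ph)]
  if (length(ph) == 0) stop(gene, ": no non-missing phenotype calls")
  tab <- table(ph)
  out <- as.numeric(tab) / length(ph)
  names(out) <- names(tab)
  attr(out, "n_missing") <- n_missing
  out
}

# Per-gene union of actionable phenotype labels over all interactions that
# involve the gene.
gene_actionable_sets <- function(catalog) {
  sets <- setNames(vector("list", length(catalog$genes)),
                   names(catalog$genes))
  for (i in seq_len(nrow(catalog$interactions))) {
    row <- catalog$interactions[i, ]
    for (g in row$genes[[1]]) {
      sets[[g]] <- union(sets[[g]], row$actionable[[1]])
    }
  }
  sets
}

#' Per-sample, per-interaction actionable flags
#'
#' A sample is actionable for a drug-gene interaction when its predicted
#' phenotype at any of the interaction's genes lies in the interaction's
#' actionable set. Missing phenotypes never flag.
#'
#' @param calls translated calls (see [translate_diplotypes()]).
#' @param catalog a `pgx_catalog`.
#' @return logical matrix, samples x interactions (columns named by drug).
#' @export
actionable_flags <- function(calls, catalog) {
  samples <- unique(calls$sample_id)
  ints <- catalog$interactions
  out <- matrix(FALSE, length(samples), nrow(ints),
                dimnames = list(samples, join_field(ints$drugs)))
  for (i in seq_len(nrow(ints))) {
    set <- ints$actionable[[i]]
    for (g in ints$genes[[i]]) {
      sub <- calls[calls$gene == g, ]
      hit <- sub$sample_id[!is.na(sub$phenotype) & sub$phenotype %in% set]
      out[match(hit, samples), i] <- TRUE
    }
  }
  out
}

#' Distribution of per-individual actionable-genotype counts
#'
#' Counts, for every sample, the number of catalog genes whose predicted
#' phenotype lies in that gene's (union) actionable set, and histograms the
#' counts. A no-call gene contributes zero; per-sample completeness is
#' reported alongside.
#'
#' @param calls translated calls over all genes.
#' @param catalog a `pgx_catalog`.
#' @return object of class `pgx_carriage`: list with `counts` (named vector
#'   over k = 0..n_genes), `fraction`, `n_total`, and `per_sample` (data
#'   frame: sample_id, k, n_gene_missing).
#' @export
carriage_distribution <- function(calls, catalog) {
  sets <- gene_actionable_sets(catalog)
  samples <- unique(calls$sample_id)
  k <- setNames(integer(length(samples)), samples)
  miss <- setNames(integer(length(samples)), samples)
  for (g in names(sets)) {
    sub <- calls[calls$gene == g, ]
    idx <- match(sub$sample_id, samples)
    hit <- !is.na(sub$phenotype) & sub$phenotype %in% sets[[g]]
    k[idx] <- k[idx] + hit
    miss[idx] <- miss[idx] + is.na(sub$phenotype)
  }
  n_genes <- length(sets)
  counts <- setNames(integer(n_genes + 1), 0:n_genes)
  tab <- table(k)
  counts[names(tab)] <- as.integer(tab)
  structure(
    list(counts = counts, fraction = counts / length(samples),
         n_total = length(samples),
         per_sample = data.frame(sample_id = samples, k = unname(k),
                                 n_gene_missing = unname(miss),
                                 stringsAsFactors = FALSE)),
    class = "pgx_carriage"
  )
}

#' @export
print.pgx_carriage <- function(x, ...) {
  cat("<pgx_carriage> n =", x$n_total, "\n")
  nz <- x$counts[x$counts > 0 | as.integer(names(x$counts)) <= 5]
  print(data.frame(k = names(nz), count = as.integer(nz),
                   pct = round(100 * nz / x$n_total, 1), row.names = NULL))
  invisible(x)
}

#' Closed-form phenotype frequencies under Hardy-Weinberg equilibrium
#'
#' Enumerates all diplotypes from the gene's allele frequencies (reference
#' allele taking the residual mass), applies the gene's phenotype rule, and
#' accumulates probabilities; optionally mixes in a gene-amplification
#' fraction (copy number 3) for ultrarapid phenotypes. This is the analytic
#' expectation the cohort simulator converges to, and serves as the
#' independent oracle for simulation-based tests.
#'
#' @param gene a `pgx_gene_model`.
#' @param dup_fraction probability that an individual carries a duplicated
#'   gene copy (copy number 3).
#' @return named numeric vector of phenotype probabilities summing to 1.
#' @export
expected_phenotype_freqs <- function(gene, dup_fraction = 0) {
  al <- gene$alleles
  p <- al$freq
  if (any(p < -1e-9)) stop(gene$gene, ": negative residual allele frequency")
  out <- setNames(numeric(length(gene$labels)), gene$labels)
  for (i in seq_along(p)) {
    for (j in i:length(p)) {
      prob <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
      if (prob == 0) next
      ph2 <- translate_phenotype(al$star_name[i], al$star_name[j], 2L, gene)
      if (dup_fraction > 0) {
        ph3 <- translate_phenotype(al$star_name[i], al$star_name[j], 3L, gene)
        out[ph2] <- out[ph2] + prob * (1 - dup_fraction)
        out[ph3] <- out[ph3] + prob * dup_fraction
      } else {
        out[ph2] <- out[ph2] + prob
      }
    }
  }
  out
}
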