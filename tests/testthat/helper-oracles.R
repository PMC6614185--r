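# Shared helpers: independent brute-force oracles and small constructors.
# The oracles re-derive expectations from the allele tables by direct
# enumeration, independently of the package's calling/translation code.

# All unordered allele pairs of a gene consistent with a dosage pattern,
# enumerated directly from the rsid lists.
brute_force_consistent_pairs <- function(dosages, gene) {
  al <- gene$alleles
  rs <- names(dosages)
  pairs <- list()
  for (i in seq_len(nrow(al))) {
    for (j in i:nrow(al)) {
      pred <- vapply(rs, function(r) {
        (r %in% al$rsids[[i]]) + (r %in% al$rsids[[j]])
      }, numeric(1))
      if (all(pred == dosages)) {
        pairs[[length(pairs) + 1]] <- sort(c(al$star_name[i],
                                             al$star_name[j]))
      }
    }
  }
  pairs
}

# Build a one-gene unphased cohort directly from a dosage matrix.
cohort_from_dosages <- function(dosage, rsids, catalog) {
  v <- catalog$variants[match(rsids, catalog$variants$rsid), ]
  new_cohort(sprintf("T%03d", seq_len(nrow(dosage))), v, dosage)
}

# Dosage vector covering every defining rsID of a gene, zero except where
# overridden.
gene_dosage <- function(gene, ...) {
  rs <- unique(unlist(gene$alleles$rsids))
  d <- setNames(rep(0, length(rs)), rs)
  over <- c(...)
  d[names(over)] <- over
  d
}

diplotype_key <- function(df) {
  paste(df$sample_id, df$gene, df$allele_1, df$allele_2)
}

# Unphased cohort covering all catalog variants for a set of per-rsid
# dosage assignments (one named list element per sample).
catalog_cohort <- function(catalog, sample_dosages) {
  m <- nrow(catalog$variants)
  n <- length(sample_dosages)
  D <- matrix(0L, n, m, dimnames = list(names(sample_dosages),
                                        catalog$variants$rsid))
  for (s in seq_len(n)) {
    d <- sample_dosages[[s]]
    D[s, names(d)] <- as.integer(d)
  }
  new_cohort(names(sample_dosages), catalog$variants, D)
}
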