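cat14 <- load_catalog()
cyp2d6 <- cat14$genes$CYP2D6
b5701 <- cat14$genes$`HLA-B*57:01`
b1502 <- cat14$genes$`HLA-B*15:02`
tpmt <- cat14$genes$TPMT

test_that("unambiguous dosage patterns force the diplotype", {
  # homozygous inactive variant: *4/*4 (the *4 haplotype carries the
  # decreased allele's SNP as well, so both SNPs read dosage 2)
  res <- resolve_unphased(gene_dosage(cyp2d6, rs3892097 = 2, rs1065852 = 2),
                          cyp2d6)
  expect_equal(res$allele_1, "*4")
  expect_equal(res$allele_2, "*4")
  expect_equal(res$call_quality, "exact")

  # single-copy HLA tag SNP: heterozygous carrier
  res <- resolve_unphased(gene_dosage(b5701, rs2395029 = 1), b5701)
  expect_equal(res$allele_1, "B*57:01")
  expect_equal(res$allele_2, "non-carrier")

  # all-reference pattern
  res <- resolve_unphased(gene_dosage(cyp2d6), cyp2d6)
  expect_equal(c(res$allele_1, res$allele_2), c("*1", "*1"))
  expect_equal(res$call_quality, "exact")
})

test_that("resolution agrees with brute-force enumeration and precedence", {
  # one copy of each CYP2D6 SNP pair: explainable as *4/*1 (one non-ref
  # allele) or *10 plus an impossible partner; enumeration must find *4/*1
  d <- gene_dosage(cyp2d6, rs3892097 = 1, rs1065852 = 1)
  pairs <- brute_force_consistent_pairs(d, cyp2d6)
  expect_true(any(vapply(pairs, identical, logical(1), c("*1", "*4"))))
  res <- resolve_unphased(d, cyp2d6)
  expect_equal(sort(c(res$allele_1, res$allele_2)), c("*1", "*4"))

  # TPMT 460G>A + 719A>G single copies: *3A/*1 (one non-reference allele)
  # wins over *3B/*3C (two) under precedence rule 1
  d <- gene_dosage(tpmt, rs1800460 = 1, rs1142345 = 1)
  pairs <- brute_force_consistent_pairs(d, tpmt)
  expect_setequal(vapply(pairs, paste, character(1), collapse = "/"),
                  c("*1/*3A", "*3B/*3C"))
  res <- resolve_unphased(d, tpmt)
  expect_equal(sort(c(res$allele_1, res$allele_2)), c("*1", "*3A"))
  expect_equal(res$call_quality, "resolved-unphased")
})

test_that("inconsistent patterns yield no-call, never a guess", {
  # two-SNP tag with homozygous first SNP but absent second SNP
  res <- resolve_unphased(gene_dosage(b1502, rs3909184 = 2, rs2844682 = 0),
                          b1502)
  expect_equal(res$call_quality, "no-call")
  expect_true(is.na(res$allele_1))
  # unbalanced tag dosages are equally unexplainable
  res <- resolve_unphased(gene_dosage(b1502, rs3909184 = 2, rs2844682 = 1),
                          b1502)
  expect_equal(res$call_quality, "no-call")
})

test_that("any returned pair reproduces the observed dosages", {
  set.seed(11)
  rs <- unique(unlist(cyp2d6$alleles$rsids))
  for (rep in 1:40) {
    d <- setNames(sample(0:2, length(rs), replace = TRUE), rs)
    res <- resolve_unphased(d, cyp2d6)
    if (res$call_quality == "no-call") {
      expect_length(brute_force_consistent_pairs(d, cyp2d6), 0)
    } else {
      al <- cyp2d6$alleles
      r1 <- al$rsids[[match(res$allele_1, al$star_name)]]
      r2 <- al$rsids[[match(res$allele_2, al$star_name)]]
      pred <- vapply(rs, function(r) (r %in% r1) + (r %in% r2), numeric(1))
      expect_equal(unname(pred), unname(d[names(pred)]))
    }
  }
})

test_that("phased calling recovers generator truth exactly", {
  sim <- simulate_cohort(simulation_config(500, seed = 2), cat14)
  calls <- call_all_diplotypes(sim$cohort, cat14)
  expect_true(all(calls$call_quality == "exact"))
  expect_equal(sort(diplotype_key(calls)), sort(diplotype_key(sim$truth)))
})

test_that("unphased calling recovers truth for nearly all samples", {
  sim <- simulate_cohort(
    simulation_config(500, seed = 2, phased_output = FALSE), cat14)
  calls <- call_all_diplotypes(sim$cohort, cat14)
  expect_true(all(calls$call_quality != "no-call"))
  hit <- diplotype_key(calls) %in% diplotype_key(sim$truth)
  expect_gte(mean(hit), 0.99)
  # every discrepancy must be flagged as an ambiguity resolution
  expect_true(all(calls$call_quality[!hit] == "resolved-unphased"))
})

test_that("sample order permutation permutes calls identically", {
  sim <- simulate_cohort(
    simulation_config(40, seed = 9, phased_output = FALSE), cat14)
  ch <- sim$cohort
  perm <- sample(seq_along(ch$sample_ids))
  ch2 <- new_cohort(ch$sample_ids[perm], ch$variants,
                    ch$dosage[perm, , drop = FALSE],
                    phased = unname(ch$phased),
                    copy_number = lapply(ch$copy_number, `[`, perm))
  c1 <- call_diplotypes(ch, cyp2d6)
  c2 <- call_diplotypes(ch2, cyp2d6)
  expect_equal(c2[order(c2$sample_id), -1],
               c1[order(c1$sample_id), -1], ignore_attr = TRUE)
})

test_that("missing genotypes propagate to no-call", {
  D <- matrix(c(1L, NA_integer_), 1, 2,
              dimnames = list("T001", c("rs1800460", "rs1142345")))
  sub <- cat14$variants[match(colnames(D), cat14$variants$rsid), ]
  ch <- new_cohort("T001", sub, D)
  calls <- call_diplotypes(ch, tpmt)
  expect_equal(calls$call_quality, "no-call")
  expect_true(is.na(calls$allele_1))
})
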