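cat14 <- load_catalog()

test_that("packaged catalog holds the expected genes and interactions", {
  expect_length(cat14$genes, 14)
  expect_setequal(
    names(cat14$genes),
    c("CYP3A5", "CYP2B6", "CYP2C9", "CYP2C19", "CYP2D6", "DPYD", "FVL",
      "HLA-A*31:01", "HLA-B*15:02", "HLA-B*57:01", "HLA-B*5801",
      "SLCO1B1", "TPMT", "VKORC1")
  )
  expect_equal(nrow(cat14$interactions), 13)
  # every interaction references catalog genes and valid labels (validated
  # at load; a malformed catalog must fail loudly, see below)
  expect_s3_class(cat14, "pgx_catalog")
})

test_that("published phenotype frequencies sum to one per gene", {
  ref <- reference_phenotype_frequencies()
  sums <- tapply(ref$freq, ref$gene, sum)
  expect_true(all(abs(sums - 1) <= 0.002))
  expect_setequal(names(sums), names(cat14$genes))
})

test_that("per-SNP marginal frequencies reproduce the published table", {
  # haplotype frequencies in the allele fixture must marginalise to the
  # published per-variant MAFs, including the nested definitions (the
  # inactive CYP2D6 allele carries the decreased allele's SNP; the TPMT
  # double-variant allele carries both single-variant SNPs)
  tab1 <- reference_variant_frequencies()
  marginal <- function(rsid) {
    total <- 0
    for (g in cat14$genes) {
      al <- g$alleles
      hit <- vapply(al$rsids, function(r) rsid %in% r, logical(1))
      total <- total + sum(al$freq[hit & !al$is_reference])
    }
    total
  }
  single <- tab1[!grepl(";", tab1$rsids), ]
  for (i in seq_len(nrow(single))) {
    expect_equal(marginal(single$rsids[i]), single$maf_gonl[i],
                 tolerance = 1e-9,
                 label = paste("marginal MAF of", single$rsids[i]))
  }
  # two-SNP haplotypes (HLA tags, TPMT *3A) are stored at the printed
  # haplotype frequency directly
  multi <- tab1[grepl(";", tab1$rsids), ]
  for (i in seq_len(nrow(multi))) {
    al <- cat14$genes[[multi$gene[i]]]$alleles
    expect_equal(al$freq[al$star_name == multi$star_name[i]],
                 multi$maf_gonl[i], tolerance = 1e-9,
                 label = paste("haplotype frequency of", multi$star_name[i]))
  }
})

test_that("actionable_fraction sums the requested labels and validates", {
  expect_equal(actionable_fraction(c(N = 0.649, I = 0.309, P = 0.042),
                                   c("I", "P")), 0.351)
  expect_equal(actionable_fraction(c(N = 0.930, I = 0.050, P = 0.020),
                                   c("I", "P")), 0.070)
  f <- c(N = 0.6, I = 0.3, P = 0.1)
  expect_equal(actionable_fraction(f, names(f)), 1)
  expect_error(actionable_fraction(f, character(0)), "non-empty")
  expect_error(actionable_fraction(f, c("I", "X")), "absent")
  expect_error(actionable_fraction(c(N = 0.9, I = 0.4), "I"), "more than 1")
  # monotone: enlarging the set never decreases the fraction
  set.seed(42)
  for (rep in 1:20) {
    sub <- sample(names(f), sample(1:2, 1))
    sup <- union(sub, sample(names(f), 1))
    expect_gte(actionable_fraction(f, sup), actionable_fraction(f, sub))
  }
})

test_that("catalog validation is exhaustive and names offenders", {
  src <- system.file("extdata", "catalog", package = "pgxposure")
  bad <- file.path(tempfile("cat"), "catalog")
  dir.create(bad, recursive = TRUE)
  file.copy(list.files(src, full.names = TRUE), bad)

  # an unknown phenotype label AND an unknown gene must both be reported
  ints <- read.delim(file.path(bad, "interactions.tsv"), check.names = FALSE)
  ints$actionable_set[ints$gene == "TPMT"] <- "X+P"
  ints$gene[ints$gene == "CYP2B6"] <- "NOSUCHGENE"
  write.table(ints, file.path(bad, "interactions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  err <- expect_error(load_catalog(bad), "2 problem")
  expect_match(conditionMessage(err), "NOSUCHGENE")
  expect_match(conditionMessage(err), "X")

  # the packaged TPMT set {I, P} is accepted (loaded at top of file)
  tpmt_int <- cat14$interactions[
    vapply(cat14$interactions$genes, function(g) "TPMT" %in% g, logical(1)), ]
  expect_setequal(tpmt_int$actionable[[1]], c("I", "P"))

  # an empty directory enumerates the required files
  empty <- tempfile("empty")
  dir.create(empty)
  err <- expect_error(load_catalog(empty), "missing required files")
  for (f in c("alleles.tsv", "phenotype_rules.tsv", "interactions.tsv")) {
    expect_match(conditionMessage(err), f, fixed = TRUE)
  }
})

test_that("catalog round-trips through write_catalog", {
  dir <- tempfile("roundtrip")
  write_catalog(cat14, dir)
  back <- load_catalog(dir)
  expect_equal(names(back$genes), names(cat14$genes))
  for (g in names(cat14$genes)) {
    a0 <- cat14$genes[[g]]$alleles
    a1 <- back$genes[[g]]$alleles
    expect_equal(a1$star_name, a0$star_name)
    expect_equal(a1$fun, a0$fun)
    expect_equal(a1$freq, a0$freq)
    expect_equal(unclass(a1$rsids), unclass(a0$rsids),
                 ignore_attr = TRUE)
    expect_equal(back$genes[[g]]$rules, cat14$genes[[g]]$rules,
                 ignore_attr = TRUE)
  }
  expect_equal(back$interactions$actionable, cat14$interactions$actionable,
               ignore_attr = TRUE)
  expect_equal(back$variants, cat14$variants, ignore_attr = TRUE)
})
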