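cat14 <- load_catalog()

test_that("diplotypes translate by the per-gene rules", {
  cyp2d6 <- cat14$genes$CYP2D6
  expect_equal(translate_phenotype("*4", "*4", 2, cyp2d6), "P")
  expect_equal(translate_phenotype("*1", "*4", 2, cyp2d6), "I")
  expect_equal(translate_phenotype("*10", "*41", 2, cyp2d6), "I")
  # a decreased allele next to a functional one stays a normal metabolizer
  # under the activity-score convention
  expect_equal(translate_phenotype("*1", "*41", 2, cyp2d6), "N")
  # gene duplication of a functional diplotype -> ultrarapid; duplication
  # never rescues a poor metabolizer
  expect_equal(translate_phenotype("*1", "*1", 3, cyp2d6), "U")
  expect_equal(translate_phenotype("*4", "*4", 3, cyp2d6), "P")

  cyp2c19 <- cat14$genes$CYP2C19
  expect_equal(translate_phenotype("*2", "*17", 2, cyp2c19), "I")
  expect_equal(translate_phenotype("*17", "*17", 2, cyp2c19), "U")
  expect_equal(translate_phenotype("*1", "*17", 2, cyp2c19), "N")

  vkorc1 <- cat14$genes$VKORC1
  expect_equal(translate_phenotype("*2", "*2", 2, vkorc1), "P")
  expect_equal(translate_phenotype("*1", "*2", 2, vkorc1), "I")

  expect_equal(translate_phenotype("B*57:01", "non-carrier", 2,
                                   cat14$genes$`HLA-B*57:01`), "Het")
  expect_true(is.na(translate_phenotype(NA, NA, 2, cyp2d6)))
  expect_error(translate_phenotype("*99", "*1", 2, cyp2d6), "unknown")
})

test_that("phenotype frequencies are fractions over non-missing calls", {
  calls <- data.frame(
    sample_id = sprintf("S%d", 1:4), gene = "TPMT",
    phenotype = c("P", NA, "N", "N"), stringsAsFactors = FALSE
  )
  f <- phenotype_frequencies(calls, "TPMT")
  expect_equal(unclass(f)[c("N", "P")], c(N = 2 / 3, P = 1 / 3),
               ignore_attr = TRUE)
  expect_equal(attr(f, "n_missing"), 1L)
  expect_equal(sum(f), 1)

  single <- data.frame(sample_id = "S1", gene = "TPMT", phenotype = "P")
  expect_equal(as.numeric(phenotype_frequencies(single, "TPMT")), 1)
})

test_that("simulated cohort frequencies match the HWE closed form", {
  sim <- simulate_cohort(simulation_config(498, seed = 4), cat14)
  calls <- translate_diplotypes(call_all_diplotypes(sim$cohort, cat14),
                                cat14)
  obs <- phenotype_frequencies(calls, "CYP2C9")
  exp <- expected_phenotype_freqs(cat14$genes$CYP2C9)  # (.64, .32, .04)
  for (lab in names(exp)) {
    se <- sqrt(exp[lab] * (1 - exp[lab]) / 498)
    o <- if (lab %in% names(obs)) obs[[lab]] else 0
    expect_lt(abs(o - exp[[lab]]), 3 * se + 1e-12)
  }
  # an all-reference cohort is uniformly normal
  zero <- setNames(rep(0, nrow(cat14$variants)), cat14$variants$rsid)
  ref <- simulate_cohort(
    simulation_config(50, seed = 1, maf_overrides = zero,
                      cyp2d6_dup_fraction = 0), cat14)
  ref_calls <- translate_diplotypes(
    call_all_diplotypes(ref$cohort, cat14), cat14)
  expect_equal(as.numeric(phenotype_frequencies(ref_calls, "CYP2C9")), 1)
  expect_equal(names(phenotype_frequencies(ref_calls, "CYP2C9")), "N")
})

test_that("carriage distribution counts actionable genes per individual", {
  genes <- names(cat14$genes)
  # the baseline non-actionable profile: normal/non-carrier everywhere
  # EXCEPT CYP3A5, where the non-expresser (P) is the benign category and
  # expressers (N, I) are the actionable ones
  normals <- setNames(rep("N", length(genes)), genes)
  normals["CYP3A5"] <- "P"
  mk_calls <- function(sample_id, phen) {
    data.frame(sample_id = sample_id, gene = names(phen),
               phenotype = unname(phen), stringsAsFactors = FALSE)
  }
  # everyone normal/non-carrier: all mass at k = 0
  calls <- rbind(mk_calls("A", normals), mk_calls("B", normals))
  cd <- carriage_distribution(calls, cat14)
  expect_equal(unname(cd$counts["0"]), 2L)
  expect_equal(sum(cd$counts), cd$n_total)

  # one poor metabolizer + one intermediate: k = 2 for that sample
  two <- normals
  two["CYP2D6"] <- "P"
  two["TPMT"] <- "I"
  cd <- carriage_distribution(rbind(mk_calls("A", two),
                                    mk_calls("B", normals)), cat14)
  expect_equal(cd$per_sample$k[cd$per_sample$sample_id == "A"], 2L)
  expect_equal(unname(cd$counts[c("0", "2")]), c(1L, 1L))

  # VKORC1 intermediate is NOT actionable (only poor is); CYP3A5 normal IS
  # (expresser logic)
  vk <- normals
  vk["VKORC1"] <- "I"
  cd <- carriage_distribution(mk_calls("A", vk), cat14)
  expect_equal(cd$per_sample$k, 0L)
  cyp3a5 <- normals
  cyp3a5["CYP3A5"] <- "N"   # expresser: actionable for the CYP3A5 drug
  cd1 <- carriage_distribution(mk_calls("A", cyp3a5), cat14)
  expect_equal(cd1$per_sample$k, 1L)

  # missing phenotypes contribute zero but are counted as incomplete
  miss <- normals
  miss["TPMT"] <- NA
  cd <- carriage_distribution(mk_calls("A", miss), cat14)
  expect_equal(cd$per_sample$n_gene_missing, 1L)
})

test_that("few individuals carry zero actionable genotypes under HWE", {
  sim <- simulate_cohort(simulation_config(498, seed = 5), cat14)
  calls <- translate_diplotypes(call_all_diplotypes(sim$cohort, cat14),
                                cat14)
  cd <- carriage_distribution(calls, cat14)
  # independent closed-form oracle: product over genes of the probability
  # of a non-actionable phenotype
  sets <- list()
  for (i in seq_len(nrow(cat14$interactions))) {
    for (g in cat14$interactions$genes[[i]]) {
      sets[[g]] <- union(sets[[g]], cat14$interactions$actionable[[i]])
    }
  }
  p0 <- 1
  for (g in names(sets)) {
    dup <- if (g == "CYP2D6") 0.0327 else 0
    ef <- expected_phenotype_freqs(cat14$genes[[g]], dup)
    p0 <- p0 * (1 - sum(ef[intersect(names(ef), sets[[g]])]))
  }
  k0 <- cd$fraction[["0"]]
  se <- sqrt(p0 * (1 - p0) / 498)
  expect_lt(abs(k0 - p0), 3 * se)
  expect_lt(k0, 0.05)
})

test_that("per-sample flags and frequency route give one number", {
  sim <- simulate_cohort(simulation_config(400, seed = 6), cat14)
  calls <- translate_diplotypes(call_all_diplotypes(sim$cohort, cat14),
                                cat14)
  flags <- actionable_flags(calls, cat14)
  ints <- cat14$interactions
  for (i in seq_len(nrow(ints))) {
    if (length(ints$genes[[i]]) != 1) next
    g <- ints$genes[[i]][1]
    f <- phenotype_frequencies(calls, g)
    full <- setNames(rep(0, length(cat14$genes[[g]]$labels)),
                     cat14$genes[[g]]$labels)
    full[names(f)] <- f
    via_freq <- actionable_fraction(full, ints$actionable[[i]])
    expect_equal(unname(colMeans(flags)[i]), via_freq, tolerance = 1e-12)
  }
})

test_that("enlarging an actionable set never decreases carriage counts", {
  sim <- simulate_cohort(simulation_config(150, seed = 8), cat14)
  calls <- translate_diplotypes(call_all_diplotypes(sim$cohort, cat14),
                                cat14)
  before <- carriage_distribution(calls, cat14)
  bigger <- cat14
  i <- which(vapply(bigger$interactions$genes,
                    function(g) identical(g, "VKORC1"), logical(1)))
  bigger$interactions$actionable[[i]] <-
    union(bigger$interactions$actionable[[i]], "I")
  after <- carriage_distribution(calls, bigger)
  expect_true(all(after$per_sample$k >= before$per_sample$k))
  expect_gt(sum(after$per_sample$k), sum(before$per_sample$k))
})
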