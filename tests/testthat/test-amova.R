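test_that("sums of squares equal the explicit pairwise-distance enumeration", {
  set.seed(31)
  for (case in 1:10) {
    npa <- sample(2:3, 1); npb <- sample(2:3, 1)
    g <- rand_genotypes(n_per_sample = max(npa, npb), n_samples = 2,
                        n_loci = 1, n_alleles = 3, seed = 300 + case)
    g <- subset_genotypes(g, c(seq_len(npa), max(npa, npb) + seq_len(npb)))
    res <- amova(g, n_permutations = 0)
    oracle <- amova_ss_oracle(g)
    expect_equal(res$table$SS[1:3], unname(oracle), tolerance = 1e-12)
  }
})

test_that("complete fixation gives FST = FIT = 1", {
  g <- genotype_matrix(matrix(c(100L, 100L, 120L, 120L)),
                       matrix(c(100L, 100L, 120L, 120L)),
                       sample = c("A", "A", "B", "B"), loci = "L1")
  a <- amova(g, n_permutations = 0)
  expect_equal(unname(a$f_stats["FST"]), 1)
  expect_equal(unname(a$f_stats["FIT"]), 1)
})

test_that("the F-statistic identity holds to 1e-12 on random data", {
  for (s in 1:5) {
    g <- rand_genotypes(n_per_sample = 12, n_samples = 4, n_loci = 3,
                        n_alleles = 5, seed = 40 + s)
    fs <- amova(g, n_permutations = 0)$f_stats
    expect_equal((1 - fs[["FIS"]]) * (1 - fs[["FST"]]), 1 - fs[["FIT"]],
                 tolerance = 1e-12)
  }
})

test_that("degrees of freedom follow the sample structure", {
  # 579 diploids in 25 samples -> df 24 / 554 / 579, total 1157
  sizes <- c(rep(23, 21), rep(24, 4))
  stopifnot(sum(sizes) == 579)
  set.seed(77)
  lab <- rep(paste0("s", 1:25), times = sizes)
  a1 <- matrix(sample(100:105, 579 * 2, TRUE), 579)
  a2 <- matrix(sample(100:105, 579 * 2, TRUE), 579)
  g <- genotype_matrix(a1, a2, sample = lab)
  a <- amova(g, n_permutations = 0)
  expect_equal(a$table$df, c(24, 554, 579, 1157))
})

test_that("samples with fewer than 2 individuals are excluded with a warning", {
  g <- rand_genotypes(n_per_sample = 5, n_samples = 2, seed = 3)
  g$sample[1] <- "lonely"
  expect_warning(res <- amova(g, n_permutations = 0), "lonely")
  expect_false("lonely" %in% res$samples)
})

test_that("permutation p-values are calibrated on exchangeable null data", {
  # two identically-distributed samples: FST p should be uniform
  set.seed(606)
  ps <- replicate(200, {
    g <- rand_genotypes(n_per_sample = 8, n_samples = 2, n_loci = 1,
                        n_alleles = 4, seed = sample.int(1e6, 1),
                        freqs = rep(0.25, 4))
    amova(g, n_permutations = 39, seed = sample.int(1e6, 1))$p_values["FST"]
  })
  rate <- mean(ps <= 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_gte(rate, ci[1] - 1e-9)
  expect_lte(rate, ci[2])
})

test_that("pairwise FST behaves at the null and at fixation", {
  # a sample duplicated under two labels: FST ~ 0, not significant
  g <- rand_genotypes(n_per_sample = 30, n_samples = 1, n_loci = 4,
                      n_alleles = 6, seed = 21)
  g$sample <- rep(c("X", "Y"), 15)
  pf <- pairwise_fst_matrix(g, n_permutations = 199, seed = 2)
  expect_lt(pf$fst["X", "Y"], 0.03)
  expect_gt(pf$p["X", "Y"], 0.05)
  expect_equal(diag(pf$fst), c(X = 0, Y = 0))
  expect_equal(pf$fst, t(pf$fst))

  gfix <- genotype_matrix(matrix(c(100L, 100L, 120L, 120L)),
                          matrix(c(100L, 100L, 120L, 120L)),
                          sample = c("A", "A", "B", "B"), loci = "L1")
  pfix <- pairwise_fst_matrix(gfix, n_permutations = 0)
  expect_equal(pfix$fst["A", "B"], 1)
})

test_that("Bonferroni bookkeeping matches the pair count identity", {
  b <- bonferroni_threshold(0.05, 27)
  expect_equal(b$n_pairs, 351)
  expect_equal(b$threshold, 0.05 / 351)
  b2 <- bonferroni_threshold(0.07, 2)
  expect_equal(b2$n_pairs, 1)
  expect_equal(b2$threshold, 0.07)
  expect_equal(b$threshold * b$n_pairs, 0.05)
})

test_that("permutation FST detects real differentiation", {
  cfg <- popsim_config(2, 50, diag(2), n_loci = 7, mutation_rate = 1e-4,
                       n_generations = 200)
  g <- simulate_metapopulation(cfg, seed = 12, sample_size = 20)
  a <- amova(g, n_permutations = 99, seed = 5)
  expect_lt(a$p_values[["FST"]], 0.05)
})
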