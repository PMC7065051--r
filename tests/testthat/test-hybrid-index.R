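panel7 <- make_parental_panels(7, shared_fraction = 0, seed = 13)

# genotypes drawn from the panels at a fixed admixture proportion
panel_genotypes <- function(panel, n, h, seed) {
  base <- genotype_matrix(matrix(101L, n, length(panel$loci)),
                          matrix(101L, n, length(panel$loci)),
                          sample = rep("s1", n), loci = panel$loci)
  inject_hybrids(base, panel, fraction = 1, h_true = h, seed = seed)
}

test_that("the likelihood is maximal at 0.5 for one copy from each species", {
  # fully diagnostic single-allele panels make the profile exactly symmetric
  p1 <- structure(list(A = list(L1 = c(`101` = 1)),
                       B = list(L1 = c(`201` = 1)),
                       loci = "L1", panel_size = 40, identifiable = TRUE),
                  class = "parental_panel")
  h <- seq(0.01, 0.99, by = 0.01)
  ll <- hybrid_loglik(101L, 201L, "L1", p1, h)
  expect_equal(h[which.max(ll)], 0.5)
  # L(h) ~ h(1-h) up to the floor terms: concave and symmetric about 0.5
  expect_equal(ll, rev(ll), tolerance = 1e-9)
  expect_true(all(diff(ll, differences = 2) < 0))
})

test_that("boundary cases: all-private individuals land at h = 1 or 0", {
  gA <- panel_genotypes(panel7, 10, h = 1, seed = 4)
  rA <- estimate_hybrid_index(gA, panel7)
  expect_equal(rA$h, rep(1, 10))
  expect_true(all(is.finite(rA$logL)))

  gB <- panel_genotypes(panel7, 10, h = 0, seed = 5)
  rB <- estimate_hybrid_index(gB, panel7)
  expect_equal(rB$h, rep(0, 10))
})

test_that("panel swap maps every estimate to 1 - h", {
  g <- panel_genotypes(panel7, 30, h = function(n) runif(n), seed = 6)
  res <- estimate_hybrid_index(g, panel7)
  swapped <- panel7
  swapped$A <- panel7$B; swapped$B <- panel7$A
  res2 <- estimate_hybrid_index(g, swapped)
  expect_equal(res2$h, 1 - res$h, tolerance = 1e-12)
})

test_that("the grid optimiser agrees with an independent smooth optimiser", {
  g <- panel_genotypes(panel7, 20, h = function(n) runif(n), seed = 14)
  res <- estimate_hybrid_index(g, panel7)
  for (i in seq_len(20)) {
    f <- function(h) hybrid_loglik(g$a1[i, ], g$a2[i, ], g$loci, panel7, h)
    opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-9)
    h_or <- min(1, max(0, opt$maximum))
    # interior optima must match to grid resolution; boundary optima to 1e-4
    # (Brent cannot sit exactly on a bound)
    expect_lt(abs(res$h[i] - h_or), 2e-4)
  }
})

test_that("duplicating the whole dataset leaves the estimates unchanged", {
  g <- panel_genotypes(panel7, 10, h = function(n) runif(n), seed = 15)
  res <- estimate_hybrid_index(g, panel7)
  gdup <- g
  gdup$a1 <- cbind(g$a1, g$a1); gdup$a2 <- cbind(g$a2, g$a2)
  dup_loci <- c(g$loci, paste0(g$loci, "bis"))
  colnames(gdup$a1) <- colnames(gdup$a2) <- dup_loci
  gdup$loci <- dup_loci
  pdup <- panel7
  pdup$A <- c(panel7$A, stats::setNames(panel7$A, paste0(names(panel7$A), "bis")))
  pdup$B <- c(panel7$B, stats::setNames(panel7$B, paste0(names(panel7$B), "bis")))
  pdup$loci <- dup_loci
  res2 <- estimate_hybrid_index(gdup, pdup)
  expect_equal(res2$h, res$h)
})

test_that("unidentifiable panels and empty individuals are flagged", {
  pid <- make_parental_panels(3, shared_fraction = 1, seed = 1)
  g <- rand_genotypes(n_loci = 3, seed = 1)
  expect_error(estimate_hybrid_index(g, pid), "unidentifiable")

  g2 <- panel_genotypes(panel7, 3, h = 1, seed = 2)
  g2$a1[2, ] <- NA_integer_; g2$a2[2, ] <- NA_integer_
  res <- estimate_hybrid_index(g2, panel7)
  expect_true(is.na(res$h[2]))
  expect_equal(attr(res, "flagged"), g2$individual[2])
})

test_that("purity filtering recovers the simulated pure fraction", {
  set.seed(16)
  n <- 300
  pure <- runif(n) < 0.53
  hs <- ifelse(pure, 1, runif(n, 0, 0.95))
  g <- panel_genotypes(panel7, n, h = hs, seed = 17)
  g$sample <- rep(c("s1", "s2", "s3"), each = 100)
  res <- estimate_hybrid_index(g, panel7)
  fp <- filter_pure(g, res)
  # all truly pure individuals kept; a hybrid can sneak past only by drawing
  # an all-A genotype by chance, so the retained fraction tracks 53%
  expect_true(all(fp$retained[pure]))
  expect_lt(abs(mean(fp$retained) - 0.53), 0.08)
  expect_equal(nrow(fp$report), 3)
  expect_equal(sum(fp$report$n_retained), sum(fp$retained))

  # threshold 0 retains everything
  fp0 <- filter_pure(g, res, threshold = 0)
  expect_true(all(fp0$retained))
  # filtering everything warns
  expect_warning(filter_pure(subset_genotypes(g, !fp$retained),
                             res[!fp$retained, ], threshold = 1),
                 "all individuals filtered")
})
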