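test_that("degree-Euclidean distances reproduce the printed landmark pairs", {
  d <- geo_distance_matrix(north_sea_sites())
  expect_equal(round(d["SCHV", "Q13A"]), 17)
  expect_equal(round(d["BLYT", "SYLT"]), 1105)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
})

test_that("haversine is geodetic: symmetric, triangle inequality, shorter E-W", {
  sites <- north_sea_sites()
  dh <- geo_distance_matrix(sites, metric = "haversine")
  de <- geo_distance_matrix(sites)
  expect_equal(dh, t(dh), ignore_attr = TRUE)
  # triangle inequality on a random triple sweep
  ids <- rownames(dh)
  set.seed(1)
  for (k in 1:50) {
    tri <- sample(ids, 3)
    expect_lte(dh[tri[1], tri[2]],
               dh[tri[1], tri[3]] + dh[tri[3], tri[2]] + 1e-9)
  }
  # east-west pairs shrink under the cosine of latitude
  expect_lt(dh["BLYT", "SYLT"], de["BLYT", "SYLT"])
})

test_that("FST to 2Nem conversion matches the island-model closed form", {
  expect_equal(fst_to_2nem(0.2), 2, ignore_attr = TRUE)
  expect_equal(fst_to_2nem(1), 0, ignore_attr = TRUE)
  expect_equal(fst_to_2nem(0.06), (1 - 0.06) / 0.12, ignore_attr = TRUE)
  expect_equal(round(fst_to_2nem(0.06), 4), 7.8333, ignore_attr = TRUE)
  # round trip: fst -> 2Nem -> fst is the identity on (0, 1]
  fst <- seq(0.01, 1, by = 0.01)
  nem2 <- fst_to_2nem(fst)
  expect_equal(1 / (1 + 2 * nem2), fst, tolerance = 1e-12, ignore_attr = TRUE)
  # non-positive FST flagged as undefined
  out <- fst_to_2nem(c(-0.01, 0, 0.5))
  expect_true(all(is.na(out[1:2])))
  expect_equal(attr(out, "undefined"), 2)
})

test_that("off-diagonal Pearson hits its fixed points and error cases", {
  A <- rand_labelled_matrix(5, seed = 3)
  expect_equal(offdiag_pearson(A, A), 1)
  expect_equal(offdiag_pearson(A, -A), -1)
  C <- A; C[] <- 0.7
  expect_error(offdiag_pearson(A, C), "zero variance")
  B <- rand_labelled_matrix(4, seed = 4)
  expect_error(offdiag_pearson(A, B), "not square|label")
})

test_that("self-correlation Mantel test: r = 1 and minimal p_greater", {
  A <- rand_labelled_matrix(6, seed = 5)
  m <- mantel_test(A, A, n_permutations = 999, seed = 1)
  expect_equal(m$r, 1)
  expect_equal(m$p_greater, 1 / 1000)
  expect_gte(m$p_less, 0.99)
  expect_false(m$symmetric)
})

test_that("Monte-Carlo p matches exhaustive enumeration on 3x3 matrices", {
  A <- rand_labelled_matrix(3, seed = 6)
  B <- rand_labelled_matrix(3, seed = 7)
  r_obs <- offdiag_pearson(A, B)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  r_all <- sapply(perms, function(p) {
    Bp <- B[p, p]; dimnames(Bp) <- dimnames(B)
    offdiag_pearson(A, Bp)
  })
  exact_greater <- mean(r_all > r_obs)
  m <- mantel_test(A, B, n_permutations = 4999, seed = 8)
  mc_frac <- (m$p_greater * 5000 - 1) / 4999
  expect_lt(abs(mc_frac - exact_greater),
            3 * sqrt(exact_greater * (1 - exact_greater) / 4999) + 1e-3)
})

test_that("jointly relabelling both matrices leaves r unchanged", {
  A <- rand_labelled_matrix(7, seed = 9)
  B <- rand_labelled_matrix(7, seed = 10)
  r0 <- offdiag_pearson(A, B)
  for (k in 1:5) {
    set.seed(k)
    p <- sample.int(7)
    Ap <- A[p, p]; Bp <- B[p, p]
    dimnames(Ap) <- dimnames(Bp) <- dimnames(A)
    expect_equal(offdiag_pearson(Ap, Bp), r0, tolerance = 1e-12)
  }
})

test_that("symmetric-mode results agree with vegan's Mantel statistic", {
  skip_if_not_installed("vegan")
  D1 <- as.matrix(dist(matrix(runif(20, 0, 10), 10, 2)))
  D2 <- as.matrix(dist(matrix(runif(20, 0, 10), 10, 2)))
  labs <- paste0("s", 1:10)
  dimnames(D1) <- dimnames(D2) <- list(labs, labs)
  ours <- mantel_test(D1, D2, n_permutations = 999, seed = 3)
  veg <- vegan::mantel(D1, D2, permutations = 999)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p_greater - veg$signif), 0.05)
  expect_true(ours$symmetric)
})

test_that("isolation by distance: positive control and label guards", {
  sites <- north_sea_sites()
  d <- geo_distance_matrix(sites)
  fst <- 0.001 * d + 0.002  # FST rising linearly with distance
  diag(fst) <- 0
  m <- ibd_test(d, fst, n_permutations = 999, seed = 2)
  expect_gt(m$r, 0.99)
  expect_lte(m$p_greater, 0.01)

  bad <- fst[1:10, 1:10]
  expect_error(ibd_test(d, bad), "site sets differ")
})

test_that("connected/unconnected FST comparison: null and scaled cases", {
  labs <- paste0("s", 1:4)
  cnt <- matrix(0L, 4, 4, dimnames = list(labs, labs))
  cnt["s1", "s2"] <- 10L; cnt["s3", "s4"] <- 4L
  # same value sets in both groups -> 0 % difference, KS D = 0, p = 1
  fst <- matrix(0, 4, 4, dimnames = list(labs, labs))
  fst["s1", "s2"] <- fst["s2", "s1"] <- 0.1
  fst["s3", "s4"] <- fst["s4", "s3"] <- 0.2
  fst["s1", "s3"] <- fst["s3", "s1"] <- 0.1
  fst["s1", "s4"] <- fst["s4", "s1"] <- 0.2
  fst["s2", "s3"] <- fst["s3", "s2"] <- 0.1
  fst["s2", "s4"] <- fst["s4", "s2"] <- 0.2
  cs <- connected_vs_unconnected(fst, cnt)
  expect_equal(cs$ks_statistic, 0)  # identical ECDFs
  expect_equal(cs$ks_p, 1)
  expect_equal(cs$percent_higher, 0)

  # unconnected values exactly 1.35x the connected ones -> 35 %
  fst2 <- fst
  up <- which(upper.tri(fst2), arr.ind = TRUE)
  conn <- (cnt + t(cnt))[upper.tri(cnt)] > 0
  for (k in which(!conn)) {
    i <- up[k, 1]; j <- up[k, 2]
    fst2[i, j] <- fst2[j, i] <- 1.35 * fst2[i, j]
  }
  cs2 <- connected_vs_unconnected(fst2, cnt)
  expect_equal(cs2$percent_higher, 35)

  # all pairs connected -> empty unconnected group
  cnt2 <- cnt; cnt2[upper.tri(cnt2)] <- 1L
  expect_error(connected_vs_unconnected(fst, cnt2), "no unconnected")
})
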