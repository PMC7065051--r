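# Hierarchical AMOVA for codominant (diploid) data, three strata:
# among samples / among individuals within samples / within individuals.
# Sums of squares are computed per locus on allele copies with the 0/1
# mismatch distance (d^2 = 1 between different alleles) and summed over
# loci; variance components come from the expected mean squares with the
# unequal-n coefficient n0 on allele copies. Missing genotypes are dropped
# per locus (pairwise deletion, never imputation).

amova_prep <- function(g, exclude_loci = character()) {
  keep_loci <- setdiff(g$loci, exclude_loci)
  if (!length(keep_loci)) stop("all loci excluded")
  li <- match(keep_loci, g$loci)
  pop_lab <- g$sample
  # drop samples with < 2 individuals
  tab <- table(pop_lab)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("excluding sample(s) with < 2 individuals: ",
            paste(small, collapse = ", "))
    ii <- !(pop_lab %in% small)
  } else ii <- rep(TRUE, length(pop_lab))
  a1 <- g$a1[ii, li, drop = FALSE]
  a2 <- g$a2[ii, li, drop = FALSE]
  pop_lab <- pop_lab[ii]
  has_data <- rowSums(!is.na(a1)) > 0
  a1 <- a1[has_data, , drop = FALSE]
  a2 <- a2[has_data, , drop = FALSE]
  pop_lab <- pop_lab[has_data]
  pop <- as.integer(factor(pop_lab, levels = unique(pop_lab)))
  P <- max(pop)
  if (P < 2) stop("AMOVA needs at least 2 samples with data")
  N <- length(pop)

  loci <- lapply(seq_along(li), function(l) {
    called <- which(!is.na(a1[, l]))
    v1 <- a1[called, l]; v2 <- a2[called, l]
    codes <- as.integer(factor(c(v1, v2)))
    K <- max(codes)
    m <- matrix(codes, ncol = 2)  # copy1, copy2 per called individual
    n_c <- 2 * length(called)
    Ck <- tabulate(codes, K)
    ss_total <- (n_c - sum(Ck^2) / n_c) / 2
    list(called = called, copies = m, K = K, ss_total = ss_total)
  })

  list(pop = pop, P = P, N = N, levels = unique(pop_lab), loci = loci)
}

# within-sample and among-sample SS given a pop assignment per individual
amova_ss_strata <- function(prep, pop) {
  P <- max(prep$P, max(pop))
  ss_total <- 0; ss_wp <- 0; ss_wi <- 0
  for (lc in prep$loci) {
    codes <- as.vector(lc$copies)
    popc <- rep(pop[lc$called], 2)
    K <- lc$K
    cnt <- tabulate((popc - 1L) * K + codes, P * K)
    cntm <- matrix(cnt, K, P)
    n_pc <- colSums(cntm)
    nz <- n_pc > 0
    ss_wp <- ss_wp + sum((n_pc[nz] - colSums(cntm[, nz, drop = FALSE]^2) /
                            n_pc[nz]) / 2)
    ss_wi <- ss_wi + 0.5 * sum(lc$copies[, 1] != lc$copies[, 2])
    ss_total <- ss_total + lc$ss_total
  }
  c(among = ss_total - ss_wp, among_ind = ss_wp - ss_wi, within = ss_wi)
}

amova_components <- function(ss, df, n0) {
  ms <- ss / df
  Vc <- ms[3]
  Vb <- (ms[2] - Vc) / 2
  Va <- (ms[1] - ms[2]) / n0
  c(Va = unname(Va), Vb = unname(Vb), Vc = unname(Vc))
}

f_stats_from_components <- function(v) {
  tot <- sum(v)
  c(FST = unname(v[1] / tot),
    FIS = unname(v[2] / (v[2] + v[3])),
    FIT = unname((v[1] + v[2]) / tot))
}

#' Analysis of molecular variance (AMOVA) with permutation tests
#'
#' Partitions allelic variation among samples, among individuals within
#' samples, and within individuals, and reports the fixation indices
#' FST = Va/(Va+Vb+Vc), FIS = Vb/(Vb+Vc) and FIT = (Va+Vb)/(Va+Vb+Vc).
#' On the unclamped components these satisfy (1-FIS)(1-FST) = 1-FIT
#' identically. P-values are permutational: individuals are shuffled among
#' samples for FST, allele copies among individuals within samples for FIS,
#' and allele copies among all individuals for FIT; each p is
#' `(count + 1) / (n_permutations + 1)` counting permuted statistics at
#' least as large as the observed one.
#'
#' @param genotypes A `genotype_matrix` with >= 2 samples of >= 2
#'   individuals (smaller samples are excluded with a warning).
#' @param n_permutations Number of permutations per test (0 = no tests).
#' @param seed Integer seed for the permutations.
#' @param exclude_loci Locus names left out of the analysis (e.g. a
#'   species-diagnostic assay locus that is not a neutral marker).
#' @return An object of class `amova_result`: list with `table` (df, SS, MS,
#'   variance component, percentage per stratum), `components`, `f_stats`,
#'   `p_values`, `n0`, `n_permutations`.
#' @export
amova <- function(genotypes, n_permutations = 999, seed = 1,
                  exclude_loci = character()) {
  prep <- amova_prep(genotypes, exclude_loci)
  pop <- prep$pop; N <- prep$N; P <- prep$P
  df <- c(P - 1, N - P, N)
  copies_per_pop <- 2 * tabulate(pop, P)
  n0 <- (2 * N - sum(copies_per_pop^2) / (2 * N)) / (P - 1)

  ss <- amova_ss_strata(prep, pop)
  v <- amova_components(ss, df, n0)
  fs <- f_stats_from_components(v)

  p <- c(FST = NA_real_, FIS = NA_real_, FIT = NA_real_)
  if (n_permutations > 0) {
    set.seed(seed)
    cnt <- c(0, 0, 0)
    for (b in seq_len(n_permutations)) {
      # FST: individuals among samples
      pop_b <- pop[sample.int(N)]
      ss_b <- amova_ss_strata(prep, pop_b)
      fs_b <- f_stats_from_components(amova_components(ss_b, df, n0))
      if (fs_b["FST"] >= fs["FST"]) cnt[1] <- cnt[1] + 1
      # FIS: copies among individuals within samples (per locus)
      ss_wi_b <- 0
      for (lc in prep$loci) {
        popl <- pop[lc$called]
        flat <- as.vector(t(lc$copies))  # copy pairs interleaved
        for (pp in unique(popl)) {
          rows <- which(popl == pp)
          ci <- c(2 * rows - 1, 2 * rows)
          flat[ci] <- flat[ci][sample.int(length(ci))]
        }
        m <- matrix(flat, ncol = 2, byrow = TRUE)
        ss_wi_b <- ss_wi_b + 0.5 * sum(m[, 1] != m[, 2])
      }
      ss_fis <- c(ss[1], ss[1] + ss[2] + ss[3] - ss[1] - ss_wi_b, ss_wi_b)
      names(ss_fis) <- names(ss)
      fs_fis <- f_stats_from_components(amova_components(ss_fis, df, n0))
      if (fs_fis["FIS"] >= fs["FIS"]) cnt[2] <- cnt[2] + 1
      # FIT: copies among all individuals (per locus)
      ss_wi_g <- 0; ss_wp_g <- 0
      for (lc in prep$loci) {
        codes <- as.vector(lc$copies)
        codes <- codes[sample.int(length(codes))]
        m <- matrix(codes, ncol = 2)
        ss_wi_g <- ss_wi_g + 0.5 * sum(m[, 1] != m[, 2])
        popc <- rep(pop[lc$called], 2)
        K <- lc$K
        cnt2 <- tabulate((popc - 1L) * K + codes, P * K)
        cntm <- matrix(cnt2, K, P)
        n_pc <- colSums(cntm)
        nz <- n_pc > 0
        ss_wp_g <- ss_wp_g +
          sum((n_pc[nz] - colSums(cntm[, nz, drop = FALSE]^2) / n_pc[nz]) / 2)
      }
      ss_tot <- sum(ss)
      ss_fit <- c(ss_tot - ss_wp_g, ss_wp_g - ss_wi_g, ss_wi_g)
      names(ss_fit) <- names(ss)
      fs_fit <- f_stats_from_components(amova_components(ss_fit, df, n0))
      if (fs_fit["FIT"] >= fs["FIT"]) cnt[3] <- cnt[3] + 1
    }
    p <- (cnt + 1) / (n_permutations + 1)
    names(p) <- c("FST", "FIS", "FIT")
  }

  tot <- sum(v)
  tab <- data.frame(
    stratum = c("Among samples", "Among individuals", "Within individuals",
                "Total"),
    df = c(df, sum(df)),
    SS = c(ss, sum(ss)),
    MS = c(ss / df, NA),
    variance = c(v, tot),
    percentage = c(100 * v / tot, 100),
    row.names = NULL
  )
  structure(list(table = tab, components = v, f_stats = fs, p_values = p,
                 n0 = n0, n_permutations = n_permutations,
                 samples = prep$levels),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", length(x$samples), " samples)\n", sep = "")
  print(x$table, digits = 4, row.names = FALSE)
  cat(sprintf("FST = %.4f  FIS = %.4f  FIT = %.4f\n",
              x$f_stats["FST"], x$f_stats["FIS"], x$f_stats["FIT"]))
  if (!is.na(x$p_values["FST"]))
    cat(sprintf("p(FST) = %.4g  p(FIS) = %.4g  p(FIT) = %.4g  [%d permutations]\n",
                x$p_values["FST"], x$p_values["FIS"], x$p_values["FIT"],
                x$n_permutations))
  invisible(x)
}

#' Pairwise FST matrix with permutation tests
#'
#' Each pair of samples is analysed by a two-sample AMOVA; the among-sample
#' fixation index is the pairwise FST. Negative estimates are clamped to 0
#' in the reported matrix (the raw values are kept in the `raw` field).
#' Significance flags apply the Bonferroni threshold `alpha / n_pairs`.
#'
#' @param genotypes A `genotype_matrix`.
#' @param n_permutations Permutations per pair (individuals shuffled between
#'   the two samples).
#' @param seed Integer seed.
#' @param alpha Family-wise error rate for the Bonferroni flags.
#' @param exclude_loci Loci left out (see [amova()]).
#' @return A `pairwise_fst` object: list with symmetric matrices `fst`
#'   (clamped), `raw`, `p` and logical `significant`, plus `n_pairs` and
#'   `threshold`.
#' @export
pairwise_fst_matrix <- function(genotypes, n_permutations = 999, seed = 1,
                                alpha = 0.05, exclude_loci = character()) {
  samples <- unique(genotypes$sample)
  ns <- length(samples)
  if (ns < 2) stop("need at least 2 samples")
  bon <- bonferroni_threshold(alpha, ns)
  fst <- matrix(0, ns, ns, dimnames = list(samples, samples))
  raw <- fst
  pm <- matrix(NA_real_, ns, ns, dimnames = list(samples, samples))
  set.seed(seed)
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    ii <- genotypes$sample %in% samples[c(i, j)]
    gp <- subset_genotypes(genotypes, ii)
    res <- tryCatch(
      pair_fst_perm(gp, n_permutations),
      error = function(e) list(fst = NA_real_, p = NA_real_))
    raw[i, j] <- raw[j, i] <- res$fst
    fst[i, j] <- fst[j, i] <- max(0, res$fst)
    pm[i, j] <- pm[j, i] <- res$p
  }
  diag(raw) <- 0
  sig <- !is.na(pm) & pm <= bon$threshold
  diag(sig) <- FALSE
  structure(list(fst = fst, raw = raw, p = pm, significant = sig,
                 n_pairs = bon$n_pairs, threshold = bon$threshold,
                 n_permutations = n_permutations),
            class = "pairwise_fst")
}

pair_fst_perm <- function(gp, n_permutations) {
  prep <- amova_prep(gp)
  pop <- prep$pop; N <- prep$N; P <- prep$P
  df <- c(P - 1, N - P, N)
  copies_per_pop <- 2 * tabulate(pop, P)
  n0 <- (2 * N - sum(copies_per_pop^2) / (2 * N)) / (P - 1)
  ss <- amova_ss_strata(prep, pop)
  fst <- f_stats_from_components(amova_components(ss, df, n0))["FST"]
  p <- NA_real_
  if (n_permutations > 0) {
    cnt <- 0
    for (b in seq_len(n_permutations)) {
      ss_b <- amova_ss_strata(prep, pop[sample.int(N)])
      fst_b <- f_stats_from_components(amova_components(ss_b, df, n0))["FST"]
      if (fst_b >= fst) cnt <- cnt + 1
    }
    p <- (cnt + 1) / (n_permutations + 1)
  }
  list(fst = unname(fst), p = p)
}

#' @export
print.pairwise_fst <- function(x, ...) {
  cat("pairwise_fst:", nrow(x$fst), "samples,", x$n_pairs, "pairs\n")
  off <- x$fst[upper.tri(x$fst)]
  cat(sprintf("  FST range [%.3f, %.3f], mean %.3f; %d pairs significant at %.3g\n",
              min(off), max(off), mean(off), sum(x$significant) / 2,
              x$threshold))
  invisible(x)
}

#' Bonferroni-corrected per-test threshold for all sample pairs
#'
#' @param alpha Family-wise error rate.
#' @param n_samples Number of samples (>= 2).
#' @return List with `n_pairs` = `n(n-1)/2` and `threshold` = `alpha/n_pairs`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 27)  # 351 pairs, 1.424e-4
bonferroni_threshold <- function(alpha, n_samples) {
  stopifnot(n_samples >= 2, alpha > 0)
  n_pairs <- n_samples * (n_samples - 1) / 2
  list(n_pairs = n_pairs, threshold = alpha / n_pairs)
}
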