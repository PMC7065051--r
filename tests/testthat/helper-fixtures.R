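# Programmatic fixtures: everything is generated in code at test time.

# Random Hardy-Weinberg genotypes: n individuals per sample, per-sample
# allele frequency tables drawn from a Dirichlet-like gamma draw.
rand_genotypes <- function(n_per_sample = 10, n_samples = 2, n_loci = 2,
                           n_alleles = 4, seed = 1, freqs = NULL) {
  set.seed(seed)
  ntot <- n_per_sample * n_samples
  a1 <- matrix(NA_integer_, ntot, n_loci)
  a2 <- matrix(NA_integer_, ntot, n_loci)
  sample_lab <- rep(paste0("s", seq_len(n_samples)), each = n_per_sample)
  for (s in seq_len(n_samples)) {
    rows <- which(sample_lab == paste0("s", s))
    for (l in seq_len(n_loci)) {
      f <- if (is.null(freqs)) {
        g <- rgamma(n_alleles, 1); g / sum(g)
      } else freqs
      a1[rows, l] <- sample(100 + seq_along(f), length(rows), TRUE, prob = f)
      a2[rows, l] <- sample(100 + seq_along(f), length(rows), TRUE, prob = f)
    }
  }
  genotype_matrix(a1, a2, sample = sample_lab,
                  loci = paste0("L", seq_len(n_loci)))
}

# labelled square matrix with random entries
rand_labelled_matrix <- function(n, seed = 1, labels = NULL) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  labels <- labels %||% paste0("s", seq_len(n))
  dimnames(m) <- list(labels, labels)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# AMOVA sums-of-squares oracle: explicit allele-copy pairwise-distance
# enumeration, SS(group) = sum over unordered copy pairs of the 0/1
# mismatch distance divided by group size. Completely independent of the
# count-based implementation.
amova_ss_oracle <- function(g) {
  ss_group <- function(copies) {
    n <- length(copies)
    if (n < 2) return(0)
    tot <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      tot <- tot + (copies[i] != copies[j])
    tot / n
  }
  ss_t <- 0; ss_wp <- 0; ss_wi <- 0
  for (l in seq_along(g$loci)) {
    called <- which(!is.na(g$a1[, l]))
    copies <- c(g$a1[called, l], g$a2[called, l])
    ss_t <- ss_t + ss_group(copies)
    for (s in unique(g$sample)) {
      idx <- intersect(called, which(g$sample == s))
      ss_wp <- ss_wp + ss_group(c(g$a1[idx, l], g$a2[idx, l]))
    }
    for (i in called)
      ss_wi <- ss_wi + ss_group(c(g$a1[i, l], g$a2[i, l]))
  }
  c(among = ss_t - ss_wp, among_ind = ss_wp - ss_wi, within = ss_wi)
}
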