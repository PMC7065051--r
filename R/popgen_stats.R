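#' Per-locus allele frequencies for one sample
#'
#' Missing genotypes are excluded from the denominators; per-locus
#' frequencies sum to 1 whenever the locus has any called genotype in the
#' sample. A locus with zero called genotypes gets an empty table and is
#' named in the `undefined_loci` attribute.
#'
#' @param genotypes A `genotype_matrix`.
#' @param sample A sample label present in `genotypes`.
#' @return Named list (per locus) of lists with `counts` (named integer
#'   allele-copy counts) and `freq` (named numeric frequencies).
#' @export
allele_frequencies <- function(genotypes, sample) {
  if (!sample %in% genotypes$sample)
    stop("unknown sample label: ", sample)
  ii <- genotypes$sample == sample
  out <- lapply(seq_along(genotypes$loci), function(l) {
    v <- c(genotypes$a1[ii, l], genotypes$a2[ii, l])
    v <- v[!is.na(v)]
    if (!length(v)) return(list(counts = integer(0), freq = numeric(0)))
    tab <- table(v)
    counts <- stats::setNames(as.integer(tab), names(tab))
    list(counts = counts, freq = counts / sum(counts))
  })
  names(out) <- genotypes$loci
  undef <- genotypes$loci[vapply(out, function(x) length(x$counts) == 0,
                                 logical(1))]
  attr(out, "undefined_loci") <- undef
  out
}

#' Expected number of distinct alleles in a rarefied subsample
#'
#' Classic rarefaction: given per-allele copy counts `N_i` summing to `N`,
#' the expected allele count in a random draw of `g` copies is
#' `sum_i [1 - C(N - N_i, g) / C(N, g)]`. Evaluated with log-binomials for
#' stability.
#'
#' @param counts Named or bare integer vector of allele copy counts.
#' @param g Rarefaction size, `1 <= g <= sum(counts)`.
#' @return Expected allele count (numeric scalar).
#' @export
#' @examples
#' allelic_richness(c(2, 2), 2)  # 5/3: all C(4,2)=6 draws enumerated
allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g < 1 || g > N) stop("rarefaction size g must be in [1, ", N, "]")
  term <- ifelse(N - counts < g, 0, exp(lchoose(N - counts, g) - lchoose(N, g)))
  sum(1 - term)
}

#' Per-sample descriptive statistics
#'
#' For each sample: mean alleles per locus (Na), effective number of alleles
#' (Ne = 1/sum p^2, averaged over loci), private alleles (Np: alleles seen in
#' that sample and no other), observed heterozygosity (Ho), Nei's expected
#' heterozygosity (He = 1 - sum p^2) and rarefied allelic richness (Ar).
#' The default rarefaction size per locus is twice the smallest number of
#' complete genotypes any sample has at that locus, so Ar is comparable
#' across unequal sample sizes.
#'
#' @param genotypes A `genotype_matrix`.
#' @param rarefaction_g Optional fixed rarefaction size (allele copies);
#'   default per-locus as described.
#' @param exclude_loci Loci left out of all statistics.
#' @return A data.frame, one row per sample, columns
#'   `sample, Na, Ne, Np, Ho, He, Ar`.
#' @export
sample_summary_stats <- function(genotypes, rarefaction_g = NULL,
                                 exclude_loci = character()) {
  g <- subset_genotypes(genotypes,
                        loci = setdiff(genotypes$loci, exclude_loci))
  samples <- unique(g$sample)
  freqs <- lapply(samples, function(s) allele_frequencies(g, s))
  names(freqs) <- samples
  nL <- length(g$loci)

  # which samples carry each allele (for private-allele counts)
  presence <- lapply(seq_len(nL), function(l) {
    tabs <- lapply(freqs, function(f) names(f[[l]]$counts))
    all_alleles <- unique(unlist(tabs))
    m <- matrix(FALSE, length(all_alleles), length(samples),
                dimnames = list(all_alleles, samples))
    for (s in samples) m[, s] <- all_alleles %in% tabs[[s]]
    m
  })

  # default rarefaction size per locus: 2 * min called genotypes across samples
  called_per <- sapply(samples, function(s) {
    ii <- g$sample == s
    colSums(!is.na(g$a1[ii, , drop = FALSE]))
  })
  if (is.null(dim(called_per))) called_per <- matrix(called_per, nrow = nL)
  g_locus <- if (is.null(rarefaction_g)) {
    pmax(2L, 2L * apply(called_per, 1, min))
  } else rep_len(rarefaction_g, nL)

  rows <- lapply(samples, function(s) {
    f <- freqs[[s]]
    ii <- g$sample == s
    per_locus <- vapply(seq_len(nL), function(l) {
      fr <- f[[l]]$freq
      if (!length(fr)) return(c(NA, NA, NA, NA, NA))
      sp2 <- sum(fr^2)
      a1 <- g$a1[ii, l]; a2 <- g$a2[ii, l]
      called <- !is.na(a1)
      ho <- if (any(called)) mean(a1[called] != a2[called]) else NA
      ar <- if (sum(f[[l]]$counts) >= g_locus[l])
        allelic_richness(f[[l]]$counts, g_locus[l]) else NA
      c(length(fr), 1 / sp2, ho, 1 - sp2, ar)
    }, numeric(5))
    np <- sum(vapply(seq_len(nL), function(l) {
      m <- presence[[l]]
      mine <- m[, s]
      sum(mine & rowSums(m) == 1)
    }, numeric(1)))
    data.frame(sample = s,
               Na = mean(per_locus[1, ], na.rm = TRUE),
               Ne = mean(per_locus[2, ], na.rm = TRUE),
               Np = np,
               Ho = mean(per_locus[3, ], na.rm = TRUE),
               He = mean(per_locus[4, ], na.rm = TRUE),
               Ar = mean(per_locus[5, ], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Null allele frequency from the heterozygosity deficit
#'
#' Null (non-amplifying) alleles inflate apparent homozygosity; their
#' frequency can be estimated from the gap between expected and observed
#' heterozygosity. Two classic moment estimators are offered:
#' Brookfield's first estimator `r = (He - Ho) / (1 + He)` and
#' Chakraborty's `r = (He - Ho) / (He + Ho)`. Negative estimates are
#' clamped to 0 and flagged.
#'
#' @param genotypes A `genotype_matrix`.
#' @param locus A locus name.
#' @param estimator `"brookfield1"` (default) or `"chakraborty"`.
#' @param sample Optional sample label; default pools all individuals.
#' @return Estimate in `[0, 1]`, with attributes `clamped` (logical) and
#'   `He`, `Ho`.
#' @export
null_allele_frequency <- function(genotypes, locus,
                                  estimator = c("brookfield1", "chakraborty"),
                                  sample = NULL) {
  estimator <- match.arg(estimator)
  l <- match(locus, genotypes$loci)
  if (is.na(l)) stop("unknown locus: ", locus)
  ii <- if (is.null(sample)) rep(TRUE, n_individuals(genotypes))
        else genotypes$sample == sample
  a1 <- genotypes$a1[ii, l]; a2 <- genotypes$a2[ii, l]
  called <- !is.na(a1)
  if (!any(called)) stop("locus ", locus, " has no called genotypes")
  ho <- mean(a1[called] != a2[called])
  fr <- table(c(a1[called], a2[called]))
  p <- as.numeric(fr) / sum(fr)
  he <- 1 - sum(p^2)
  if (he == 0 && ho == 0) {
    out <- NA_real_
    attr(out, "flag") <- "undefined: He = Ho = 0"
    return(out)
  }
  r <- switch(estimator,
              brookfield1 = (he - ho) / (1 + he),
              chakraborty = (he - ho) / (he + ho))
  clamped <- r < 0
  out <- max(0, r)
  attr(out, "clamped") <- clamped
  attr(out, "He") <- he
  attr(out, "Ho") <- ho
  out
}
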