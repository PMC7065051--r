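#' Build a pair of parental reference allele-frequency panels
#'
#' Two hybridising species are emulated by two per-locus allele frequency
#' tables with controllable overlap. With `shared_fraction = 0` every allele
#' is private to one species (fully diagnostic loci); with
#' `shared_fraction = 1` the two tables are identical and a downstream
#' hybrid index is unidentifiable (the panel is flagged).
#'
#' @param n_loci Number of loci (>= 1).
#' @param n_private_per_locus Private alleles per species per locus.
#' @param shared_fraction Fraction of each species' frequency mass placed on
#'   a common shared allele set, in `[0, 1]`.
#' @param n_shared Size of the shared allele set per locus.
#' @param panel_size Diploid reference individuals per species (used for the
#'   frequency floor applied to unseen alleles downstream).
#' @param seed Integer seed.
#' @return A `parental_panel`: list with per-locus frequency tables `A` and
#'   `B` (named numeric vectors summing to 1), `loci`, `panel_size`, and
#'   `identifiable` flag.
#' @export
make_parental_panels <- function(n_loci, n_private_per_locus = 3,
                                 shared_fraction = 0, n_shared = 4,
                                 panel_size = 40, seed = 1) {
  stopifnot(n_loci >= 1, shared_fraction >= 0, shared_fraction <= 1)
  set.seed(seed)
  rdirich <- function(k) { g <- stats::rgamma(k, 2); g / sum(g) }
  A <- vector("list", n_loci); B <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    npA <- n_private_per_locus
    privA <- 100L + seq_len(npA)
    privB <- 200L + seq_len(npA)
    shr <- 300L + seq_len(n_shared)
    fshr <- rdirich(n_shared)
    fA <- c(stats::setNames((1 - shared_fraction) * rdirich(npA), privA),
            stats::setNames(shared_fraction * fshr, shr))
    fB <- c(stats::setNames((1 - shared_fraction) * rdirich(npA), privB),
            stats::setNames(shared_fraction * fshr, shr))
    fA <- fA[fA > 0]; fB <- fB[fB > 0]
    if (abs(sum(fA) - 1) > 1e-9 || abs(sum(fB) - 1) > 1e-9)
      stop("internal consistency error: panel frequencies do not sum to 1")
    A[[l]] <- fA; B[[l]] <- fB
  }
  loci <- paste0("L", seq_len(n_loci))
  names(A) <- names(B) <- loci
  structure(list(A = A, B = B, loci = loci, panel_size = panel_size,
                 identifiable = shared_fraction < 1),
            class = "parental_panel")
}

#' @export
print.parental_panel <- function(x, ...) {
  cat("parental_panel:", length(x$loci), "loci,",
      if (x$identifiable) "identifiable" else "UNIDENTIFIABLE (identical tables)",
      "\n")
  invisible(x)
}

draw_from_freqs <- function(f, n) {
  sample(as.integer(names(f)), n, TRUE, prob = f)
}

#' Inject hybrid individuals into a genotype matrix
#'
#' A selected fraction of individuals have their genotypes replaced by
#' hybrid genotypes: each allele copy at each locus is drawn independently
#' from species A's frequency table with probability `h` and from species
#' B's with probability `1 - h` (h = 1 means pure species A). The true `h`
#' per individual is recorded for recovery tests. Independence of allele
#' copies given `h` mirrors the hybrid-index likelihood, so estimator
#' recovery is exact in expectation.
#'
#' @param genotypes A `genotype_matrix` whose loci match the panel's.
#' @param panel A `parental_panel`.
#' @param fraction Fraction of individuals replaced, in `[0, 1]`.
#' @param h_true A single number in `[0, 1]`, a numeric vector (one value
#'   per selected individual, recycled), or a function `f(n)` drawing `n`
#'   values.
#' @param seed Integer seed.
#' @return The modified `genotype_matrix` with attributes `true_h` (numeric
#'   per individual, `NA` where untouched) and `is_hybridised` (logical).
#' @export
inject_hybrids <- function(genotypes, panel, fraction, h_true, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (!all(genotypes$loci %in% panel$loci))
    stop("panel loci do not cover genotype loci: missing ",
         paste(setdiff(genotypes$loci, panel$loci), collapse = ", "))
  set.seed(seed)
  n <- n_individuals(genotypes)
  sel <- which(stats::runif(n) < fraction)
  if (fraction >= 1) sel <- seq_len(n)
  hs <- if (is.function(h_true)) h_true(length(sel))
        else rep_len(h_true, length(sel))
  stopifnot(all(hs >= 0 & hs <= 1))
  th <- rep(NA_real_, n)
  for (k in seq_along(sel)) {
    i <- sel[k]; h <- hs[k]
    for (l in seq_along(genotypes$loci)) {
      fa <- panel$A[[genotypes$loci[l]]]
      fb <- panel$B[[genotypes$loci[l]]]
      pick <- stats::runif(2) < h
      al <- integer(2)
      for (c2 in 1:2)
        al[c2] <- if (pick[c2]) draw_from_freqs(fa, 1) else draw_from_freqs(fb, 1)
      genotypes$a1[i, l] <- al[1]
      genotypes$a2[i, l] <- al[2]
    }
    th[i] <- h
  }
  attr(genotypes, "true_h") <- th
  attr(genotypes, "is_hybridised") <- !is.na(th)
  genotypes
}

#' Silence allele copies to emulate null alleles
#'
#' Each allele copy is independently silenced with the per-locus probability
#' `null_freq`. A genotype with one silenced copy is scored as a homozygote
#' for the visible allele (the classic null-allele artefact inflating
#' homozygosity); both copies silenced gives a missing genotype.
#'
#' @param genotypes A `genotype_matrix`.
#' @param null_freq Scalar or per-locus vector of silencing probabilities in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return The degraded `genotype_matrix`.
#' @export
apply_null_alleles <- function(genotypes, null_freq, seed = 1) {
  nf <- rep_len(null_freq, length(genotypes$loci))
  stopifnot(all(nf >= 0 & nf <= 1))
  set.seed(seed)
  n <- n_individuals(genotypes)
  for (l in seq_along(genotypes$loci)) {
    called <- !is.na(genotypes$a1[, l])
    s1 <- stats::runif(n) < nf[l]
    s2 <- stats::runif(n) < nf[l]
    both <- called & s1 & s2
    only1 <- called & s1 & !s2
    only2 <- called & !s1 & s2
    genotypes$a1[both, l] <- NA_integer_
    genotypes$a2[both, l] <- NA_integer_
    genotypes$a1[only1, l] <- genotypes$a2[only1, l]
    genotypes$a2[only2, l] <- genotypes$a1[only2, l]
  }
  genotypes
}
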