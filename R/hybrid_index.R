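# Maximum-likelihood hybrid index from two parental reference panels.
# h is the proportion of an individual's alleles inherited from species A
# (h = 1: pure A). Each allele copy contributes log[h*pA + (1-h)*pB];
# the log-likelihood is concave in h, so the grid maximum is unique up to
# ties on degenerate data.

# Panel frequencies with a floor for alleles absent from a finite reference
# sample: unseen alleles get eps = 1/(2*panel_size + 1) before renormalising,
# so a single unshared allele cannot force the likelihood to -Inf.
panel_freq_floored <- function(f, alleles, panel_size) {
  eps <- 1 / (2 * panel_size + 1)
  out <- stats::setNames(rep(0, length(alleles)), alleles)
  out[names(f)[names(f) %in% alleles]] <- f[names(f) %in% alleles]
  out[out == 0] <- eps
  out / sum(out)
}

# symmetric evaluation grid: the upper half is constructed as 1 - lower
# half, so mirroring panels mirrors the grid values bitwise
sym_grid <- function(step) {
  lower <- seq(0, 0.5 - step, by = step)
  c(lower, 0.5, rev(1 - lower))
}

# index of the maximum, middle element on exact ties (mirror-stable)
argmax_mid <- function(v) {
  idx <- which(v == max(v))
  idx[ceiling(length(idx) / 2)]
}

#' Log-likelihood of a hybrid index for one individual
#'
#' @param a1,a2 Integer allele vectors over loci (`NA` = missing).
#' @param loci Locus names matching the panel.
#' @param panel A `parental_panel`.
#' @param h Hybrid index in `[0, 1]` (may be a vector; a vector of
#'   log-likelihoods is returned).
#' @return `log L(h) = sum over called copies of log[h*pA + (1-h)*pB]`.
#' @export
hybrid_loglik <- function(a1, a2, loci, panel, h) {
  stopifnot(all(h >= 0 & h <= 1))
  ll <- numeric(length(h))
  for (l in seq_along(loci)) {
    if (is.na(a1[l])) next
    fa <- panel$A[[loci[l]]]; fb <- panel$B[[loci[l]]]
    alleles <- as.character(sort(unique(as.integer(c(names(fa), names(fb),
                                                     a1[l], a2[l])))))
    pa <- panel_freq_floored(fa, alleles, panel$panel_size)
    pb <- panel_freq_floored(fb, alleles, panel$panel_size)
    for (a in c(a1[l], a2[l])) {
      key <- as.character(a)
      ll <- ll + log(h * pa[[key]] + (1 - h) * pb[[key]])
    }
  }
  ll
}

# weight-pair evaluation used by the estimator: wA and wB are supplied
# separately so that a panel swap evaluates exactly the same products in
# mirrored order (bitwise mirror symmetry of the likelihood profile)
loglik_weights <- function(pa_copies, pb_copies, wA, wB) {
  ll <- numeric(length(wA))
  for (k in seq_along(pa_copies))
    ll <- ll + log(wA * pa_copies[k] + wB * pb_copies[k])
  ll
}

#' Maximum-likelihood hybrid index for every individual
#'
#' The likelihood is maximised on a symmetric grid (default step 1e-3)
#' followed by a 1e-6 fine grid around the coarse maximum; both stages are
#' deterministic and mirror-symmetric, so swapping the two panels maps
#' every estimate to `1 - h` exactly (to floating-point precision).
#' Individuals with zero called loci get `NA` and a flag. With an
#' unidentifiable panel (identical frequency tables) estimation stops with
#' an error.
#'
#' @param genotypes A `genotype_matrix`.
#' @param panel A `parental_panel` (orientation: A = the species scored as
#'   `h = 1`).
#' @param grid_step Coarse grid step in `(0, 0.1]`.
#' @param exclude_loci Loci left out of the likelihood (default: none; a
#'   locus with heavy missing data is the classic candidate).
#' @return A data.frame of class `hybrid_index_result`: columns
#'   `individual, sample, h, logL, loci_used`.
#' @export
estimate_hybrid_index <- function(genotypes, panel, grid_step = 1e-3,
                                  exclude_loci = character()) {
  if (grid_step <= 0 || grid_step > 0.1)
    stop("grid_step must be in (0, 0.1]")
  if (!panel$identifiable)
    stop("parental panels are identical: hybrid index is unidentifiable")
  use_loci <- setdiff(intersect(genotypes$loci, panel$loci), exclude_loci)
  if (!length(use_loci)) stop("no usable loci shared with the panel")
  li <- match(use_loci, genotypes$loci)
  n <- n_individuals(genotypes)

  grid <- sym_grid(grid_step)
  grid_rev <- rev(grid)
  fine_off <- seq(-grid_step, grid_step, by = 1e-6)

  h_hat <- numeric(n); logl <- numeric(n); used <- integer(n)
  # per-locus floored panel frequencies over the union allele set
  pa_tab <- list(); pb_tab <- list()
  for (l in seq_along(use_loci)) {
    fa <- panel$A[[use_loci[l]]]; fb <- panel$B[[use_loci[l]]]
    alleles <- as.character(sort(unique(as.integer(c(
      names(fa), names(fb),
      genotypes$a1[, li[l]], genotypes$a2[, li[l]])))))
    alleles <- alleles[!is.na(alleles)]
    pa_tab[[l]] <- panel_freq_floored(fa, alleles, panel$panel_size)
    pb_tab[[l]] <- panel_freq_floored(fb, alleles, panel$panel_size)
  }

  for (i in seq_len(n)) {
    pa <- numeric(0); pb <- numeric(0)
    for (l in seq_along(use_loci)) {
      a <- c(genotypes$a1[i, li[l]], genotypes$a2[i, li[l]])
      if (is.na(a[1])) next
      key <- as.character(a)
      pa <- c(pa, pa_tab[[l]][key])
      pb <- c(pb, pb_tab[[l]][key])
    }
    if (!length(pa)) {
      h_hat[i] <- NA_real_; logl[i] <- NA_real_; used[i] <- 0L
      next
    }
    used[i] <- length(pa) / 2
    ll <- loglik_weights(pa, pb, grid, grid_rev)
    k <- argmax_mid(ll)
    centre <- grid[k]
    mirror_centre <- grid_rev[k]
    wA <- centre + fine_off
    wB <- mirror_centre - fine_off
    ok <- wA >= 0 & wA <= 1 & wB >= 0 & wB <= 1
    llf <- loglik_weights(pa, pb, wA[ok], wB[ok])
    kf <- argmax_mid(llf)
    h_hat[i] <- wA[ok][kf]
    logl[i] <- llf[kf]
  }

  out <- data.frame(individual = genotypes$individual,
                    sample = genotypes$sample,
                    h = h_hat, logL = logl, loci_used = used,
                    stringsAsFactors = FALSE)
  class(out) <- c("hybrid_index_result", "data.frame")
  attr(out, "flagged") <- genotypes$individual[used == 0]
  out
}

#' Retain pure individuals by hybrid-index threshold
#'
#' An individual is pure when its estimate reaches the threshold within a
#' numerical tolerance (a finite optimiser rarely returns exactly 1.0).
#' Defaults implement the "h < 1 is a hybrid" rule: threshold 1.0,
#' tolerance 1e-6.
#'
#' @param genotypes A `genotype_matrix`.
#' @param results The matching `hybrid_index_result`.
#' @param threshold Purity threshold in `(0, 1]`.
#' @param tolerance Numerical tolerance subtracted from the threshold.
#' @return List with `genotypes` (the retained subset), `retained` (logical
#'   per individual) and `report` (per-sample data.frame: n, n_retained,
#'   fraction).
#' @export
filter_pure <- function(genotypes, results, threshold = 1.0,
                        tolerance = 1e-6) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  stopifnot(identical(results$individual, genotypes$individual))
  keep <- !is.na(results$h) & results$h >= threshold - tolerance
  rep_df <- do.call(rbind, lapply(unique(genotypes$sample), function(s) {
    ii <- genotypes$sample == s
    data.frame(sample = s, n = sum(ii), n_retained = sum(keep & ii),
               fraction = sum(keep & ii) / sum(ii),
               stringsAsFactors = FALSE)
  }))
  if (!any(keep))
    warning("all individuals filtered out: no pure individuals at threshold ",
            threshold)
  list(genotypes = subset_genotypes(genotypes, keep),
       retained = keep, report = rep_df)
}
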