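#' Pairwise geographic distance matrix between sites
#'
#' Two metrics. `degree_euclidean` (default): straight-line distance on raw
#' decimal degrees scaled at 111.19 km per degree,
#' `d = 111.19 * sqrt(dlat^2 + dlon^2)`; this is the plane the particle
#' model lives on, and it reproduces the study region's printed pairwise
#' distances. `haversine`: great-circle distance on the WGS1984 sphere
#' (geodetically correct; systematically shorter in the east-west direction
#' at these latitudes).
#'
#' @param sites A `site_table`; outgroup rows are dropped unless
#'   `include_outgroups = TRUE`.
#' @param metric `"degree_euclidean"` or `"haversine"`.
#' @param include_outgroups Keep outgroup sites (default `FALSE`).
#' @return Symmetric distance matrix in km with site ids as labels and a
#'   `metric` attribute.
#' @export
geo_distance_matrix <- function(sites,
                                metric = c("degree_euclidean", "haversine"),
                                include_outgroups = FALSE) {
  metric <- match.arg(metric)
  if (!include_outgroups) sites <- ingroup_sites(sites)
  if (anyNA(sites$lat) || anyNA(sites$lon))
    stop("missing coordinates for site ",
         sites$site_id[is.na(sites$lat) | is.na(sites$lon)][1])
  n <- nrow(sites)
  if (metric == "degree_euclidean") {
    d <- 111.19 * sqrt(outer(sites$lat, sites$lat, "-")^2 +
                         outer(sites$lon, sites$lon, "-")^2)
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n)) {
      d[i, ] <- geosphere::distHaversine(
        cbind(sites$lon[i], sites$lat[i]),
        cbind(sites$lon, sites$lat)) / 1000
    }
  }
  dimnames(d) <- list(sites$site_id, sites$site_id)
  attr(d, "metric") <- metric
  d
}

#' Convert FST to effective migrants under Wright's infinite island model
#'
#' Inverts `FST = 1 / (1 + 4*Ne*m)` to `2*Ne*m = (1 - FST) / (2 * FST)`.
#' Non-positive FST means unbounded migration: such entries return `NA` and
#' are flagged, to be excluded from correlations.
#'
#' @param fst Numeric vector or matrix of FST values.
#' @return `2Nem` values of the same shape; `NA` where `fst <= 0`, with
#'   attribute `undefined` counting them.
#' @export
#' @examples
#' fst_to_2nem(0.2)   # 2
#' fst_to_2nem(1)     # 0
fst_to_2nem <- function(fst) {
  out <- ifelse(is.na(fst) | fst <= 0, NA_real_, (1 - fst) / (2 * fst))
  if (is.matrix(fst)) dimnames(out) <- dimnames(fst)
  attr(out, "undefined") <- sum(!is.na(fst) & fst <= 0)
  out
}

#' Pearson correlation over off-diagonal matrix cells
#'
#' Vectorises both triangles (the inputs may be asymmetric) and correlates
#' cell-wise; the diagonal is excluded by default because self-distances
#' and self-differentiation are structural zeros.
#'
#' @param A,B Square matrices with identical labels in identical order.
#' @param include_diagonal Include the diagonal cells (default `FALSE`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation coefficient.
#' @export
offdiag_pearson <- function(A, B, include_diagonal = FALSE,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  check_square_labelled(A); check_square_labelled(B)
  if (!identical(rownames(A), rownames(B)))
    stop("matrices must share labels in the same order")
  va <- if (include_diagonal) as.vector(A) else offdiag(A)
  vb <- if (include_diagonal) as.vector(B) else offdiag(B)
  ok <- !is.na(va) & !is.na(vb)
  va <- va[ok]; vb <- vb[ok]
  if (length(va) < 3) stop("fewer than 3 paired off-diagonal cells")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance in off-diagonal cells: correlation undefined")
  stats::cor(va, vb, method = method)
}

#' Mantel permutation test for (a)symmetric matrices
#'
#' Correlates the off-diagonal cells of two square matrices and assesses
#' significance by jointly permuting the rows and columns of `B` with a
#' single random site relabelling per permutation - which preserves the
#' asymmetric structure, so the test is valid for directed exchange
#' matrices as well as classical distance matrices. P-values count strictly
#' more extreme permuted correlations with the add-one rule
#' `(count + 1) / (n + 1)`; all three alternatives are always reported.
#'
#' @param A,B Square matrices, identical labels in identical order.
#' @param n_permutations Number of random relabellings (>= 99).
#' @param seed Integer seed.
#' @param method Correlation flavour passed to [offdiag_pearson()].
#' @return A `mantel_result`: list with `r`, `p_greater`, `p_less`,
#'   `p_two_sided`, `n_permutations`, `symmetric` (were both inputs
#'   symmetric?) and the permutation correlations `r_perm`.
#' @export
mantel_test <- function(A, B, n_permutations = 10000, seed = 1,
                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (n_permutations < 99) stop("use at least 99 permutations")
  check_square_labelled(A); check_square_labelled(B)
  if (!identical(rownames(A), rownames(B)))
    stop("matrix size/label mismatch: A has {",
         paste(utils::head(rownames(A)), collapse = ","), "...}, B has {",
         paste(utils::head(rownames(B)), collapse = ","), "...}")
  r_obs <- offdiag_pearson(A, B, method = method)
  n <- nrow(A)
  set.seed(seed)
  r_perm <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    pi <- sample.int(n)
    Bp <- B[pi, pi]
    dimnames(Bp) <- dimnames(B)  # relabelled in place: cells move, labels stay
    r_perm[b] <- offdiag_pearson(A, Bp, method = method)
  }
  res <- list(
    r = r_obs,
    p_greater = (sum(r_perm > r_obs) + 1) / (n_permutations + 1),
    p_less = (sum(r_perm < r_obs) + 1) / (n_permutations + 1),
    p_two_sided = (sum(abs(r_perm) > abs(r_obs)) + 1) / (n_permutations + 1),
    n_permutations = n_permutations,
    symmetric = isTRUE(all.equal(A, t(A))) && isTRUE(all.equal(B, t(B))),
    r_perm = r_perm,
    method = method
  )
  class(res) <- "mantel_result"
  res
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf(
    "Mantel test (%s, %s): r = %.4f\n  p_greater = %.4g  p_less = %.4g  p_two_sided = %.4g  [%d permutations]\n",
    x$method, if (x$symmetric) "symmetric" else "asymmetric-capable",
    x$r, x$p_greater, x$p_less, x$p_two_sided, x$n_permutations))
  invisible(x)
}

#' Isolation-by-distance Mantel test
#'
#' Symmetric-mode Mantel test of geographic distance against pairwise FST.
#'
#' @param distances Symmetric site distance matrix (km).
#' @param fst A `pairwise_fst` object or a symmetric FST matrix with the
#'   same site labels.
#' @param n_permutations,seed Passed to [mantel_test()].
#' @return A `mantel_result`.
#' @export
ibd_test <- function(distances, fst, n_permutations = 10000, seed = 1) {
  fm <- if (inherits(fst, "pairwise_fst")) fst$fst else fst
  common <- intersect(rownames(distances), rownames(fm))
  if (!setequal(rownames(distances), rownames(fm)))
    stop("site sets differ between distance and FST matrices; rows-only: {",
         paste(setdiff(rownames(distances), rownames(fm)), collapse = ", "),
         "}, fst-only: {",
         paste(setdiff(rownames(fm), rownames(distances)), collapse = ", "),
         "}")
  d <- distances[common, common]
  f <- fm[common, common]
  mantel_test(d, f, n_permutations = n_permutations, seed = seed)
}

#' Compare FST between particle-connected and unconnected site pairs
#'
#' A pair of sites is "connected" when the particle model moves particles
#' between them in either direction (symmetrised OR over the two ordered
#' cells); the diagonal (local retention) is excluded. Reports the
#' percentage by which mean FST of unconnected pairs exceeds that of
#' connected pairs, and a two-sample Kolmogorov-Smirnov comparison of the
#' two FST sets.
#'
#' @param fst A `pairwise_fst` object or symmetric FST matrix.
#' @param particles An `arrival_matrix` or a bare counts matrix with the
#'   same site labels.
#' @return List with `percent_higher`, `ks_statistic`, `ks_p`,
#'   `mean_connected`, `mean_unconnected`, `n_connected`, `n_unconnected`.
#' @export
connected_vs_unconnected <- function(fst, particles) {
  fm <- if (inherits(fst, "pairwise_fst")) fst$fst else fst
  pm <- if (inherits(particles, "arrival_matrix")) particles$counts
        else particles
  common <- intersect(rownames(fm), rownames(pm))
  if (length(common) < 3) stop("too few shared site labels")
  fm <- fm[common, common]; pm <- pm[common, common]
  up <- upper.tri(fm)
  connected <- (pm + t(pm))[up] > 0
  f_con <- fm[up][connected]
  f_unc <- fm[up][!connected]
  if (!length(f_con)) stop("empty group: no connected pairs")
  if (!length(f_unc)) stop("empty group: no unconnected pairs")
  ks <- suppressWarnings(stats::ks.test(f_unc, f_con))
  list(percent_higher = 100 * (mean(f_unc) - mean(f_con)) / mean(f_con),
       ks_statistic = unname(ks$statistic),
       ks_p = ks$p.value,
       mean_connected = mean(f_con),
       mean_unconnected = mean(f_unc),
       n_connected = length(f_con),
       n_unconnected = length(f_unc))
}
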