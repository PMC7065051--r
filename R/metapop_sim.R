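#' Configuration for the forward Wright-Fisher metapopulation simulator
#'
#' The simulator is a discrete-generation, constant-size Wright-Fisher model
#' over `n_demes` demes connected by a backward migration matrix: an
#' offspring born in deme `j` draws its parental deme `i` with probability
#' `migration[i, j]` (source rows x destination columns; columns are
#' normalised to sum to 1). Microsatellite loci mutate under the strict
#' one-step stepwise model: each transmitted allele copy changes by +/-1
#' repeat unit with probability `mutation_rate` per gamete per generation,
#' reflecting at a repeat-count floor of 1.
#'
#' @param n_demes Number of demes.
#' @param deme_sizes Diploid individuals per deme (scalar or vector, >= 2).
#' @param migration `n_demes x n_demes` backward migration matrix, source
#'   rows x destination columns. Columns are renormalised; a zero column is
#'   an error.
#' @param n_loci Number of unlinked microsatellite loci (default 7).
#' @param mutation_rate Per gamete per generation per locus (default
#'   0.001564, a microsatellite-scale rate).
#' @param n_generations Generations to run.
#' @param founder_alleles Number of equifrequent founder alleles per locus
#'   (default 20, centred near repeat count 100), or a list of per-locus
#'   named frequency vectors.
#' @return A list of class `popsim_config`.
#' @export
popsim_config <- function(n_demes, deme_sizes, migration,
                          n_loci = 7, mutation_rate = 0.001564,
                          n_generations = 100, founder_alleles = 20) {
  deme_sizes <- rep_len(deme_sizes, n_demes)
  if (any(deme_sizes < 2)) stop("deme_sizes must be >= 2")
  migration <- as.matrix(migration)
  if (!all(dim(migration) == c(n_demes, n_demes)))
    stop("migration matrix must be ", n_demes, " x ", n_demes,
         ", got ", nrow(migration), " x ", ncol(migration))
  if (any(migration < 0)) stop("migration probabilities must be >= 0")
  cs <- colSums(migration)
  if (any(cs == 0)) stop("migration matrix has a zero column (deme ",
                         which(cs == 0)[1], " has no parent source)")
  migration <- sweep(migration, 2, cs, "/")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must be in [0, 1]")
  structure(list(n_demes = n_demes, deme_sizes = deme_sizes,
                 migration = migration, n_loci = n_loci,
                 mutation_rate = mutation_rate,
                 n_generations = n_generations,
                 founder_alleles = founder_alleles),
            class = "popsim_config")
}

#' Island-model backward migration matrix
#'
#' Every deme receives a fraction `m` of its offspring from elsewhere,
#' split equally over the other demes; `1 - m` are philopatric. With deme
#' size N, `m = Nem / N` gives `Nem` effective immigrants per deme per
#' generation.
#'
#' @param n_demes Number of demes.
#' @param m Total immigration probability per offspring, in `[0, 1)`.
#' @return An `n_demes x n_demes` column-stochastic matrix.
#' @export
island_migration <- function(n_demes, m) {
  stopifnot(m >= 0, m < 1, n_demes >= 2)
  M <- matrix(m / (n_demes - 1), n_demes, n_demes)
  diag(M) <- 1 - m
  M
}

#' Forward Wright-Fisher simulation of a microsatellite metapopulation
#'
#' Runs the model described in [popsim_config()] and returns the final
#' generation's diploid genotypes. Deme sizes are constant across
#' generations (census conservation); with identity migration and zero
#' mutation each deme's allele pool changes only by resampling.
#'
#' @param config A `popsim_config`.
#' @param seed Integer seed.
#' @param sample_size Individuals to sample per deme for the returned
#'   genotypes (default all).
#' @return A `genotype_matrix` whose samples are the demes
#'   (`deme_1`, ...), with attributes `migration` (the true column-normalised
#'   backward matrix, source rows x destination columns) and `config`.
#' @export
simulate_metapopulation <- function(config, seed = 1, sample_size = NULL) {
  stopifnot(inherits(config, "popsim_config"))
  set.seed(seed)
  d <- config$n_demes
  N <- config$deme_sizes
  L <- config$n_loci
  M <- config$migration
  mu <- config$mutation_rate
  Ntot <- sum(N)
  n_copies <- 2 * Ntot

  # fixed row blocks: copies of deme j occupy rows offset[j]+1 .. offset[j]+2N_j
  offset <- c(0, cumsum(2 * N))[seq_len(d)]

  # founder pool
  if (is.list(config$founder_alleles)) {
    fp <- config$founder_alleles
    stopifnot(length(fp) == L)
    pool <- matrix(0L, n_copies, L)
    for (l in seq_len(L)) {
      f <- fp[[l]]
      if (abs(sum(f) - 1) > 1e-8) stop("founder frequencies must sum to 1")
      pool[, l] <- sample(as.integer(names(f)), n_copies, TRUE, prob = f)
    }
  } else {
    k <- config$founder_alleles
    alleles <- 100L - as.integer(ceiling(k / 2)) + seq_len(k)
    pool <- matrix(sample(alleles, n_copies * L, TRUE), n_copies, L)
  }
  storage.mode(pool) <- "integer"

  for (gen in seq_len(config$n_generations)) {
    newpool <- matrix(0L, n_copies, L)
    # destination-major offspring layout: offspring of deme j sit in j's block
    src <- integer(Ntot)
    pos <- 0
    for (j in seq_len(d)) {
      src[pos + seq_len(N[j])] <- sample.int(d, N[j], TRUE, prob = M[, j])
      pos <- pos + N[j]
    }
    for (s in seq_len(d)) {
      off <- which(src == s)
      ks <- length(off)
      if (!ks) next
      rows <- offset[s] + sample.int(2 * N[s], 2 * ks * L, TRUE)
      vals <- pool[rep((seq_len(L) - 1) * n_copies, each = 2 * ks) + rows]
      vm <- matrix(vals, 2 * ks, L)
      # offspring i's two copies sit at global copy rows 2i-1, 2i
      newpool[2 * off - 1, ] <- vm[seq_len(ks), , drop = FALSE]
      newpool[2 * off, ] <- vm[ks + seq_len(ks), , drop = FALSE]
    }
    if (mu > 0) {
      nmut <- stats::rbinom(1, n_copies * L, mu)
      if (nmut > 0) {
        idx <- sample.int(n_copies * L, nmut)
        step <- sample(c(-1L, 1L), nmut, TRUE)
        a <- newpool[idx] + step
        a[a < 1L] <- 2L  # reflect at the repeat-count floor
        newpool[idx] <- a
      }
    }
    pool <- newpool
  }

  # sample individuals per deme
  ind_deme <- rep(seq_len(d), times = N)
  if (!is.null(sample_size)) {
    keep <- unlist(lapply(seq_len(d), function(j) {
      base <- c(0, cumsum(N))[j]
      base + sort(sample.int(N[j], min(sample_size, N[j])))
    }))
  } else {
    keep <- seq_len(Ntot)
  }
  a1 <- pool[2 * keep - 1, , drop = FALSE]
  a2 <- pool[2 * keep, , drop = FALSE]
  labs <- paste0("deme_", ind_deme[keep])
  g <- genotype_matrix(a1, a2, sample = labs,
                       individual = paste0(labs, "_i", ave(keep, ind_deme[keep],
                                                           FUN = seq_along)),
                       loci = paste0("L", seq_len(L)))
  attr(g, "migration") <- M
  attr(g, "config") <- config
  g
}
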