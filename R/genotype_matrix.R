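#' Diploid multilocus genotype container
#'
#' Microsatellite genotypes are held as two integer allele matrices
#' (individuals x loci); an entry is either fully called (both alleles
#' positive integers, e.g. repeat numbers or fragment sizes) or fully missing
#' (both `NA`). Haploid records are rejected: a half-called genotype is a
#' scoring error, not data.
#'
#' @param a1,a2 Integer matrices, individuals x loci, `NA` = missing. Both
#'   alleles of a genotype must be called or both missing.
#' @param sample Character vector, one sample (population) label per
#'   individual.
#' @param individual Optional individual identifiers (default `ind_1`, ...).
#' @param loci Optional locus names (default taken from `colnames(a1)`).
#' @return An object of class `genotype_matrix` with fields `a1`, `a2`,
#'   `sample`, `individual`, `loci`.
#' @export
genotype_matrix <- function(a1, a2, sample, individual = NULL, loci = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  stopifnot(identical(dim(a1), dim(a2)), nrow(a1) == length(sample))
  if (is.null(loci)) loci <- colnames(a1) %||% paste0("L", seq_len(ncol(a1)))
  if (is.null(individual)) individual <- paste0("ind_", seq_len(nrow(a1)))
  half <- which(is.na(a1) != is.na(a2))
  if (length(half)) {
    i <- ((half[1] - 1) %% nrow(a1)) + 1
    l <- ((half[1] - 1) %/% nrow(a1)) + 1
    stop("haploid record: individual '", individual[i], "' at locus '",
         loci[l], "' has one allele called and one missing")
  }
  bad <- which(!is.na(a1) & (a1 < 1 | a2 < 1))
  if (length(bad)) stop("allele labels must be positive integers")
  colnames(a1) <- colnames(a2) <- loci
  rownames(a1) <- rownames(a2) <- individual
  structure(list(a1 = a1, a2 = a2,
                 sample = as.character(sample),
                 individual = as.character(individual),
                 loci = as.character(loci)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$individual), "individuals,",
      length(unique(x$sample)), "samples,", length(x$loci), "loci\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals
#' @param g A `genotype_matrix`.
#' @return Integer count.
#' @export
n_individuals <- function(g) length(g$individual)

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param g A `genotype_matrix`.
#' @param individuals Logical or integer index over individuals.
#' @param loci Character names, logical or integer index over loci.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(g, individuals = NULL, loci = NULL) {
  ii <- individuals %||% seq_along(g$individual)
  if (is.character(loci)) {
    miss <- setdiff(loci, g$loci)
    if (length(miss)) stop("unknown loci: ", paste(miss, collapse = ", "))
    loci <- match(loci, g$loci)
  }
  ll <- loci %||% seq_along(g$loci)
  genotype_matrix(g$a1[ii, ll, drop = FALSE], g$a2[ii, ll, drop = FALSE],
                  sample = g$sample[ii],
                  individual = g$individual[ii],
                  loci = g$loci[ll])
}

#' Read genotypes from GenePop or long CSV
#'
#' Two dialects are supported. `genepop`: the classic text format with
#' 3-digit allele coding and `000` for missing. `long_csv`: columns
#' `sample,individual,locus,allele1,allele2` with `0` coding a missing allele.
#' A record with exactly one missing allele is rejected as haploid.
#'
#' @param path File path.
#' @param dialect `"genepop"` or `"long_csv"`.
#' @return A `genotype_matrix`.
#' @export
read_genotype_table <- function(path, dialect = c("genepop", "long_csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "genepop") read_genepop(path) else read_long_csv(path)
}

read_long_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample", "individual", "locus", "allele1", "allele2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("long CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  half <- which((df$allele1 == 0) != (df$allele2 == 0))
  if (length(half))
    stop("haploid record in row ", half[1], ": individual '",
         df$individual[half[1]], "', locus '", df$locus[half[1]], "'")
  loci <- unique(df$locus)
  key <- paste(df$sample, df$individual, sep = "\r")
  inds <- unique(key)
  a1 <- matrix(NA_integer_, length(inds), length(loci),
               dimnames = list(NULL, loci))
  a2 <- a1
  ri <- match(key, inds)
  ci <- match(df$locus, loci)
  v1 <- ifelse(df$allele1 == 0, NA_integer_, as.integer(df$allele1))
  v2 <- ifelse(df$allele2 == 0, NA_integer_, as.integer(df$allele2))
  a1[cbind(ri, ci)] <- v1
  a2[cbind(ri, ci)] <- v2
  parts <- strsplit(inds, "\r", fixed = TRUE)
  genotype_matrix(a1, a2,
                  sample = vapply(parts, `[[`, "", 1),
                  individual = vapply(parts, `[[`, "", 2),
                  loci = loci)
}

#' Write genotypes as long CSV
#'
#' @param g A `genotype_matrix`.
#' @param path Output path.
#' @param provenance Optional character lines for the `#` header.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(g, path, provenance = NULL) {
  nL <- length(g$loci); nI <- length(g$individual)
  df <- data.frame(
    sample = rep(g$sample, times = nL),
    individual = rep(g$individual, times = nL),
    locus = rep(g$loci, each = nI),
    allele1 = as.vector(ifelse(is.na(g$a1), 0L, g$a1)),
    allele2 = as.vector(ifelse(is.na(g$a2), 0L, g$a2)),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(provenance)) writeLines(provenance, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- GenePop (3-digit coding) -----------------------------------------------

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("not a GenePop file: too few lines")
  body <- lines[-1]  # drop title
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop("not a GenePop file: no 'Pop' line")
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  samples <- character(); individuals <- character()
  rows1 <- list(); rows2 <- list()
  pop_no <- 0
  in_pop <- FALSE
  for (ln in body[-seq_len(pop_idx[1] - 1)]) {
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      pop_no <- pop_no + 1
      in_pop <- TRUE
      next
    }
    if (!in_pop) stop("malformed GenePop file near: ", ln)
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed GenePop record: ", ln)
    id <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(gts) != length(loci))
      stop("individual '", id, "' has ", length(gts),
           " genotypes for ", length(loci), " loci")
    w <- nchar(gts[1]) / 2
    if (!w %in% c(2, 3)) stop("unsupported allele coding width in: ", gts[1])
    g1 <- as.integer(substr(gts, 1, w))
    g2 <- as.integer(substr(gts, w + 1, 2 * w))
    half <- which((g1 == 0) != (g2 == 0))
    if (length(half))
      stop("haploid record: individual '", id, "', locus '",
           loci[half[1]], "'")
    g1[g1 == 0] <- NA_integer_; g2[g2 == 0] <- NA_integer_
    if (grepl(":", id, fixed = TRUE)) {
      sp <- strsplit(id, ":", fixed = TRUE)[[1]]
      samples <- c(samples, sp[1])
      individuals <- c(individuals, paste(sp[-1], collapse = ":"))
    } else {
      samples <- c(samples, paste0("pop_", pop_no))
      individuals <- c(individuals, id)
    }
    rows1[[length(rows1) + 1]] <- g1
    rows2[[length(rows2) + 1]] <- g2
  }
  if (!length(rows1)) stop("GenePop file has no genotype records")
  genotype_matrix(do.call(rbind, rows1), do.call(rbind, rows2),
                  sample = samples, individual = individuals, loci = loci)
}

#' Write genotypes in GenePop format (3-digit coding)
#'
#' Allele labels must be in 1..999. Missing genotypes are written as
#' `000000`. Individuals are grouped into `Pop` blocks by sample, in the
#' order samples first appear.
#'
#' @param g A `genotype_matrix`.
#' @param path Output path.
#' @param title Title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(g, path, title = "stepstone genotypes") {
  if (max(c(g$a1, g$a2), na.rm = TRUE) > 999)
    stop("GenePop 3-digit coding cannot represent alleles > 999")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(g$loci, con)
  for (s in unique(g$sample)) {
    writeLines("Pop", con)
    for (i in which(g$sample == s)) {
      enc <- sprintf("%03d%03d",
                     ifelse(is.na(g$a1[i, ]), 0L, g$a1[i, ]),
                     ifelse(is.na(g$a2[i, ]), 0L, g$a2[i, ]))
      # sample label folded into the id ("sample:individual") so that a
      # write -> read round trip preserves sample membership exactly
      writeLines(paste0(s, ":", g$individual[i], " ,  ",
                        paste(enc, collapse = " ")), con)
    }
  }
  invisible(path)
}
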