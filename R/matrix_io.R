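#' Write a labelled square matrix as CSV
#'
#' The fixed orientation throughout the package is rows = source/origin,
#' columns = destination; this is stated in the file header because the
#' exchange matrices are asymmetric and orientation mistakes are silent.
#'
#' @param m A square numeric matrix with identical row and column names.
#' @param path Output path.
#' @param hash,seed Optional provenance stamped into the `#` header.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path, hash = NULL, seed = NULL) {
  check_square_labelled(m)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(provenance_header(hash = hash, seed = seed), con)
  df <- data.frame(source = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labelled square matrix from CSV
#'
#' @param path Path to a CSV written by [write_matrix_csv()] (first column =
#'   source labels, remaining columns = destinations; `#` lines ignored).
#' @return A numeric matrix with matching row and column names.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  rn <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rn
  check_square_labelled(m)
  m
}

#' Validate a labelled square matrix
#'
#' Checks squareness and that row and column labels are identical and in
#' the same order; errors list the differing labels.
#'
#' @param m A matrix.
#' @return `TRUE` invisibly, or an error.
#' @export
check_square_labelled <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("matrix is not square: ", nrow(m), " x ", ncol(m))
  rn <- rownames(m); cn <- colnames(m)
  if (is.null(rn) || is.null(cn))
    stop("matrix must carry row and column labels")
  if (!setequal(rn, cn)) {
    d1 <- setdiff(rn, cn); d2 <- setdiff(cn, rn)
    stop("row/column label mismatch; rows-only: {",
         paste(d1, collapse = ", "), "}, columns-only: {",
         paste(d2, collapse = ", "), "}")
  }
  if (!identical(rn, cn))
    stop("row and column labels must be in the same order")
  invisible(TRUE)
}

offdiag <- function(m) m[row(m) != col(m)]
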