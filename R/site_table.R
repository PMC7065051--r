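#' Read a table of georeferenced sampling / release sites
#'
#' Sites are the sampling locations of the study and double as the release
#' and capture points of the particle tracking model. The CSV must have a
#' header with at least `site_id`, `lat` and `lon` (decimal degrees, WGS1984);
#' optional columns `full_name`, `depth_m`, `dist_shore_km` and `is_outgroup`
#' are carried through. Outgroup sites (reference populations outside the
#' study region) are retained but excluded by default from pairwise geometry.
#'
#' @param path Path to a CSV file. Lines starting with `#` are ignored.
#' @return A `data.frame` of class `site_table`, one row per site.
#' @export
read_site_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  as_site_table(df)
}

#' Validate a data frame of sites
#'
#' @param df A data.frame with columns `site_id`, `lat`, `lon` and optionally
#'   `full_name`, `depth_m`, `dist_shore_km`, `is_outgroup`.
#' @return The validated `site_table`.
#' @export
as_site_table <- function(df) {
  if (nrow(df) == 0) stop("no sites: the site table is empty")
  need <- c("site_id", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("site table is missing column(s): ",
                         paste(miss, collapse = ", "))
  df$site_id <- as.character(df$site_id)
  dup <- unique(df$site_id[duplicated(df$site_id)])
  if (length(dup)) stop("duplicate site_id: ", paste(dup, collapse = ", "))
  for (cc in c("lat", "lon")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad)) stop("unparseable ", cc, " in row ", bad[1],
                          " (site ", df$site_id[bad[1]], ")")
    if (anyNA(v)) stop("missing ", cc, " in row ", which(is.na(v))[1])
    df[[cc]] <- v
  }
  if (any(df$lat < -90 | df$lat > 90))
    stop("latitude out of range [-90, 90] in row ",
         which(df$lat < -90 | df$lat > 90)[1])
  if (any(df$lon < -180 | df$lon > 180))
    stop("longitude out of range [-180, 180] in row ",
         which(df$lon < -180 | df$lon > 180)[1])
  if (is.null(df$is_outgroup)) df$is_outgroup <- FALSE
  df$is_outgroup <- as.logical(df$is_outgroup)
  df$is_outgroup[is.na(df$is_outgroup)] <- FALSE
  if (is.null(df$full_name)) df$full_name <- df$site_id
  class(df) <- c("site_table", "data.frame")
  df
}

#' Drop outgroup sites
#'
#' @param sites A `site_table`.
#' @return The `site_table` restricted to non-outgroup rows.
#' @export
ingroup_sites <- function(sites) {
  out <- sites[!sites$is_outgroup, , drop = FALSE]
  if (nrow(out) < 2)
    stop("fewer than 2 non-outgroup sites; pairwise analyses need at least 2")
  out
}

#' Sampling sites of the southern North Sea mussel study
#'
#' The 27 sampling locations (25 study sites plus the two outgroup reference
#' populations, Limfjorden and Lisbon) with their WGS1984 coordinates and
#' distance to the nearest coastline, shipped as a plain-text CSV.
#'
#' @return A `site_table` with 27 rows, two of them flagged as outgroups.
#' @export
#' @examples
#' sites <- north_sea_sites()
#' nrow(sites)            # 27
#' sum(sites$is_outgroup) # 2
north_sea_sites <- function() {
  read_site_table(system.file("extdata", "north_sea_sites.csv",
                              package = "stepstone", mustWork = TRUE))
}
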