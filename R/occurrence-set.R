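#' Construct an occurrence set
#'
#' The unit of presence/analogue data: a data frame of point records with
#' cleaning metadata. Coordinates are kilometres on planar equal-area grids
#' (`crs = "planar_km"`, the synthetic default) or decimal degrees
#' (`crs = "lonlat"`), which switches all distance computations to
#' great-circle (haversine) distance.
#'
#' @param lon,lat coordinates (km or degrees depending on `crs`).
#' @param year integer observation year (`NA` allowed).
#' @param coord_uncertainty_m reported coordinate uncertainty in metres
#'   (`NA` allowed; must be nonnegative when present).
#' @param is_fossil,is_absence_record logical record-type flags.
#' @param source free-text provenance label.
#' @param crs `"planar_km"` or `"lonlat"`.
#' @return data.frame of class `occurrence_set`.
#' @export
occurrence_set <- function(lon, lat, year = NA_integer_,
                           coord_uncertainty_m = NA_real_,
                           is_fossil = FALSE, is_absence_record = FALSE,
                           source = "unknown", crs = "planar_km") {
  if (!all(is.finite(lon)) || !all(is.finite(lat)))
    stop("coordinates must be finite")
  if (any(coord_uncertainty_m < 0, na.rm = TRUE))
    stop("coord_uncertainty_m must be nonnegative when present")
  crs <- match.arg(crs, c("planar_km", "lonlat"))
  n <- length(lon)
  year <- rep_len(year, n); coord_uncertainty_m <- rep_len(coord_uncertainty_m, n)
  is_fossil <- rep_len(is_fossil, n)
  is_absence_record <- rep_len(is_absence_record, n)
  source <- rep_len(source, n)
  df <- data.frame(lon = as.numeric(lon), lat = as.numeric(lat),
                   year = as.integer(year),
                   coord_uncertainty_m = as.numeric(coord_uncertainty_m),
                   is_fossil = as.logical(is_fossil),
                   is_absence_record = as.logical(is_absence_record),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  attr(df, "crs") <- crs
  class(df) <- c("occurrence_set", "data.frame")
  df
}

occ_crs <- function(x) {
  crs <- attr(x, "crs")
  if (is.null(crs)) "planar_km" else crs
}

as_occurrence_set <- function(df, crs = "planar_km") {
  keep <- attr(df, "crs")
  if (!is.null(keep)) crs <- keep
  occurrence_set(df$lon, df$lat, df$year, df$coord_uncertainty_m,
                 df$is_fossil, df$is_absence_record, df$source, crs = crs)
}

# Pairwise distance matrix in km, honouring the set's CRS.
occ_dist_km <- function(a, b = a) {
  if (occ_crs(a) == "lonlat")
    outer(seq_len(nrow(a)), seq_len(nrow(b)),
          function(i, j) haversine_km(a$lon[i], a$lat[i], b$lon[j], b$lat[j]))
  else
    planar_dist_km(a[c("lon", "lat")], b[c("lon", "lat")])
}

#' Write an occurrence set to CSV
#'
#' Standard column schema: `lon, lat, year, coord_uncertainty_m, is_fossil,
#' is_absence_record, source`; extra columns are preserved.
#'
#' @param occ an `occurrence_set` (or conforming data frame).
#' @param path output path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}

#' Read an occurrence set from CSV
#'
#' @param path CSV with at least `lon` and `lat` columns; missing metadata
#'   columns are filled with defaults, extra columns pass through.
#' @param crs coordinate system of the file.
#' @return an `occurrence_set`.
#' @export
read_occurrences <- function(path, crs = "planar_km") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lon", "lat") %in% names(df)))
    stop("malformed occurrence CSV: needs lon and lat columns")
  defaults <- list(year = NA_integer_, coord_uncertainty_m = NA_real_,
                   is_fossil = FALSE, is_absence_record = FALSE,
                   source = "file")
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  out <- occurrence_set(df$lon, df$lat, df$year, df$coord_uncertainty_m,
                        df$is_fossil, df$is_absence_record, df$source,
                        crs = crs)
  extra <- setdiff(names(df), names(out))
  for (nm in extra) out[[nm]] <- df[[nm]]
  out
}
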