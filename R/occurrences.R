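#' Occurrence cleaning rules
#'
#' Encodes the standard presence-only hygiene filters: reported coordinate
#' uncertainty above a cap, records outside the predictor time frame or
#' without a year, fossil and absence records, exact duplicates, points near
#' city centres, spatial outliers far from every other record, and optional
#' polygon exclusion masks.
#'
#' @param max_uncertainty_km drop records with reported uncertainty above
#'   this (default 5 km). Records with *missing* uncertainty are kept unless
#'   `strict_uncertainty = TRUE` (observer-estimated distances are allowed).
#' @param min_year drop records before this year (default 1970).
#' @param require_year drop records without a year (default TRUE).
#' @param drop_fossils,drop_absences drop flagged records (default TRUE).
#' @param city_exclusion_km radius around supplied city centres (default 10).
#' @param outlier_radius_km drop records farther than this from every other
#'   record (default 30).
#' @param drop_duplicates drop exact coordinate duplicates after rounding to
#'   6 decimal places (default TRUE).
#' @param strict_uncertainty treat missing uncertainty as a violation.
#' @param excluded_region_masks list of polygons (each a list with `x`, `y`
#'   vertex vectors) whose interior is excluded.
#' @return object of class `cleaning_rules`.
#' @export
cleaning_rules <- function(max_uncertainty_km = 5, min_year = 1970L,
                           require_year = TRUE, drop_fossils = TRUE,
                           drop_absences = TRUE, city_exclusion_km = 10,
                           outlier_radius_km = 30, drop_duplicates = TRUE,
                           strict_uncertainty = FALSE,
                           excluded_region_masks = list()) {
  if (max_uncertainty_km <= 0 || city_exclusion_km <= 0 || outlier_radius_km <= 0)
    stop("all rule distances must be positive")
  structure(list(max_uncertainty_km = max_uncertainty_km,
                 min_year = as.integer(min_year),
                 require_year = require_year, drop_fossils = drop_fossils,
                 drop_absences = drop_absences,
                 city_exclusion_km = city_exclusion_km,
                 outlier_radius_km = outlier_radius_km,
                 drop_duplicates = drop_duplicates,
                 strict_uncertainty = strict_uncertainty,
                 excluded_region_masks = excluded_region_masks),
            class = "cleaning_rules")
}

point_in_polygon <- function(x, y, poly) {
  # even-odd ray casting
  px <- poly$x; py <- poly$y
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Clean raw occurrence records
#'
#' Applies every rule in a [cleaning_rules()] object and reports how many
#' records each rule matched (a record can match several rules; it is
#' counted once per rule and removed once). The spatial-outlier rule is
#' iterated to a fixed point so that cleaning is idempotent.
#'
#' @param records an [occurrence_set()].
#' @param rules a [cleaning_rules()].
#' @param city_points optional data frame of city centres (`lon`, `lat`, in
#'   the records' CRS); the city rule is skipped when absent.
#' @return list with `occ` (the retained `occurrence_set`) and `report`
#'   (named removal counts per rule, plus `n_in`/`n_out`; class
#'   `cleaning_report`). Removing every record is flagged with a warning,
#'   not an error.
#' @export
clean <- function(records, rules = cleaning_rules(), city_points = NULL) {
  if (nrow(records) == 0) stop("empty occurrence set")
  n <- nrow(records)
  viol <- list()
  unc_km <- records$coord_uncertainty_m / 1000
  viol$uncertainty <- ifelse(is.na(unc_km), rules$strict_uncertainty,
                             unc_km > rules$max_uncertainty_km)
  viol$missing_year <- if (rules$require_year) is.na(records$year) else rep(FALSE, n)
  viol$old_year <- !is.na(records$year) & records$year < rules$min_year
  viol$fossil <- if (rules$drop_fossils) records$is_fossil %in% TRUE else rep(FALSE, n)
  viol$absence <- if (rules$drop_absences) records$is_absence_record %in% TRUE else rep(FALSE, n)
  if (rules$drop_duplicates) {
    key <- paste(round(records$lon, 6), round(records$lat, 6))
    viol$duplicate <- duplicated(key)
  } else viol$duplicate <- rep(FALSE, n)
  if (!is.null(city_points) && nrow(city_points) > 0) {
    d <- occ_dist_km(records, city_points)
    viol$city <- apply(d, 1L, min) <= rules$city_exclusion_km
  } else viol$city <- rep(FALSE, n)
  if (length(rules$excluded_region_masks)) {
    inside <- rep(FALSE, n)
    for (poly in rules$excluded_region_masks)
      inside <- inside | point_in_polygon(records$lon, records$lat, poly)
    viol$excluded_region <- inside
  } else viol$excluded_region <- rep(FALSE, n)

  keep <- !Reduce(`|`, viol)

  # outliers: nearest neighbour among surviving records > radius; iterate to
  # a fixed point so clean(clean(x)) = clean(x)
  viol$outlier <- rep(FALSE, n)
  repeat {
    idx <- which(keep)
    if (length(idx) < 2) break
    d <- occ_dist_km(records[idx, , drop = FALSE])
    diag(d) <- Inf
    nn <- apply(d, 1L, min)
    out <- nn > rules$outlier_radius_km
    if (!any(out)) break
    viol$outlier[idx[out]] <- TRUE
    keep[idx[out]] <- FALSE
  }

  report <- structure(c(lapply(viol, sum),
                        list(n_in = n, n_out = sum(keep))),
                      class = "cleaning_report")
  if (!any(keep)) warning("all records removed by cleaning rules")
  list(occ = as_occurrence_set(records[keep, , drop = FALSE]),
       report = report)
}

#' Spatially thin an occurrence set
#'
#' Seeded random ordering followed by greedy accept-if-far-enough: a record
#' is retained iff it lies at least `min_dist_km` from every previously
#' retained record. Output is a subset of the input with all pairwise
#' distances `>= min_dist_km`; deterministic given the seed.
#'
#' @param points an [occurrence_set()].
#' @param min_dist_km minimum pairwise distance (default 30 km).
#' @param seed integer seed for the ordering.
#' @return thinned `occurrence_set`.
#' @export
thin <- function(points, min_dist_km = 30, seed = 1L) {
  if (min_dist_km <= 0) stop("min_dist_km must be positive")
  n <- nrow(points)
  if (n <= 1) return(points)
  ord <- with_seed(seed, sample.int(n))
  d <- occ_dist_km(points)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(d[i, kept] >= min_dist_km))
      kept <- c(kept, i)
  }
  as_occurrence_set(points[sort(kept), , drop = FALSE])
}

#' Remove spatial outliers
#'
#' Single pass: drops every record whose nearest neighbour (within the
#' input) is farther than `radius_km`.
#'
#' @param points an [occurrence_set()] with at least 2 records.
#' @param radius_km outlier radius (default 30 km).
#' @return `occurrence_set` without the outliers.
#' @export
remove_outliers <- function(points, radius_km = 30) {
  if (nrow(points) < 2) stop("need at least 2 points")
  d <- occ_dist_km(points)
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  as_occurrence_set(points[nn <= radius_km, , drop = FALSE])
}
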