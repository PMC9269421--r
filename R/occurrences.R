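# Occurrence records: validation, greedy radius thinning, and overlay on a
# suitability map.

EARTH_RADIUS_M <- 6371000  # mean Earth radius; haversine distances

#' Construct a validated occurrence set
#'
#' @param df data.frame with columns `species`, `lat`, `lon` (decimal
#'   degrees; `lat` in `[-90, 90]`, `lon` in `[-180, 180)`).
#' @param provenance free-text origin tag.
#' @return `ecx_occurrences` data.frame.
#' @export
occurrence_set <- function(df, provenance = "unknown") {
  need <- c("species", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss)) ecx_stop("occurrence data missing: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  bad <- which(!stats::complete.cases(df) |
                 df$lat < -90 | df$lat > 90 |
                 df$lon < -180 | df$lon >= 180)
  if (length(bad)) {
    ecx_stop("invalid coordinates at row(s): ",
             paste(utils::head(bad, 10), collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("ecx_occurrences", "data.frame"))
}

#' Read an occurrence CSV (`species, lat, lon`)
#'
#' @param path CSV path; `#` lines are skipped.
#' @return `ecx_occurrences`.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) ecx_stop("occurrence file not found: ", path)
  occurrence_set(utils::read.csv(path, comment.char = "#"), provenance = path)
}

#' Write an occurrence CSV
#'
#' @param occ `ecx_occurrences`.
#' @param path output path.
#' @param seed optional seed recorded in the metadata header.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path, seed = NULL) {
  stopifnot(inherits(occ, "ecx_occurrences"))
  write_csv_with_header(as.data.frame(occ), path,
                        ecx_metadata_header(seed, "occurrence records"))
}

#' Thin occurrence records by a distance radius
#'
#' Greedy sequential retention over points sorted by `(lat, lon, species)`:
#' a point is kept iff its great-circle distance (haversine, mean Earth
#' radius 6371 km) to every previously kept point exceeds `radius_km`.
#' Deterministic for a given input; duplicates (zero distance) always
#' collapse to one record. 10 km is the conventional radius for reducing
#' collection bias in herbarium/database records.
#'
#' @param occ `ecx_occurrences`.
#' @param radius_km thinning radius, km (>= 0).
#' @return thinned `ecx_occurrences` (a subset of the input rows).
#' @export
thin_by_radius <- function(occ, radius_km = 10) {
  stopifnot(inherits(occ, "ecx_occurrences"))
  check_number(radius_km, "radius_km", lo = 0)
  df <- as.data.frame(occ)
  if (nrow(df) <= 1L) return(occ)
  ord <- order(df$lat, df$lon, df$species)
  df <- df[ord, , drop = FALSE]
  pts <- cbind(df$lon, df$lat)
  kept <- 1L
  for (i in 2:nrow(df)) {
    d <- geosphere::distHaversine(pts[i, , drop = FALSE],
                                  pts[kept, , drop = FALSE],
                                  r = EARTH_RADIUS_M)
    if (all(d > radius_km * 1000)) kept <- c(kept, i)
  }
  out <- df[kept, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, provenance = attr(occ, "provenance"),
            class = c("ecx_occurrences", "data.frame"))
}

# Snap points to nearest cell centres of a (possibly irregular) lat/lon
# grid. Points farther than half the median cell spacing from the nearest
# centre in either axis are "outside". Returns the row index into `map`
# (NA = outside).
snap_to_cells <- function(lat, lon, map) {
  ulat <- sort(unique(map$lat))
  ulon <- sort(unique(map$lon))
  sp_lat <- if (length(ulat) > 1) stats::median(diff(ulat)) else Inf
  sp_lon <- if (length(ulon) > 1) stats::median(diff(ulon)) else Inf
  nlat <- vapply(lat, function(x) ulat[which.min(abs(ulat - x))], 0)
  nlon <- vapply(lon, function(x) ulon[which.min(abs(ulon - x))], 0)
  outside <- abs(nlat - lat) > sp_lat / 2 | abs(nlon - lon) > sp_lon / 2
  idx <- match(paste(nlat, nlon), paste(map$lat, map$lon))
  idx[outside | is.na(idx)] <- NA_integer_
  idx
}

#' Overlay occurrence points on a suitability map
#'
#' Each point is assigned to the nearest cell centre within half the median
#' cell spacing; class shares are computed over assigned points and points
#' outside the grid are counted separately. The high-class share is the
#' model-validation statistic: the percentage of known occurrences that the
#' model places in highly suitable climate.
#'
#' @param occ `ecx_occurrences`.
#' @param map `ecx_map` suitability map.
#' @return `ecx_overlay`: list with `n_points`, `n_assigned`,
#'   `n_outside_grid`, and `share_per_class` (named percentages over
#'   assigned points, summing to 100).
#' @export
overlay_occurrences <- function(occ, map) {
  stopifnot(inherits(occ, "ecx_occurrences"), inherits(map, "ecx_map"))
  if (nrow(map) == 0L) ecx_stop("suitability map is empty")
  idx <- snap_to_cells(occ$lat, occ$lon, map)
  assigned <- !is.na(idx)
  if (nrow(occ) > 0L && !any(assigned)) {
    ecx_stop("all occurrence points fall outside the grid")
  }
  cls <- factor(map$class[idx[assigned]], levels = EI_CLASSES)
  tab <- table(cls)
  share <- if (sum(tab) > 0) 100 * as.numeric(tab) / sum(tab) else rep(NA_real_, 3)
  structure(
    list(n_points = nrow(occ), n_assigned = sum(assigned),
         n_outside_grid = sum(!assigned),
         share_per_class = stats::setNames(share, EI_CLASSES)),
    class = "ecx_overlay"
  )
}

#' @export
print.ecx_overlay <- function(x, ...) {
  cat("Occurrence overlay:", x$n_points, "points,", x$n_outside_grid,
      "outside grid\n")
  print(round(x$share_per_class, 2))
  invisible(x)
}

#' Write an overlay report as JSON
#'
#' Keys: `n_points`, `share_unsuitable`, `share_low`, `share_high`,
#' `n_outside_grid`.
#'
#' @param ov `ecx_overlay`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_overlay_json <- function(ov, path) {
  stopifnot(inherits(ov, "ecx_overlay"))
  jsonlite::write_json(
    list(n_points = ov$n_points,
         share_unsuitable = ov$share_per_class[["unsuitable"]],
         share_low = ov$share_per_class[["low"]],
         share_high = ov$share_per_class[["high"]],
         n_outside_grid = ov$n_outside_grid),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
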