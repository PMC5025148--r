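# Range metrics: extent of occurrence (convex hull area on an equal-area
# projection), area of occupancy (occupied 2 km cells), Criterion B style
# range screening, the EOO < 5000 km^2 endemism rule and the natural-break
# gap profile.

#' Extent of occurrence (EOO)
#'
#' Area of the minimum convex polygon enclosing a species' localities,
#' measured on a Lambert azimuthal equal-area projection centered on the
#' points' centroid. Degenerate point sets (a single locality, coincident
#' or collinear points) fall back to the area of occupancy, so EOO for one
#' record is 4 km^2 (one occupied 2 km cell).
#'
#' @param lon,lat Numeric vectors of record coordinates (degrees, WGS84).
#' @return EOO in km^2. The convex hull vertices (lon/lat) are attached as
#'   attribute `"hull"`; attribute `"degenerate"` flags the AOO fallback.
#' @examples
#' compute_eoo(c(0, 1, 0), c(0, 0, 1))
#' @export
compute_eoo <- function(lon, lat) {
  if (length(lon) == 0) kd_stop("compute_eoo: empty point set")
  if (length(lon) != length(lat)) kd_stop("lon/lat length mismatch")
  check_coords(lon, lat)
  xy <- laea_project(lon, lat, mean(lon), mean(lat))
  h <- chull(xy)
  area <- if (length(h) >= 3) shoelace_area(xy[h, , drop = FALSE]) else 0
  if (area <= 1e-9) {
    out <- compute_aoo(lon, lat)
    attr(out, "hull") <- cbind(lon = lon[h], lat = lat[h])
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  structure(area, hull = cbind(lon = lon[h], lat = lat[h]),
            degenerate = FALSE)
}

#' Area of occupancy (AOO)
#'
#' Counts distinct occupied cells of a `cell_km` x `cell_km` grid laid out
#' in a Lambert azimuthal equal-area projection and returns
#' `cell_km^2 * n_cells` (the IUCN convention: 4 km^2 per occupied 2 km
#' cell). The grid is anchored at the projection origin, which defaults to
#' (0, 0) so that the measure is monotone when records are added; no
#' origin optimization is attempted.
#'
#' @param lon,lat Record coordinates (degrees).
#' @param cell_km Grid cell edge length in km (default 2).
#' @param origin Projection center `c(lon0, lat0)` (default `c(0, 0)`).
#' @return AOO in km^2.
#' @export
compute_aoo <- function(lon, lat, cell_km = 2, origin = c(0, 0)) {
  if (length(lon) == 0) kd_stop("compute_aoo: empty point set")
  check_coords(lon, lat)
  xy <- laea_project(lon, lat, origin[1], origin[2])
  idx <- paste(floor(xy[, 1] / cell_km), floor(xy[, 2] / cell_km))
  as.numeric(cell_km^2 * length(unique(idx)))
}

#' @noRd
check_coords <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)) ||
      any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90)) {
    kd_stop("coordinates must be finite, lon in [-180,180], lat in [-90,90]")
  }
  invisible(TRUE)
}

#' Criterion B style range screening
#'
#' Range-threshold screening only (no subcriteria): CR if EOO < 100 or
#' AOO < 10; else EN if EOO < 5000 or AOO < 500; else VU if EOO < 20000 or
#' AOO < 2000; else LC. Thresholds in km^2.
#'
#' @param eoo_km2,aoo_km2 Non-negative areas; `aoo_km2` defaults to `Inf`
#'   (EOO-only screening).
#' @return Character vector of categories.
#' @examples
#' screen_criterion_b(4000)       # "EN"
#' screen_criterion_b(6000, 2500) # "VU"
#' @export
screen_criterion_b <- function(eoo_km2, aoo_km2 = Inf) {
  n <- max(length(eoo_km2), length(aoo_km2))
  eoo_km2 <- rep_len(as.numeric(eoo_km2), n)
  aoo_km2 <- rep_len(as.numeric(aoo_km2), n)
  if (any(is.na(eoo_km2)) || any(eoo_km2 < 0) ||
      any(is.na(aoo_km2)) || any(aoo_km2 < 0)) {
    kd_stop("EOO/AOO must be non-negative")
  }
  out <- rep("LC", n)
  out[eoo_km2 < 20000 | aoo_km2 < 2000] <- "VU"
  out[eoo_km2 < 5000 | aoo_km2 < 500] <- "EN"
  out[eoo_km2 < 100 | aoo_km2 < 10] <- "CR"
  out
}

#' Range-based endemism flag
#'
#' A species is treated as endemic (narrow-range) when its extent of
#' occurrence is strictly below 5000 km^2 — the Criterion B cut-off for EN
#' and the natural break in the range-size distribution.
#'
#' @param eoo_km2 Non-negative EOO values.
#' @return Logical vector.
#' @export
flag_endemic <- function(eoo_km2) {
  if (any(is.na(eoo_km2)) || any(eoo_km2 < 0)) kd_stop("EOO must be >= 0")
  eoo_km2 < 5000
}

#' Successive-gap profile of EOO values
#'
#' Sorts range sizes and reports the gap to the next value and that gap as
#' a fraction of the smaller value, supporting natural-break inspection of
#' the endemism threshold.
#'
#' @param eoo_km2 Named (by species) numeric vector, length >= 2.
#' @return Data frame sorted ascending with columns `species_id`,
#'   `eoo_km2`, `gap` and `rel_gap` (last row has `NA` gaps).
#' @export
eoo_gap_profile <- function(eoo_km2) {
  if (length(eoo_km2) < 2) kd_stop("need >= 2 species")
  ids <- names(eoo_km2)
  if (is.null(ids)) ids <- as.character(seq_along(eoo_km2))
  o <- order(eoo_km2)
  v <- eoo_km2[o]
  gap <- c(diff(v), NA_real_)
  data.frame(species_id = ids[o], eoo_km2 = as.numeric(v),
             gap = gap, rel_gap = gap / ifelse(v > 0, v, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-species range summary
#'
#' Computes EOO, AOO, the screened range-only category and the endemism
#' flag for every species in an occurrence table.
#'
#' @param occurrences Data frame with columns `species_id`, `lon`, `lat`.
#' @param cell_km AOO grid cell edge (km).
#' @return Data frame with columns `species_id`, `n_points`, `eoo_km2`,
#'   `aoo_km2`, `screened_status`, `endemic` and `eoo_lt_aoo` (flagging
#'   hull areas smaller than the occupancy estimate).
#' @export
summarize_ranges <- function(occurrences, cell_km = 2) {
  stopifnot(all(c("species_id", "lon", "lat") %in% names(occurrences)))
  sp <- split(occurrences, occurrences$species_id)
  rows <- lapply(sp, function(d) {
    eoo <- compute_eoo(d$lon, d$lat)
    aoo <- compute_aoo(d$lon, d$lat, cell_km = cell_km)
    data.frame(species_id = d$species_id[1], n_points = nrow(d),
               eoo_km2 = as.numeric(eoo), aoo_km2 = aoo,
               screened_status = screen_criterion_b(as.numeric(eoo), aoo),
               endemic = flag_endemic(as.numeric(eoo)),
               eoo_lt_aoo = as.numeric(eoo) < aoo,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
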