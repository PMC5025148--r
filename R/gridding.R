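# Degree fishnet over a study polygon, record-to-cell assignment and
# per-cell richness and mean-score metrics.

#' Build a degree fishnet over a study region
#'
#' Lays a `cell_deg` x `cell_deg` graticule aligned to `origin` over the
#' region polygon(s), clips every intersecting cell to the region and
#' computes its land area on the sphere. Cells with no intersection are
#' dropped. Cell ids follow map-sheet convention: a letter for the latitude
#' row (A at the southern edge, increasing north) and a number for the
#' longitude column (1 at the western edge, increasing east) — labels are
#' cosmetic and never used in computation.
#'
#' @param region A two-column (lon, lat) ring matrix or a list of such
#'   rings (multipolygon; rings assumed disjoint, holes unsupported).
#' @param cell_deg Cell size in degrees (default 1).
#' @param origin Graticule anchor `c(lon, lat)` (default `c(0, 0)`).
#' @return Object of class `fishnet_grid`: a data frame with columns
#'   `cell_id`, `lon0`, `lat0`, `lon1`, `lat1`, `land_area_km2`,
#'   `centroid_lon`, `centroid_lat`, with the clipped polygon rings in
#'   attribute `"polygons"` (a named list of lists of rings) and the grid
#'   parameters in attributes `"cell_deg"` and `"origin"`.
#' @export
build_fishnet <- function(region, cell_deg = 1, origin = c(0, 0)) {
  if (is.matrix(region)) region <- list(region)
  if (!length(region) || !all(vapply(region, function(r)
    is.matrix(r) && nrow(r) >= 3, logical(1)))) {
    kd_stop("region must be one or more rings with >= 3 vertices")
  }
  if (cell_deg <= 0) kd_stop("cell_deg must be positive")
  allv <- do.call(rbind, region)
  lon_lo <- origin[1] + cell_deg * floor((min(allv[, 1]) - origin[1]) / cell_deg)
  lat_lo <- origin[2] + cell_deg * floor((min(allv[, 2]) - origin[2]) / cell_deg)
  lons <- seq(lon_lo, max(allv[, 1]) - 1e-12, by = cell_deg)
  lats <- seq(lat_lo, max(allv[, 2]) - 1e-12, by = cell_deg)
  rows <- list(); polys <- list()
  for (j in seq_along(lats)) {
    for (i in seq_along(lons)) {
      x0 <- lons[i]; y0 <- lats[j]
      pieces <- list()
      for (r in region) {
        cl <- clip_ring_rect(r, x0, y0, x0 + cell_deg, y0 + cell_deg)
        if (!is.null(cl) && shoelace_area(cl) > 1e-10) {
          pieces[[length(pieces) + 1L]] <- cl
        }
      }
      if (!length(pieces)) next
      area <- sum(vapply(pieces, ring_area_km2, numeric(1)))
      if (area <= 0) next
      # area-weighted centroid over pieces (planar, adequate at 1 degree)
      cw <- vapply(pieces, function(p) shoelace_area(p), numeric(1))
      cents <- t(vapply(pieces, ring_centroid, numeric(2)))
      cen <- colSums(cents * cw) / sum(cw)
      id <- paste0(cell_letter(j), i)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = id, lon0 = x0, lat0 = y0,
        lon1 = x0 + cell_deg, lat1 = y0 + cell_deg,
        land_area_km2 = area,
        centroid_lon = cen[1], centroid_lat = cen[2],
        stringsAsFactors = FALSE)
      polys[[id]] <- pieces
    }
  }
  if (!length(rows)) kd_stop("region does not intersect the graticule")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, polygons = polys, cell_deg = cell_deg, origin = origin,
            class = c("fishnet_grid", "data.frame"))
}

#' Spreadsheet-style letters A, B, ..., Z, AA, AB, ...
#' @noRd
cell_letter <- function(i) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]; s <- ""
    while (n > 0) {
      r <- (n - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      n <- (n - 1) %/% 26
    }
    out[k] <- s
  }
  out
}

#' Assign occurrence records to grid cells
#'
#' Membership is half-open: a record belongs to the cell with
#' `lon0 <= lon < lon1` and `lat0 <= lat < lat1`, so records exactly on an
#' interior edge fall in the cell to the east/north. Records whose cell is
#' not part of the grid (outside the region) are left unassigned and
#' reported with a warning.
#'
#' @param occurrences Data frame with `species_id`, `lon`, `lat`.
#' @param grid A `fishnet_grid`.
#' @return The occurrence data frame with an added `cell_id` column (`NA`
#'   for unassigned records); the unassigned count is attached as attribute
#'   `"n_unassigned"`.
#' @export
assign_records <- function(occurrences, grid) {
  stopifnot(inherits(grid, "fishnet_grid"))
  check_coords(occurrences$lon, occurrences$lat)
  cd <- attr(grid, "cell_deg"); org <- attr(grid, "origin")
  key <- function(lon, lat) paste(floor((lon - org[1]) / cd),
                                  floor((lat - org[2]) / cd))
  gkey <- key(grid$lon0 + cd / 2, grid$lat0 + cd / 2)
  m <- match(key(occurrences$lon, occurrences$lat), gkey)
  occurrences$cell_id <- grid$cell_id[m]
  n_un <- sum(is.na(m))
  if (n_un > 0) kd_warn("%d record(s) fall outside the grid; unassigned", n_un)
  attr(occurrences, "n_unassigned") <- n_un
  occurrences
}

#' Per-cell richness and mean-score metrics
#'
#' For every grid cell computes the record count, the deduplicated species
#' set, four richness counts — total, threatened (CR/EN/VU species),
#' endemic (EOO < 5000 km^2) and sensitive (LH = 3) — and the mean of each
#' of the six composite scores over the species present (species-level
#' averaging: record multiplicity does not enter). Cells without records
#' are kept as no-data rows (`NA` metrics), distinct from zero.
#'
#' @param assigned Occurrence table with `cell_id` (from
#'   [assign_records()]).
#' @param grid A `fishnet_grid`.
#' @param scores Score table from [score_species()] (must cover every
#'   species present; DD species must have been excluded upstream).
#' @param ranges Optional range summary from [summarize_ranges()]; if
#'   `NULL`, `richness_endemic` is `NA`.
#' @return Data frame, one row per grid cell: `cell_id`, `n_records`,
#'   `richness_total`, `richness_threatened`, `richness_endemic`,
#'   `richness_sensitive`, `land_area_km2` and columns `mean_<name>` for
#'   the six composites. Per-cell species sets are in attribute
#'   `"species"`.
#' @export
cell_metrics <- function(assigned, grid, scores, ranges = NULL) {
  stopifnot(inherits(grid, "fishnet_grid"))
  ok <- !is.na(assigned$cell_id)
  asg <- assigned[ok, , drop = FALSE]
  missing_sp <- setdiff(unique(asg$species_id), scores$species_id)
  if (length(missing_sp)) {
    kd_stop("species without score rows: %s",
            paste(missing_sp, collapse = ", "))
  }
  threatened <- scores$status %in% c("CR", "EN", "VU")
  names(threatened) <- scores$species_id
  sensitive <- scores$LH == 3
  names(sensitive) <- scores$species_id
  endemic <- NULL
  if (!is.null(ranges)) {
    endemic <- setNames(ranges$endemic, ranges$species_id)
  }
  comp <- composite_names()
  smat <- as.matrix(scores[, comp])
  rownames(smat) <- scores$species_id

  sets <- split(asg$species_id, asg$cell_id)
  nrec <- vapply(sets, length, integer(1))
  sets <- lapply(sets, unique)

  out <- data.frame(cell_id = grid$cell_id, n_records = 0L,
                    richness_total = NA_integer_,
                    richness_threatened = NA_integer_,
                    richness_endemic = NA_integer_,
                    richness_sensitive = NA_integer_,
                    land_area_km2 = grid$land_area_km2,
                    stringsAsFactors = FALSE)
  for (nm in comp) out[[paste0("mean_", nm)]] <- NA_real_
  rownames(out) <- out$cell_id
  for (cid in names(sets)) {
    sp <- sets[[cid]]
    out[cid, "n_records"] <- nrec[[cid]]
    out[cid, "richness_total"] <- length(sp)
    out[cid, "richness_threatened"] <- sum(threatened[sp])
    out[cid, "richness_sensitive"] <- sum(sensitive[sp])
    out[cid, "richness_endemic"] <- if (is.null(endemic)) NA_integer_ else {
      if (any(is.na(endemic[sp]))) NA_integer_ else sum(endemic[sp])
    }
    out[cid, paste0("mean_", comp)] <-
      colMeans(smat[sp, , drop = FALSE])
  }
  rownames(out) <- NULL
  attr(out, "species") <- sets
  out
}

#' Species-by-cell incidence or abundance matrix
#'
#' Builds the community matrix (rows = cells with data, columns = species)
#' used by the rarefaction module.
#'
#' @param assigned Occurrence table with `cell_id`.
#' @param counts If `TRUE` (default) entries are record counts; otherwise
#'   presence/absence 0/1.
#' @return Integer matrix with cell ids as row names.
#' @export
community_matrix <- function(assigned, counts = TRUE) {
  ok <- !is.na(assigned$cell_id)
  tab <- table(assigned$cell_id[ok], assigned$species_id[ok])
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  if (!counts) m <- (m > 0) + 0L
  m
}

#' Write a fishnet grid to GeoJSON
#'
#' @param grid A `fishnet_grid`.
#' @param path Output path.
#' @export
write_grid_geojson <- function(grid, path) {
  polys <- attr(grid, "polygons")
  rings <- list(); props <- list()
  for (i in seq_len(nrow(grid))) {
    pieces <- polys[[grid$cell_id[i]]]
    for (p in pieces) {
      rings[[length(rings) + 1L]] <- p
      props[[length(props) + 1L]] <- data.frame(
        cell_id = grid$cell_id[i], land_area_km2 = grid$land_area_km2[i],
        stringsAsFactors = FALSE)
    }
  }
  write_geojson_polygons(rings, path, properties = do.call(rbind, props))
}
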