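# Minimal planar/spherical geometry used by the gridding and range modules:
# Lambert azimuthal equal-area projection, Sutherland-Hodgman clipping of a
# polygon ring by an axis-aligned rectangle, spherical polygon areas and
# GeoJSON polygon I/O. Rings are two-column (lon, lat) matrices, not closed
# (first vertex is not repeated at the end); holes are not supported.

KD_EARTH_RADIUS_KM <- 6371.0088  # mean Earth radius

#' Lambert azimuthal equal-area projection
#'
#' Projects lon/lat (degrees, WGS84 treated as spherical) to planar km,
#' centered at (`lon0`, `lat0`). Equal-area everywhere, so areas measured
#' in the projected plane equal spherical areas.
#'
#' @param lon,lat Numeric vectors of coordinates in degrees.
#' @param lon0,lat0 Projection center in degrees.
#' @return Two-column matrix (x, y) in km.
#' @export
laea_project <- function(lon, lat, lon0, lat0) {
  to <- pi / 180
  lam <- lon * to; phi <- lat * to
  lam0 <- lon0 * to; phi0 <- lat0 * to
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  denom[denom < 1e-12] <- 1e-12  # antipode guard
  kp <- sqrt(2 / denom)
  cbind(x = KD_EARTH_RADIUS_KM * kp * cos(phi) * sin(lam - lam0),
        y = KD_EARTH_RADIUS_KM * kp *
          (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0)))
}

#' Planar polygon area (shoelace)
#' @param xy Two-column matrix of ring vertices (not closed).
#' @return Absolute area in squared input units.
#' @noRd
shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}

#' Clip a polygon ring to an axis-aligned rectangle
#'
#' Sutherland--Hodgman clipping of an arbitrary (possibly non-convex)
#' polygon ring against the rectangle `[xmin, xmax] x [ymin, ymax]`.
#'
#' @param ring Two-column matrix (lon, lat), vertices in order, not closed.
#' @param xmin,ymin,xmax,ymax Rectangle bounds.
#' @return Clipped ring matrix, or `NULL` if the intersection is empty.
#' @export
clip_ring_rect <- function(ring, xmin, ymin, xmax, ymax) {
  clip_edge <- function(pts, keep, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- vector("list", 2L * n)
    k <- 0L
    prev <- pts[n, ]
    prev_in <- keep(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- keep(cur)
      if (cur_in) {
        if (!prev_in) { k <- k + 1L; out[[k]] <- intersect(prev, cur) }
        k <- k + 1L; out[[k]] <- cur
      } else if (prev_in) {
        k <- k + 1L; out[[k]] <- intersect(prev, cur)
      }
      prev <- cur; prev_in <- cur_in
    }
    if (k == 0L) return(ring[0, , drop = FALSE])
    do.call(rbind, out[seq_len(k)])
  }
  ix <- function(p, q, val, axis) {
    # intersection of segment pq with line axis == val
    t <- (val - p[axis]) / (q[axis] - p[axis])
    p + t * (q - p)
  }
  pts <- ring
  pts <- clip_edge(pts, function(p) p[1] >= xmin, function(p, q) ix(p, q, xmin, 1))
  pts <- clip_edge(pts, function(p) p[1] <= xmax, function(p, q) ix(p, q, xmax, 1))
  pts <- clip_edge(pts, function(p) p[2] >= ymin, function(p, q) ix(p, q, ymin, 2))
  pts <- clip_edge(pts, function(p) p[2] <= ymax, function(p, q) ix(p, q, ymax, 2))
  if (nrow(pts) < 3) return(NULL)
  # drop consecutive duplicates
  d <- c(TRUE, rowSums(abs(diff(pts))) > 1e-12)
  pts <- pts[d, , drop = FALSE]
  if (nrow(pts) >= 2 && all(abs(pts[1, ] - pts[nrow(pts), ]) < 1e-12)) {
    pts <- pts[-nrow(pts), , drop = FALSE]
  }
  if (nrow(pts) < 3) return(NULL)
  colnames(pts) <- c("lon", "lat")
  pts
}

#' Spherical area of a lon/lat ring in square km
#'
#' @param ring Two-column (lon, lat) matrix, not closed.
#' @return Area in km^2 (WGS84 ellipsoid, via geosphere).
#' @export
ring_area_km2 <- function(ring) {
  if (is.null(ring) || nrow(ring) < 3) return(0)
  abs(geosphere::areaPolygon(ring)) / 1e6
}

#' Planar centroid of a ring (in lon/lat degrees)
#' @noRd
ring_centroid <- function(ring) {
  n <- nrow(ring)
  i2 <- c(2:n, 1)
  cr <- ring[, 1] * ring[i2, 2] - ring[i2, 1] * ring[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(ring))
  c(lon = sum((ring[, 1] + ring[i2, 1]) * cr) / (6 * a),
    lat = sum((ring[, 2] + ring[i2, 2]) * cr) / (6 * a))
}

#' Point-in-polygon test (even-odd rule)
#' @param lon,lat Point coordinates.
#' @param ring Two-column ring matrix.
#' @return Logical vector.
#' @export
point_in_ring <- function(lon, lat, ring) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  vapply(seq_along(lon), function(k) {
    x <- lon[k]; y <- lat[k]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((ys[i] > y) != (ys[j] > y) &&
          x < (xs[j] - xs[i]) * (y - ys[i]) / (ys[j] - ys[i]) + xs[i]) {
        inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

# ---- GeoJSON ------------------------------------------------------------

#' Read polygons from a GeoJSON file
#'
#' Accepts a FeatureCollection, Feature or bare geometry of type Polygon or
#' MultiPolygon (RFC 7946, WGS84). Only outer rings are used; interior
#' rings (holes) are dropped with a warning.
#'
#' @param path Path to a `.geojson` / `.json` file.
#' @return List of two-column (lon, lat) ring matrices (not closed), with
#'   a `names` attribute from feature `id`/`name` properties when present.
#' @export
read_geojson_polygons <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- switch(g$type,
    FeatureCollection = g$features,
    Feature = list(g),
    Polygon = list(list(geometry = g)),
    MultiPolygon = list(list(geometry = g)),
    kd_stop("unsupported GeoJSON type: %s", g$type))
  rings <- list(); nms <- character(0); holes <- 0L
  ring_mat <- function(r) {
    m <- do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))
    if (all(abs(m[1, ] - m[nrow(m), ]) < 1e-12)) m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("lon", "lat")
    m
  }
  for (f in feats) {
    geom <- f$geometry
    nm <- f$properties$name
    if (is.null(nm)) nm <- if (!is.null(f$id)) as.character(f$id) else ""
    if (geom$type == "Polygon") {
      holes <- holes + max(0L, length(geom$coordinates) - 1L)
      rings <- c(rings, list(ring_mat(geom$coordinates[[1]])))
      nms <- c(nms, nm)
    } else if (geom$type == "MultiPolygon") {
      for (poly in geom$coordinates) {
        holes <- holes + max(0L, length(poly) - 1L)
        rings <- c(rings, list(ring_mat(poly[[1]])))
        nms <- c(nms, nm)
      }
    } else {
      kd_stop("unsupported geometry type: %s", geom$type)
    }
  }
  if (holes > 0) kd_warn("%d interior ring(s) (holes) dropped", holes)
  if (!length(rings)) kd_stop("no polygons found in %s", path)
  names(rings) <- nms
  rings
}

#' Write polygons to a GeoJSON FeatureCollection
#'
#' @param rings List of two-column (lon, lat) ring matrices (not closed).
#' @param path Output file path.
#' @param properties Optional data frame of per-feature properties.
#' @export
write_geojson_polygons <- function(rings, path, properties = NULL) {
  if (is.matrix(rings)) rings <- list(rings)
  feats <- lapply(seq_along(rings), function(i) {
    r <- rings[[i]]
    coords <- lapply(seq_len(nrow(r) + 1L), function(j) {
      k <- if (j > nrow(r)) 1L else j
      c(r[k, 1], r[k, 2])
    })
    props <- if (is.null(properties)) {
      nm <- names(rings)[i]
      if (is.null(nm) || !nzchar(nm)) stats::setNames(list(), character(0))
      else list(name = nm)
    } else as.list(properties[i, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
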