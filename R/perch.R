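#' Median location of a perching event
#'
#' The coordinate-wise median of the GPS fixes recorded while the owl was
#' perched, i.e. from the landing until the next take-off (or for 60 s if no
#' take-off follows). The median suppresses GPS jitter around the true perch.
#'
#' @param perch_sec Landing time of the perching event, s.
#' @param takeoffs Take-off times of the night, s.
#' @param gps 1 Hz track (tibble `t`, `x`, `y`).
#' @return Numeric `c(x, y)`; `c(NA, NA)` when no fix falls in the interval.
#' @export
median_location <- function(perch_sec, takeoffs, gps) {
  nxt <- takeoffs[takeoffs > perch_sec]
  t_end <- if (length(nxt)) nxt[1] else perch_sec + 60
  sel <- gps$t >= perch_sec & gps$t < t_end
  if (!any(sel)) return(c(NA_real_, NA_real_))
  c(stats::median(gps$x[sel]), stats::median(gps$y[sel]))
}

#' Assign a perch type from the habitat within 2 m
#'
#' The perch type of the nearest habitat feature within `radius` meters of
#' the location: point distance for poles and trees, boundary distance for
#' building polygons (zero inside the polygon). No feature within the radius
#' gives `"unknown"`. Exact distance ties break by the fixed priority
#' pole > tree > building.
#'
#' @param location Numeric `c(x, y)` in map units (m).
#' @param map Habitat feature table (see [generate_habitat_map()]).
#' @param radius Search radius, m.
#' @return One of `"pole"`, `"tree"`, `"building"`, `"unknown"`.
#' @export
assign_perch_type <- function(location, map, radius = 2) {
  if (nrow(map) == 0 || anyNA(location)) return("unknown")
  d <- vapply(seq_len(nrow(map)), function(i) {
    feature_distance(location, map$coords[[i]], map$geom_type[i])
  }, numeric(1))
  near <- which(d <= radius)
  if (!length(near)) return("unknown")
  dmin <- min(d[near])
  tied <- near[abs(d[near] - dmin) < 1e-9]
  if (length(tied) > 1) {
    pri <- c(pole = 1, tree = 2, building = 3)
    tied <- tied[order(pri[map$perch_type[tied]])]
  }
  map$perch_type[tied[1]]
}

# distance from a point to a feature geometry
feature_distance <- function(p, coords, geom_type) {
  if (geom_type == "point") {
    return(sqrt((p[1] - coords[1, 1])^2 + (p[2] - coords[1, 2])^2))
  }
  if (point_in_polygon(p, coords)) return(0)
  n <- nrow(coords)
  min(vapply(seq_len(n - 1L), function(i) {
    point_segment_distance(p, coords[i, ], coords[i + 1L, ])
  }, numeric(1)))
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  tt <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  proj <- a + tt * ab
  sqrt(sum((p - proj)^2))
}

# even-odd ray casting
point_in_polygon <- function(p, coords) {
  n <- nrow(coords)
  if (all(coords[1, ] == coords[n, ])) n <- n - 1L
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- coords[i, 1]; yi <- coords[i, 2]
    xj <- coords[j, 1]; yj <- coords[j, 2]
    if ((yi > p[2]) != (yj > p[2]) &&
        p[1] < (xj - xi) * (p[2] - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

#' Read a habitat map from GeoJSON
#'
#' Accepts a FeatureCollection of Point and Polygon features carrying a
#' `perch_type` property from the closed set pole/tree/building; planar
#' coordinates in meters (or lon/lat under a declared local equirectangular
#' projection handled upstream).
#'
#' @param path GeoJSON file path.
#' @return Habitat feature tibble (`id`, `perch_type`, `geom_type`, `coords`).
#' @export
read_habitat_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  feats <- gj$features
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    type <- f$properties$perch_type
    if (is.null(type) || !type %in% c("pole", "tree", "building")) {
      stop("feature ", i, " lacks a valid perch_type property")
    }
    gtype <- tolower(f$geometry$type)
    coords <- if (gtype == "point") {
      matrix(unlist(f$geometry$coordinates), ncol = 2)
    } else if (gtype == "polygon") {
      ring <- f$geometry$coordinates[[1]]
      do.call(rbind, lapply(ring, function(xy) unlist(xy)[1:2]))
    } else {
      stop("unsupported geometry type: ", f$geometry$type)
    }
    tibble::tibble(id = i, perch_type = type, geom_type = gtype,
                   coords = list(coords))
  })
  dplyr::bind_rows(rows)
}

#' Write a habitat map to GeoJSON
#'
#' @param map Habitat feature tibble (see [generate_habitat_map()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_habitat_geojson <- function(map, path) {
  feats <- lapply(seq_len(nrow(map)), function(i) {
    coords <- map$coords[[i]]
    geometry <- if (map$geom_type[i] == "point") {
      list(type = "Point", coordinates = as.numeric(coords[1, ]))
    } else {
      ring <- lapply(seq_len(nrow(coords)), function(j) as.numeric(coords[j, ]))
      list(type = "Polygon", coordinates = list(ring))
    }
    list(type = "Feature",
         properties = list(perch_type = map$perch_type[i]),
         geometry = geometry)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
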