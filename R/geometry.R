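# Planar/spherical geometry primitives shared by the IO, feature and
# simulation layers. All spherical computations use a sphere of radius
# 6,371,000 m; at paddock scale (<1 km) the sphere/ellipsoid difference is
# far below the 4.4 m GPS error.

EARTH_RADIUS_M <- 6371000

.deg2rad <- function(x) x * pi / 180

#' Great-circle distance between fixes
#'
#' Haversine distance on a sphere of radius 6,371,000 m. Vectorised over all
#' four coordinate arguments (recycled as usual).
#'
#' @param lat1,lon1 Coordinates of the first fix, decimal degrees WGS84.
#' @param lat2,lon2 Coordinates of the second fix, decimal degrees WGS84.
#' @return Distance(s) in metres. Zero if and only if the coordinates are
#'   identical; symmetric in its arguments.
#' @examples
#' haversine_distance(0, 0, 0, 1)   # ~111.19 km, one degree of longitude
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2) {
  stopifnot(is.numeric(lat1), is.numeric(lon1), is.numeric(lat2), is.numeric(lon2))
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90]")
  }
  phi1 <- .deg2rad(lat1)
  phi2 <- .deg2rad(lat2)
  dphi <- .deg2rad(lat2 - lat1)
  dlam <- .deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_M * asin(sqrt(a))
}

#' Project WGS84 coordinates to a local planar frame
#'
#' Equirectangular projection about an origin: x is metres east, y metres
#' north of the origin. Intended for paddock-scale work; points more than one
#' degree from the origin are rejected because the local approximation breaks
#' down there.
#'
#' @param lat,lon Coordinates to project, decimal degrees (vectorised).
#' @param origin_lat,origin_lon Origin of the local frame, decimal degrees.
#' @return A two-column matrix with columns `x` and `y`, in metres.
#' @seealso [local_xy_to_wgs84()] for the exact inverse.
#' @examples
#' to_local_xy(-27.551, 152.333, -27.552, 152.333)  # ~111 m north of origin
#' @export
to_local_xy <- function(lat, lon, origin_lat, origin_lon) {
  stopifnot(length(origin_lat) == 1, length(origin_lon) == 1)
  if (any(abs(lat - origin_lat) > 1 | abs(lon - origin_lon) > 1, na.rm = TRUE)) {
    stop("points farther than 1 degree from the origin: local projection invalid")
  }
  x <- EARTH_RADIUS_M * cos(.deg2rad(origin_lat)) * .deg2rad(lon - origin_lon)
  y <- EARTH_RADIUS_M * .deg2rad(lat - origin_lat)
  cbind(x = x, y = y)
}

#' Inverse of [to_local_xy()]
#'
#' @param x,y Local planar coordinates in metres (vectorised).
#' @param origin_lat,origin_lon Origin of the local frame, decimal degrees.
#' @return A two-column matrix with columns `lat` and `lon`.
#' @export
local_xy_to_wgs84 <- function(x, y, origin_lat, origin_lon) {
  stopifnot(length(origin_lat) == 1, length(origin_lon) == 1)
  lat <- origin_lat + (y / EARTH_RADIUS_M) * 180 / pi
  lon <- origin_lon + (x / (EARTH_RADIUS_M * cos(.deg2rad(origin_lat)))) * 180 / pi
  cbind(lat = lat, lon = lon)
}

# Shoelace signed area of a polygon given as an n x 2 matrix (not closed).
.polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Ray-casting point-in-polygon test, vectorised over points.
# Points on the boundary may land on either side; callers needing boundary
# tolerance combine this with .dist_to_boundary().
.point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Minimum distance from points to the polygon boundary (edges as segments).
.dist_to_boundary <- function(px, py, v) {
  n <- nrow(v)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- v[j, 1]; ay <- v[j, 2]
    bx <- v[i, 1]; by <- v[i, 2]
    abx <- bx - ax; aby <- by - ay
    len2 <- abx^2 + aby^2
    t <- if (len2 > 0) pmin(pmax(((px - ax) * abx + (py - ay) * aby) / len2, 0), 1) else 0
    dx <- px - (ax + t * abx)
    dy <- py - (ay + t * aby)
    d2 <- pmin(d2, dx^2 + dy^2)
    j <- i
  }
  sqrt(d2)
}
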