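#' Paddock geofence
#'
#' A paddock is a simple polygon in a local planar frame (metres) together
#' with the WGS84 origin of that frame. `paddock()` takes explicit vertices;
#' `paddock_rect()` builds the common case of an axis-aligned rectangle
#' centred on the origin.
#'
#' @param vertices Numeric matrix (n x 2, n >= 3) of polygon vertices in local
#'   metres, listed once (do not repeat the first vertex).
#' @param origin Numeric length-2 vector `c(lat, lon)`: the WGS84 point mapped
#'   to local (0, 0).
#' @return An object of class `paddock`: a list with elements `vertices`,
#'   `origin`, `area` (m^2) and `is_rect`.
#' @examples
#' pad <- paddock_rect()        # the default 105 m x 30 m study paddock
#' pad$area                     # 3150
#' @export
paddock <- function(vertices, origin) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2 || nrow(vertices) < 3) {
    stop("paddock vertices must be a numeric matrix with >= 3 rows and 2 columns")
  }
  if (anyNA(vertices)) stop("paddock vertices contain missing values")
  if (length(origin) != 2 || anyNA(origin)) stop("origin must be c(lat, lon)")
  area <- .polygon_area(vertices)
  if (abs(area) < sqrt(.Machine$double.eps)) {
    stop("degenerate paddock polygon: area is zero")
  }
  if (area < 0) {              # enforce counter-clockwise vertex order
    vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
    area <- -area
  }
  structure(
    list(vertices = unname(vertices), origin = c(lat = origin[[1]], lon = origin[[2]]),
         area = area, is_rect = .is_axis_rect(vertices)),
    class = "paddock"
  )
}

#' @rdname paddock
#' @param width,height Rectangle dimensions in metres (east-west and
#'   north-south extent). Defaults are the 105 m x 30 m study paddock.
#' @export
paddock_rect <- function(width = 105, height = 30,
                         origin = c(-27.552297, 152.333471)) {
  stopifnot(width > 0, height > 0)
  w <- width / 2; h <- height / 2
  paddock(rbind(c(-w, -h), c(w, -h), c(w, h), c(-w, h)), origin)
}

.is_axis_rect <- function(v) {
  nrow(v) == 4 &&
    length(unique(round(v[, 1], 9))) == 2 &&
    length(unique(round(v[, 2], 9))) == 2
}

#' @export
print.paddock <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf(
    "<paddock> %d vertices, area %.0f m^2, bbox %.1f x %.1f m, origin (%.6f, %.6f)\n",
    nrow(x$vertices), x$area, diff(bb[, 1]), diff(bb[, 2]),
    x$origin[["lat"]], x$origin[["lon"]]
  ))
  invisible(x)
}

# Fixes (lat/lon vectors) -> inside test with an optional outward buffer in
# metres (polygon dilated by `buffer`, implemented as inside-or-within-buffer
# of the boundary).
.paddock_contains <- function(pad, lat, lon, buffer = 0) {
  xy <- to_local_xy(lat, lon, pad$origin[["lat"]], pad$origin[["lon"]])
  inside <- .point_in_polygon(xy[, 1], xy[, 2], pad$vertices)
  if (buffer > 0) {
    inside <- inside | .dist_to_boundary(xy[, 1], xy[, 2], pad$vertices) <= buffer
  }
  inside
}
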