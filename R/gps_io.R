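# Trajectory ingestion and export. A trajectory is a data.frame with columns
# animal_id (character), timestamp (POSIXct, UTC), lat, lon (degrees WGS84),
# strictly increasing in time within an animal. Ingestion sorts by time and
# keeps the first of any duplicated (animal, timestamp) pair: a zero elapsed
# time would make the rate of movement undefined downstream.

#' Construct a trajectory from raw fixes
#'
#' Validates, time-sorts and de-duplicates a set of fixes for one animal.
#'
#' @param animal_id Animal identifier (length 1, coerced to character).
#' @param timestamp `POSIXct` times (converted to UTC) or strings parseable by
#'   [parse_iso8601()].
#' @param lat,lon Coordinates in decimal degrees WGS84.
#' @return A `trajectory` object (a data.frame with columns `animal_id`,
#'   `timestamp`, `lat`, `lon`). The number of duplicate rows dropped is
#'   reported via a message and stored in attribute `n_duplicates`.
#' @export
as_trajectory <- function(animal_id, timestamp, lat, lon) {
  animal_id <- as.character(animal_id)
  stopifnot(length(animal_id) == 1, !is.na(animal_id))
  if (is.character(timestamp)) timestamp <- parse_iso8601(timestamp)
  stopifnot(inherits(timestamp, "POSIXct"))
  attr(timestamp, "tzone") <- "UTC"
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  n <- length(timestamp)
  stopifnot(length(lat) == n, length(lon) == n)
  if (anyNA(timestamp)) stop("trajectory timestamps contain missing values")
  if (anyNA(lat) || anyNA(lon)) stop("trajectory coordinates contain missing values")
  if (any(abs(lat) > 90) || any(lon <= -180) || any(lon > 180)) {
    stop("coordinates outside valid WGS84 ranges")
  }
  ord <- order(timestamp)
  timestamp <- timestamp[ord]; lat <- lat[ord]; lon <- lon[ord]
  dup <- duplicated(timestamp)
  if (any(dup)) {
    message(sprintf("animal %s: dropped %d fix(es) with duplicated timestamps",
                    animal_id, sum(dup)))
    timestamp <- timestamp[!dup]; lat <- lat[!dup]; lon <- lon[!dup]
  }
  out <- data.frame(
    animal_id = rep(animal_id, length(timestamp)),
    timestamp = timestamp, lat = lat, lon = lon,
    stringsAsFactors = FALSE
  )
  class(out) <- c("trajectory", "data.frame")
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Parse ISO-8601 timestamps
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS` with an optional trailing `Z` and an optional
#' space instead of `T`. All times are interpreted as UTC.
#'
#' @param x Character vector of timestamps.
#' @return `POSIXct` in UTC. Unparseable entries raise an error naming the
#'   offending element.
#' @export
parse_iso8601 <- function(x) {
  x0 <- x
  x <- sub("Z$", "", x)
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop(sprintf("unparseable timestamp at element %d: '%s'", bad, x0[bad]))
  }
  out
}

.format_iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Read trajectories from a GPX file
#'
#' Parses GPX 1.0/1.1 tracks: one trajectory per `<trk>`, the track `<name>`
#' (or `track_<i>` if absent) becoming the animal id. Trackpoints without a
#' `<time>` child are rejected with a warning; fixes are returned time-sorted
#' and de-duplicated.
#'
#' @param path Path to a GPX file.
#' @return A list of `trajectory` objects.
#' @seealso [write_gpx()]
#' @export
read_gpx <- function(path) {
  if (!file.exists(path)) stop(sprintf("GPX file not found: '%s'", path))
  doc <- xml2::read_xml(path)        # malformed XML errors here, naming the line
  xml2::xml_ns_strip(doc)
  trks <- xml2::xml_find_all(doc, ".//trk")
  out <- list()
  for (i in seq_along(trks)) {
    trk <- trks[[i]]
    nm <- xml2::xml_text(xml2::xml_find_first(trk, "./name"))
    if (is.na(nm) || !nzchar(nm)) nm <- sprintf("track_%d", i)
    pts <- xml2::xml_find_all(trk, ".//trkpt")
    if (length(pts) == 0) {
      warning(sprintf("track '%s' has no trackpoints; skipped", nm))
      next
    }
    lat <- as.numeric(xml2::xml_attr(pts, "lat"))
    lon <- as.numeric(xml2::xml_attr(pts, "lon"))
    tim <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
    timed <- !is.na(tim) & nzchar(tim)
    if (!any(timed)) {
      warning(sprintf("track '%s' has no timed trackpoints; returning empty trajectory", nm))
      next
    }
    if (any(!timed)) {
      warning(sprintf("track '%s': rejected %d untimed trackpoint(s)", nm, sum(!timed)))
    }
    out[[nm]] <- as_trajectory(nm, parse_iso8601(tim[timed]), lat[timed], lon[timed])
  }
  unname(out)
}

#' Write trajectories to a GPX 1.1 file
#'
#' One `<trk>` per trajectory with the animal id as track name and ISO-8601
#' UTC `<time>` on every trackpoint. Coordinates are written with 7 decimal
#' places (~1 cm), so a write/read round trip preserves them to 1e-7 degrees.
#'
#' @param trajs A `trajectory` or list of trajectories.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gpx <- function(trajs, path) {
  trajs <- .as_traj_list(trajs)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gpx version="1.1" creator="herdmove" xmlns="http://www.topografix.com/GPX/1/1">'
  )
  for (tr in trajs) {
    lines <- c(lines, "  <trk>",
               sprintf("    <name>%s</name>", tr$animal_id[1]), "    <trkseg>")
    lines <- c(lines, sprintf(
      '      <trkpt lat="%.7f" lon="%.7f"><time>%s</time></trkpt>',
      tr$lat, tr$lon, .format_iso8601(tr$timestamp)
    ))
    lines <- c(lines, "    </trkseg>", "  </trk>")
  }
  lines <- c(lines, "</gpx>")
  writeLines(lines, path)
  invisible(path)
}

#' Read trajectories from a fix CSV
#'
#' The canonical CSV dialect is comma-separated with a header row and columns
#' `animal_id,timestamp,lat,lon`, timestamps in ISO-8601 UTC. Rows are grouped
#' by animal, time-sorted, and duplicated (animal, timestamp) rows are dropped
#' (first kept, count reported).
#'
#' @param path Path to a CSV file.
#' @return A list of `trajectory` objects, one per animal, in order of first
#'   appearance.
#' @seealso [write_fix_csv()]
#' @export
read_fix_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("fix CSV not found: '%s'", path))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("animal_id", "timestamp", "lat", "lon")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop(sprintf("fix CSV is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  ts <- tryCatch(parse_iso8601(df$timestamp), error = function(e) {
    stop(sprintf("fix CSV '%s': %s", path, conditionMessage(e)), call. = FALSE)
  })
  ids <- unique(df$animal_id)
  lapply(ids, function(id) {
    sel <- df$animal_id == id
    as_trajectory(id, ts[sel], as.numeric(df$lat[sel]), as.numeric(df$lon[sel]))
  })
}

#' Write trajectories to a fix CSV
#'
#' Emits the canonical `animal_id,timestamp,lat,lon` schema with ISO-8601 UTC
#' timestamps and '.' decimal separator; output is byte-stable for a fixed
#' input.
#'
#' @param trajs A `trajectory` or list of trajectories.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fix_csv <- function(trajs, path) {
  trajs <- .as_traj_list(trajs)
  df <- do.call(rbind, lapply(trajs, function(tr) {
    data.frame(animal_id = tr$animal_id,
               timestamp = .format_iso8601(tr$timestamp),
               lat = sprintf("%.7f", tr$lat),
               lon = sprintf("%.7f", tr$lon),
               stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.as_traj_list <- function(trajs) {
  if (inherits(trajs, "trajectory")) return(list(trajs))
  stopifnot(is.list(trajs), all(vapply(trajs, inherits, logical(1), "trajectory")))
  trajs
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> animal %s: %d fixes", x$animal_id[1], nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf(", %s to %s UTC",
                format(min(x$timestamp), "%Y-%m-%d %H:%M:%S"),
                format(max(x$timestamp), "%Y-%m-%d %H:%M:%S")))
  }
  cat("\n")
  invisible(x)
}
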