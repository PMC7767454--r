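# Per-relocation movement variables: step distance, rate of movement (ROM),
# heading, turning angle and windowed linearity ratio. One "relocation" is a
# pair of successive fixes; an n-fix trajectory yields n - 1 step records.

#' Signed turning angle between two headings
#'
#' Smallest signed rotation from `prev_heading` to `next_heading`, in radians
#' within `(-pi, pi]`. Headings are measured from east, counter-clockwise
#' positive, so a positive turning angle is a left turn. `NA` headings (zero
#' length steps have no defined heading) propagate to `NA` angles.
#'
#' @param prev_heading,next_heading Headings in radians (vectorised).
#' @return Turning angle(s) in radians, in `(-pi, pi]`.
#' @examples
#' turning_angle(0, pi / 2)   #  +pi/2: east then north, a quarter left turn
#' turning_angle(0, pi)       #  pi: full reversal, the attainable extreme
#' @export
turning_angle <- function(prev_heading, next_heading) {
  d <- (next_heading - prev_heading) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Step records for one trajectory
#'
#' Computes, for each pair of successive fixes: elapsed time `dt` (s),
#' great-circle `distance` (m), `rom = distance / dt` (m/s), `heading`
#' (radians from east, counter-clockwise, in the local planar frame) and the
#' signed `turning_angle` relative to the previous step. The heading of a
#' zero-length step is `NA`, and a turning angle is `NA` whenever either
#' adjacent step has zero length (or for the first step of a track).
#'
#' @param traj A `trajectory` (>= 2 fixes gives records; fewer gives an empty
#'   table).
#' @param origin Optional `c(lat, lon)` origin for the planar frame used for
#'   headings; defaults to the trajectory's first fix. Headings are
#'   origin-insensitive at paddock scale.
#' @return A `step_table` data.frame with one row per relocation: `animal_id`,
#'   `t_start`, `t_end`, `dt`, `distance`, `rom`, `heading`, `turning_angle`.
#' @export
compute_steps <- function(traj, origin = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj)
  if (n < 2) {
    out <- data.frame(animal_id = character(0),
                      t_start = as.POSIXct(character(0), tz = "UTC"),
                      t_end = as.POSIXct(character(0), tz = "UTC"),
                      dt = numeric(0), distance = numeric(0), rom = numeric(0),
                      heading = numeric(0), turning_angle = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("step_table", "data.frame")
    return(out)
  }
  dt <- as.numeric(difftime(traj$timestamp[-1], traj$timestamp[-n], units = "secs"))
  if (any(dt <= 0)) stop("internal error: non-increasing timestamps in trajectory")
  if (is.null(origin)) origin <- c(traj$lat[1], traj$lon[1])
  xy <- to_local_xy(traj$lat, traj$lon, origin[1], origin[2])
  dxy <- diff(xy)
  distance <- haversine_distance(traj$lat[-n], traj$lon[-n], traj$lat[-1], traj$lon[-1])
  heading <- ifelse(distance > 0, atan2(dxy[, 2], dxy[, 1]), NA_real_)
  turn <- c(NA_real_, turning_angle(heading[-(n - 1)], heading[-1]))
  out <- data.frame(
    animal_id = traj$animal_id[-1],
    t_start = traj$timestamp[-n], t_end = traj$timestamp[-1],
    dt = dt, distance = distance, rom = distance / dt,
    heading = heading, turning_angle = turn, stringsAsFactors = FALSE
  )
  class(out) <- c("step_table", "data.frame")
  out
}

#' Linearity ratio of a movement window
#'
#' Straight-line distance from the first to the last fix of a window divided
#' by the cumulative path length within it: 1 for perfectly direct movement,
#' 0 for a closed loop. By the triangle inequality the ratio never exceeds 1.
#'
#' @param lat,lon Coordinates of >= 3 fixes, in window order.
#' @return The ratio in `[0, 1]`, or `NA` when the total path length is zero.
#' @examples
#' linearity_ratio(c(0, 0, 0), c(0, 0.001, 0.002))  # straight path: 1
#' @export
linearity_ratio <- function(lat, lon) {
  n <- length(lat)
  stopifnot(length(lon) == n)
  if (n < 3) stop("linearity ratio needs a window of at least 3 fixes")
  path <- sum(haversine_distance(lat[-n], lon[-n], lat[-1], lon[-1]))
  if (path == 0) return(NA_real_)
  min(haversine_distance(lat[1], lon[1], lat[n], lon[n]) / path, 1)
}

#' Remove fixes outside the paddock geofence
#'
#' Drops fixes falling strictly outside the paddock polygon dilated by
#' `buffer` metres; order is preserved. The buffer default equals the logger's
#' positional accuracy, so fixes within one GPS error of the fence are kept.
#'
#' @param traj A `trajectory`.
#' @param paddock A [paddock()].
#' @param buffer Outward dilation of the fence in metres (default 4.4).
#' @return The filtered `trajectory`, with attribute `n_removed` giving the
#'   number of fixes removed.
#' @export
filter_paddock <- function(traj, paddock, buffer = 4.4) {
  stopifnot(inherits(traj, "trajectory"), inherits(paddock, "paddock"))
  if (buffer < 0) stop("buffer must be non-negative")
  if (nrow(traj) == 0) {
    attr(traj, "n_removed") <- 0L
    return(traj)
  }
  keep <- .paddock_contains(paddock, traj$lat, traj$lon, buffer = buffer)
  out <- traj[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trajectory", "data.frame")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Hourly activity profile
#'
#' Bins step records by the local clock hour of their end fix and totals
#' relocation counts and distance per hour. Counts over the 24 bins sum to
#' the number of steps, distances to the total distance.
#'
#' @param steps A `step_table` (possibly covering several animals).
#' @param timezone Time zone used for the local clock (default UTC+10, i.e.
#'   `"Etc/GMT-10"`).
#' @return An `hourly_summary` data.frame with columns `hour` (0-23),
#'   `relocations` and `distance`.
#' @export
hourly_summary <- function(steps, timezone = "Etc/GMT-10") {
  stopifnot(inherits(steps, "data.frame"), nrow(steps) > 0)
  hr <- as.POSIXlt(steps$t_end, tz = timezone)$hour
  out <- data.frame(
    hour = 0:23,
    relocations = as.integer(tabulate(hr + 1L, nbins = 24)),
    distance = vapply(0:23, function(h) sum(steps$distance[hr == h]), numeric(1))
  )
  class(out) <- c("hourly_summary", "data.frame")
  out
}

#' Build the clustering feature table
#'
#' Joins the per-step variables of [compute_steps()] across animals with a
#' windowed linearity ratio: a sliding window of `window` consecutive steps
#' (hence `window + 1` fixes), assigned to the window's central step. Rows
#' with any missing variable (track edges, zero-length neighbours) are kept
#' but flagged `complete = FALSE`; only complete rows enter clustering.
#'
#' With `standardize = TRUE` (default, recommended: the four variables differ
#' by orders of magnitude) a per-column z-scored copy of the complete rows is
#' attached as attribute `scaled`, with the centring/scaling vectors stored
#' for inverse transformation. Use [feature_matrix()] to retrieve it.
#'
#' @param trajs A `trajectory` or list of trajectories.
#' @param window Number of steps per linearity window (>= 3).
#' @param standardize Attach a z-scored feature matrix?
#' @return A `feature_table` data.frame with columns `animal_id`, `timestamp`
#'   (step end), `dt`, `distance`, `rom`, `linearity`, `turning_angle`,
#'   `complete`.
#' @export
build_feature_table <- function(trajs, window = 30, standardize = TRUE) {
  trajs <- .as_traj_list(trajs)
  if (window < 3) stop("linearity window must be at least 3 steps")
  rows <- lapply(trajs, function(tr) {
    st <- compute_steps(tr)
    n_steps <- nrow(st)
    lin <- rep(NA_real_, n_steps)
    if (n_steps >= window) {
      half <- window %/% 2
      path_cum <- c(0, cumsum(st$distance))
      for (i in seq_len(n_steps - window + 1)) {
        j <- i + window      # fixes i .. i+window bound the window's steps
        path <- path_cum[j] - path_cum[i]
        lin[i + half] <- if (path > 0) {
          min(haversine_distance(tr$lat[i], tr$lon[i], tr$lat[j], tr$lon[j]) / path, 1)
        } else NA_real_
      }
    }
    data.frame(animal_id = st$animal_id, timestamp = st$t_end, dt = st$dt,
               distance = st$distance, rom = st$rom, linearity = lin,
               turning_angle = st$turning_angle, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$complete <- complete.cases(out[, c("distance", "rom", "linearity", "turning_angle")])
  class(out) <- c("feature_table", "data.frame")
  if (standardize) {
    m <- as.matrix(out[out$complete, c("distance", "rom", "linearity", "turning_angle")])
    ctr <- colMeans(m)
    scl <- apply(m, 2, sd)
    scl[scl == 0] <- 1          # constant column: leave centred at 0
    z <- sweep(sweep(m, 2, ctr), 2, scl, "/")
    rownames(z) <- which(out$complete)
    attr(out, "scaled") <- z
    attr(out, "center") <- ctr
    attr(out, "scale") <- scl
  }
  out
}

#' Feature matrix for clustering
#'
#' @param ft A `feature_table`.
#' @param standardized Return the z-scored copy (default) or the raw complete
#'   rows.
#' @return Numeric matrix of complete rows, with rownames giving the row
#'   indices into `ft`.
#' @export
feature_matrix <- function(ft, standardized = TRUE) {
  stopifnot(inherits(ft, "feature_table"))
  if (standardized) {
    z <- attr(ft, "scaled")
    if (is.null(z)) stop("feature table was built with standardize = FALSE")
    return(z)
  }
  m <- as.matrix(ft[ft$complete, c("distance", "rom", "linearity", "turning_angle")])
  rownames(m) <- which(ft$complete)
  m
}
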