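test_that("haversine distance matches closed-form arcs and is a proper metric", {
  expect_equal(haversine_distance(10, 20, 10, 20), 0)
  expect_equal(haversine_distance(0, 0, 0, 1), 111194.9, tolerance = 0.1 / 111194.9)
  expect_equal(haversine_distance(0, 0, 90, 0), 10007543, tolerance = 1 / 10007543)
  set.seed(1)
  la1 <- runif(10, -60, 60); lo1 <- runif(10, -179, 179)
  la2 <- la1 + runif(10, -1, 1); lo2 <- lo1 + runif(10, -1, 1)
  expect_equal(haversine_distance(la1, lo1, la2, lo2),
               haversine_distance(la2, lo2, la1, lo1))       # symmetry
  skip_if_not_installed("geosphere")
  expect_equal(haversine_distance(la1, lo1, la2, lo2),
               geosphere::distHaversine(cbind(lo1, la1), cbind(lo2, la2), r = 6371000),
               tolerance = 1e-9)
})

test_that("step records reproduce arithmetic and geometric oracles", {
  # 13.4 m in 20 s -> 0.67 m/s, the scale of the herd's overall mean speed
  tr <- traj_from_xy(c(0, 13.4), c(0, 0))
  st <- compute_steps(tr)
  expect_equal(nrow(st), 1)
  expect_equal(st$rom, 0.67, tolerance = 1e-6)
  expect_equal(st$dt, 20)
  # stationary pair: zero distance, zero ROM, no heading
  st0 <- compute_steps(traj_from_xy(c(5, 5), c(3, 3)))
  expect_equal(st0$distance, 0)
  expect_equal(st0$rom, 0)
  expect_true(is.na(st0$heading))
  # three collinear equally spaced fixes: equal distance and heading, zero turn
  # (haversine on the sphere makes equal planar offsets agree only to ~1e-6
  # relative at this latitude)
  st3 <- compute_steps(traj_from_xy(c(0, 10, 20), c(0, 10, 20)))
  expect_equal(st3$distance[1], st3$distance[2], tolerance = 1e-5)
  expect_equal(st3$heading[1], st3$heading[2], tolerance = 1e-5)
  expect_equal(st3$turning_angle[2], 0, tolerance = 1e-5)
  expect_equal(st3$heading[1], pi / 4, tolerance = 1e-4)
  # rom * dt == distance exactly, and n fixes give n - 1 records
  sim <- small_sim(seed = 21, n_animals = 2, days = 0.5)
  for (tr in sim$trajectories) {
    st <- compute_steps(tr)
    expect_equal(nrow(st), nrow(tr) - 1)
    expect_equal(st$rom * st$dt, st$distance, tolerance = 1e-12)
  }
  expect_equal(nrow(compute_steps(traj_from_xy(0, 0))), 0)
})

test_that("turning angles are signed, wrapped to (-pi, pi], and reach the pi extreme", {
  expect_equal(turning_angle(0, 0), 0)
  expect_equal(turning_angle(0, pi / 2), pi / 2)      # east then north: left turn
  expect_equal(turning_angle(0, -pi / 2), -pi / 2)
  expect_equal(abs(turning_angle(0.3, 0.3 + pi)), pi) # full reversal
  grid <- seq(-pi, pi, length.out = 73)
  angles <- outer(grid, grid, turning_angle)
  expect_true(all(angles > -pi & angles <= pi))
  expect_equal(max(abs(angles)), pi)
  expect_true(is.na(turning_angle(NA, 1)))
})

test_that("linearity ratio hits its closed-form cases and stays in [0, 1]", {
  org <- c(-27.552297, 152.333471)
  path_ll <- function(x, y) local_xy_to_wgs84(x, y, org[1], org[2])
  straight <- path_ll(c(0, 10, 20), c(0, 0, 0))
  expect_equal(linearity_ratio(straight[, "lat"], straight[, "lon"]), 1, tolerance = 1e-9)
  square <- path_ll(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0))
  expect_equal(linearity_ratio(square[, "lat"], square[, "lon"]), 0, tolerance = 1e-9)
  lshape <- path_ll(c(0, 10, 10), c(0, 0, 10))
  expect_equal(linearity_ratio(lshape[, "lat"], lshape[, "lon"]), sqrt(2) / 2,
               tolerance = 1e-6)
  expect_true(is.na(linearity_ratio(rep(org[1], 3), rep(org[2], 3))))
  expect_error(linearity_ratio(org[1], org[2]), "at least 3")
  set.seed(2)
  for (i in 1:20) {
    pts <- path_ll(cumsum(rnorm(8)), cumsum(rnorm(8)))
    lr <- linearity_ratio(pts[, "lat"], pts[, "lon"])
    expect_gte(lr, 0); expect_lte(lr, 1)
  }
})

test_that("geofence filtering respects the dilated polygon", {
  pad <- paddock_rect()
  t0 <- as.POSIXct("2015-09-07 00:00:00", tz = "UTC")
  xs <- c(0, 62.5, 55.6, -52, 0)           # centroid, 10 m out, 3.1 m out, inside, centroid
  tr <- traj_from_xy(xs, c(0, 0, 0, 0, 1), animal = "a")
  f0 <- filter_paddock(tr, pad, buffer = 0)
  expect_equal(nrow(f0), 3)
  expect_equal(attr(f0, "n_removed"), 2L)
  f44 <- filter_paddock(tr, pad, buffer = 4.4)
  expect_equal(nrow(f44), 4)               # 3.1 m outside is inside the 4.4 m buffer
  expect_equal(f44$timestamp, tr$timestamp[c(1, 3, 4, 5)])  # order preserved
  all_in <- filter_paddock(traj_from_xy(c(0, 5, -5), c(0, 5, -5)), pad, 0)
  expect_equal(attr(all_in, "n_removed"), 0L)
  expect_error(paddock(rbind(c(0, 0), c(1, 1), c(2, 2)), c(0, 0)), "degenerate")
})

test_that("hourly summary bins by local clock hour and conserves totals", {
  t0 <- as.POSIXct("2015-09-07 08:10:00", tz = "Etc/GMT-10")  # 18:10 UTC+10? no: 08:10 local
  tr <- traj_from_xy(cumsum(rep(3, 10)), rep(0, 10), t0 = as.POSIXct(t0, tz = "UTC"))
  st <- compute_steps(tr)
  hs <- hourly_summary(st, timezone = "Etc/GMT-10")
  expect_equal(nrow(hs), 24)
  expect_equal(sum(hs$relocations), nrow(st))
  expect_equal(sum(hs$distance), sum(st$distance), tolerance = 1e-6)
  # all steps fall in a single local hour bin
  expect_equal(sum(hs$relocations > 0), 1)
  hr <- as.POSIXlt(st$t_end[1], tz = "Etc/GMT-10")$hour
  expect_equal(hs$relocations[hs$hour == hr], nrow(st))
})

test_that("feature table joins steps with windowed linearity and standardizes", {
  # straight constant-speed track: all linearity 1, all turning angles 0
  tr <- traj_from_xy(seq(0, 40, by = 4), rep(0, 11))
  ft <- build_feature_table(tr, window = 3)
  expect_equal(nrow(ft), 10)
  mid <- ft$complete
  expect_true(any(mid))
  expect_equal(ft$linearity[mid], rep(1, sum(mid)), tolerance = 1e-9)
  expect_equal(ft$turning_angle[mid], rep(0, sum(mid)), tolerance = 1e-9)
  # standardized copy has mean 0 / sd 1 and row bookkeeping is exact
  sim <- small_sim(seed = 22, n_animals = 3, days = 0.5)
  ft2 <- build_feature_table(sim$trajectories, window = 5)
  expect_equal(nrow(ft2), sum(vapply(sim$trajectories, nrow, integer(1))) - 3)
  z <- feature_matrix(ft2)
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4), tolerance = 1e-9)
  expect_equal(nrow(z), sum(ft2$complete))
  expect_error(build_feature_table(tr, window = 2), "at least 3")
})
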