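# In-code fixtures shared across test files.

# Trajectory built from local planar offsets (metres) around a reference
# origin, with fixes every `dt` seconds.
traj_from_xy <- function(x, y, dt = 20, animal = "calf_01",
                         origin = c(-27.552297, 152.333471),
                         t0 = as.POSIXct("2015-09-07 00:00:00", tz = "UTC")) {
  ll <- herdmove::local_xy_to_wgs84(x, y, origin[1], origin[2])
  herdmove::as_trajectory(animal, t0 + seq_along(x) * dt - dt,
                          ll[, "lat"], ll[, "lon"])
}

# A small two-track GPX document as text.
gpx_text <- function() {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<gpx version="1.1" creator="test" xmlns="http://www.topografix.com/GPX/1/1">',
    "  <trk><name>calf_a</name><trkseg>",
    '    <trkpt lat="-27.5520" lon="152.3330"><time>2015-09-07T00:00:20Z</time></trkpt>',
    '    <trkpt lat="-27.5521" lon="152.3331"><time>2015-09-07T00:00:00Z</time></trkpt>',
    '    <trkpt lat="-27.5522" lon="152.3332"><time>2015-09-07T00:00:40Z</time></trkpt>',
    "  </trkseg></trk>",
    "  <trk><name>calf_b</name><trkseg>",
    '    <trkpt lat="-27.5523" lon="152.3333"><time>2015-09-07T01:00:00Z</time></trkpt>',
    '    <trkpt lat="-27.5524" lon="152.3334"/>',
    '    <trkpt lat="-27.5525" lon="152.3335"><time>2015-09-07T01:00:40Z</time></trkpt>',
    "  </trkseg></trk>",
    "</gpx>")
}

# Small deterministic herd simulation reused by several tests.
small_sim <- function(seed = 1, n_animals = 3, days = 1) {
  herdmove::simulate_herd(herdmove::sim_config(
    n_animals = n_animals, logger_failure_prob = 0,
    duration = days * 86400, seed = seed
  ))
}

# Densely sampled variant (no dropout) for IO round-trip tests.
dense_sim <- function(seed = 1, n_animals = 2, duration = 1800) {
  herdmove::simulate_herd(herdmove::sim_config(
    n_animals = n_animals, logger_failure_prob = 0,
    dropout_prob_per_fix = 0, duration = duration, seed = seed
  ))
}

# Ground-truth state per step (state of the fix each step ends on), aligned
# with the rows of build_feature_table()/compute_steps() output.
truth_step_states <- function(sim) {
  by_animal <- split(sim$truth, sim$truth$animal_id)
  unlist(lapply(sim$trajectories, function(tr) {
    by_animal[[tr$animal_id[1]]]$state[-1]
  }), use.names = FALSE)
}
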