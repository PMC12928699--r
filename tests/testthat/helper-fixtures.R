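# Shared fixtures: everything is generated in code at test time.

# geometry of the EEG session: display at 0.54 m, head radius 8 cm
eeg_geom <- function(location_deg = 0) {
  head_geometry(x = azimuth_to_x(location_deg, 0.54), z = 0.54)
}

# a small but complete epoch simulation; defaults keep unit tests fast
tiny_sim <- function(...) {
  args <- utils::modifyList(
    list(n_sensors = 12, sample_rate_hz = 32, noise_sd = 6, gamma = 0,
         seed = 11L),
    list(...))
  do.call(sim_config, args)
}

tiny_schedule <- function(participant = 1L, n_blocks = 2L, seed = 11L) {
  make_eeg_schedule(participant_id = participant, n_blocks = n_blocks,
                    n_trials = 5L, n_presentations = 10L, seed = seed)
}

tiny_epochs <- function(sim = tiny_sim(), schedule = tiny_schedule()) {
  simulate_epochs(schedule, sim)
}

# deterministic toy epoch_set with hand-set contents
toy_epochs <- function(n_trials = 6, n_sensors = 4, n_time = 8,
                       conditions = rep("A", n_trials),
                       locations = rep(c(-15, 15), length.out = n_trials),
                       fill = function(i, s, t) i + s / 10 + t / 100) {
  dat <- array(0, c(n_trials, n_sensors, n_time))
  for (i in seq_len(n_trials)) {
    for (s in seq_len(n_sensors)) {
      dat[i, s, ] <- fill(i, s, seq_len(n_time))
    }
  }
  epoch_set(dat, times = (seq_len(n_time) - 4) / 32, sample_rate = 32,
            labels = data.frame(condition = conditions,
                                location_deg = locations))
}
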