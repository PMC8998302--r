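# Build a trace tibble for hand-specified cells of one recording.
# `cells` is a named list: cell_id -> fluorescence vector on `time_s`.
make_traces <- function(cells, time_s, well_id = "W1", stimulus = "stim",
                        condition = "untreated") {
  dplyr::bind_rows(lapply(names(cells), function(id) {
    tibble::tibble(
      condition = condition, well_id = well_id, stimulus = stimulus,
      cell_id = id, frame_index = seq_along(time_s) - 1L,
      time_s = time_s, fluorescence_au = cells[[id]]
    )
  }))
}

# Independent brute-force oracle for the delta-F statistic: an explicit
# frame-by-frame scan, kept free of the vectorised implementation's code
# path. Ties at the peak keep the earliest frame (strict > comparison).
brute_force_delta_f <- function(time_s, fluorescence_au, baseline_end_s = 10) {
  base_vals <- c()
  f1 <- -Inf
  peak_t <- NA_real_
  for (i in seq_along(time_s)) {
    if (time_s[i] < baseline_end_s) {
      base_vals <- c(base_vals, fluorescence_au[i])
    } else if (fluorescence_au[i] > f1) {
      f1 <- fluorescence_au[i]
      peak_t <- time_s[i]
    }
  }
  f0 <- mean(base_vals)
  list(f0 = f0, f1 = f1, peak_time_s = peak_t, delta_f = f1 - f0)
}

# A negative-control-plus-stimulus trace table for one simulated well.
sim_well_pair <- function(config, stim, effect = treatment_effect(),
                          well_id = "W1") {
  nc <- simulate_well(config, stimulus_spec("negative_control",
                                            amplitude_mean = 0),
                      effect, well_id = well_id)
  st <- simulate_well(config, stim, effect, well_id = well_id,
                      seed = derive_seed_for_test(config$seed, well_id))
  dplyr::bind_rows(nc, st)
}

# test-only seed derivation distinct from the well default, so the two
# recordings of a pair use different noise
derive_seed_for_test <- function(seed, well_id) {
  (seed * 7919L + sum(utf8ToInt(well_id))) %% 2147483000L + 1L
}
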