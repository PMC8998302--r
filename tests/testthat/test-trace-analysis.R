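test_that("F0 is the pre-stimulus mean and requires two baseline frames", {
  t <- c(0, 5, 10, 15, 20)
  expect_equal(compute_f0(t, rep(100, 5)), 100)
  expect_equal(compute_f0(t, c(98, 102, 150, 140, 120)), 100)
  # stimulus frame (time == baseline_end_s) belongs to the post window
  expect_equal(compute_f0(t, c(98, 102, 999, 0, 0)), 100)
  expect_error(compute_f0(c(0, 5, 10), c(1, 2, 3), baseline_end_s = 3),
               "at least 2 frames")
})

test_that("peak search is post-stimulus only with earliest-frame ties", {
  t <- c(0, 5, 10, 15, 20)
  # baseline spike must not define F1
  p <- find_peak(t, c(500, 100, 100, 130, 110))
  expect_equal(p$f1, 130)
  expect_equal(p$peak_time_s, 15)
  # monotone decreasing post-stimulus trace: first post frame wins
  p <- find_peak(t, c(0, 0, 90, 80, 70))
  expect_equal(p$f1, 90)
  expect_equal(p$peak_time_s, 10)
  # exact tie: earliest timepoint returned
  p <- find_peak(t, c(0, 0, 100, 130, 130))
  expect_equal(p$peak_time_s, 15)
  expect_error(find_peak(c(0, 5), c(1, 2), baseline_end_s = 10),
               "Post-stimulus window is empty")
})

test_that("trace validation rejects malformed traces", {
  expect_error(compute_f0(c(0, 5, 5, 10), rep(1, 4)), "strictly increasing")
  expect_error(compute_f0(c(0, 5, 10), c(1, NA, 3)), "finite")
  expect_error(compute_f0(c(0, 5), c(1, 2, 3)), "equal length")
})

test_that("delta-F is exactly F1 - F0, unfloored, and shift-invariant", {
  t <- seq(0, 44, by = 0.5)
  flat <- rep(100, length(t))
  tr <- make_traces(list(c1 = flat), t)
  expect_equal(compute_delta_f(tr)$delta_f, 0)

  # a declining trace yields a negative delta-F (no truncation)
  decl <- 100 - t
  expect_lt(compute_delta_f(make_traces(list(c1 = decl), t))$delta_f, 0)

  set.seed(31)
  for (i in 1:20) {
    y <- 100 + rnorm(length(t), 0, 5)
    d0 <- compute_delta_f(make_traces(list(c1 = y), t))
    dc <- compute_delta_f(make_traces(list(c1 = y + 37.5), t))
    expect_equal(dc$delta_f, d0$delta_f, tolerance = 1e-12)
    expect_equal(dc$f0, d0$f0 + 37.5, tolerance = 1e-12)
  }
})

test_that("delta-F equals the brute-force frame scan on random traces", {
  set.seed(1234)
  t <- seq(0, 44.5, by = 0.5)
  n <- 250
  cells <- lapply(seq_len(n), function(i) {
    100 + rnorm(length(t), 0, runif(1, 0.5, 8))
  })
  names(cells) <- sprintf("c%04d", seq_len(n))
  got <- compute_delta_f(make_traces(cells, t)) |> dplyr::arrange(cell_id)
  for (i in seq_len(n)) {
    oracle <- brute_force_delta_f(t, cells[[i]])
    expect_identical(got$f1[i], oracle$f1)
    expect_identical(got$peak_time_s[i], oracle$peak_time_s)
    expect_equal(got$f0[i], oracle$f0)
    expect_equal(got$delta_f[i], oracle$delta_f)
  }
})

test_that("well threshold is min(mean + 3 SD, cap) with sample SD", {
  t <- c(0, 5, 10, 15)
  # two cells with delta-F {0, 2}: mean 1, sample SD sqrt(2), raw 1+3*sqrt(2)
  cells <- list(c1 = c(100, 100, 100, 100), c2 = c(100, 100, 102, 101))
  tr <- make_traces(cells, t, stimulus = "negative_control")
  thr <- compute_well_threshold(tr)
  expect_equal(thr$raw_threshold, 1 + 3 * sd(c(0, 2)))
  expect_equal(thr$effective_threshold, thr$raw_threshold)

  # mean 10, SD 5 -> raw 25 -> capped at 18
  vals <- c(5, 10, 15) # sample SD of {10-a, 10, 10+a} is a
  expect_equal(sd(vals), 5)
  cells <- lapply(vals, function(v) c(100, 100, 100 + v, 100))
  names(cells) <- c("c1", "c2", "c3")
  thr <- compute_well_threshold(
    make_traces(cells, t, stimulus = "negative_control"))
  expect_equal(thr$raw_threshold, 25)
  expect_equal(thr$effective_threshold, 18)

  # identical delta-F: SD 0, effective = min(mean, cap)
  cells <- list(c1 = c(100, 100, 105, 100), c2 = c(200, 200, 205, 200))
  thr <- compute_well_threshold(
    make_traces(cells, t, stimulus = "negative_control"))
  expect_equal(thr$raw_threshold, 5)
  expect_equal(thr$effective_threshold, 5)

  expect_error(compute_well_threshold(
    make_traces(list(c1 = c(100, 100, 100, 100)), t,
                stimulus = "negative_control")), "fewer than 2")
  expect_error(compute_well_threshold(
    make_traces(cells, t, stimulus = "negative_control"), cap = -1), "cap")
  expect_error(compute_well_threshold(make_traces(cells, t, stimulus = "kcl")),
               "negative-control")
})

test_that("responder calls use strict inequality at the threshold", {
  t <- c(0, 5, 10, 15)
  # negative-control delta-F {0, 3, 6}: mean 3, SD 3, threshold 12 exactly
  nc <- make_traces(list(c1 = c(100, 100, 100, 100),
                         c2 = c(100, 100, 103, 100),
                         c3 = c(100, 100, 106, 100)),
                    t, stimulus = "negative_control")
  thr <- compute_well_threshold(nc)
  eff <- thr$effective_threshold
  expect_equal(eff, 12)
  # baseline 0 makes delta-F bitwise equal to the crafted post value
  st <- make_traces(list(c1 = c(0, 0, eff, 0),
                         c2 = c(0, 0, eff + 1e-9, 0)),
                    t, stimulus = "p2x3_agonist")
  calls <- suppressWarnings(call_responders(dplyr::bind_rows(nc, st), thr))
  calls <- dplyr::filter(calls, stimulus == "p2x3_agonist") |>
    dplyr::arrange(cell_id)
  expect_equal(calls$delta_f[1], eff)
  expect_false(calls$reactive[1]) # delta_f == threshold -> non-reactive
  expect_true(calls$reactive[2])
})

test_that("calling fails without a threshold and warns on dropped cells", {
  t <- c(0, 5, 10, 15)
  st <- make_traces(list(c1 = c(100, 100, 120, 100)), t,
                    stimulus = "kcl", well_id = "W9")
  expect_error(call_responders(st), "negative-control")

  nc <- make_traces(list(c1 = c(100, 100, 101, 100),
                         c2 = c(100, 100, 103, 100)),
                    t, stimulus = "negative_control", well_id = "W9")
  expect_warning(call_responders(dplyr::bind_rows(nc, st)),
                 "missing")
})

test_that("responsive fraction recovers the true fraction at high amplitude", {
  cfg <- sim_config(n_cells_per_well = 1000, seed = 55, noise_sd = 2,
                    true_responder_fraction = c(negative_control = 0,
                                                p2x3_agonist = 0.5))
  tr <- sim_well_pair(cfg, stimulus_spec("p2x3_agonist", amplitude_mean = 60))
  frac <- responsive_fractions(call_responders(tr)) |>
    dplyr::filter(stimulus == "p2x3_agonist")
  expect_lt(abs(frac$responsive_fraction - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("baseline index is 100 for control and scales linearly", {
  cfg <- sim_config(n_cells_per_well = 100, n_wells_per_condition = 2,
                    n_biological = 1, seed = 77)
  exp <- simulate_experiment(
    cfg,
    schedule = default_schedule()["negative_control"],
    effects = list(effect_preset("untreated"))
  )
  tr <- exp$traces
  scaled <- dplyr::mutate(tr, condition = "scaled",
                          well_id = paste0(well_id, "_s"),
                          fluorescence_au = fluorescence_au * 1.2)
  idx <- baseline_index(dplyr::bind_rows(tr, scaled))
  expect_equal(idx$pct_of_control[idx$condition == "untreated"], 100)
  expect_equal(idx$pct_of_control[idx$condition == "scaled"], 120)
  expect_error(baseline_index(tr, control = "nope"), "not present")
})

test_that("simulated baseline shift 1.15 yields an index near 115", {
  cfg <- sim_config(n_cells_per_well = 300, n_wells_per_condition = 2,
                    n_biological = 1, noise_sd = 1, seed = 13)
  exp <- simulate_experiment(
    cfg,
    schedule = default_schedule()["negative_control"],
    effects = list(
      effect_preset("untreated"),
      treatment_effect(compound = "shift", concentration_nM = 1,
                       baseline_shift_factor = 1.15)
    )
  )
  idx <- baseline_index(exp$traces)
  got <- idx$pct_of_control[idx$condition == "shift_1nM"]
  expect_equal(got, 115, tolerance = 0.02)
})

test_that("attenuation profile normalises to control and flags zero controls", {
  cfg <- sim_config(n_cells_per_well = 150, n_wells_per_condition = 2,
                    n_biological = 3, seed = 23,
                    true_responder_fraction = c(negative_control = 0,
                                                p2x3_agonist = 0.8,
                                                kcl = 0.9))
  sched <- default_schedule()[c("negative_control", "p2x3_agonist", "kcl")]
  exp <- simulate_experiment(cfg, schedule = sched,
                             effects = list(effect_preset("untreated")))
  calls <- call_responders(exp$traces, include_negative_control = FALSE)
  att <- attenuation_profile(calls)
  expect_true(all(att$pct_of_control[att$condition == "untreated"] == 100))
  expect_true(all(att$normalized))
  expect_equal(att$n_biological, rep(3, nrow(att)))

  # zero control fraction: unnormalised fraction reported with a flag
  zero_calls <- dplyr::mutate(calls,
                              reactive = ifelse(stimulus == "kcl", FALSE,
                                                reactive))
  att0 <- attenuation_profile(zero_calls)
  kcl <- dplyr::filter(att0, stimulus == "kcl")
  expect_true(all(!kcl$normalized))
  expect_true(all(kcl$pct_of_control == 0))
})

test_that("SEM is computed over biological replicates only", {
  # two biological reps with technical wells collapsing to bio means 0.5 and
  # 0.7 -> SEM = sd(c(50, 70)/0.6*?)... construct calls directly
  calls <- tibble::tibble(
    condition = rep(c("untreated", "treated"), each = 8),
    biological_rep = rep(rep(1:2, each = 4), 2),
    well_id = rep(sprintf("w%d", 1:8), 2),
    stimulus = "p2x3_agonist",
    cell_id = sprintf("c%02d", 1:16),
    reactive = c(rep(TRUE, 8), # control: fraction 1 everywhere
                 TRUE, TRUE, FALSE, FALSE,   # treated bio 1: wells 1,1,0,0
                 TRUE, FALSE, FALSE, FALSE)  # treated bio 2: wells 1,0,0,0
  )
  att <- attenuation_profile(calls)
  tr <- dplyr::filter(att, condition == "treated")
  # bio means 0.5 and 0.25 -> pct 50 and 25 -> mean 37.5, SEM sd/sqrt(2)
  expect_equal(tr$pct_of_control, 37.5)
  expect_equal(tr$sem_pct, sd(c(50, 25)) / sqrt(2))
  expect_equal(tr$n_biological, 2)
})
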