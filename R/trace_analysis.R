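#' Baseline (ground-state) fluorescence of one trace
#'
#' F0 is the mean fluorescence over all frames recorded strictly before
#' stimulus application (`time_s < baseline_end_s`), i.e. over the 10-s
#' baseline window of a standard recording.
#'
#' @param time_s Strictly increasing numeric vector of frame times (s).
#' @param fluorescence_au Fluorescence values (a.u.), same length.
#' @param baseline_end_s Stimulus application time (s); default 10.
#' @return F0 (a.u.).
#' @examples
#' compute_f0(c(0, 5, 10, 15), c(98, 102, 150, 120)) # mean(98, 102) = 100
#' @export
compute_f0 <- function(time_s, fluorescence_au, baseline_end_s = 10) {
  check_trace(time_s, fluorescence_au)
  pre <- time_s < baseline_end_s
  if (sum(pre) < 2) {
    stop("Baseline window must contain at least 2 frames (time_s < ",
         baseline_end_s, " s).", call. = FALSE)
  }
  mean(fluorescence_au[pre])
}

#' Peak fluorescence after stimulus application
#'
#' F1 is the maximum fluorescence over frames at or after stimulus
#' application (`time_s >= baseline_end_s`); the peak search is restricted
#' to the post-stimulus window so baseline noise spikes cannot define F1.
#' Ties are broken by the earliest frame.
#'
#' @inheritParams compute_f0
#' @return A list with `f1` (a.u.) and `peak_time_s` (s).
#' @examples
#' find_peak(c(0, 5, 10, 15, 20), c(100, 99, 100, 130, 110))
#' @export
find_peak <- function(time_s, fluorescence_au, baseline_end_s = 10) {
  check_trace(time_s, fluorescence_au)
  post <- time_s >= baseline_end_s
  if (!any(post)) {
    stop("Post-stimulus window is empty: no frame at or after ",
         baseline_end_s, " s.", call. = FALSE)
  }
  f_post <- fluorescence_au[post]
  t_post <- time_s[post]
  i <- which.max(f_post) # which.max returns the first (earliest) maximum
  list(f1 = f_post[i], peak_time_s = t_post[i])
}

check_trace <- function(time_s, fluorescence_au) {
  if (length(time_s) != length(fluorescence_au)) {
    stop("`time_s` and `fluorescence_au` must have equal length.",
         call. = FALSE)
  }
  if (!all(is.finite(time_s)) || !all(is.finite(fluorescence_au))) {
    stop("Trace values must all be finite.", call. = FALSE)
  }
  if (is.unsorted(time_s, strictly = TRUE)) {
    stop("`time_s` must be strictly increasing.", call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-cell delta-F statistics for a trace table
#'
#' For every cell of every recording, computes the ground-state baseline F0
#' (mean over pre-stimulus frames), the post-stimulus peak F1 and its time,
#' and the response statistic `delta_f = f1 - f0` used for responder
#' calling. `delta_f` may be negative (no flooring); this is required for
#' an unbiased negative-control noise estimate.
#'
#' @param traces Long-format trace tibble with columns `well_id`,
#'   `stimulus`, `cell_id`, `time_s`, `fluorescence_au`; any additional
#'   per-cell metadata columns (condition, compound, concentration,
#'   replicate) are carried through.
#' @param baseline_end_s Stimulus application time (s); default 10.
#' @return A tibble with one row per cell per recording: metadata columns,
#'   `f0`, `f1`, `peak_time_s`, `delta_f`.
#' @examples
#' cfg <- sim_config(n_cells_per_well = 10, seed = 1)
#' tr <- simulate_well(cfg, stimulus_spec("kcl", amplitude_mean = 80))
#' compute_delta_f(tr)
#' @export
compute_delta_f <- function(traces, baseline_end_s = 10) {
  traces <- tibble::as_tibble(traces)
  req <- c("well_id", "stimulus", "cell_id", "time_s", "fluorescence_au")
  miss <- setdiff(req, names(traces))
  if (length(miss)) {
    stop("Trace table lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  meta <- intersect(c("condition", "compound", "concentration_nM",
                      "biological_rep", "true_responder"), names(traces))
  traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(meta, "well_id", "stimulus", "cell_id")))) |>
    dplyr::summarise(
      f0 = compute_f0(.data$time_s, .data$fluorescence_au, baseline_end_s),
      f1 = find_peak(.data$time_s, .data$fluorescence_au, baseline_end_s)$f1,
      peak_time_s = find_peak(.data$time_s, .data$fluorescence_au,
                              baseline_end_s)$peak_time_s,
      .groups = "drop"
    ) |>
    dplyr::mutate(delta_f = .data$f1 - .data$f0)
}

#' Noise-derived responder threshold per well
#'
#' Each well's threshold is derived from its negative-control (HBSS)
#' recording: `raw = mean(delta_f) + 3 * SD(delta_f)` over cells (sample
#' SD), capped at an upper limit (`effective = min(raw, cap)`, default cap
#' 18 a.u.). The same threshold is then applied to every subsequent
#' stimulus of that well.
#'
#' @param traces Long-format trace tibble (see [compute_delta_f()]) that
#'   contains the negative-control recordings.
#' @param baseline_end_s Stimulus application time (s).
#' @param cap Upper threshold limit (a.u.); default 18.
#' @param negative_control Stimulus label of the negative control.
#' @return A tibble with one row per well: `well_id`, `n_cells_used`,
#'   `mean_delta_f`, `sd_delta_f`, `raw_threshold`, `cap`,
#'   `effective_threshold`.
#' @examples
#' cfg <- sim_config(n_cells_per_well = 50, seed = 2)
#' tr <- simulate_well(cfg, stimulus_spec("negative_control",
#'                                        amplitude_mean = 0))
#' compute_well_threshold(tr)
#' @export
compute_well_threshold <- function(traces, baseline_end_s = 10, cap = 18,
                                   negative_control = "negative_control") {
  if (!is.finite(cap) || cap < 0) {
    stop("`cap` must be finite and >= 0.", call. = FALSE)
  }
  nc <- dplyr::filter(tibble::as_tibble(traces),
                      .data$stimulus == negative_control)
  if (nrow(nc) == 0) {
    stop("No recordings with negative-control stimulus '", negative_control,
         "' found; the threshold requires them.", call. = FALSE)
  }
  df <- compute_delta_f(nc, baseline_end_s)
  out <- df |>
    dplyr::group_by(.data$well_id) |>
    dplyr::summarise(
      n_cells_used = dplyr::n(),
      mean_delta_f = mean(.data$delta_f),
      sd_delta_f = sd(.data$delta_f),
      .groups = "drop"
    )
  if (any(out$n_cells_used < 2)) {
    stop("Wells with fewer than 2 negative-control cells (SD undefined): ",
         paste(out$well_id[out$n_cells_used < 2], collapse = ", "),
         call. = FALSE)
  }
  out |>
    dplyr::mutate(
      raw_threshold = .data$mean_delta_f + 3 * .data$sd_delta_f,
      cap = cap,
      effective_threshold = pmin(.data$raw_threshold, cap)
    )
}

#' Call reactive cells against the per-well noise threshold
#'
#' Classifies every cell of every stimulated recording as reactive
#' (`delta_f > effective_threshold`, strictly) or non-reactive
#' (`delta_f <= effective_threshold`), using each well's threshold derived
#' from its own negative-control recording. Cells present in the
#' negative-control recording but missing from a stimulated recording are
#' dropped with a warning.
#'
#' @param traces Long-format trace tibble holding, for every well, one
#'   negative-control recording and the stimulated recordings.
#' @param thresholds Optional precomputed threshold table from
#'   [compute_well_threshold()]; computed from `traces` when `NULL`.
#' @param baseline_end_s Stimulus application time (s).
#' @param cap Upper threshold limit (a.u.).
#' @param negative_control Stimulus label of the negative control.
#' @param include_negative_control Keep the negative-control recording in
#'   the output (its responsive fraction estimates the false-positive
#'   rate)? Default `TRUE`.
#' @return A tibble with one row per cell per stimulated recording:
#'   metadata, `delta_f`, `effective_threshold`, `reactive`.
#' @seealso [responsive_fractions()] to summarise to per-well fractions.
#' @export
call_responders <- function(traces, thresholds = NULL, baseline_end_s = 10,
                            cap = 18,
                            negative_control = "negative_control",
                            include_negative_control = TRUE) {
  traces <- tibble::as_tibble(traces)
  if (is.null(thresholds)) {
    thresholds <- compute_well_threshold(traces, baseline_end_s, cap,
                                         negative_control)
  }
  df <- compute_delta_f(traces, baseline_end_s)
  stim_wells <- unique(df$well_id[df$stimulus != negative_control])
  missing_thr <- setdiff(stim_wells, thresholds$well_id)
  if (length(missing_thr)) {
    stop("No negative-control threshold available for well(s): ",
         paste(missing_thr, collapse = ", "), call. = FALSE)
  }
  # cells known from the negative control but absent in a stimulated recording
  nc_cells <- df |>
    dplyr::filter(.data$stimulus == negative_control) |>
    dplyr::distinct(.data$well_id, .data$cell_id)
  dropped <- df |>
    dplyr::filter(.data$stimulus != negative_control) |>
    dplyr::distinct(.data$well_id, .data$stimulus, .data$cell_id) |>
    dplyr::count(.data$well_id, .data$stimulus, name = "n_stim") |>
    dplyr::left_join(dplyr::count(nc_cells, .data$well_id, name = "n_nc"),
                     by = "well_id") |>
    dplyr::filter(.data$n_stim < .data$n_nc)
  if (nrow(dropped)) {
    warning("Cells present in the negative-control recording are missing ",
            "from stimulated recording(s) in well(s): ",
            paste(unique(dropped$well_id), collapse = ", "),
            "; missing cells are dropped.", call. = FALSE)
  }
  out <- df |>
    dplyr::inner_join(
      dplyr::select(thresholds, "well_id", "effective_threshold"),
      by = "well_id"
    ) |>
    dplyr::mutate(reactive = .data$delta_f > .data$effective_threshold)
  if (!include_negative_control) {
    out <- dplyr::filter(out, .data$stimulus != negative_control)
  }
  out
}

#' Responsive fraction per well and stimulus
#'
#' @param calls Per-cell call table from [call_responders()].
#' @return A tibble per well and stimulus with `n_cells`, `n_reactive` and
#'   `responsive_fraction = n_reactive / n_cells`, metadata carried through.
#' @export
responsive_fractions <- function(calls) {
  meta <- intersect(c("condition", "compound", "concentration_nM",
                      "biological_rep"), names(calls))
  calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(meta, "well_id", "stimulus")))) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_reactive = sum(.data$reactive),
      responsive_fraction = mean(.data$reactive),
      .groups = "drop"
    )
}

#' Resting-baseline calcium index per condition
#'
#' Quantifies resting intracellular calcium as the mean per-cell baseline
#' fluorescence F0 of the negative-control recording, averaged within wells
#' and then across wells of a condition, and expresses it as % of the
#' untreated-control condition.
#'
#' @param traces Long-format trace tibble with a `condition` column.
#' @param control Condition label of the untreated control.
#' @param baseline_end_s Stimulus application time (s).
#' @param negative_control Stimulus label of the negative control.
#' @return A tibble per condition: `mean_f0` (a.u.) and `pct_of_control`
#'   (100 for the control by construction).
#' @export
baseline_index <- function(traces, control = "untreated",
                           baseline_end_s = 10,
                           negative_control = "negative_control") {
  nc <- dplyr::filter(tibble::as_tibble(traces),
                      .data$stimulus == negative_control)
  if (nrow(nc) == 0) {
    stop("No negative-control recordings found.", call. = FALSE)
  }
  if (!("condition" %in% names(nc))) {
    stop("Trace table lacks a `condition` column.", call. = FALSE)
  }
  df <- compute_delta_f(nc, baseline_end_s)
  per_cond <- df |>
    dplyr::group_by(.data$condition, .data$well_id) |>
    dplyr::summarise(well_f0 = mean(.data$f0), .groups = "drop") |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_f0 = mean(.data$well_f0), .groups = "drop")
  if (!(control %in% per_cond$condition)) {
    stop("Control condition '", control, "' not present.", call. = FALSE)
  }
  ctrl_f0 <- per_cond$mean_f0[per_cond$condition == control]
  dplyr::mutate(per_cond, pct_of_control = .data$mean_f0 / ctrl_f0 * 100)
}

#' Agonist-response attenuation profile as % of untreated control
#'
#' Summarises per-cell responder calls into the assay's treatment endpoint:
#' for every condition and stimulus, the fraction of reactive cells
#' normalised to the untreated control's fraction for the same stimulus
#' (x100). Technical-replicate wells are averaged within each biological
#' replicate first; the mean and SEM are then taken over biological
#' replicates only. When the control fraction for a stimulus is zero the
#' normalised value is undefined; the unnormalised fraction is reported and
#' flagged (`normalized = FALSE`).
#'
#' @param calls Per-cell call table from [call_responders()], covering the
#'   control and treated conditions (columns `condition`, `biological_rep`,
#'   `well_id`, `stimulus`, `reactive`).
#' @param control Condition label of the untreated control.
#' @return A tibble per condition and stimulus: `mean_fraction` (raw),
#'   `pct_of_control` (mean over biological replicates), `sem_pct`
#'   (SEM over biological replicates), `n_biological`, `normalized`.
#' @export
attenuation_profile <- function(calls, control = "untreated") {
  if (!("condition" %in% names(calls))) {
    stop("Call table lacks a `condition` column.", call. = FALSE)
  }
  if (!(control %in% calls$condition)) {
    stop("Control condition '", control, "' not present.", call. = FALSE)
  }
  if (!("biological_rep" %in% names(calls))) {
    calls$biological_rep <- 1L
  }
  frac <- responsive_fractions(calls)
  meta <- intersect(c("compound", "concentration_nM"), names(frac))
  # technical wells collapse to one value per biological replicate
  bio <- frac |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("condition", meta, "biological_rep", "stimulus")))) |>
    dplyr::summarise(bio_fraction = mean(.data$responsive_fraction),
                     .groups = "drop")
  ctrl <- bio |>
    dplyr::filter(.data$condition == control) |>
    dplyr::group_by(.data$stimulus) |>
    dplyr::summarise(control_fraction = mean(.data$bio_fraction),
                     .groups = "drop")
  bio |>
    dplyr::left_join(ctrl, by = "stimulus") |>
    dplyr::mutate(
      normalized = .data$control_fraction > 0,
      pct_bio = dplyr::if_else(.data$normalized,
                               .data$bio_fraction / .data$control_fraction * 100,
                               .data$bio_fraction)
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("condition", meta, "stimulus", "normalized")))) |>
    dplyr::summarise(
      mean_fraction = mean(.data$bio_fraction),
      pct_of_control = mean(.data$pct_bio),
      sem_pct = sd(.data$pct_bio) / sqrt(dplyr::n()),
      n_biological = dplyr::n(),
      .groups = "drop"
    )
}
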