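#' @importFrom rlang .data
#' @importFrom stats rnorm rbinom rlnorm sd setNames quantile
NULL

# Evaluate expr with a temporarily seeded RNG, restoring the caller's state.
with_seed_ <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic substream seed from (seed, key), independent of insertion
# order. Polynomial byte hash mod a Mersenne prime; stays < 2^31.
derive_seed <- function(seed, key) {
  bytes <- utf8ToInt(paste(seed, key, sep = "/"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1)
}

lnorm_pars <- function(mean, cv) {
  # log-normal with the given arithmetic mean and CV
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulation configuration for synthetic calcium-imaging experiments
#'
#' Collects the acquisition and population parameters of a simulated
#' plate: recordings of `recording_duration` seconds at `frame_rate`
#' frames/s, per-cell resting baselines drawn log-normally across cells,
#' iid Gaussian frame noise, and per-stimulus true responder fractions.
#'
#' Defaults emulate the standard assay: 45-s recordings with stimulus
#' application after a 10-s baseline, and noise such that the per-well
#' negative-control threshold (mean + 3 SD of delta-F) falls around
#' 7–9 a.u., well below the 18 a.u. cap.
#'
#' @param n_wells_per_condition Technical-replicate wells per condition and
#'   biological replicate.
#' @param n_cells_per_well Cells per well.
#' @param n_biological Biological replicates (independent cell preparations).
#' @param frame_rate Acquisition rate (frames/s).
#' @param recording_duration Recording length (s); default 45.
#' @param baseline_mean Mean resting fluorescence across cells (a.u.).
#' @param baseline_cell_cv Across-cell CV of the resting baseline
#'   (log-normal).
#' @param noise_sd Per-frame additive Gaussian noise SD (a.u.).
#' @param true_responder_fraction Named vector mapping stimulus labels to the
#'   untreated probability that a cell responds to that stimulus (each in
#'   `[0, 1]`).
#' @param seed Integer seed; identical config and seed give bit-identical
#'   output.
#'
#' @return A list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_cells_per_well = 100, seed = 7)
#' @export
sim_config <- function(n_wells_per_condition = 3,
                       n_cells_per_well = 200,
                       n_biological = 3,
                       frame_rate = 2,
                       recording_duration = 45,
                       baseline_mean = 100,
                       baseline_cell_cv = 0.2,
                       noise_sd = 2,
                       true_responder_fraction = c(negative_control = 0,
                                                   p2x3_agonist = 0.8,
                                                   trpv1_agonist = 0.7,
                                                   kcl = 0.9),
                       seed = 1L) {
  stopifnot(n_wells_per_condition >= 1, n_cells_per_well >= 1,
            n_biological >= 1, frame_rate > 0, recording_duration > 0)
  if (recording_duration * frame_rate < 2) {
    stop("Config must yield at least 2 frames per recording.", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be finite and >= 0.", call. = FALSE)
  }
  if (!is.finite(baseline_mean) || baseline_mean <= 0 ||
      !is.finite(baseline_cell_cv) || baseline_cell_cv < 0) {
    stop("Baseline parameters must be finite, mean > 0, cv >= 0.",
         call. = FALSE)
  }
  if (any(!is.finite(true_responder_fraction)) ||
      any(true_responder_fraction < 0 | true_responder_fraction > 1)) {
    stop("Responder fractions must lie in [0, 1].", call. = FALSE)
  }
  structure(
    list(n_wells_per_condition = as.integer(n_wells_per_condition),
         n_cells_per_well = as.integer(n_cells_per_well),
         n_biological = as.integer(n_biological),
         frame_rate = frame_rate,
         recording_duration = recording_duration,
         baseline_mean = baseline_mean,
         baseline_cell_cv = baseline_cell_cv,
         noise_sd = noise_sd,
         true_responder_fraction = true_responder_fraction,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Treatment effect acting on simulated wells
#'
#' A compound treatment acts on the simulation in two ways: it multiplies
#' the per-stimulus responder fraction (a multiplier of 0 silences that
#' receptor's response entirely) and it scales the resting baseline
#' fluorescence (a factor above 1 models elevated resting intracellular
#' calcium).
#'
#' @param compound Compound label; `"untreated"` for the control.
#' @param concentration_nM Concentration (nM); 0 for the control.
#' @param responder_fraction_multiplier Named vector mapping stimulus labels
#'   to multipliers in `[0, 1]`.
#' @param baseline_shift_factor Multiplier (`>= 0`) applied to resting
#'   fluorescence.
#' @param condition Optional condition label; defaults to the compound for
#'   the untreated control and `"<compound>_<conc>nM"` otherwise.
#'
#' @return A list of class `"treatment_effect"`.
#' @seealso [effect_preset()] for ready-made illustrative parameterisations.
#' @export
treatment_effect <- function(compound = "untreated",
                             concentration_nM = 0,
                             responder_fraction_multiplier =
                               c(negative_control = 1, p2x3_agonist = 1,
                                 trpv1_agonist = 1, kcl = 1),
                             baseline_shift_factor = 1,
                             condition = NULL) {
  m <- responder_fraction_multiplier
  if (any(!is.finite(m)) || any(m < 0 | m > 1)) {
    stop("Responder-fraction multipliers must lie in [0, 1].", call. = FALSE)
  }
  if (!is.finite(baseline_shift_factor) || baseline_shift_factor < 0) {
    stop("`baseline_shift_factor` must be finite and >= 0.", call. = FALSE)
  }
  if (is.null(condition)) {
    condition <- if (compound == "untreated") "untreated"
                 else paste0(compound, "_", concentration_nM, "nM")
  }
  structure(
    list(compound = compound,
         concentration_nM = concentration_nM,
         responder_fraction_multiplier = m,
         baseline_shift_factor = baseline_shift_factor,
         condition = condition),
    class = "treatment_effect"
  )
}

#' Illustrative treatment-effect presets
#'
#' Named parameterisations of [treatment_effect()] mirroring the qualitative
#' effect structure observed for the compound classes studied with this
#' assay; the numbers are illustrative, not measured values.
#'
#' * `"untreated"` — all multipliers 1, baseline shift 1.
#' * `"PI-like"` — proteasome-inhibitor-like: complete shutdown of the P2X3
#'   response (multiplier 0) with intact TRPV1 and KCl responses and a mildly
#'   elevated resting baseline (shift 1.2).
#' * `"taxol-like"` — no functional calcium-signalling effect at the tested
#'   concentration: all multipliers 1, shift 1.
#'
#' @param name Preset name.
#' @param compound,concentration_nM Optional relabelling of the preset.
#' @return A `treatment_effect`.
#' @export
effect_preset <- function(name = c("untreated", "PI-like", "taxol-like"),
                          compound = NULL, concentration_nM = NULL) {
  name <- match.arg(name)
  pars <- switch(name,
    "untreated" = list(compound = "untreated", conc = 0,
                       mult = c(negative_control = 1, p2x3_agonist = 1,
                                trpv1_agonist = 1, kcl = 1),
                       shift = 1),
    "PI-like" = list(compound = "PI_like", conc = 10,
                     mult = c(negative_control = 1, p2x3_agonist = 0,
                              trpv1_agonist = 1, kcl = 1),
                     shift = 1.2),
    "taxol-like" = list(compound = "taxol_like", conc = 1000,
                        mult = c(negative_control = 1, p2x3_agonist = 1,
                                 trpv1_agonist = 1, kcl = 1),
                        shift = 1)
  )
  treatment_effect(
    compound = compound %||% pars$compound,
    concentration_nM = concentration_nM %||% pars$conc,
    responder_fraction_multiplier = pars$mult,
    baseline_shift_factor = pars$shift
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one well recording for one stimulus
#'
#' Generates `n_cells_per_well` single-cell fluorescence traces for a 45-s
#' (by default) recording with the stimulus applied at its
#' `application_time`. Each cell is independently a responder with
#' probability `true_responder_fraction[stimulus] * multiplier[stimulus]`;
#' a responder's trace is its (treatment-shifted) resting baseline plus a
#' per-cell amplitude times the stimulus kernel, plus iid Gaussian frame
#' noise; non-responders omit the kernel term. The negative-control
#' stimulus always uses the null kernel.
#'
#' @param config A [sim_config()].
#' @param stimulus A [stimulus_spec()].
#' @param effect A [treatment_effect()]; default untreated.
#' @param well_id Well label.
#' @param seed Substream seed; defaults to a value derived from
#'   `config$seed` and `well_id`.
#' @param baselines Optional numeric vector of per-cell resting baselines
#'   (before treatment shift), used to share cell identities across the
#'   stimuli of one well; drawn log-normally when `NULL`.
#'
#' @return A tibble with one row per cell per frame: `condition`,
#'   `compound`, `concentration_nM`, `well_id`, `stimulus`, `cell_id`,
#'   `frame_index` (0-based), `time_s`, `fluorescence_au`, plus the
#'   simulation-truth column `true_responder`.
#' @examples
#' cfg <- sim_config(n_cells_per_well = 20, seed = 7)
#' tr <- simulate_well(cfg, stimulus_spec("p2x3_agonist", amplitude_mean = 60))
#' dplyr::count(tr, cell_id)
#' @export
simulate_well <- function(config, stimulus,
                          effect = treatment_effect(),
                          well_id = "W1",
                          seed = NULL,
                          baselines = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(stimulus, "stimulus_spec"),
            inherits(effect, "treatment_effect"))
  if (stimulus$application_time >= config$recording_duration) {
    stop("Stimulus application time must fall within the recording.",
         call. = FALSE)
  }
  frac <- config$true_responder_fraction
  if (!(stimulus$name %in% names(frac))) {
    stop("No true responder fraction configured for stimulus '",
         stimulus$name, "'.", call. = FALSE)
  }
  mult <- effect$responder_fraction_multiplier
  if (!(stimulus$name %in% names(mult))) {
    stop("Treatment effect lacks a responder-fraction multiplier for ",
         "stimulus '", stimulus$name, "'.", call. = FALSE)
  }
  seed <- seed %||% derive_seed(config$seed, well_id)

  n_cells <- config$n_cells_per_well
  n_frames <- as.integer(ceiling(config$recording_duration * config$frame_rate))
  time_s <- (seq_len(n_frames) - 1) / config$frame_rate
  p_resp <- frac[[stimulus$name]] * mult[[stimulus$name]]

  sim <- with_seed_(seed, {
    if (is.null(baselines)) {
      lp <- lnorm_pars(config$baseline_mean, config$baseline_cell_cv)
      baselines <- if (config$baseline_cell_cv > 0) {
        rlnorm(n_cells, lp$meanlog, lp$sdlog)
      } else rep(config$baseline_mean, n_cells)
    }
    responder <- rbinom(n_cells, 1L, p_resp)
    amp <- if (stimulus$amplitude_cv > 0) {
      la <- lnorm_pars(max(stimulus$amplitude_mean, .Machine$double.eps),
                       stimulus$amplitude_cv)
      rlnorm(n_cells, la$meanlog, la$sdlog) *
        (stimulus$amplitude_mean > 0)
    } else rep(stimulus$amplitude_mean, n_cells)
    noise <- if (config$noise_sd > 0) {
      matrix(rnorm(n_cells * n_frames, 0, config$noise_sd), n_cells, n_frames)
    } else matrix(0, n_cells, n_frames)
    list(baselines = baselines, responder = responder, amp = amp,
         noise = noise)
  })

  k <- response_kernel(stimulus$kernel, time_s - stimulus$application_time,
                       rise_time_constant = stimulus$rise_time_constant,
                       decay_time_constant = stimulus$decay_time_constant)
  base_shift <- sim$baselines * effect$baseline_shift_factor
  fl <- base_shift %o% rep(1, n_frames) +
    (sim$amp * sim$responder) %o% k + sim$noise

  tibble::tibble(
    condition = effect$condition,
    compound = effect$compound,
    concentration_nM = effect$concentration_nM,
    well_id = well_id,
    stimulus = stimulus$name,
    cell_id = rep(sprintf("%s_c%04d", well_id, seq_len(n_cells)),
                  each = n_frames),
    frame_index = rep(0:(n_frames - 1), times = n_cells),
    time_s = rep(time_s, times = n_cells),
    fluorescence_au = as.vector(t(fl)),
    true_responder = rep(sim$responder == 1L, each = n_frames)
  )
}

#' Simulate a full multi-condition calcium-imaging experiment
#'
#' For every treatment condition, biological replicate and well, generates
#' one recording per scheduled stimulus. All recordings of a well share the
#' same cell identities and per-cell resting baselines, mirroring repeated
#' imaging of the same field; responder identity is drawn independently per
#' stimulus. The schedule must contain a negative-control stimulus because
#' downstream responder calling derives each well's noise threshold from it.
#'
#' @param config A [sim_config()].
#' @param schedule A list of [stimulus_spec()]s; default [default_schedule()].
#' @param effects A list of [treatment_effect()]s, one per condition;
#'   default untreated control only.
#'
#' @return A list of class `"ca_experiment"` with elements `traces` (one
#'   long tibble over all recordings) and `platemap` (one row per well:
#'   condition, compound, concentration, biological replicate, well id).
#' @examples
#' cfg <- sim_config(n_cells_per_well = 30, n_wells_per_condition = 1,
#'                   n_biological = 1, seed = 3)
#' exp <- simulate_experiment(cfg)
#' dplyr::count(exp$traces, stimulus)
#' @export
simulate_experiment <- function(config,
                                schedule = default_schedule(),
                                effects = list(effect_preset("untreated"))) {
  stopifnot(inherits(config, "sim_config"), length(schedule) >= 1)
  stim_names <- vapply(schedule, function(s) s$name, character(1))
  if (!("negative_control" %in% stim_names)) {
    stop("Schedule must include a negative_control stimulus: each well's ",
         "responder threshold is derived from its negative-control ",
         "recording.", call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    cond_idx = seq_along(effects),
    biological_rep = seq_len(config$n_biological),
    tech = seq_len(config$n_wells_per_condition)
  )
  lp <- lnorm_pars(config$baseline_mean, config$baseline_cell_cv)

  rows <- purrr::pmap(grid, function(cond_idx, biological_rep, tech) {
    effect <- effects[[cond_idx]]
    well_id <- sprintf("%s_b%d_w%d", effect$condition, biological_rep, tech)
    base_seed <- derive_seed(config$seed, well_id)
    baselines <- with_seed_(base_seed, {
      if (config$baseline_cell_cv > 0) {
        rlnorm(config$n_cells_per_well, lp$meanlog, lp$sdlog)
      } else rep(config$baseline_mean, config$n_cells_per_well)
    })
    recs <- purrr::imap(schedule, function(stim, nm) {
      simulate_well(config, stim, effect, well_id = well_id,
                    seed = derive_seed(config$seed,
                                       paste(well_id, stim$name, sep = ":")),
                    baselines = baselines)
    })
    traces <- dplyr::bind_rows(recs)
    traces$biological_rep <- biological_rep
    traces
  })
  traces <- dplyr::bind_rows(rows)
  platemap <- dplyr::distinct(
    traces, .data$condition, .data$compound, .data$concentration_nM,
    .data$biological_rep, .data$well_id
  )
  structure(list(traces = traces, platemap = platemap),
            class = "ca_experiment")
}

#' @export
print.ca_experiment <- function(x, ...) {
  cat("Simulated calcium-imaging experiment\n")
  cat("  conditions: ", paste(unique(x$platemap$condition), collapse = ", "),
      "\n", sep = "")
  cat("  wells:      ", nrow(x$platemap), "\n", sep = "")
  cat("  stimuli:    ", paste(unique(x$traces$stimulus), collapse = ", "),
      "\n", sep = "")
  cat("  trace rows: ", nrow(x$traces), "\n", sep = "")
  invisible(x)
}

#' Simulate a two-endpoint concentration-response table
#'
#' Draws replicate endpoint values (% of untreated control) around a
#' declining four-parameter logistic mean
#' \deqn{\mu(c) = bottom + (top - bottom) / (1 + (c/ec50)^{h})}
#' with multiplicative Gaussian noise of the stated CV. The control
#' (`c = 0`) has expectation `top` (100% by default).
#'
#' @param compound Compound label.
#' @param endpoint `"neurite_area"` or `"viability"`.
#' @param ec50 Half-effect concentration (nM), `> 0`.
#' @param hill_slope Hill coefficient, `> 0`.
#' @param bottom Lower asymptote (% of control), `>= 0`.
#' @param top Upper asymptote; fixed at 100 in the analysis and defaulted
#'   here.
#' @param concentrations Concentration series (nM), including 0 for the
#'   control, strictly increasing thereafter.
#' @param n_technical,n_biological Replicate structure (technical wells
#'   within biological cell preparations).
#' @param noise_cv CV of the multiplicative replicate noise.
#' @param seed Integer seed.
#'
#' @return A tibble: `compound`, `concentration_nM`, `endpoint`,
#'   `biological_rep`, `technical_rep`, `value_pct_control`.
#' @examples
#' simulate_dose_response(ec50 = 10, noise_cv = 0, seed = 1)
#' @export
simulate_dose_response <- function(compound = "compound_A",
                                   endpoint = c("neurite_area", "viability"),
                                   ec50 = 10,
                                   hill_slope = 1,
                                   bottom = 0,
                                   top = 100,
                                   concentrations = c(0, 1, 3, 10, 30, 100, 300),
                                   n_technical = 3,
                                   n_biological = 3,
                                   noise_cv = 0.1,
                                   seed = 1L) {
  endpoint <- match.arg(endpoint)
  if (!is.finite(ec50) || ec50 <= 0) stop("`ec50` must be > 0.", call. = FALSE)
  if (!is.finite(hill_slope) || hill_slope <= 0) {
    stop("`hill_slope` must be > 0.", call. = FALSE)
  }
  if (!is.finite(bottom) || bottom < 0) stop("`bottom` must be >= 0.",
                                             call. = FALSE)
  if (!(0 %in% concentrations)) {
    stop("`concentrations` must include 0 (the untreated control).",
         call. = FALSE)
  }
  nz <- sort(concentrations[concentrations > 0])
  if (anyDuplicated(nz)) {
    stop("Nonzero concentrations must be strictly increasing.", call. = FALSE)
  }
  concentrations <- c(0, nz)
  grid <- tidyr::expand_grid(
    concentration_nM = concentrations,
    biological_rep = seq_len(n_biological),
    technical_rep = seq_len(n_technical)
  )
  mu <- logistic4_mean(grid$concentration_nM, top, bottom, ec50, hill_slope)
  noise <- with_seed_(derive_seed(seed, paste(compound, endpoint)), {
    if (noise_cv > 0) rnorm(nrow(grid), 0, noise_cv) else rep(0, nrow(grid))
  })
  tibble::tibble(
    compound = compound,
    concentration_nM = grid$concentration_nM,
    endpoint = endpoint,
    biological_rep = grid$biological_rep,
    technical_rep = grid$technical_rep,
    value_pct_control = mu * (1 + noise)
  )
}

# Declining 4-parameter logistic mean; c = 0 maps to the top asymptote.
logistic4_mean <- function(conc, top, bottom, ec50, hill_slope) {
  ifelse(conc <= 0, top,
         bottom + (top - bottom) / (1 + (conc / ec50)^hill_slope))
}
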