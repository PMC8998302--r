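#' Default end-to-end run configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]: simulation
#' parameters, the treatment conditions (as [effect_preset()] names or
#' [treatment_effect()] objects), thresholding settings (cap 18 a.u.,
#' baseline end 10 s), the benchmark-concentration settings (25% benchmark,
#' ratio cutoff 3), and the concentration-response scenarios to simulate
#' and classify.
#'
#' @param seed Integer seed for the whole run.
#' @return A named list of class `"run_config"`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulation = list(
      n_wells_per_condition = 3, n_cells_per_well = 300, n_biological = 3,
      frame_rate = 2, recording_duration = 45,
      baseline_mean = 100, baseline_cell_cv = 0.2, noise_sd = 2
    ),
    effects = c("untreated", "PI-like", "taxol-like"),
    thresholding = list(cap = 18, baseline_end_s = 10),
    bmc = list(benchmark = 0.25, ratio_cutoff = 3),
    dose_response = list(
      list(compound = "PI_like",
           neurite_area = list(ec50 = 20, hill_slope = 1.5, bottom = 0),
           viability = list(ec50 = 200, hill_slope = 2, bottom = 0),
           concentrations = c(0, 1, 3, 10, 30, 100, 300, 1000),
           n_technical = 3, n_biological = 3, noise_cv = 0.1),
      list(compound = "cytotoxic_like",
           neurite_area = list(ec50 = 100, hill_slope = 2, bottom = 0),
           viability = list(ec50 = 150, hill_slope = 2, bottom = 0),
           concentrations = c(0, 1, 3, 10, 30, 100, 300, 1000),
           n_technical = 3, n_biological = 3, noise_cv = 0.1)
    )
  ), class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path Path to a JSON file with sections `seed`, `simulation`,
#'   `effects`, `thresholding`, `bmc`, `dose_response` (missing sections
#'   fall back to [default_run_config()]).
#' @return A `"run_config"` list.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  cfg <- default_run_config(seed = raw$seed %||% 1L)
  for (section in c("simulation", "thresholding", "bmc")) {
    if (!is.null(raw[[section]])) {
      cfg[[section]] <- utils::modifyList(cfg[[section]], raw[[section]])
    }
  }
  if (!is.null(raw$effects)) {
    cfg$effects <- lapply(raw$effects, function(e) {
      if (is.character(e) && length(e) == 1) return(e)
      treatment_effect(
        compound = e$compound %||% "untreated",
        concentration_nM = e$concentration_nM %||% 0,
        responder_fraction_multiplier =
          unlist(e$responder_fraction_multiplier %||%
                   list(negative_control = 1, p2x3_agonist = 1,
                        trpv1_agonist = 1, kcl = 1)),
        baseline_shift_factor = e$baseline_shift_factor %||% 1
      )
    })
  }
  if (!is.null(raw$dose_response)) cfg$dose_response <- raw$dose_response
  cfg
}

resolve_effects <- function(effects) {
  lapply(effects, function(e) {
    if (inherits(e, "treatment_effect")) e else effect_preset(e)
  })
}

#' Run the full simulate / call / profile / classify pipeline
#'
#' Executes, as one seeded and reproducible run: (1) simulation of a
#' multi-condition calcium-imaging experiment; (2) per-well noise
#' thresholding and responder calling; (3) attenuation profiling (% of
#' untreated control, mean and SEM over biological replicates) and the
#' resting-baseline index; (4) simulation, curve fitting, BMC25 estimation
#' and neurite-specificity classification of the configured
#' concentration-response scenarios. Intermediate tables and the report
#' can be written to `out_dir` as CSV/JSON.
#'
#' @param config A `"run_config"` (see [default_run_config()]) or a path
#'   to a JSON configuration.
#' @param out_dir Optional output directory; created when missing.
#' @param seed Optional seed overriding the configured one.
#' @param write_traces Also write the (large) per-frame trace table when
#'   `out_dir` is given? Default `FALSE`.
#' @return A list of class `"run_report"` with elements `config`, `seed`,
#'   `thresholds`, `fractions`, `attenuation`, `baseline`, `specificity`,
#'   `effect_thresholds`, `bmc`, `version`, `timestamp`. Rerunning with
#'   the identical config and seed reproduces all numeric fields exactly.
#' @examples
#' \donttest{
#' cfg <- default_run_config(seed = 42)
#' cfg$simulation$n_cells_per_well <- 50
#' rep <- run_pipeline(cfg)
#' rep$attenuation
#' }
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         seed = NULL, write_traces = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)

  sim <- config$simulation
  cfg <- sim_config(
    n_wells_per_condition = sim$n_wells_per_condition %||% 3,
    n_cells_per_well = sim$n_cells_per_well %||% 300,
    n_biological = sim$n_biological %||% 3,
    frame_rate = sim$frame_rate %||% 2,
    recording_duration = sim$recording_duration %||% 45,
    baseline_mean = sim$baseline_mean %||% 100,
    baseline_cell_cv = sim$baseline_cell_cv %||% 0.2,
    noise_sd = sim$noise_sd %||% 2,
    seed = config$seed
  )
  effects <- resolve_effects(config$effects)
  message("Stage 1/4: simulating calcium-imaging experiment (",
          length(effects), " conditions)")
  experiment <- simulate_experiment(cfg, effects = effects)

  issues <- validate_traces(experiment$traces)
  if (any(issues$severity == "error")) {
    stop("Simulated trace table failed validation:\n",
         paste(issues$message[issues$severity == "error"], collapse = "\n"),
         call. = FALSE)
  }

  thr_cfg <- config$thresholding
  baseline_end_s <- thr_cfg$baseline_end_s %||% 10
  cap <- thr_cfg$cap %||% 18
  message("Stage 2/4: calling responders (cap ", cap, " a.u.)")
  thresholds <- compute_well_threshold(experiment$traces, baseline_end_s, cap)
  calls <- call_responders(experiment$traces, thresholds, baseline_end_s, cap)
  fractions <- responsive_fractions(calls)

  message("Stage 3/4: attenuation and baseline profiling")
  attenuation <- attenuation_profile(
    dplyr::filter(calls, .data$stimulus != "negative_control"),
    control = "untreated"
  )
  baseline <- baseline_index(experiment$traces, control = "untreated",
                             baseline_end_s = baseline_end_s)

  message("Stage 4/4: concentration-response fitting and classification")
  bmc_cfg <- config$bmc
  benchmark <- bmc_cfg$benchmark %||% 0.25
  ratio_cutoff <- bmc_cfg$ratio_cutoff %||% 3
  dr <- purrr::map(config$dose_response, function(sc) {
    fits <- purrr::map(
      setNames(c("neurite_area", "viability"), c("neurite_area", "viability")),
      function(ep) {
        pars <- sc[[ep]]
        d <- simulate_dose_response(
          compound = sc$compound, endpoint = ep,
          ec50 = pars$ec50, hill_slope = pars$hill_slope %||% 1,
          bottom = pars$bottom %||% 0,
          concentrations = unlist(sc$concentrations),
          n_technical = sc$n_technical %||% 3,
          n_biological = sc$n_biological %||% 3,
          noise_cv = sc$noise_cv %||% 0.1,
          seed = derive_seed(config$seed, paste("dr", sc$compound, ep))
        )
        fit_curve(d)
      })
    x <- bmc(fits$neurite_area, benchmark)
    y <- bmc(fits$viability, benchmark)
    list(fits = fits,
         bmc = dplyr::bind_rows(x, y),
         specificity = classify_specificity(x, y, ratio_cutoff),
         thresholds = effect_thresholds(fits))
  })

  report <- structure(list(
    config = config,
    seed = config$seed,
    thresholds = thresholds,
    fractions = fractions,
    attenuation = attenuation,
    baseline = baseline,
    bmc = dplyr::bind_rows(purrr::map(dr, "bmc")),
    specificity = dplyr::bind_rows(purrr::map(dr, "specificity")),
    effect_thresholds = dplyr::bind_rows(purrr::map(dr, "thresholds")),
    fits = purrr::map(dr, "fits"),
    version = as.character(utils::packageVersion("calcitox")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), class = "run_report")

  if (!is.null(out_dir)) {
    write_run_report(report, out_dir,
                     traces = if (write_traces) experiment$traces else NULL,
                     calls = calls)
  }
  report
}

#' Write a run report and its intermediate tables
#'
#' @param report A `"run_report"` from [run_pipeline()].
#' @param out_dir Output directory.
#' @param traces,calls Optional intermediate tables to write alongside.
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir, traces = NULL, calls = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(report$thresholds, "well_thresholds.csv")
  wcsv(report$fractions, "responsive_fractions.csv")
  wcsv(report$attenuation, "attenuation_profile.csv")
  wcsv(report$baseline, "baseline_index.csv")
  wcsv(report$bmc, "bmc_results.csv")
  wcsv(report$specificity, "specificity.csv")
  wcsv(report$effect_thresholds, "effect_thresholds.csv")
  if (!is.null(traces)) wcsv(traces, "traces.csv")
  if (!is.null(calls)) wcsv(calls, "responder_calls.csv")
  json <- list(
    seed = report$seed,
    version = report$version,
    timestamp = report$timestamp,
    thresholds = report$thresholds,
    attenuation = report$attenuation,
    baseline = report$baseline,
    bmc = report$bmc,
    specificity = report$specificity,
    effect_thresholds = report$effect_thresholds
  )
  jsonlite::write_json(json, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("calcitox run report (seed ", x$seed, ", v", x$version, ")\n",
      sep = "")
  cat("\nAttenuation profile (% of untreated control):\n")
  print(as.data.frame(
    dplyr::select(x$attenuation, dplyr::any_of(
      c("condition", "stimulus", "pct_of_control", "sem_pct")))),
    digits = 4, row.names = FALSE)
  cat("\nBaseline index (% of untreated control):\n")
  print(as.data.frame(x$baseline), digits = 4, row.names = FALSE)
  if (nrow(x$specificity)) {
    cat("\nNeurite-specificity classification:\n")
    print(as.data.frame(x$specificity), digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Validate a long-format trace table
#'
#' Checks the schema and internal consistency of a per-cell per-frame
#' trace table: required columns, finite values, strictly increasing time
#' within each trace, a shared time grid within each well, and the
#' presence of a negative-control recording for every well (required for
#' thresholding). Always returns a report; callers decide whether errors
#' abort.
#'
#' @param traces Trace tibble (see [compute_delta_f()] for the schema).
#' @param negative_control Negative-control stimulus label.
#' @return A tibble of issues with columns `severity` (`"error"` or
#'   `"warning"`), `well_id`, `message`; zero rows when clean.
#' @export
validate_traces <- function(traces, negative_control = "negative_control") {
  issues <- list()
  add <- function(severity, well_id, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      severity = severity, well_id = well_id, message = message)
  }
  req <- c("well_id", "stimulus", "cell_id", "frame_index", "time_s",
           "fluorescence_au")
  miss <- setdiff(req, names(traces))
  if (length(miss)) {
    add("error", NA_character_,
        paste0("Missing column(s): ", paste(miss, collapse = ", ")))
    return(dplyr::bind_rows(issues))
  }
  if (!all(is.finite(traces$fluorescence_au))) {
    add("error", NA_character_, "Non-finite fluorescence values present.")
  }
  per_trace <- traces |>
    dplyr::group_by(.data$well_id, .data$stimulus, .data$cell_id) |>
    dplyr::summarise(
      monotone = !is.unsorted(.data$time_s, strictly = TRUE),
      grid = paste(signif(.data$time_s, 10), collapse = ","),
      .groups = "drop"
    )
  bad <- per_trace$well_id[!per_trace$monotone]
  if (length(bad)) {
    add("error", paste(unique(bad), collapse = ", "),
        "Non-monotone time within trace(s).")
  }
  grid_check <- per_trace |>
    dplyr::group_by(.data$well_id) |>
    dplyr::summarise(n_grids = dplyr::n_distinct(.data$grid),
                     .groups = "drop") |>
    dplyr::filter(.data$n_grids > 1)
  for (w in grid_check$well_id) {
    add("warning", w, paste0("Well ", w,
                             ": traces do not share one time grid."))
  }
  wells <- unique(traces$well_id)
  nc_wells <- unique(traces$well_id[traces$stimulus == negative_control])
  for (w in setdiff(wells, nc_wells)) {
    add("error", w, paste0("Well ", w, " lacks a negative-control ('",
                           negative_control, "') recording."))
  }
  if (!length(issues)) {
    return(tibble::tibble(severity = character(), well_id = character(),
                          message = character()))
  }
  dplyr::bind_rows(issues)
}

#' Validate a dose-response table
#'
#' @param data Tibble with `compound`, `concentration_nM`, `endpoint`,
#'   replicate columns and `value_pct_control`.
#' @return A tibble of issues (`severity`, `message`); zero rows when
#'   clean. Fewer than 4 nonzero concentrations is a warning, not an
#'   error.
#' @export
validate_dose_response <- function(data) {
  issues <- list()
  add <- function(severity, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      severity = severity, message = message)
  }
  req <- c("concentration_nM", "value_pct_control")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    add("error", paste0("Missing column(s): ", paste(miss, collapse = ", ")))
    return(dplyr::bind_rows(issues))
  }
  if (!all(is.finite(data$value_pct_control))) {
    add("error", "Non-finite endpoint values present.")
  }
  if (!any(data$concentration_nM == 0)) {
    add("error", "No control records (concentration 0).")
  }
  n_nz <- length(unique(data$concentration_nM[data$concentration_nM > 0]))
  if (n_nz < 4) {
    add("warning", paste0("Only ", n_nz, " nonzero concentration(s); ",
                          ">= 4 recommended for stable BMC estimates."))
  }
  if (!length(issues)) {
    return(tibble::tibble(severity = character(), message = character()))
  }
  dplyr::bind_rows(issues)
}
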