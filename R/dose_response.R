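#' Fit a declining concentration-response curve
#'
#' Fits a declining four-parameter logistic with the top asymptote pinned
#' to 100 (data are % of untreated control),
#' \deqn{\mu(c) = bottom + (100 - bottom) / (1 + (c/ec50)^{h}),}
#' to endpoint measurements. Technical replicates are averaged within each
#' biological replicate before fitting; biological-replicate means enter
#' the least-squares fit with uniform weights. When the nonlinear fit does
#' not converge, a monotone (isotonic, non-increasing) interpolation of the
#' concentration means is used instead and flagged via `method`.
#'
#' @param data Tibble with columns `concentration_nM`, `value_pct_control`
#'   and optionally `compound`, `endpoint`, `biological_rep`,
#'   `technical_rep`. Control records (`concentration_nM == 0`) must be
#'   present; at least 3 distinct nonzero concentrations are required (a
#'   warning recommends 4 or more).
#'
#' @return An object of class `"dr_fit"`: parameters (`top = 100`,
#'   `bottom`, `ec50`, `hill_slope`), `residual_sd`, `converged`, `method`
#'   (`"logistic4"` or `"interpolation"`), the biological-mean data and
#'   `tested_max`. Supports [predict()][predict.dr_fit],
#'   [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' d <- simulate_dose_response(ec50 = 10, noise_cv = 0, seed = 1)
#' fit <- fit_curve(d)
#' tidy(fit)
#' @export
fit_curve <- function(data) {
  data <- tibble::as_tibble(data)
  req <- c("concentration_nM", "value_pct_control")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("Dose-response table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(data$value_pct_control))) {
    stop("Endpoint values must be finite.", call. = FALSE)
  }
  if (!any(data$concentration_nM == 0)) {
    stop("Control records (concentration 0) are required.", call. = FALSE)
  }
  nz <- sort(unique(data$concentration_nM[data$concentration_nM > 0]))
  if (length(nz) < 3) {
    stop("At least 3 distinct nonzero concentrations are required.",
         call. = FALSE)
  }
  if (length(nz) < 4) {
    warning("Fewer than 4 nonzero concentrations; BMC estimates may be ",
            "unstable.", call. = FALSE)
  }
  compound <- if ("compound" %in% names(data)) data$compound[1] else NA_character_
  endpoint <- if ("endpoint" %in% names(data)) data$endpoint[1] else NA_character_
  if (!("biological_rep" %in% names(data))) data$biological_rep <- 1L

  # technical replicates collapse to biological means before fitting
  bio <- data |>
    dplyr::group_by(.data$concentration_nM, .data$biological_rep) |>
    dplyr::summarise(value = mean(.data$value_pct_control), .groups = "drop")

  start <- list(
    bottom = max(0, min(bio$value)),
    ec50 = exp(mean(log(nz))),
    hill_slope = 1
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      value ~ logistic4_mean(concentration_nM, 100, bottom, ec50, hill_slope),
      data = bio, start = start,
      lower = c(bottom = 0, ec50 = 1e-9, hill_slope = 0.05),
      upper = c(bottom = 100, ec50 = 1e9, hill_slope = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  means <- bio |>
    dplyr::group_by(.data$concentration_nM) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$concentration_nM)

  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    obj <- list(
      compound = compound, endpoint = endpoint, method = "logistic4",
      top = 100, bottom = unname(cf["bottom"]), ec50 = unname(cf["ec50"]),
      hill_slope = unname(cf["hill_slope"]),
      residual_sd = sqrt(mean(stats::residuals(fit)^2)),
      converged = TRUE,
      bio_means = bio, conc_means = means,
      tested_max = max(nz)
    )
  } else {
    # monotone non-increasing interpolation of the concentration means
    iso <- stats::isoreg(seq_len(nrow(means)), -means$value)
    obj <- list(
      compound = compound, endpoint = endpoint, method = "interpolation",
      top = 100, bottom = NA_real_, ec50 = NA_real_,
      hill_slope = NA_real_,
      residual_sd = sqrt(mean((means$value - (-iso$yf))^2)),
      converged = FALSE,
      bio_means = bio,
      conc_means = dplyr::mutate(means, value = -iso$yf),
      tested_max = max(nz)
    )
  }
  structure(obj, class = "dr_fit")
}

#' Fitted mean of a concentration-response fit
#'
#' @param object A `"dr_fit"` from [fit_curve()].
#' @param newdata Optional data frame with a `concentration_nM` column, or
#'   a numeric concentration vector; defaults to the fitted concentrations.
#' @param ... Unused.
#' @return Numeric vector of fitted mean values (% of control).
#' @export
predict.dr_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) {
    object$conc_means$concentration_nM
  } else if (is.data.frame(newdata)) {
    newdata$concentration_nM
  } else {
    as.numeric(newdata)
  }
  if (object$method == "logistic4") {
    logistic4_mean(conc, object$top, object$bottom, object$ec50,
                   object$hill_slope)
  } else {
    m <- object$conc_means
    # piecewise-linear between tested concentrations, constant beyond
    stats::approx(m$concentration_nM, m$value, xout = conc, rule = 2)$y
  }
}

#' @export
print.dr_fit <- function(x, ...) {
  cat("Concentration-response fit (", x$method, ")\n", sep = "")
  if (!is.na(x$compound)) cat("  compound: ", x$compound, "\n", sep = "")
  if (!is.na(x$endpoint)) cat("  endpoint: ", x$endpoint, "\n", sep = "")
  if (x$method == "logistic4") {
    cat(sprintf("  top 100 (fixed), bottom %.2f, ec50 %.4g nM, hill %.3g\n",
                x$bottom, x$ec50, x$hill_slope))
  }
  cat(sprintf("  residual SD %.3g, converged: %s\n",
              x$residual_sd, x$converged))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_curve
#' @param x A `"dr_fit"` object.
#' @param ... Unused.
#' @method tidy dr_fit
#' @export
tidy.dr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("top", "bottom", "ec50", "hill_slope"),
    estimate = c(x$top, x$bottom, x$ec50, x$hill_slope),
    fixed = c(TRUE, FALSE, FALSE, FALSE)
  )
}

#' @rdname fit_curve
#' @method glance dr_fit
#' @export
glance.dr_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    converged = x$converged,
    residual_sd = x$residual_sd,
    n_concentrations = nrow(x$conc_means),
    tested_max = x$tested_max
  )
}

#' Benchmark concentration (BMC) from a fitted curve
#'
#' Inverts the fitted mean curve at the benchmark response level
#' `100 * (1 - response_fraction)` percent of control: the BMC25 is the
#' concentration at which the fitted curve reaches 75% of control. When
#' the fitted curve at the highest tested concentration stays above the
#' benchmark level, the BMC is censored (`BMC > tested_max`); no numeric
#' value is imputed.
#'
#' @param fit A `"dr_fit"` from [fit_curve()].
#' @param response_fraction Benchmark response as a decrease fraction in
#'   (0, 1); default 0.25 (BMC25).
#' @param tested_max Highest tested concentration (nM); defaults to the
#'   fit's.
#' @return One-row tibble: `compound`, `endpoint`, `response_fraction`,
#'   `bmc` (nM, `NA` when censored), `censored`, `tested_max`.
#' @examples
#' d <- simulate_dose_response(ec50 = 10, noise_cv = 0, seed = 1)
#' bmc(fit_curve(d)) # ~ 10/3 nM
#' @export
bmc <- function(fit, response_fraction = 0.25, tested_max = NULL) {
  stopifnot(inherits(fit, "dr_fit"))
  if (!is.finite(response_fraction) || response_fraction <= 0 ||
      response_fraction >= 1) {
    stop("`response_fraction` must lie in (0, 1).", call. = FALSE)
  }
  tested_max <- tested_max %||% fit$tested_max
  level <- 100 * (1 - response_fraction)
  at_max <- predict(fit, tested_max)
  if (at_max > level) {
    return(tibble::tibble(
      compound = fit$compound, endpoint = fit$endpoint,
      response_fraction = response_fraction,
      bmc = NA_real_, censored = TRUE, tested_max = tested_max
    ))
  }
  value <- if (fit$method == "logistic4") {
    if (fit$bottom >= level) {
      NA_real_ # asymptote above the benchmark; unreachable
    } else {
      fit$ec50 * ((fit$top - level) / (level - fit$bottom))^(1 / fit$hill_slope)
    }
  } else {
    stats::uniroot(function(c) predict(fit, c) - level,
                   lower = 0, upper = tested_max, tol = 1e-9)$root
  }
  censored <- !is.finite(value) || value > tested_max
  tibble::tibble(
    compound = fit$compound, endpoint = fit$endpoint,
    response_fraction = response_fraction,
    bmc = if (censored) NA_real_ else value,
    censored = censored, tested_max = tested_max
  )
}

#' Neurite-specificity prediction model
#'
#' Classifies a compound effect from the BMC25 of the two endpoints:
#' X = neurite area, Y = viability. A ratio Y/X strictly greater than the
#' cutoff (3 by default) marks a neurite-specific effect — the compound
#' affects neurites at concentrations more than three-fold lower than cell
#' viability. Y/X at or below the cutoff is not neurite-specific
#' ("cytotoxic"). Censoring is handled explicitly: Y censored with X
#' finite is neurite-specific (viability untouched up to the highest
#' tested concentration); both censored is "no effect".
#'
#' @param x BMC result for the neurite-area endpoint (from [bmc()]).
#' @param y BMC result for the viability endpoint.
#' @param ratio_cutoff Classification cutoff on Y/X; default 3 (strict
#'   inequality).
#' @return One-row tibble: `compound`, `bmc25_neurite`, `neurite_censored`,
#'   `bmc25_viability`, `viability_censored`, `ratio`, `label` (one of
#'   `"neurite_specific"`, `"not_neurite_specific"`, `"no_effect"`).
#' @export
classify_specificity <- function(x, y, ratio_cutoff = 3) {
  x <- tibble::as_tibble(x); y <- tibble::as_tibble(y)
  if (!identical(x$endpoint, "neurite_area") ||
      !identical(y$endpoint, "viability")) {
    stop("Endpoints swapped or unlabeled: `x` must be the neurite_area ",
         "BMC and `y` the viability BMC.", call. = FALSE)
  }
  ratio <- if (!x$censored && !y$censored) y$bmc / x$bmc else NA_real_
  label <- if (x$censored && y$censored) {
    "no_effect"
  } else if (y$censored && !x$censored) {
    "neurite_specific"
  } else if (x$censored && !y$censored) {
    "not_neurite_specific"
  } else if (ratio > ratio_cutoff) {
    "neurite_specific"
  } else {
    "not_neurite_specific"
  }
  tibble::tibble(
    compound = x$compound,
    bmc25_neurite = x$bmc, neurite_censored = x$censored,
    bmc25_viability = y$bmc, viability_censored = y$censored,
    ratio = ratio, label = label
  )
}

#' Lowest effective concentrations against the assay thresholds
#'
#' Locates, on the tested concentration series, the lowest concentration
#' whose fitted viability falls below the 90% cytotoxicity threshold and
#' the lowest whose fitted neurite area falls below the 75% neurite-effect
#' threshold (`NA` when no tested concentration qualifies).
#'
#' @param fits Named list with `"dr_fit"` elements `neurite_area` and
#'   `viability`.
#' @param concentrations Tested concentration series (nM); defaults to the
#'   union of fitted nonzero concentrations.
#' @param viability_threshold,neurite_threshold Horizontal thresholds (% of
#'   control); defaults 90 and 75.
#' @return One-row tibble: `lowest_cytotoxic_conc`,
#'   `lowest_neurite_effect_conc` (nM or `NA`).
#' @export
effect_thresholds <- function(fits, concentrations = NULL,
                              viability_threshold = 90,
                              neurite_threshold = 75) {
  stopifnot(all(c("neurite_area", "viability") %in% names(fits)))
  if (is.null(concentrations)) {
    concentrations <- sort(unique(c(
      fits$neurite_area$conc_means$concentration_nM,
      fits$viability$conc_means$concentration_nM
    )))
    concentrations <- concentrations[concentrations > 0]
  }
  if (!length(concentrations)) {
    stop("Empty concentration series.", call. = FALSE)
  }
  concentrations <- sort(concentrations)
  viab <- predict(fits$viability, concentrations)
  neur <- predict(fits$neurite_area, concentrations)
  first_below <- function(values, thr) {
    i <- which(values < thr)
    if (length(i)) concentrations[min(i)] else NA_real_
  }
  tibble::tibble(
    compound = fits$neurite_area$compound,
    lowest_cytotoxic_conc = first_below(viab, viability_threshold),
    lowest_neurite_effect_conc = first_below(neur, neurite_threshold)
  )
}
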