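#' Response kernels for simulated calcium transients
#'
#' A response kernel describes the deterministic shape of a cell's calcium
#' signal after stimulus application, evaluated on post-stimulus time
#' `t = time - application_time` (seconds) and normalised to a unit peak so
#' that an amplitude parameter directly sets the expected peak delta-F of a
#' responding cell.
#'
#' Available kinds:
#' * `"transient_decaying"` — difference of exponentials
#'   \eqn{(1 - e^{-t/\tau_r})\, e^{-t/\tau_d}}, the shape of a
#'   self-inactivating P2X3 transient: the signal rises and then decays
#'   despite continued agonist presence.
#' * `"slow_decaying"` — same form with a long decay constant, as for a
#'   capsaicin/TRPV1 response.
#' * `"sustained_plateau"` — saturating rise \eqn{1 - e^{-t/\tau_r}}, the
#'   sustained depolarisation response to high-potassium (KCl).
#' * `"null"` — identically zero; used for the negative-control (HBSS)
#'   stimulus.
#'
#' @param kind Kernel identifier, one of `"transient_decaying"`,
#'   `"sustained_plateau"`, `"slow_decaying"`, `"null"`.
#' @param t Numeric vector of times since stimulus application (s). Values
#'   `< 0` evaluate to 0.
#' @param rise_time_constant Rise time constant \eqn{\tau_r} (s), `> 0`.
#' @param decay_time_constant Decay time constant \eqn{\tau_d} (s), `> 0`;
#'   ignored for `"sustained_plateau"` and `"null"`.
#'
#' @return Numeric vector of kernel values in `[0, 1]`, same length as `t`.
#' @examples
#' t <- seq(0, 35, by = 0.5)
#' k <- response_kernel("transient_decaying", t,
#'                      rise_time_constant = 1, decay_time_constant = 4)
#' max(k) # 1 (unit peak)
#' @export
response_kernel <- function(kind, t,
                            rise_time_constant = 1,
                            decay_time_constant = 4) {
  kind <- match.arg(kind, c("transient_decaying", "sustained_plateau",
                            "slow_decaying", "null"))
  if (kind == "null") {
    return(rep(0, length(t)))
  }
  stopifnot(is.finite(rise_time_constant), rise_time_constant > 0)
  tr <- rise_time_constant
  tp <- pmax(t, 0)
  on <- as.numeric(t >= 0)
  if (kind == "sustained_plateau") {
    return(on * (1 - exp(-tp / tr)))
  }
  stopifnot(is.finite(decay_time_constant), decay_time_constant > 0)
  td <- decay_time_constant
  raw <- (1 - exp(-tp / tr)) * exp(-tp / td)
  # analytic peak of the difference of exponentials, at t* = tr*log(1 + td/tr)
  tstar <- tr * log(1 + td / tr)
  peak <- (1 - exp(-tstar / tr)) * exp(-tstar / td)
  on * raw / peak
}

#' Stimulus specification
#'
#' Describes one stimulus application within a 45-s recording: its label,
#' when it is applied, which response kernel it evokes and the across-cell
#' distribution of peak amplitudes.
#'
#' @param name Stimulus label; one of `"negative_control"`, `"p2x3_agonist"`,
#'   `"trpv1_agonist"`, `"kcl"` or any custom label.
#' @param application_time Time of application (s from recording start),
#'   `> 0` and less than the recording duration. Default 10 s (stimulus after
#'   the baseline recording).
#' @param kernel Response-kernel kind (see [response_kernel()]). The
#'   negative control always uses the `"null"` kernel.
#' @param amplitude_mean Mean peak amplitude across responding cells
#'   (fluorescence a.u., `>= 0`).
#' @param amplitude_cv Coefficient of variation of the per-cell amplitude
#'   (`>= 0`).
#' @param rise_time_constant,decay_time_constant Kernel time constants (s).
#'
#' @return A list of class `"stimulus_spec"`.
#' @examples
#' stimulus_spec("p2x3_agonist", amplitude_mean = 60)
#' @export
stimulus_spec <- function(name,
                          application_time = 10,
                          kernel = NULL,
                          amplitude_mean = 60,
                          amplitude_cv = 0.2,
                          rise_time_constant = NULL,
                          decay_time_constant = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(application_time) || application_time <= 0) {
    stop("`application_time` must be a positive, finite number of seconds.",
         call. = FALSE)
  }
  if (!is.finite(amplitude_mean) || amplitude_mean < 0) {
    stop("`amplitude_mean` must be finite and >= 0.", call. = FALSE)
  }
  if (!is.finite(amplitude_cv) || amplitude_cv < 0) {
    stop("`amplitude_cv` must be finite and >= 0.", call. = FALSE)
  }
  defaults <- list(
    negative_control = list(kernel = "null", rise = 1, decay = 4),
    p2x3_agonist     = list(kernel = "transient_decaying", rise = 0.8, decay = 3),
    trpv1_agonist    = list(kernel = "slow_decaying", rise = 1.5, decay = 15),
    kcl              = list(kernel = "sustained_plateau", rise = 1.5, decay = Inf)
  )
  d <- defaults[[name]]
  if (is.null(kernel)) {
    kernel <- if (is.null(d)) "transient_decaying" else d$kernel
  }
  kernel <- match.arg(kernel, c("transient_decaying", "sustained_plateau",
                                "slow_decaying", "null"))
  if (name == "negative_control") kernel <- "null"
  if (is.null(rise_time_constant)) {
    rise_time_constant <- if (is.null(d)) 1 else d$rise
  }
  if (is.null(decay_time_constant)) {
    decay_time_constant <- if (is.null(d) || !is.finite(d$decay)) 4 else d$decay
  }
  structure(
    list(name = name,
         application_time = application_time,
         kernel = kernel,
         amplitude_mean = amplitude_mean,
         amplitude_cv = amplitude_cv,
         rise_time_constant = rise_time_constant,
         decay_time_constant = decay_time_constant),
    class = "stimulus_spec"
  )
}

#' Default four-stimulus schedule
#'
#' The standard per-well schedule: negative control (HBSS), P2X3 agonist
#' (alpha,beta-methylene ATP), TRPV1 agonist (capsaicin), and KCl
#' depolarisation, each applied after a 10-s baseline in its own 45-s
#' recording.
#'
#' @param application_time Stimulus application time (s), default 10.
#' @return A named list of [stimulus_spec()] objects.
#' @export
default_schedule <- function(application_time = 10) {
  list(
    negative_control = stimulus_spec("negative_control", application_time,
                                     amplitude_mean = 0),
    p2x3_agonist = stimulus_spec("p2x3_agonist", application_time,
                                 amplitude_mean = 60),
    trpv1_agonist = stimulus_spec("trpv1_agonist", application_time,
                                  amplitude_mean = 50),
    kcl = stimulus_spec("kcl", application_time, amplitude_mean = 80)
  )
}
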