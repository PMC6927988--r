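# Passive and subthreshold measurements: resting potential, input
# resistance, sag ratio and the prominent-H-current rule.

# mean voltage over [t0, t1) ms
window_mean <- function(sweep, t0, t1) {
  t <- sweep_times(length(sweep$voltage), sweep$sampling_rate)
  mean(sweep$voltage[t >= t0 & t < t1])
}

#' Resting membrane potential
#'
#' The membrane potential with no injected current: the mean voltage over a
#' baseline window immediately preceding the step, averaged across sweeps
#' (every sweep carries zero command current before its step).  A baseline
#' contaminated by a spike (voltage above \code{spike_guard} mV) is excluded;
#' if no clean zero-current epoch remains the result is \code{NA} with a
#' \code{reason} attribute.
#'
#' @param recording An \code{icp_recording}.
#' @param baseline_ms Baseline window length, ms, ending at step onset.
#' @param spike_guard Voltage criterion (mV) above which a baseline counts as
#'   spike-contaminated.
#' @return RMP in mV with attribute \code{window} (ms), or \code{NA} with
#'   attribute \code{reason}.
#' @export
resting_potential <- function(recording, baseline_ms = 50, spike_guard = -20) {
  stopifnot(inherits(recording, "icp_recording"))
  vals <- vapply(recording$sweeps, function(sw) {
    t0 <- max(0, sw$step_onset - baseline_ms)
    if (sw$step_onset <= 0) return(NA_real_)  # no pre-step zero-current epoch
    t <- sweep_times(length(sw$voltage), sw$sampling_rate)
    sel <- t >= t0 & t < sw$step_onset
    v <- sw$voltage[sel]
    if (!length(v) || any(v > spike_guard)) return(NA_real_)
    mean(v)
  }, numeric(1))
  if (all(is.na(vals)))
    return(structure(NA_real_, reason = "no clean zero-current baseline epoch"))
  structure(mean(vals, na.rm = TRUE),
            window = c(-baseline_ms, 0))
}

#' Input resistance from hyperpolarizing steps
#'
#' Default estimator: steady-state voltage deflection divided by injected
#' current on the \code{step_pa} sweep (Ohm's law at -100 pA), with the
#' steady state taken as the mean over the final \code{steady_fraction} of
#' the step.  The alternative \code{method = "fit"} regresses steady-state
#' deflection on amplitude over all hyperpolarizing sweeps.
#'
#' @param recording An \code{icp_recording}.
#' @param method \code{"step"} (single-step, default) or \code{"fit"}
#'   (slope of the deflection-current line over hyperpolarizing sweeps).
#' @param step_pa Amplitude of the sweep used by \code{method = "step"}.
#' @param baseline_ms Pre-step baseline window, ms.
#' @param steady_fraction Final fraction of the step averaged as steady state.
#' @return Input resistance in MOhm, or \code{NA} with a \code{reason}
#'   attribute when no hyperpolarizing sweep exists.
#' @export
input_resistance <- function(recording, method = c("step", "fit"),
                             step_pa = -100, baseline_ms = 50,
                             steady_fraction = 0.2) {
  stopifnot(inherits(recording, "icp_recording"))
  method <- match.arg(method)
  hyper <- Filter(function(sw) sw$step_amplitude < 0, recording$sweeps)
  if (length(hyper) == 0)
    return(structure(NA_real_, reason = "no hyperpolarizing sweep"))
  deflection <- function(sw) {
    base <- window_mean(sw, max(0, sw$step_onset - baseline_ms), sw$step_onset)
    t1 <- sw$step_offset
    t0 <- t1 - steady_fraction * (sw$step_offset - sw$step_onset)
    window_mean(sw, t0, t1) - base
  }
  if (method == "step") {
    sw <- sweep_with_amplitude(recording, step_pa)
    if (is.null(sw)) sw <- hyper[[1]]
    # mV / pA = GOhm -> x1000 MOhm
    return(1000 * deflection(sw) / sw$step_amplitude)
  }
  amps <- vapply(hyper, `[[`, numeric(1), "step_amplitude")
  dvs <- vapply(hyper, deflection, numeric(1))
  if (length(hyper) == 1) return(1000 * dvs / amps)
  1000 * unname(stats::coef(stats::lm(dvs ~ amps))[2])
}

#' Sag ratio of a hyperpolarizing step
#'
#' The ratio of the difference between the peak and the steady-state
#' hyperpolarization to the peak amplitude: \code{(|peak| - |steady|) /
#' |peak|}, with both deflections measured from the pre-step baseline.  The
#' peak is the most hyperpolarized point during the step; the steady state is
#' the mean over the final \code{steady_fraction} of the step.  A pure RC
#' response (monotone approach to steady state) gives 0.
#'
#' @param sweep An \code{icp_sweep} with a hyperpolarizing step.
#' @param baseline_ms,steady_fraction Measurement windows as in
#'   \code{\link{input_resistance}}.
#' @return Sag ratio (dimensionless fraction in [0, 1)).
#' @export
sag_ratio <- function(sweep, baseline_ms = 50, steady_fraction = 0.2) {
  stopifnot(inherits(sweep, "icp_sweep"))
  if (sweep$step_amplitude >= 0)
    stop("sag_ratio: requires a hyperpolarizing step (got ",
         sweep$step_amplitude, " pA)")
  base <- window_mean(sweep, max(0, sweep$step_onset - baseline_ms),
                      sweep$step_onset)
  t <- sweep_times(length(sweep$voltage), sweep$sampling_rate)
  in_step <- t >= sweep$step_onset & t < sweep$step_offset
  peak <- min(sweep$voltage[in_step]) - base
  t0 <- sweep$step_offset - steady_fraction * (sweep$step_offset - sweep$step_onset)
  steady <- window_mean(sweep, t0, sweep$step_offset) - base
  if (peak >= 0) return(structure(NA_real_, reason = "no hyperpolarizing deflection"))
  sag <- (abs(peak) - abs(steady)) / abs(peak)
  max(sag, 0)
}

#' Prominent H-current classification
#'
#' A cell is classified as having a prominent H-current when its sag ratio
#' strictly exceeds 5\%.
#'
#' @param sag Sag ratio (fraction).
#' @param threshold Classification threshold (default 0.05, strict).
#' @return Logical; \code{NA} when the sag is undefined.
#' @export
classify_h_current <- function(sag, threshold = 0.05) {
  ifelse(is.na(sag), NA, sag > threshold)
}

#' All passive features of a recording
#'
#' Convenience wrapper returning RMP, input resistance, sag ratio and the
#' prominent-H flag as a one-row data frame.
#'
#' @inheritParams input_resistance
#' @return A one-row \code{data.frame} with columns \code{rmp},
#'   \code{input_resistance}, \code{sag_ratio}, \code{prominent_h}.
#' @export
passive_features <- function(recording, baseline_ms = 50,
                             steady_fraction = 0.2, step_pa = -100) {
  rmp <- resting_potential(recording, baseline_ms = baseline_ms)
  rin <- input_resistance(recording, step_pa = step_pa,
                          baseline_ms = baseline_ms,
                          steady_fraction = steady_fraction)
  sw <- sweep_with_amplitude(recording, step_pa)
  if (is.null(sw)) {
    hyper <- Filter(function(s) s$step_amplitude < 0, recording$sweeps)
    sw <- if (length(hyper)) hyper[[1]] else NULL
  }
  sag <- if (is.null(sw)) NA_real_ else
    sag_ratio(sw, baseline_ms = baseline_ms, steady_fraction = steady_fraction)
  data.frame(rmp = as.numeric(rmp),
             input_resistance = as.numeric(rin),
             sag_ratio = as.numeric(sag),
             prominent_h = classify_h_current(as.numeric(sag)))
}
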