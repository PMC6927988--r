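#' Construct a single current-clamp sweep
#'
#' A sweep is one trial: a voltage trace (mV), the command-current trace (pA),
#' the sampling rate and the square-step metadata.  Sample 1 lies at t = 0 ms;
#' the step occupies the half-open window [onset, offset) in ms.
#'
#' @param voltage Numeric vector, membrane potential in mV.
#' @param sampling_rate Sampling rate in Hz.
#' @param step_amplitude Step amplitude in pA.
#' @param step_onset,step_offset Step window in ms.
#' @param command_current Optional explicit command trace (pA); reconstructed
#'   from the step metadata when omitted.
#' @return An object of class \code{icp_sweep}.
#' @export
new_sweep <- function(voltage, sampling_rate, step_amplitude,
                      step_onset, step_offset, command_current = NULL) {
  n <- length(voltage)
  if (n < 2) stop("sweep: voltage series must have at least 2 samples")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sweep: sampling_rate must be positive")
  dur <- 1000 * n / sampling_rate
  if (step_onset < 0 || step_offset > dur + 1e-9 || step_offset <= step_onset)
    stop("sweep: step window [", step_onset, ", ", step_offset,
         ") must lie inside the sweep (0 to ", round(dur, 3), " ms)")
  if (is.null(command_current)) {
    t <- sweep_times(n, sampling_rate)
    command_current <- ifelse(t >= step_onset & t < step_offset,
                              step_amplitude, 0)
  }
  if (length(command_current) != n)
    stop("sweep: voltage and command-current series differ in length (",
         n, " vs ", length(command_current), ")")
  structure(list(voltage = as.numeric(voltage),
                 command_current = as.numeric(command_current),
                 sampling_rate = sampling_rate,
                 step_amplitude = step_amplitude,
                 step_onset = step_onset,
                 step_offset = step_offset),
            class = "icp_sweep")
}

# time base in ms, sample 1 at t = 0
sweep_times <- function(n, sampling_rate) (seq_len(n) - 1) * 1000 / sampling_rate

#' @export
print.icp_sweep <- function(x, ...) {
  cat(sprintf("<icp_sweep> %d samples @ %g kHz, step %+g pA [%g, %g) ms\n",
              length(x$voltage), x$sampling_rate / 1000, x$step_amplitude,
              x$step_onset, x$step_offset))
  invisible(x)
}

#' Construct a cell recording (ordered sweep set)
#'
#' @param sweeps List of \code{icp_sweep} objects sharing one sampling rate.
#' @param cell_id Character identifier.
#' @param group Free-text group label (e.g. \code{"control"}).
#' @param junction_potential_corrected Whether traces were corrected for the
#'   liquid junction potential.  Defaults to FALSE with the junction value
#'   carried as metadata, the common practice for K-gluconate internals.
#' @param junction_potential_mv Junction potential, mV.
#' @param temperature Bath temperature, degrees C (optional).
#' @return An object of class \code{icp_recording}.
#' @export
new_recording <- function(sweeps, cell_id = "cell", group = NA_character_,
                          junction_potential_corrected = FALSE,
                          junction_potential_mv = 15.2,
                          temperature = NULL) {
  if (length(sweeps) < 1) stop("recording: at least one sweep is required")
  ok <- vapply(sweeps, inherits, logical(1), what = "icp_sweep")
  if (!all(ok)) stop("recording: all elements must be icp_sweep objects")
  rates <- vapply(sweeps, `[[`, numeric(1), "sampling_rate")
  if (length(unique(rates)) != 1)
    stop("recording: all sweeps must share one sampling rate")
  structure(list(cell_id = cell_id,
                 group = group,
                 sweeps = sweeps,
                 sampling_rate = rates[1],
                 junction_potential_corrected = junction_potential_corrected,
                 junction_potential_mv = junction_potential_mv,
                 temperature = temperature),
            class = "icp_recording")
}

#' @export
print.icp_recording <- function(x, ...) {
  amps <- vapply(x$sweeps, `[[`, numeric(1), "step_amplitude")
  cat(sprintf("<icp_recording> '%s'%s: %d sweeps @ %g kHz, steps %g .. %g pA\n",
              x$cell_id,
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              length(x$sweeps), x$sampling_rate / 1000, min(amps), max(amps)))
  invisible(x)
}

# fetch the sweep with a given step amplitude (first match), or NULL
sweep_with_amplitude <- function(recording, amplitude, tol = 1e-6) {
  amps <- vapply(recording$sweeps, `[[`, numeric(1), "step_amplitude")
  i <- which(abs(amps - amplitude) < tol)
  if (length(i) == 0) return(NULL)
  recording$sweeps[[i[1]]]
}
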