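#' Simulate one cell under a current-step protocol
#'
#' Integrates the two-compartment conductance-based model (see
#' \code{\link{neuron_params}}) for every step amplitude in the protocol and
#' returns the somatic voltage traces as an \code{\link{new_recording}}
#' together with the generating ground truth.  Integration is exponential
#' Euler at the sampling interval subdivided into \code{substeps} internal
#' steps (default keeps the internal step at or below 0.01 ms at 50 kHz);
#' every sweep is checked for numerical stability and a non-finite voltage
#' aborts with the offending parameter set.  With \code{noise_sd = 0} the
#' output is fully deterministic; otherwise membrane noise is
#' Ornstein-Uhlenbeck current noise driven by R's RNG, so a fixed
#' \code{seed} reproduces traces bit for bit.
#'
#' Ground-truth spike times are the upward crossings of 0 mV by the somatic
#' voltage during integration (internal-step resolution).
#'
#' @param params A \code{\link{neuron_params}} object.
#' @param protocol A \code{\link{protocol_spec}} object.
#' @param seed Integer seed for the membrane-noise RNG.
#' @param cell_id,group Metadata attached to the returned recording.
#' @param substeps Internal integration steps per sample (default chosen from
#'   the sampling rate so the internal step is at most 0.01 ms).
#' @return A list with elements \code{recording} (an \code{icp_recording})
#'   and \code{truth} (parameters, seed, per-sweep spike times in ms, the
#'   model resting potential and the leak-derived input resistance in MOhm).
#' @examples
#' sim <- simulate_cell(neuron_params(), protocol_spec(step_amplitudes = c(-100, 200)))
#' sim$recording
#' @export
simulate_cell <- function(params, protocol, seed = 1L,
                          cell_id = "cell", group = NA_character_,
                          substeps = NULL) {
  stopifnot(inherits(params, "neuron_params"), inherits(protocol, "protocol_spec"))
  validate_neuron_params(params)
  if (is.null(substeps)) {
    sample_dt <- 1000 / protocol$sampling_rate
    substeps <- max(1L, as.integer(ceiling(sample_dt / 0.01)))
  }
  n_samples <- as.integer(round(protocol$total_duration *
                                protocol$sampling_rate / 1000))
  set.seed(as.integer(seed))
  out <- .sim_sweeps_cpp(unclass(params), protocol$step_amplitudes,
                         protocol$step_onset, protocol$step_duration,
                         protocol$sampling_rate, n_samples,
                         substeps, 0)
  offset <- protocol$step_onset + protocol$step_duration
  sweeps <- lapply(seq_along(protocol$step_amplitudes), function(i) {
    new_sweep(out$voltage[, i], protocol$sampling_rate,
              protocol$step_amplitudes[i], protocol$step_onset, offset)
  })
  recording <- new_recording(sweeps, cell_id = cell_id, group = group)
  truth <- list(params = params,
                seed = seed,
                spike_times = out$spike_times,
                rmp = out$resting_voltage,
                input_resistance = 1000 / params$leak_conductance)
  list(recording = recording, truth = truth)
}

#' Simulate a two-group cohort
#'
#' Draws \code{n_per_group} cells per group by jittering each group's
#' template parameters and simulating every cell under the shared protocol.
#' Jitter is multiplicative lognormal-like on conductances and capacitances
#' (template times \code{1 + variability * z}) and additive on the leak
#' reversal (\code{variability * 10} mV sd), the natural scales for
#' cell-to-cell variability in a patch-clamp cohort.  Conductances that jitter
#' below zero are clipped at zero and reported via a warning.  All draws come
#' from R's RNG seeded once, so a fixed \code{seed} reproduces the cohort.
#'
#' @param control_params,shifted_params \code{\link{neuron_params}} templates
#'   for the two groups.
#' @param n_per_group Cells per group (>= 1).
#' @param inter_cell_variability Fractional sd of the multiplicative jitter.
#' @param protocol Shared \code{\link{protocol_spec}}.
#' @param seed Integer seed.
#' @param labels Character vector of two group labels.
#' @return A list of two lists of \code{simulate_cell} results, named by
#'   group label.
#' @export
simulate_cohort <- function(control_params, shifted_params,
                            n_per_group = 25,
                            inter_cell_variability = 0.1,
                            protocol = protocol_spec(),
                            seed = 1L,
                            labels = c("control", "shifted")) {
  stopifnot(n_per_group >= 1, length(labels) == 2)
  set.seed(as.integer(seed))
  jitter_names <- c("leak_conductance", "capacitance_soma", "capacitance_ais",
                    "axial_conductance", "gNa_ais", "gNa_soma", "gK_dr",
                    "gSK", "gH")
  clipped <- 0L
  draw_cell <- function(template) {
    p <- unclass(template)
    for (nm in jitter_names) {
      val <- p[[nm]] * (1 + inter_cell_variability * rnorm(1))
      if (val < 0) { val <- 0; clipped <<- clipped + 1L }
      p[[nm]] <- val
    }
    p$leak_reversal <- p$leak_reversal + inter_cell_variability * 10 * rnorm(1)
    # capacitances must stay positive
    for (nm in c("capacitance_soma", "capacitance_ais"))
      p[[nm]] <- max(p[[nm]], 0.05 * unclass(template)[[nm]])
    structure(p, class = "neuron_params")
  }
  templates <- list(control_params, shifted_params)
  cohort <- lapply(1:2, function(g) {
    cell_params <- replicate(n_per_group, draw_cell(templates[[g]]),
                             simplify = FALSE)
    cell_seeds <- sample.int(.Machine$integer.max - 1L, n_per_group)
    lapply(seq_len(n_per_group), function(i) {
      simulate_cell(cell_params[[i]], protocol, seed = cell_seeds[i],
                    cell_id = sprintf("%s_%02d", labels[g], i),
                    group = labels[g])
    })
  })
  names(cohort) <- labels
  if (clipped > 0)
    warning(clipped, " jittered conductance(s) fell below zero and were clipped")
  cohort
}
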