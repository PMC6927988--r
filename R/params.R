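#' Biophysical parameters for the two-compartment model neuron
#'
#' Bundles the conductances, capacitances and kinetic time constants of the
#' synthetic-neuron model.  The model has a somatic and an axon-initial-segment
#' (AIS) compartment coupled by an axial conductance.  Sodium channels in the
#' AIS activate at a more hyperpolarized midpoint than somatic ones
#' (\code{na_halfact_shift} < 0), mimicking the low-threshold Nav1.6 /
#' high-threshold Nav1.2 segregation that gives the somatic action-potential
#' upstroke its two kinetic components.  The medium afterhyperpolarization is
#' produced by an SK-like conductance gated by a phenomenological calcium pool
#' (incremented at each spike, exponential decay), and the sag by an HCN-like
#' current with slow first-order activation.
#'
#' Defaults describe a regular-spiking layer-5 pyramidal cell: input
#' resistance near 130 MOhm, resting potential near -66 mV, rheobase of order
#' 100-250 pA, spike threshold near -35 mV and a medium AHP of 10-20 mV.
#'
#' @param leak_conductance Leak conductance, nS.  The passive input
#'   resistance is exactly \code{1000 / leak_conductance} MOhm.
#' @param leak_reversal Leak reversal potential, mV; the resting potential in
#'   the passive limit.
#' @param capacitance_soma,capacitance_ais Compartment capacitances, pF.
#' @param axial_conductance Soma-AIS coupling conductance, nS.
#' @param gNa_ais,gNa_soma Maximal sodium conductances, nS.
#' @param na_halfact_shift Offset (mV, negative) of the AIS sodium activation
#'   midpoint relative to the somatic one.
#' @param gK_dr Delayed-rectifier potassium conductance, nS.
#' @param gSK SK-type (calcium-activated) potassium conductance, nS.
#' @param ca_increment Calcium-pool increment per somatic spike
#'   (dimensionless pool units).
#' @param ca_tau Calcium-pool decay time constant, ms.
#' @param gH HCN (h-current) conductance, nS.
#' @param h_tau HCN activation time constant, ms.
#' @param noise_sd Standard deviation (mV) of Ornstein-Uhlenbeck membrane
#'   noise; 0 (default) gives fully deterministic traces.
#' @param kinetics Optional named list overriding gating kinetics (midpoints
#'   \code{vm_na}, \code{vh_na}, \code{vn_k}, \code{vr_h}; slopes
#'   \code{km_na}, \code{kh_na}, \code{kn_k}, \code{kr_h}; time constants
#'   \code{tau_m}, \code{tau_h}, \code{tau_n}; reversals \code{e_na},
#'   \code{e_k}, \code{e_h}).  \code{NULL} keeps the documented defaults.
#' @return An object of class \code{neuron_params} (a named list).
#' @examples
#' p <- neuron_params()
#' p$gSK <- 20
#' @export
neuron_params <- function(leak_conductance = 7.7,
                          leak_reversal = -66,
                          capacitance_soma = 150,
                          capacitance_ais = 5,
                          axial_conductance = 150,
                          gNa_ais = 300,
                          gNa_soma = 2200,
                          na_halfact_shift = -8,
                          gK_dr = 1200,
                          gSK = 25,
                          ca_increment = 0.12,
                          ca_tau = 120,
                          gH = 1.6,
                          h_tau = 50,
                          noise_sd = 0,
                          kinetics = NULL) {
  p <- list(leak_conductance = leak_conductance,
            leak_reversal = leak_reversal,
            capacitance_soma = capacitance_soma,
            capacitance_ais = capacitance_ais,
            axial_conductance = axial_conductance,
            gNa_ais = gNa_ais,
            gNa_soma = gNa_soma,
            na_halfact_shift = na_halfact_shift,
            gK_dr = gK_dr,
            gSK = gSK,
            ca_increment = ca_increment,
            ca_tau = ca_tau,
            gH = gH,
            h_tau = h_tau,
            noise_sd = noise_sd,
            kinetics = kinetics)
  validate_neuron_params(p)
  structure(p, class = "neuron_params")
}

validate_neuron_params <- function(p) {
  conds <- c("leak_conductance", "axial_conductance", "gNa_ais", "gNa_soma",
             "gK_dr", "gSK", "gH")
  for (nm in conds)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("neuron_params: '", nm, "' must be a finite non-negative conductance")
  for (nm in c("capacitance_soma", "capacitance_ais"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("neuron_params: '", nm, "' must be a positive capacitance")
  if (!is.finite(p$na_halfact_shift) || p$na_halfact_shift >= 0)
    stop("neuron_params: 'na_halfact_shift' must be negative ",
         "(AIS sodium activates below the somatic midpoint)")
  for (nm in c("ca_tau", "h_tau"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("neuron_params: '", nm, "' must be a positive time constant")
  if (!is.finite(p$noise_sd) || p$noise_sd < 0)
    stop("neuron_params: 'noise_sd' must be non-negative")
  invisible(p)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>\n")
  cat(sprintf("  leak %.2f nS -> %.1f mV | C_soma %.0f pF, C_ais %.1f pF, g_ax %.1f nS\n",
              x$leak_conductance, x$leak_reversal, x$capacitance_soma,
              x$capacitance_ais, x$axial_conductance))
  cat(sprintf("  gNa ais/soma %.0f/%.0f nS (shift %.1f mV) | gK %.0f | gSK %.1f (tau %.0f ms) | gH %.2f (tau %.0f ms)\n",
              x$gNa_ais, x$gNa_soma, x$na_halfact_shift, x$gK_dr, x$gSK,
              x$ca_tau, x$gH, x$h_tau))
  cat(sprintf("  noise_sd %.2f mV\n", x$noise_sd))
  invisible(x)
}

#' Current-step stimulation protocol
#'
#' Describes a family of square current steps delivered from a common
#' baseline.  The default mirrors a standard intrinsic-excitability protocol:
#' 50 kHz sampling, a single -100 pA hyperpolarizing step and a depolarizing
#' ladder from 50 to 1,500 pA in 50 pA increments, each step lasting 500 ms
#' with 100 ms of baseline before and after.
#'
#' @param step_amplitudes Numeric vector of step amplitudes, pA.
#' @param step_onset Step onset, ms from sweep start.
#' @param step_duration Step duration, ms.
#' @param post_baseline Baseline after step offset, ms.
#' @param sampling_rate Sampling rate, Hz.
#' @return An object of class \code{protocol_spec}.
#' @export
protocol_spec <- function(step_amplitudes = c(-100, seq(50, 1500, by = 50)),
                          step_onset = 100,
                          step_duration = 500,
                          post_baseline = 100,
                          sampling_rate = 50000) {
  if (length(step_amplitudes) == 0)
    stop("protocol_spec: at least one step amplitude is required")
  if (any(!is.finite(step_amplitudes)))
    stop("protocol_spec: step amplitudes must be finite")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("protocol_spec: sampling_rate must be positive")
  if (step_onset < 0 || step_duration <= 0 || post_baseline < 0)
    stop("protocol_spec: onset/duration/post_baseline must be non-negative (duration positive)")
  total <- step_onset + step_duration + post_baseline
  structure(list(step_amplitudes = as.numeric(step_amplitudes),
                 step_onset = step_onset,
                 step_duration = step_duration,
                 post_baseline = post_baseline,
                 sampling_rate = sampling_rate,
                 total_duration = total),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol_spec> %d steps [%g .. %g pA], onset %g ms, duration %g ms, %g kHz, sweep %g ms\n",
              length(x$step_amplitudes), min(x$step_amplitudes),
              max(x$step_amplitudes), x$step_onset, x$step_duration,
              x$sampling_rate / 1000, x$total_duration))
  invisible(x)
}
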