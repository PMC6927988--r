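# Phase-plot construction and decomposition of the AP rising phase into
# axon-initial-segment (AIS) and somatodendritic (SD) components.
#
# At the soma the upstroke of a pyramidal-cell AP has two kinetic
# components: an initial ramp driven by axial current from the spiking AIS,
# then the steeper somatodendritic depolarization carried by perisomatic
# sodium channels.  The transition shows up as a trough of d2V/dt2 in the
# rising phase; the SD contribution is summarized by the ratio a/b, where b
# is the peak upstroke slope and a the maximal slope of the SD component.

#' Phase-plane samples of one spike
#'
#' (V, dV/dt) pairs from the spike threshold to the end of repolarization
#' (first recrossing of the threshold voltage after the peak, capped at
#' \code{window_ms} past the peak).
#'
#' @param sweep An \code{icp_sweep}.
#' @param peak_index Spike peak sample index.
#' @param threshold \code{\link{ap_threshold}} result for this spike.
#' @param window_ms Post-peak cap, ms.
#' @return Data frame with columns \code{time} (ms), \code{v} (mV),
#'   \code{dvdt} (mV/ms).
#' @export
phase_plot <- function(sweep, peak_index, threshold, window_ms = 10) {
  stopifnot(inherits(sweep, "icp_sweep"))
  v <- sweep$voltage
  rate <- sweep$sampling_rate
  dt <- 1000 / rate
  d <- dvdt(v, rate)
  i0 <- max(1L, as.integer(floor(threshold$index)))
  cap <- min(length(v), peak_index + as.integer(round(window_ms / dt)))
  rep_i <- crossing_index(v, threshold$voltage, peak_index, cap, "down")
  i1 <- if (is.na(rep_i)) cap else as.integer(ceiling(rep_i))
  idx <- i0:i1
  data.frame(time = (idx - 1) * dt, v = v[idx], dvdt = d[idx])
}

#' Breakpoint between the AIS and SD components of the upstroke
#'
#' Locates the most negative strict local minimum of d2V/dt2 in the open
#' window between the threshold time and the time of the dV/dt maximum.  A
#' monophasic upstroke (no local minimum in the window) returns \code{NULL};
#' downstream decompositions are then undefined.
#'
#' @param sweep An \code{icp_sweep}.
#' @param peak_index Spike peak sample index.
#' @param threshold \code{\link{ap_threshold}} result for this spike.
#' @param min_prominence Minimum depth (mV/ms^2) of the trough below the
#'   larger of its two flanking local maxima of d2V/dt2; default 0 accepts
#'   any strict local minimum.
#' @return A list: \code{index} (sample), \code{time} (ms), \code{voltage}
#'   (mV), \code{dvdt} (mV/ms at the breakpoint), \code{d2v} (mV/ms^2),
#'   \code{prominence}; or \code{NULL}.
#' @export
find_breakpoint <- function(sweep, peak_index, threshold, min_prominence = 0) {
  stopifnot(inherits(sweep, "icp_sweep"))
  v <- sweep$voltage
  rate <- sweep$sampling_rate
  dt <- 1000 / rate
  d <- dvdt(v, rate)
  d2 <- d2vdt2(v, rate)
  thr_i <- as.integer(ceiling(threshold$index))
  # time of the dV/dt maximum over the upstroke
  up <- thr_i:peak_index
  bmax_i <- up[which.max(d[up])]
  lo <- thr_i + 1L
  hi <- bmax_i - 1L
  if (hi - lo < 1L) return(NULL)
  win <- lo:hi
  inner <- win[-c(1, length(win))]
  if (!length(inner)) return(NULL)
  is_min <- d2[inner] < d2[inner - 1L] & d2[inner] < d2[inner + 1L]
  cand <- inner[is_min]
  if (!length(cand)) return(NULL)
  bp <- cand[which.min(d2[cand])]
  # prominence: rise from the trough to the higher flanking value inside the
  # search window
  left_max <- max(d2[lo:bp])
  right_max <- max(d2[bp:hi])
  prom <- max(left_max, right_max) - d2[bp]
  if (prom < min_prominence) return(NULL)
  list(index = bp, time = (bp - 1) * dt, voltage = v[bp],
       dvdt = d[bp], d2v = d2[bp], prominence = prom)
}

#' SD-component slope ratio (a/b) of one spike
#'
#' b is the peak dV/dt of the upstroke.  Under the default
#' \code{"shoulder"} convention a = b - dV/dt(breakpoint): the SD
#' contribution is the rise of the upstroke slope above the AIS shoulder, so
#' b - a is the AIS component.  The alternative \code{"local_max"}
#' convention takes a as dV/dt at the first local maximum of the phase plot
#' after the breakpoint when one exists (falling back to b).  Every result
#' names the convention used.
#'
#' @param sweep An \code{icp_sweep}.
#' @param peak_index Spike peak sample index.
#' @param threshold \code{\link{ap_threshold}} result for this spike.
#' @param convention \code{"shoulder"} (default) or \code{"local_max"}.
#' @param min_prominence Passed to \code{\link{find_breakpoint}}.
#' @return A list: \code{a}, \code{b}, \code{b_minus_a} (mV/ms),
#'   \code{ratio} (a/b in (0, 1]), \code{breakpoint}, \code{convention}; or
#'   \code{NULL} when the breakpoint is undefined.
#' @export
slope_sd_ratio <- function(sweep, peak_index, threshold,
                           convention = c("shoulder", "local_max"),
                           min_prominence = 0) {
  convention <- match.arg(convention)
  bp <- find_breakpoint(sweep, peak_index, threshold,
                        min_prominence = min_prominence)
  if (is.null(bp)) return(NULL)
  d <- dvdt(sweep$voltage, sweep$sampling_rate)
  thr_i <- as.integer(ceiling(threshold$index))
  up <- thr_i:peak_index
  b <- max(d[up])
  if (convention == "shoulder") {
    a <- b - bp$dvdt
  } else {
    seg <- bp$index:peak_index
    inner <- seg[-c(1, length(seg))]
    loc <- inner[d[inner] > d[inner - 1L] & d[inner] > d[inner + 1L]]
    a <- if (length(loc)) d[loc[1]] else b
  }
  list(a = a, b = b, b_minus_a = b - a, ratio = a / b,
       breakpoint = bp, convention = convention)
}

#' First AP of the n-spike train
#'
#' Selects the sweep evoking the target spike count (default 7, with the
#' preferred-below fallback of \code{\link{find_n_spike_sweep}}) and returns
#' its first spike, the event feeding the SD slope-ratio analysis.
#'
#' @param recording An \code{icp_recording}.
#' @param n Target spike count.
#' @param criterion Detection voltage, mV.
#' @return A list: \code{sweep}, \code{sweep_index}, \code{current},
#'   \code{peak_index}, \code{threshold}, \code{exact}; or \code{NULL}.
#' @export
first_ap_of_train <- function(recording, n = 7, criterion = 0) {
  sel <- find_n_spike_sweep(recording, n = n, criterion = criterion)
  if (is.null(sel)) return(NULL)
  det <- detect_spikes(sel$sweep, criterion = criterion)
  thr <- ap_threshold(sel$sweep, det$peak_index[1])
  if (is.null(thr)) return(NULL)
  list(sweep = sel$sweep, sweep_index = sel$sweep_index,
       current = sel$current, peak_index = det$peak_index[1],
       threshold = thr, exact = sel$exact)
}
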