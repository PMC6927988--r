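# Spike detection and single-AP / spike-train measurements.
#
# Shared derivative estimator: central finite differences on the raw trace
# (the acquisition chain is assumed to have filtered the signal already; no
# additional smoothing by default).  dV/dt is reported in mV/ms, numerically
# equal to V/s.

#' First time derivative of a voltage trace
#'
#' Central differences; one-sided at the ends.  Units mV/ms (= V/s).
#'
#' @param voltage Numeric vector, mV.
#' @param sampling_rate Hz.
#' @return Numeric vector of the same length.
#' @export
dvdt <- function(voltage, sampling_rate) {
  n <- length(voltage)
  dt <- 1000 / sampling_rate
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (voltage[3:n] - voltage[1:(n - 2)]) / (2 * dt)
  d[1] <- (voltage[2] - voltage[1]) / dt
  d[n] <- (voltage[n] - voltage[n - 1]) / dt
  d
}

#' Second time derivative (central differences applied twice)
#'
#' @inheritParams dvdt
#' @return Numeric vector, mV/ms^2.
#' @export
d2vdt2 <- function(voltage, sampling_rate) {
  dvdt(dvdt(voltage, sampling_rate), sampling_rate)
}

#' Detect action potentials in a sweep
#'
#' A spike is an upward crossing of the voltage \code{criterion} followed by
#' a local maximum; the detector is refractory until the voltage falls back
#' below the criterion, so merged depolarizations that never repolarize below
#' it count once.
#'
#' @param sweep An \code{icp_sweep}.
#' @param criterion Detection voltage, mV (default 0).
#' @return A data frame with one row per spike: \code{peak_index} (1-based
#'   sample), \code{peak_time} (ms), \code{peak_voltage} (mV).  Zero rows
#'   when the sweep is subthreshold.
#' @export
detect_spikes <- function(sweep, criterion = 0) {
  stopifnot(inherits(sweep, "icp_sweep"))
  v <- sweep$voltage
  n <- length(v)
  above <- v >= criterion
  up <- which(!above[-n] & above[-1]) + 1L   # first sample at/above criterion
  down <- which(above[-n] & !above[-1])      # last sample above criterion
  peaks <- integer(0)
  for (u in up) {
    d <- down[down >= u]
    end <- if (length(d)) d[1] else n
    seg <- u:end
    peaks <- c(peaks, seg[which.max(v[seg])])
  }
  data.frame(peak_index = peaks,
             peak_time = (peaks - 1) * 1000 / sweep$sampling_rate,
             peak_voltage = v[peaks])
}

#' Action-potential threshold at the dV/dt criterion
#'
#' The voltage at which dV/dt first reaches \code{criterion_vps} V/s on the
#' upstroke.  The search runs backward from the spike peak to the last
#' sub-criterion sample; with \code{interpolate = TRUE} (default) the
#' crossing is located by linear interpolation in dV/dt between the
#' straddling samples and the threshold voltage interpolated accordingly.
#'
#' @param sweep An \code{icp_sweep}.
#' @param peak_index Sample index of the spike peak (from
#'   \code{\link{detect_spikes}}).
#' @param criterion_vps Slope criterion in V/s (= mV/ms); default 20.
#' @param interpolate Interpolate between straddling samples.
#' @param search_back_ms How far before the peak to search, ms.
#' @return A list with \code{voltage} (mV), \code{time} (ms), \code{index}
#'   (fractional sample index), or \code{NULL} when dV/dt never reaches the
#'   criterion before the peak (the event is not a spike).
#' @export
ap_threshold <- function(sweep, peak_index, criterion_vps = 20,
                         interpolate = TRUE, search_back_ms = 10) {
  stopifnot(inherits(sweep, "icp_sweep"))
  rate <- sweep$sampling_rate
  d <- dvdt(sweep$voltage, rate)
  lo <- max(1L, peak_index - as.integer(round(search_back_ms * rate / 1000)))
  # walk back from the peak into the supra-criterion region of the upstroke,
  # then through it to the last sub-criterion sample before it
  i <- peak_index
  while (i > lo && d[i] < criterion_vps) i <- i - 1L
  if (d[i] < criterion_vps) return(NULL)  # dV/dt never reaches the criterion
  while (i > lo && d[i] >= criterion_vps) i <- i - 1L
  if (d[i] >= criterion_vps) return(NULL) # window edge: no sub-criterion region
  j <- i + 1L                             # first sample at/above criterion
  dt <- 1000 / rate
  if (interpolate && d[j] > d[i]) {
    frac <- (criterion_vps - d[i]) / (d[j] - d[i])
    idx <- i + frac
    v <- sweep$voltage[i] + frac * (sweep$voltage[j] - sweep$voltage[i])
  } else {
    idx <- as.numeric(j)
    v <- sweep$voltage[j]
  }
  list(voltage = v, time = (idx - 1) * dt, index = idx)
}

# linearly interpolated voltage at fractional sample index
interp_v <- function(v, idx) {
  i <- floor(idx)
  f <- idx - i
  if (i >= length(v)) return(v[length(v)])
  v[i] * (1 - f) + v[i + 1] * f
}

# first fractional index in [from, to] where v crosses `level` in the given
# direction ("up" or "down"); NA when it never crosses
crossing_index <- function(v, level, from, to, direction) {
  idx <- seq.int(from, to)
  if (direction == "up") {
    hit <- which(v[idx[-length(idx)]] < level & v[idx[-1]] >= level)
  } else {
    hit <- which(v[idx[-length(idx)]] >= level & v[idx[-1]] < level)
  }
  if (!length(hit)) return(NA_real_)
  i <- idx[hit[1]]
  f <- (level - v[i]) / (v[i + 1] - v[i])
  i + f
}

#' Single-AP waveform shape
#'
#' Peak amplitude (peak minus threshold), half-width (duration at half
#' amplitude above threshold, crossings linearly interpolated) and the dV/dt
#' extrema over the spike window (threshold to repolarization below
#' threshold, capped at \code{window_ms} past the peak).
#'
#' @param sweep An \code{icp_sweep}.
#' @param peak_index Spike peak sample index.
#' @param threshold Result of \code{\link{ap_threshold}} for this spike.
#' @param window_ms Cap on the post-peak window, ms.
#' @return A list: \code{peak_amplitude} (mV), \code{half_width} (ms; NA when
#'   the repolarization never recrosses half amplitude), \code{dvdt_max},
#'   \code{dvdt_min} (mV/ms).
#' @export
ap_shape <- function(sweep, peak_index, threshold, window_ms = 10) {
  stopifnot(inherits(sweep, "icp_sweep"))
  v <- sweep$voltage
  rate <- sweep$sampling_rate
  dt <- 1000 / rate
  amp <- v[peak_index] - threshold$voltage
  half <- threshold$voltage + amp / 2
  thr_i <- max(1L, as.integer(floor(threshold$index)))
  end_i <- min(length(v), peak_index + as.integer(round(window_ms / dt)))
  # half-amplitude crossings around the peak
  up <- crossing_index(v, half, thr_i, peak_index, "up")
  dn <- crossing_index(v, half, peak_index, end_i, "down")
  hw <- if (is.na(up) || is.na(dn)) NA_real_ else (dn - up) * dt
  # spike window for slope extrema: threshold to repolarization below threshold
  rep_i <- crossing_index(v, threshold$voltage, peak_index, end_i, "down")
  win_end <- if (is.na(rep_i)) end_i else as.integer(ceiling(rep_i))
  d <- dvdt(v, rate)
  win <- thr_i:win_end
  list(peak_amplitude = amp,
       half_width = hw,
       dvdt_max = max(d[win]),
       dvdt_min = min(d[win]))
}

#' Medium afterhyperpolarization of one spike
#'
#' mAHP = threshold voltage minus the voltage trough in the window from the
#' spike peak to 100 ms after it, truncated at the next spike's threshold
#' time or the step offset, whichever comes first.  Inter-spike troughs are
#' thereby attributed to the preceding spike.
#'
#' @param sweep An \code{icp_sweep}.
#' @param peak_index Spike peak sample index.
#' @param threshold \code{\link{ap_threshold}} result for this spike.
#' @param next_threshold_time Threshold time (ms) of the following spike, or
#'   \code{NULL}.
#' @param window_ms Search window, ms (default 100).
#' @return mAHP in mV with attribute \code{truncated_at} (\code{"window"},
#'   \code{"next_spike"} or \code{"step_offset"}); \code{NA} when the window
#'   is empty.
#' @export
ap_mahp <- function(sweep, peak_index, threshold, next_threshold_time = NULL,
                    window_ms = 100) {
  stopifnot(inherits(sweep, "icp_sweep"))
  rate <- sweep$sampling_rate
  dt <- 1000 / rate
  peak_time <- (peak_index - 1) * dt
  t_end <- peak_time + window_ms
  lim <- "window"
  if (sweep$step_offset < t_end) { t_end <- sweep$step_offset; lim <- "step_offset" }
  if (!is.null(next_threshold_time) && next_threshold_time < t_end) {
    t_end <- next_threshold_time; lim <- "next_spike"
  }
  i0 <- peak_index + 1L
  i1 <- min(length(sweep$voltage), as.integer(floor(t_end / dt)) + 1L)
  if (i1 <= i0)
    return(structure(NA_real_, reason = "empty mAHP window"))
  trough <- min(sweep$voltage[i0:i1])
  structure(threshold$voltage - trough, truncated_at = lim)
}

#' Full per-spike feature table of one sweep
#'
#' Runs detection, threshold, shape and mAHP for every spike and returns one
#' row per accepted spike (events whose dV/dt never reaches the threshold
#' criterion are dropped).
#'
#' @param sweep An \code{icp_sweep}.
#' @param criterion Detection voltage, mV.
#' @param criterion_vps Threshold slope criterion, V/s.
#' @return Data frame with columns \code{spike}, \code{threshold_voltage},
#'   \code{threshold_time}, \code{peak_voltage}, \code{peak_time},
#'   \code{peak_amplitude}, \code{half_width}, \code{mahp}, \code{dvdt_max},
#'   \code{dvdt_min}.
#' @export
ap_feature_table <- function(sweep, criterion = 0, criterion_vps = 20) {
  det <- detect_spikes(sweep, criterion = criterion)
  if (nrow(det) == 0) return(empty_ap_table())
  thr <- lapply(det$peak_index, function(pi)
    ap_threshold(sweep, pi, criterion_vps = criterion_vps))
  keep <- !vapply(thr, is.null, logical(1))
  det <- det[keep, , drop = FALSE]
  thr <- thr[keep]
  if (nrow(det) == 0) return(empty_ap_table())
  rows <- lapply(seq_len(nrow(det)), function(k) {
    sh <- ap_shape(sweep, det$peak_index[k], thr[[k]])
    nxt <- if (k < nrow(det)) thr[[k + 1]]$time else NULL
    mahp <- ap_mahp(sweep, det$peak_index[k], thr[[k]],
                    next_threshold_time = nxt)
    data.frame(spike = k,
               threshold_voltage = thr[[k]]$voltage,
               threshold_time = thr[[k]]$time,
               peak_voltage = det$peak_voltage[k],
               peak_time = det$peak_time[k],
               peak_amplitude = sh$peak_amplitude,
               half_width = sh$half_width,
               mahp = as.numeric(mahp),
               dvdt_max = sh$dvdt_max,
               dvdt_min = sh$dvdt_min)
  })
  do.call(rbind, rows)
}

empty_ap_table <- function() {
  data.frame(spike = integer(0), threshold_voltage = numeric(0),
             threshold_time = numeric(0), peak_voltage = numeric(0),
             peak_time = numeric(0), peak_amplitude = numeric(0),
             half_width = numeric(0), mahp = numeric(0),
             dvdt_max = numeric(0), dvdt_min = numeric(0))
}

#' Rheobase and spike latency
#'
#' Rheobase is the smallest depolarizing step amplitude whose sweep contains
#' at least one spike; latency is the first spike's threshold time minus the
#' step onset on that sweep.  A ladder whose lowest sweep already spikes is
#' flagged \code{ladder_floor}.
#'
#' @param recording An \code{icp_recording} with a depolarizing ladder.
#' @param criterion Detection voltage, mV.
#' @return A list: \code{rheobase} (pA), \code{latency} (ms),
#'   \code{sweep_index}, \code{ladder_floor} (logical), \code{increment}
#'   (ladder resolution, pA; NA for a single-step ladder); or \code{NULL}
#'   when no sweep spikes.
#' @export
find_rheobase <- function(recording, criterion = 0) {
  stopifnot(inherits(recording, "icp_recording"))
  amps <- vapply(recording$sweeps, `[[`, numeric(1), "step_amplitude")
  dep <- which(amps > 0)
  if (!length(dep)) return(NULL)
  dep <- dep[order(amps[dep])]
  counts <- vapply(dep, function(i)
    nrow(detect_spikes(recording$sweeps[[i]], criterion = criterion)),
    integer(1))
  hit <- which(counts >= 1)
  if (!length(hit)) return(NULL)
  k <- dep[hit[1]]
  sw <- recording$sweeps[[k]]
  det <- detect_spikes(sw, criterion = criterion)
  thr <- ap_threshold(sw, det$peak_index[1])
  latency <- if (is.null(thr)) NA_real_ else thr$time - sw$step_onset
  sorted_amps <- sort(amps[dep])
  increment <- if (length(sorted_amps) > 1) min(diff(sorted_amps)) else NA_real_
  list(rheobase = sw$step_amplitude,
       latency = latency,
       sweep_index = k,
       ladder_floor = hit[1] == 1,
       increment = increment)
}

#' Find the sweep evoking a target spike count
#'
#' Returns the sweep with exactly \code{n} spikes at the smallest such
#' current.  When no sweep has exactly \code{n}, the sweep whose count is
#' nearest below \code{n} (largest count < n) is returned and flagged
#' approximate; if all spiking sweeps overshoot, the nearest count above is
#' used instead.
#'
#' @param recording An \code{icp_recording}.
#' @param n Target spike count (default 7).
#' @param criterion Detection voltage, mV.
#' @return A list: \code{sweep}, \code{sweep_index}, \code{current} (pA),
#'   \code{n_spikes}, \code{exact} (logical); \code{NULL} when nothing spikes.
#' @export
find_n_spike_sweep <- function(recording, n = 7, criterion = 0) {
  stopifnot(inherits(recording, "icp_recording"))
  amps <- vapply(recording$sweeps, `[[`, numeric(1), "step_amplitude")
  dep <- which(amps > 0)
  if (!length(dep)) return(NULL)
  counts <- vapply(dep, function(i)
    nrow(detect_spikes(recording$sweeps[[i]], criterion = criterion)),
    integer(1))
  spiking <- counts > 0
  if (!any(spiking)) return(NULL)
  pick_min_current <- function(cands) cands[which.min(amps[cands])]
  exact <- dep[counts == n]
  if (length(exact)) {
    k <- pick_min_current(exact); ex <- TRUE
  } else {
    below <- counts[spiking][counts[spiking] < n]
    if (length(below)) {
      best <- max(below)
    } else {
      best <- min(counts[spiking][counts[spiking] > n])
    }
    k <- pick_min_current(dep[counts == best]); ex <- FALSE
  }
  list(sweep = recording$sweeps[[k]],
       sweep_index = k,
       current = amps[k],
       n_spikes = counts[match(k, dep)],
       exact = ex)
}

#' Interspike intervals and accommodation ratio of a spike train
#'
#' For a train of at least 7 spikes, \code{isi_1} and \code{isi_6} are the
#' first and sixth interspike intervals and the accommodation ratio is
#' \code{(isi_6 - isi_1) / isi_6} (negative values are allowed and indicate
#' a train that speeds up).
#'
#' @param spike_times Numeric vector of spike times, ms, ascending.
#' @return A list \code{isi_1}, \code{isi_6}, \code{accommodation_ratio};
#'   all \code{NA} when fewer than 7 spikes are supplied.
#' @export
isi_accommodation <- function(spike_times) {
  if (length(spike_times) < 7)
    return(list(isi_1 = NA_real_, isi_6 = NA_real_,
                accommodation_ratio = NA_real_))
  isi <- diff(spike_times)
  list(isi_1 = isi[1], isi_6 = isi[6],
       accommodation_ratio = (isi[6] - isi[1]) / isi[6])
}

#' Current-frequency (I-F) relationship
#'
#' Spike count (or rate over the step duration) per depolarizing step
#' amplitude, ordered by current.
#'
#' @param recording An \code{icp_recording}.
#' @param as_rate Report spikes/s over the step duration instead of counts.
#' @param criterion Detection voltage, mV.
#' @return Data frame with columns \code{current} (pA) and \code{n_spikes}
#'   (or \code{rate}, Hz).
#' @export
fi_curve <- function(recording, as_rate = FALSE, criterion = 0) {
  stopifnot(inherits(recording, "icp_recording"))
  dep <- Filter(function(sw) sw$step_amplitude > 0, recording$sweeps)
  amps <- vapply(dep, `[[`, numeric(1), "step_amplitude")
  o <- order(amps)
  counts <- vapply(dep[o], function(sw)
    nrow(detect_spikes(sw, criterion = criterion)), integer(1))
  if (as_rate) {
    dur_s <- vapply(dep[o], function(sw)
      (sw$step_offset - sw$step_onset) / 1000, numeric(1))
    return(data.frame(current = amps[o], rate = counts / dur_s))
  }
  data.frame(current = amps[o], n_spikes = counts)
}
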