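# Scoring of behavioural event logs: prepulse inhibition of the acoustic
# startle response, radial-arm-maze working memory, open-field jumping.

#' Prepulse inhibition percentage
#'
#' PPI = 100 - (mean startle over prepulse trials / mean startle over
#' startle-only trials) x 100, for one prepulse intensity.  Values are
#' unbounded below (facilitation gives negative PPI) and reach 100 only when
#' the prepulse-trial mean is zero.
#'
#' @param session Data frame with columns \code{trial_type} (character; use
#'   \code{"startle_only"} for pulse-alone trials and any other label, e.g.
#'   \code{"pp70"}, for prepulse trials) and \code{startle} (response
#'   amplitude, arbitrary units, non-negative).
#' @param prepulse_level Trial-type label of the prepulse trials to score.
#' @return PPI in percent; \code{NA} with a \code{reason} attribute when the
#'   startle-only mean is zero.
#' @examples
#' s <- data.frame(trial_type = c("startle_only", "startle_only", "pp82", "pp82"),
#'                 startle = c(100, 100, 20, 30))
#' ppi_percent(s, "pp82")  # 75
#' @export
ppi_percent <- function(session, prepulse_level) {
  stopifnot(is.data.frame(session),
            all(c("trial_type", "startle") %in% names(session)))
  if (any(session$startle < 0))
    stop("ppi_percent: startle amplitudes must be non-negative")
  so <- session$startle[session$trial_type == "startle_only"]
  pp <- session$startle[session$trial_type == prepulse_level]
  if (length(so) < 1)
    stop("ppi_percent: no startle-only trials in session")
  if (length(pp) < 1)
    stop("ppi_percent: no trials of type '", prepulse_level, "'")
  if (mean(so) == 0)
    return(structure(NA_real_, reason = "zero mean startle-only response"))
  100 - mean(pp) / mean(so) * 100
}

#' Working-memory errors in a radial-arm-maze session
#'
#' Re-entering an already-visited arm counts as one working-memory error;
#' every re-entry counts.  Sensor debouncing: when timestamps are supplied,
#' consecutive identical arm ids closer together than \code{debounce_s} are
#' collapsed into one visit (hardware re-triggers within one visit are not
#' entries); genuine, separated re-entries into the same arm still count.
#' Completion time is the timestamp at which the last of the 8 arms is first
#' entered, minus the doors-open time; it is undefined when the session ends
#' before all arms have been visited.
#'
#' @param arms Integer vector of arm entries in order (ids 1-8).
#' @param times Optional numeric timestamps (s), non-decreasing, one per
#'   entry.
#' @param doors_open Doors-open timestamp (s), default 0.
#' @param n_arms Number of arms (default 8).
#' @param debounce_s Debounce window (s) for consecutive identical entries;
#'   only applied when \code{times} is supplied.
#' @return A list: \code{errors}, \code{arms_visited},
#'   \code{completion_time} (s, \code{NA} if incomplete).
#' @examples
#' working_memory_errors(c(1, 2, 1, 3))$errors  # 1
#' @export
working_memory_errors <- function(arms, times = NULL, doors_open = 0,
                                  n_arms = 8, debounce_s = 2) {
  if (length(arms) == 0)
    return(list(errors = 0L, arms_visited = 0L, completion_time = NA_real_))
  if (any(!arms %in% seq_len(n_arms)))
    stop("working_memory_errors: arm ids must lie in 1..", n_arms)
  if (!is.null(times)) {
    if (length(times) != length(arms))
      stop("working_memory_errors: one timestamp per entry required")
    if (any(diff(times) < 0))
      stop("working_memory_errors: timestamps must be non-decreasing")
  }
  # collapse sensor re-triggers: a consecutive duplicate within the
  # debounce window is the same visit
  if (!is.null(times) && length(arms) > 1) {
    keep <- c(TRUE, !(arms[-1] == arms[-length(arms)] &
                        diff(times) < debounce_s))
    arms <- arms[keep]
    times <- times[keep]
  }
  revisit <- duplicated(arms)
  visited <- unique(arms)
  completion <- NA_real_
  if (length(visited) == n_arms && !is.null(times)) {
    last_new <- which(!revisit)[n_arms]
    completion <- times[last_new] - doors_open
  }
  list(errors = sum(revisit),
       arms_visited = length(visited),
       completion_time = completion)
}

#' Average daily working-memory errors over a test block
#'
#' @param sessions List of per-day sessions, each a list with elements
#'   \code{arms} and optionally \code{times} as in
#'   \code{\link{working_memory_errors}}.
#' @return A list: \code{per_day} (data frame of day, errors, completion
#'   time) and \code{average_errors} over the supplied days.
#' @export
maze_error_average <- function(sessions) {
  rows <- lapply(seq_along(sessions), function(d) {
    s <- sessions[[d]]
    r <- working_memory_errors(s$arms, s$times %||% NULL)
    data.frame(day = d, errors = r$errors,
               completion_time = r$completion_time)
  })
  per_day <- do.call(rbind, rows)
  list(per_day = per_day, average_errors = mean(per_day$errors))
}

#' Total jump time from open-field beam breaks
#'
#' The event stream is cut into fixed bins; a bin is a jump bin when it
#' contains at least one Z-axis (rearing) beam break and no X- or Y-axis
#' break.  Jump time is the summed duration of jump bins, in seconds.
#'
#' @param log Data frame with columns \code{time_ms} (non-decreasing) and
#'   \code{axis} (one of \code{"X"}, \code{"Y"}, \code{"Z"}).
#' @param bin_ms Bin width, ms (default 100, a typical beam-scan epoch).
#' @return Total jump time in seconds.
#' @examples
#' log <- data.frame(time_ms = c(50, 150, 250), axis = c("Z", "Z", "X"))
#' jump_time(log)  # 0.2
#' @export
jump_time <- function(log, bin_ms = 100) {
  if (nrow(log) == 0) return(0)
  stopifnot(all(c("time_ms", "axis") %in% names(log)))
  if (any(diff(log$time_ms) < 0))
    stop("jump_time: timestamps must be non-decreasing")
  if (any(!log$axis %in% c("X", "Y", "Z")))
    stop("jump_time: axis labels must be X, Y or Z")
  bin <- floor(log$time_ms / bin_ms)
  z_bins <- unique(bin[log$axis == "Z"])
  xy_bins <- unique(bin[log$axis != "Z"])
  length(setdiff(z_bins, xy_bins)) * bin_ms / 1000
}
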