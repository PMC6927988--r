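# Sweep-archive reader/writer.
#
# Canonical on-disk format: a directory holding `manifest.json` plus one CSV
# per sweep (columns time_ms, <voltage>, <current>).  The manifest is
# self-describing: units, sampling rate and the step table live there, and
# units are normalized to mV / pA / ms on load whatever the file declares.
# Values are written with full double precision (%.17g) so an archive
# round-trips bit-identically, and the writer is deterministic: identical
# recordings give byte-identical archives.

.voltage_units <- c(V = 1000, mV = 1, uV = 1e-3)
.current_units <- c(A = 1e12, mA = 1e9, uA = 1e6, nA = 1e3, pA = 1)

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a cell recording to a sweep archive
#'
#' @param recording An \code{icp_recording}.
#' @param path Directory to create (must not be an existing non-empty file).
#' @return \code{path}, invisibly.
#' @seealso \code{\link{read_archive}}
#' @export
write_archive <- function(recording, path) {
  stopifnot(inherits(recording, "icp_recording"))
  if (length(recording$sweeps) == 0) stop("write_archive: empty sweep list")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("sweep_%03d.csv", seq_along(recording$sweeps))
  for (i in seq_along(recording$sweeps)) {
    sw <- recording$sweeps[[i]]
    n <- length(sw$voltage)
    con <- file(file.path(path, files[i]), "wb")  # "wb": byte-stable newlines
    writeLines("time_ms,voltage_mV,current_pA", con)
    writeLines(paste(fmt17(sweep_times(n, sw$sampling_rate)),
                     fmt17(sw$voltage), fmt17(sw$command_current), sep = ","),
               con)
    close(con)
  }
  manifest <- list(
    format = "icephys-sweep-archive",
    version = 1L,
    cell_id = recording$cell_id,
    group = recording$group,
    sampling_rate_hz = recording$sampling_rate,
    voltage_unit = "mV",
    current_unit = "pA",
    junction_potential_corrected = recording$junction_potential_corrected,
    junction_potential_mv = recording$junction_potential_mv,
    temperature_c = recording$temperature,
    sweeps = lapply(seq_along(recording$sweeps), function(i) {
      sw <- recording$sweeps[[i]]
      list(file = files[i],
           step_amplitude_pa = sw$step_amplitude,
           step_onset_ms = sw$step_onset,
           step_offset_ms = sw$step_offset,
           n_samples = length(sw$voltage))
    }))
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  con <- file(file.path(path, "manifest.json"), "wb")
  writeLines(json, con)
  close(con)
  invisible(path)
}

#' Read a sweep archive
#'
#' Loads an archive written by \code{\link{write_archive}} (or assembled by
#' hand in the same layout).  Units named in the manifest are converted to
#' mV and pA on load; unknown units, missing fields and trace/manifest length
#' mismatches are rejected with messages naming the offending field or file.
#'
#' @param path Archive directory.
#' @return An \code{icp_recording}.
#' @export
read_archive <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop("read_archive: no manifest.json under '", path, "'")
  man <- jsonlite::fromJSON(mf, simplifyVector = FALSE)
  for (field in c("sampling_rate_hz", "voltage_unit", "current_unit", "sweeps"))
    if (is.null(man[[field]]))
      stop("read_archive: manifest field '", field, "' is missing")
  vu <- unname(.voltage_units[man$voltage_unit])
  cu <- unname(.current_units[man$current_unit])
  if (is.na(vu)) stop("read_archive: unknown voltage unit '", man$voltage_unit, "'")
  if (is.na(cu)) stop("read_archive: unknown current unit '", man$current_unit, "'")
  rate <- man$sampling_rate_hz
  sweeps <- lapply(man$sweeps, function(s) {
    f <- file.path(path, s$file)
    if (!file.exists(f)) stop("read_archive: sweep file '", s$file, "' is missing")
    d <- utils::read.csv(f)
    need <- length(grep("^voltage", names(d))) && length(grep("^current", names(d)))
    if (!need)
      stop("read_archive: '", s$file, "' lacks voltage/current columns")
    vcol <- grep("^voltage", names(d), value = TRUE)[1]
    ccol <- grep("^current", names(d), value = TRUE)[1]
    if (!is.null(s$n_samples) && nrow(d) != s$n_samples)
      stop("read_archive: '", s$file, "' holds ", nrow(d),
           " samples but the manifest declares ", s$n_samples,
           " (truncated file?)")
    if (anyNA(d[[vcol]]) || anyNA(d[[ccol]]))
      stop("read_archive: '", s$file, "' contains unparseable samples")
    new_sweep(voltage = d[[vcol]] * vu,
              sampling_rate = rate,
              step_amplitude = s$step_amplitude_pa * cu,
              step_onset = s$step_onset_ms,
              step_offset = s$step_offset_ms,
              command_current = d[[ccol]] * cu)
  })
  new_recording(sweeps,
                cell_id = man$cell_id %||% "cell",
                group = man$group %||% NA_character_,
                junction_potential_corrected =
                  isTRUE(man$junction_potential_corrected),
                junction_potential_mv = man$junction_potential_mv %||% 15.2,
                temperature = man$temperature_c)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Protocol capability descriptor
#'
#' Inspects the step table of a recording and flags which downstream
#' analyses are computable: sag needs a -100 pA step, input resistance any
#' hyperpolarizing step, rheobase/I-F a depolarizing ladder.
#'
#' @param recording An \code{icp_recording}.
#' @return A list: \code{step_amplitudes}, \code{sag_capable},
#'   \code{rin_capable}, \code{rheobase_capable}, \code{fi_capable},
#'   \code{ladder_monotone} (depolarizing amplitudes strictly increasing in
#'   sweep order), \code{ladder_increment} (pA; NA when < 2 depolarizing
#'   steps).
#' @export
validate_protocol <- function(recording) {
  stopifnot(inherits(recording, "icp_recording"))
  amps <- vapply(recording$sweeps, `[[`, numeric(1), "step_amplitude")
  dep <- amps[amps > 0]
  list(step_amplitudes = amps,
       sag_capable = any(abs(amps + 100) < 1e-6),
       rin_capable = any(amps < 0),
       rheobase_capable = length(dep) >= 1,
       fi_capable = length(dep) >= 2,
       ladder_monotone = length(dep) >= 2 && all(diff(dep) > 0),
       ladder_increment = if (length(dep) >= 2) min(diff(sort(dep))) else NA_real_)
}
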