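# Orchestration: simulate or load -> extract per-cell features -> two-group
# comparison tables (full cohort and the prominent-H subgroup) -> CSV/JSON
# report.

#' Group templates for a two-group synthetic cohort
#'
#' The control template is \code{\link{neuron_params}()} defaults.  The
#' shifted template moves the dials in the directions characteristic of a
#' two-hit (maternal-immune-activation plus social-isolation) phenotype:
#' lower leak conductance (higher input
#' resistance), more negative leak reversal (hyperpolarized RMP), stronger
#' SK (larger mAHP, slower trains) and a larger somatic share of the sodium
#' conductance (larger SD slope ratio).
#'
#' @return A list with elements \code{control} and \code{shifted}.
#' @export
cohort_templates <- function() {
  list(control = neuron_params(),
       shifted = neuron_params(leak_conductance = 6.06,
                               leak_reversal = -69,
                               gSK = 40,
                               gNa_soma = 2600,
                               gNa_ais = 240,
                               # sag is not expected to differ between groups:
                               # a slightly smaller gH offsets the larger
                               # voltage excursion that the higher input
                               # resistance produces on the -100 pA step
                               gH = 1.2))
}

#' Extract the full feature row of one cell
#'
#' Runs every extractor on one recording: passive properties, rheobase-AP
#' waveform features, 7-AP-train metrics and the rising-phase decomposition
#' of the first AP of the train.  Features whose preconditions fail are NA
#' (never silent zeros).
#'
#' @param recording An \code{icp_recording}.
#' @param n_train Target spike count of the train analysis (default 7).
#' @param convention Slope-ratio convention, see \code{\link{slope_sd_ratio}}.
#' @return A one-row data frame.
#' @export
extract_cell_features <- function(recording, n_train = 7,
                                  convention = "shoulder") {
  pf <- passive_features(recording)
  row <- data.frame(cell_id = recording$cell_id,
                    group = recording$group,
                    pf,
                    rheobase = NA_real_, spike_latency = NA_real_,
                    threshold = NA_real_, peak_amplitude = NA_real_,
                    half_width = NA_real_, mahp = NA_real_,
                    dvdt_max = NA_real_, dvdt_min = NA_real_,
                    n7_current = NA_real_, n7_exact = NA,
                    isi_1 = NA_real_, isi_6 = NA_real_,
                    accommodation_ratio = NA_real_,
                    slope_a = NA_real_, slope_b = NA_real_,
                    ais_component = NA_real_, slope_sd_ratio = NA_real_,
                    stringsAsFactors = FALSE)
  rb <- find_rheobase(recording)
  if (!is.null(rb)) {
    row$rheobase <- rb$rheobase
    row$spike_latency <- rb$latency
    tab <- ap_feature_table(recording$sweeps[[rb$sweep_index]])
    if (nrow(tab) >= 1) {
      row$threshold <- tab$threshold_voltage[1]
      row$peak_amplitude <- tab$peak_amplitude[1]
      row$half_width <- tab$half_width[1]
      row$mahp <- tab$mahp[1]
      row$dvdt_max <- tab$dvdt_max[1]
      row$dvdt_min <- tab$dvdt_min[1]
    }
  }
  sel <- find_n_spike_sweep(recording, n = n_train)
  if (!is.null(sel)) {
    row$n7_current <- sel$current
    row$n7_exact <- sel$exact
    det <- detect_spikes(sel$sweep)
    acc <- isi_accommodation(det$peak_time)
    row$isi_1 <- acc$isi_1
    row$isi_6 <- acc$isi_6
    row$accommodation_ratio <- acc$accommodation_ratio
    fa <- first_ap_of_train(recording, n = n_train)
    if (!is.null(fa)) {
      sr <- slope_sd_ratio(fa$sweep, fa$peak_index, fa$threshold,
                           convention = convention)
      if (!is.null(sr)) {
        row$slope_a <- sr$a
        row$slope_b <- sr$b
        row$ais_component <- sr$b_minus_a
        row$slope_sd_ratio <- sr$ratio
      }
    }
  }
  row
}

# feature columns entering the comparison tables
.compared_features <- c("rmp", "input_resistance", "sag_ratio", "rheobase",
                        "spike_latency", "threshold", "peak_amplitude",
                        "half_width", "mahp", "n7_current", "isi_1", "isi_6",
                        "accommodation_ratio", "slope_sd_ratio")

build_comparison <- function(features, labels) {
  rows <- lapply(.compared_features, function(param) {
    a <- features[features$group == labels[1], param]
    b <- features[features$group == labels[2], param]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      return(data.frame(parameter = param,
                        mean_1 = NA_real_, sem_1 = NA_real_, n_1 = length(a),
                        mean_2 = NA_real_, sem_2 = NA_real_, n_2 = length(b),
                        test = NA_character_, statistic = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    cmp <- route_and_compare(a, b, labels = labels)
    data.frame(parameter = param,
               mean_1 = cmp$summary_a$mean, sem_1 = cmp$summary_a$sem,
               n_1 = cmp$summary_a$n,
               mean_2 = cmp$summary_b$mean, sem_2 = cmp$summary_b$sem,
               n_2 = cmp$summary_b$n,
               test = cmp$test, statistic = cmp$statistic, p = cmp$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[c(2:4, 5:7)] <- c(paste0(c("mean_", "sem_", "n_"), labels[1]),
                               paste0(c("mean_", "sem_", "n_"), labels[2]))
  out
}

# deterministic polynomial hash over a JSON rendering of the config
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     force = TRUE))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full two-group analysis pipeline
#'
#' Takes a cohort (simulated via \code{\link{simulate_cohort}} or a list of
#' two lists of recordings), extracts the per-cell feature table, compares
#' every feature between groups with the normality-routed test, repeats the
#' comparison on the prominent-H subgroup (sag ratio > 5\%; a pure filter
#' that never alters full-cohort numbers), and reports the prominent-H
#' fractions per group.  Deterministic given the cohort.
#'
#' @param cohort Either the result of \code{\link{simulate_cohort}} or a
#'   named list of two lists of \code{icp_recording} objects.
#' @param n_train,convention Passed to \code{\link{extract_cell_features}}.
#' @param config Optional list recorded (hashed) in the provenance block.
#' @return An object of class \code{icp_group_report}: \code{features},
#'   \code{comparison}, \code{subgroup_comparison}, \code{prominent_h}
#'   (per-group counts and fractions), \code{provenance}.
#' @export
run_pipeline <- function(cohort, n_train = 7, convention = "shoulder",
                         config = list()) {
  labels <- names(cohort)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("run_pipeline: cohort must be a named list of two groups")
  recs <- lapply(cohort, function(grp) lapply(grp, function(el) {
    if (inherits(el, "icp_recording")) el else el$recording
  }))
  if (any(vapply(recs, length, integer(1)) == 0))
    stop("run_pipeline: a group has zero usable cells")
  features <- do.call(rbind, lapply(unlist(recs, recursive = FALSE),
                                    extract_cell_features,
                                    n_train = n_train,
                                    convention = convention))
  rownames(features) <- NULL
  comparison <- build_comparison(features, labels)
  sub <- features[!is.na(features$prominent_h) & features$prominent_h, ]
  subgroup_comparison <- build_comparison(sub, labels)
  ph <- do.call(rbind, lapply(labels, function(lb) {
    f <- features[features$group == lb, ]
    n_h <- sum(f$prominent_h, na.rm = TRUE)
    n <- sum(!is.na(f$prominent_h))
    data.frame(group = lb, n_prominent_h = n_h, n = n,
               fraction_pct = 100 * n_h / n, stringsAsFactors = FALSE)
  }))
  structure(list(features = features,
                 comparison = comparison,
                 subgroup_comparison = subgroup_comparison,
                 prominent_h = ph,
                 provenance = list(
                   package_version = as.character(utils::packageVersion("icephys")),
                   n_train = n_train,
                   convention = convention,
                   config = config,
                   config_hash = config_hash(c(config, n_train = n_train,
                                               convention = convention)))),
            class = "icp_group_report")
}

#' @export
print.icp_group_report <- function(x, ...) {
  cat("<icp_group_report>\n")
  cat("  cells:", nrow(x$features), "in groups",
      paste(unique(x$features$group), collapse = " / "), "\n")
  cat("  prominent-H fractions:",
      paste(sprintf("%s %.1f%% (%d/%d)", x$prominent_h$group,
                    x$prominent_h$fraction_pct, x$prominent_h$n_prominent_h,
                    x$prominent_h$n), collapse = ", "), "\n")
  sig <- x$comparison[!is.na(x$comparison$p) & x$comparison$p < 0.05, ]
  cat("  significant parameters (p < 0.05):",
      if (nrow(sig)) paste(sig$parameter, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Render a group report to files
#'
#' Writes \code{features.csv}, \code{comparison.csv},
#' \code{subgroup_comparison.csv}, \code{prominent_h.csv} and
#' \code{provenance.json} into \code{dir}.  Missing values render as NA.
#'
#' @param report An \code{icp_group_report}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
report_render <- function(report, dir) {
  stopifnot(inherits(report, "icp_group_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(report$comparison, file.path(dir, "comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(report$subgroup_comparison,
                   file.path(dir, "subgroup_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(report$prominent_h, file.path(dir, "prominent_h.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(report$provenance, auto_unbox = TRUE,
                              digits = NA, pretty = TRUE, force = TRUE),
             file.path(dir, "provenance.json"))
  invisible(dir)
}
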