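#' Write a dataset to a directory
#'
#' Lays the dataset out as plain text: `protocol.json` (and
#' `provenance.json` when present) at the root, and one subdirectory per
#' cell under `cells/`, holding one two-column CSV (`sample,value`) plus one
#' JSON sidecar of labels per sweep. Traces are written with 17 significant
#' digits so a read-back reproduces them exactly.
#'
#' @param dataset a \code{\link{bm_dataset}}.
#' @param path output directory (created if missing).
#' @return \code{path}, invisibly.
#' @seealso \code{\link{read_dataset}}
#' @export
write_dataset <- function(dataset, path) {
  validate_dataset(dataset)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort("cannot create directory %s", path)
  jsonlite::write_json(unclass(dataset$protocol),
                       file.path(path, "protocol.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(dataset$provenance))
    jsonlite::write_json(dataset$provenance,
                         file.path(path, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  for (cid in names(dataset$cells)) {
    cdir <- file.path(path, "cells", cid)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    sweeps <- dataset$cells[[cid]]
    for (k in seq_along(sweeps)) {
      sw <- sweeps[[k]]
      csv <- file.path(cdir, sprintf("sweep_%04d.csv", k))
      writeLines(c("sample,value",
                   sprintf("%d,%.17g", seq_along(sw$trace), sw$trace)),
                 csv)
      meta <- list(clamp_mode = sw$clamp_mode, eye = sw$eye, led = sw$led,
                   stimulus = if (is_blank(sw)) "blank" else sw$stimulus,
                   trial_index = sw$trial_index,
                   stimulus_onset_s = sw$stimulus_onset,
                   sampling_rate_hz = sw$sampling_rate)
      jsonlite::write_json(meta,
                           file.path(cdir, sprintf("sweep_%04d.meta.json", k)),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(path)
}

#' Read a dataset directory
#'
#' Inverse of \code{\link{write_dataset}}. Malformed sweeps are reported
#' with the offending file name; sweeps whose direction label is not in the
#' protocol's direction set, and cells mixing sampling rates or clamp
#' modes, are rejected.
#'
#' @param path dataset directory.
#' @return a \code{\link{bm_dataset}}.
#' @export
read_dataset <- function(path) {
  proto_file <- file.path(path, "protocol.json")
  if (!file.exists(proto_file))
    abort("missing protocol file: %s", proto_file)
  pj <- jsonlite::read_json(proto_file, simplifyVector = TRUE)
  protocol <- stim_protocol(
    n_directions = pj$n_directions, direction_step = pj$direction_step,
    stimulus_duration = pj$stimulus_duration,
    temporal_frequency = pj$temporal_frequency, n_cycles = pj$n_cycles,
    cycle_window_start = pj$cycle_window_start,
    cycle_window_end = pj$cycle_window_end,
    spatial_frequency = pj$spatial_frequency,
    sampling_rate = pj$sampling_rate)
  prov_file <- file.path(path, "provenance.json")
  provenance <- if (file.exists(prov_file))
    jsonlite::read_json(prov_file, simplifyVector = TRUE) else list()

  cells <- list()
  cell_root <- file.path(path, "cells")
  cell_dirs <- if (dir.exists(cell_root))
    list.dirs(cell_root, recursive = FALSE) else character(0)
  for (cdir in cell_dirs) {
    cid <- basename(cdir)
    metas <- sort(list.files(cdir, pattern = "^sweep_\\d+\\.meta\\.json$",
                             full.names = TRUE))
    sweeps <- vector("list", length(metas))
    for (k in seq_along(metas)) {
      mfile <- metas[k]
      csv <- sub("\\.meta\\.json$", ".csv", mfile)
      if (!file.exists(csv)) abort("%s: missing trace file %s", mfile, csv)
      m <- jsonlite::read_json(mfile, simplifyVector = TRUE)
      req <- c("clamp_mode", "eye", "led", "stimulus", "trial_index",
               "stimulus_onset_s", "sampling_rate_hz")
      miss <- setdiff(req, names(m))
      if (length(miss))
        abort("%s: missing metadata keys: %s", mfile, paste(miss, collapse = ", "))
      if (!m$clamp_mode %in% c("current_clamp", "voltage_clamp"))
        abort("%s: unknown clamp_mode '%s'", mfile, m$clamp_mode)
      if (!m$eye %in% c("contra", "ipsi"))
        abort("%s: unknown eye label '%s'", mfile, m$eye)
      if (!m$led %in% c("off", "on"))
        abort("%s: unknown LED label '%s'", mfile, m$led)
      stimulus <- m$stimulus
      if (!identical(stimulus, "blank")) {
        stimulus <- suppressWarnings(as.numeric(stimulus))
        if (is.na(stimulus)) abort("%s: unparseable stimulus label", mfile)
      }
      tab <- read.csv(csv, colClasses = c("integer", "numeric"))
      sw <- sweep_record(cid, m$clamp_mode, m$eye, m$led, stimulus,
                         m$trial_index, tab$value, m$stimulus_onset_s,
                         m$sampling_rate_hz)
      validate_sweep(sw, protocol, context = csv)
      sweeps[[k]] <- sw
    }
    cells[[cid]] <- sweeps
  }
  bm_dataset(protocol, cells, provenance)
}

#' Write analysis result tables
#'
#' Writes the per-cell metrics table (`cell_results.tsv`), the long
#' tuning-curve table (`tuning_curves.tsv`) and, when a cohort comparison is
#' supplied, a structured `cohort_summary.json`. Numeric columns keep 15
#' significant digits.
#'
#' @param analysis a \code{bm_analysis} from \code{\link{analyze_dataset}}.
#' @param path output directory (created if missing).
#' @param cohort optional \code{cohort_comparison} from
#'   \code{\link{compare_cohorts}}.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(analysis, path, cohort = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tab <- cell_results_table(analysis)
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(x) signif(x, 15))
  write.table(tab, file.path(path, "cell_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tc <- analysis$curves
  tc$magnitude <- signif(tc$magnitude, 15)
  write.table(tc, file.path(path, "tuning_curves.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort))
    jsonlite::write_json(cohort_summary_list(cohort),
                         file.path(path, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
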