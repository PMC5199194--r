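#' A single labeled intracellular sweep
#'
#' One raw trace from one stimulus presentation, labeled with everything the
#' analysis needs: recording mode, stimulated eye, optogenetic LED state and
#' drift direction (or \code{"blank"} for the gray screen).
#'
#' @param cell_id character cell identifier.
#' @param clamp_mode \code{"current_clamp"} (trace in mV) or
#'   \code{"voltage_clamp"} (trace in pA).
#' @param eye \code{"contra"} or \code{"ipsi"}.
#' @param led \code{"off"} or \code{"on"} (cortical silencing LED).
#' @param stimulus drift direction in degrees or \code{"blank"}.
#' @param trial_index integer repeat index (1-based).
#' @param trace numeric vector of raw samples.
#' @param stimulus_onset seconds from trace start to stimulus onset.
#' @param sampling_rate sampling rate in Hz.
#' @return an object of class \code{sweep_record}.
#' @export
sweep_record <- function(cell_id, clamp_mode, eye, led, stimulus,
                         trial_index, trace, stimulus_onset, sampling_rate) {
  clamp_mode <- match.arg(clamp_mode, c("current_clamp", "voltage_clamp"))
  eye <- match.arg(eye, c("contra", "ipsi"))
  led <- match.arg(led, c("off", "on"))
  if (!identical(stimulus, "blank")) {
    if (!is_scalar_num(stimulus))
      abort("stimulus must be 'blank' or a direction in degrees")
    stimulus <- as.numeric(stimulus)
  }
  if (!is.numeric(trace) || length(trace) < 2L)
    abort("trace must be a numeric vector with at least 2 samples")
  s <- list(cell_id = as.character(cell_id), clamp_mode = clamp_mode,
            eye = eye, led = led, stimulus = stimulus,
            trial_index = as.integer(trial_index),
            trace = as.numeric(trace),
            stimulus_onset = stimulus_onset,
            sampling_rate = sampling_rate)
  class(s) <- "sweep_record"
  s
}

is_blank <- function(sweep) identical(sweep$stimulus, "blank")

#' Bundle sweeps into a dataset
#'
#' @param protocol a \code{\link{stim_protocol}}.
#' @param cells named list; each element is a list of
#'   \code{\link{sweep_record}} objects belonging to one cell.
#' @param provenance free-form metadata list (cohort label, generator seed,
#'   ...).
#' @return an object of class \code{bm_dataset}.
#' @export
bm_dataset <- function(protocol, cells = list(), provenance = list()) {
  d <- list(protocol = protocol, cells = cells, provenance = provenance)
  class(d) <- "bm_dataset"
  validate_dataset(d)
  d
}

# checks sweep labels and per-cell consistency; `context` names the offending
# source (e.g. a file) in error messages
validate_sweep <- function(sweep, protocol, context = "sweep") {
  if (!is_blank(sweep)) {
    dirs <- protocol_directions(protocol)
    if (!any(abs(dirs - sweep$stimulus) < 1e-9))
      abort("%s: direction %s is not in the protocol's direction set {%s}",
            context, format(sweep$stimulus), paste(dirs, collapse = ","))
  }
  need <- sweep$stimulus_onset + protocol$stimulus_duration
  if (length(sweep$trace) / sweep$sampling_rate < need)
    abort("%s: trace (%g s) does not cover the stimulus period (needs %g s)",
          context, length(sweep$trace) / sweep$sampling_rate, need)
  invisible(sweep)
}

validate_dataset <- function(d) {
  stopifnot(inherits(d, "bm_dataset"))
  validate_protocol(d$protocol)
  for (cid in names(d$cells)) {
    sweeps <- d$cells[[cid]]
    if (length(sweeps) == 0L) next
    modes <- unique(vapply(sweeps, `[[`, "", "clamp_mode"))
    if (length(modes) != 1L)
      abort("cell %s mixes clamp modes (%s)", cid, paste(modes, collapse = ","))
    rates <- unique(vapply(sweeps, `[[`, 0, "sampling_rate"))
    if (length(rates) != 1L)
      abort("cell %s mixes sampling rates (%s)", cid, paste(rates, collapse = ","))
    for (k in seq_along(sweeps))
      validate_sweep(sweeps[[k]], d$protocol,
                     context = sprintf("cell %s sweep %d", cid, k))
  }
  invisible(d)
}

#' @export
print.bm_dataset <- function(x, ...) {
  n_sw <- sum(vapply(x$cells, length, integer(1)))
  cat(sprintf("<bm_dataset> %d cell(s), %d sweep(s)\n",
              length(x$cells), n_sw))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance),
                               vapply(x$provenance, function(v) paste(format(v), collapse = " "), ""),
                               sep = "=", collapse = "; "), "\n")
  print(x$protocol)
  invisible(x)
}
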