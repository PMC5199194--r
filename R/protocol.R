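#' Drifting-grating stimulus protocol
#'
#' Describes the visual-stimulation protocol and acquisition parameters the
#' analysis assumes: full-field sinusoidal gratings drifting in
#' \code{n_directions} directions spaced \code{direction_step} degrees apart,
#' each presented for \code{stimulus_duration} seconds at
#' \code{temporal_frequency} cycles per second (so \code{n_cycles} grating
#' cycles per presentation), with responses cycle-averaged over the window
#' \code{[cycle_window_start, cycle_window_end]} after each cycle onset.
#'
#' The defaults encode the standard protocol: 12 directions at 30 degrees,
#' 1.5 s stimuli at 2 Hz (3 cycles), a 50–550 ms cycle window, and 10 kHz
#' sampling.
#'
#' @param n_directions number of drift directions (default 12).
#' @param direction_step spacing between directions in degrees (default 30).
#' @param stimulus_duration stimulus length in seconds (default 1.5).
#' @param temporal_frequency grating temporal frequency, cycles/s (default 2).
#' @param n_cycles grating cycles per presentation (default 3).
#' @param cycle_window_start,cycle_window_end cycle-averaging window in
#'   seconds after each cycle onset (defaults 0.050 and 0.550).
#' @param spatial_frequency cycles/degree, metadata only (default 0.02).
#' @param sampling_rate acquisition rate in Hz (default 10000).
#' @return an object of class \code{stim_protocol}.
#' @export
#' @examples
#' p <- stim_protocol()
#' protocol_directions(p)
stim_protocol <- function(n_directions = 12L,
                          direction_step = 30,
                          stimulus_duration = 1.5,
                          temporal_frequency = 2,
                          n_cycles = 3L,
                          cycle_window_start = 0.050,
                          cycle_window_end = 0.550,
                          spatial_frequency = 0.02,
                          sampling_rate = 10000) {
  p <- list(
    n_directions = as.integer(n_directions),
    direction_step = direction_step,
    stimulus_duration = stimulus_duration,
    temporal_frequency = temporal_frequency,
    n_cycles = as.integer(n_cycles),
    cycle_window_start = cycle_window_start,
    cycle_window_end = cycle_window_end,
    spatial_frequency = spatial_frequency,
    sampling_rate = sampling_rate
  )
  class(p) <- "stim_protocol"
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  tol <- 1e-9
  if (abs(p$n_directions * p$direction_step - 360) > tol)
    abort("protocol invariant violated: n_directions * direction_step must be 360 (got %g)",
          p$n_directions * p$direction_step)
  if (abs(p$n_cycles / p$temporal_frequency - p$stimulus_duration) > tol)
    abort("protocol invariant violated: n_cycles / temporal_frequency must equal stimulus_duration")
  if (abs((p$cycle_window_end - p$cycle_window_start) - 1 / p$temporal_frequency) > tol)
    abort("protocol invariant violated: cycle window must span one cycle period (%g s)",
          1 / p$temporal_frequency)
  if (p$sampling_rate <= 0) abort("sampling_rate must be positive")
  invisible(p)
}

#' Direction set of a protocol
#'
#' @param protocol a \code{\link{stim_protocol}}.
#' @return integer-valued vector of drift directions in degrees,
#'   \code{0, step, ..., 360 - step}.
#' @export
protocol_directions <- function(protocol) {
  seq(0, 360 - protocol$direction_step, by = protocol$direction_step)
}

# cycle period in seconds
cycle_period <- function(protocol) 1 / protocol$temporal_frequency

#' @export
print.stim_protocol <- function(x, ...) {
  cat("Drifting-grating protocol\n")
  cat(sprintf("  %d directions at %g deg; %g s stimulus = %d cycles at %g Hz\n",
              x$n_directions, x$direction_step, x$stimulus_duration,
              x$n_cycles, x$temporal_frequency))
  cat(sprintf("  cycle window %g-%g ms; sampling %g Hz; SF %g cyc/deg\n",
              1000 * x$cycle_window_start, 1000 * x$cycle_window_end,
              x$sampling_rate, x$spatial_frequency))
  invisible(x)
}
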