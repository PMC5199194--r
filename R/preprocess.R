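#' Preprocessing configuration
#'
#' Tunable parameters of the trace pipeline, with the standard defaults:
#' spike detection at 10 mV/ms on the first derivative with a 2 ms
#' refractory window, a 6 ms median filter for spike removal, a 40 ms mean
#' filter for current smoothing, and a third-cycle adaptation threshold of
#' 0.5 (the third cycle is dropped from the cycle average when its
#' peak-to-baseline amplitude falls below half the mean of the first two).
#'
#' @param dvdt_threshold_mv_per_ms spike-detection dV/dt threshold.
#' @param refractory_ms suppression window after each detected spike.
#' @param median_window_ms spike-removal median-filter window.
#' @param mean_window_ms current-smoothing mean-filter window.
#' @param adaptation_ratio_threshold third-cycle amplitude fraction below
#'   which only the first two cycles are averaged.
#' @return a list of class \code{bm_config}.
#' @export
bm_config <- function(dvdt_threshold_mv_per_ms = 10,
                      refractory_ms = 2,
                      median_window_ms = 6,
                      mean_window_ms = 40,
                      adaptation_ratio_threshold = 0.5) {
  cfg <- list(dvdt_threshold_mv_per_ms = dvdt_threshold_mv_per_ms,
              refractory_ms = refractory_ms,
              median_window_ms = median_window_ms,
              mean_window_ms = mean_window_ms,
              adaptation_ratio_threshold = adaptation_ratio_threshold)
  class(cfg) <- "bm_config"
  cfg
}

# reflect-pad x by nl samples on the left and nr on the right
reflect_pad <- function(x, nl, nr = nl) {
  n <- length(x)
  if (nl >= n || nr >= n) abort("trace shorter than one filter window")
  c(x[(nl + 1):2], x, x[(n - 1):(n - nr)])
}

#' Detect spikes by a dV/dt threshold
#'
#' A spike onset is the time point at which the first derivative of the
#' voltage trace (scaled to mV/ms) crosses \code{dvdt_threshold} upward.
#' Crossings within \code{refractory_ms} of a previous detection are
#' suppressed.
#'
#' @param trace membrane-potential samples (mV, current clamp).
#' @param sampling_rate Hz.
#' @param dvdt_threshold positive threshold in mV/ms.
#' @param refractory_ms absolute refractory window (default 2 ms).
#' @return spike onset times in seconds from trace start (possibly empty).
#' @export
detect_spikes <- function(trace, sampling_rate, dvdt_threshold = 10,
                          refractory_ms = 2) {
  if (!is_scalar_num(dvdt_threshold) || dvdt_threshold <= 0)
    abort("dvdt_threshold must be a positive scalar")
  if (length(trace) < 2L) abort("trace must have at least 2 samples")
  dvdt <- diff(trace) * sampling_rate / 1000  # mV per ms
  above <- dvdt >= dvdt_threshold
  crossing <- which(above & !c(FALSE, above[-length(above)]))
  if (length(crossing) == 0L) return(numeric(0))
  times <- (crossing - 1) / sampling_rate
  keep <- logical(length(times))
  last <- -Inf
  refr <- refractory_ms / 1000
  for (i in seq_along(times)) {
    if (times[i] - last >= refr) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Remove spikes with a running median filter
#'
#' Replaces each sample by the median over a 6 ms (by default) window
#' centered on it, which erases brief spike transients while leaving the
#' slow subthreshold membrane potential intact. The window length in
#' samples is \code{round(window_ms/1000 * sampling_rate)}, forced odd;
#' edges are handled by reflect padding so the output has the input's
#' length.
#'
#' @param trace membrane-potential samples (mV).
#' @param sampling_rate Hz.
#' @param window_ms median window (default 6 ms).
#' @return subthreshold trace, same length as the input.
#' @export
remove_spikes <- function(trace, sampling_rate, window_ms = 6) {
  w <- round(window_ms / 1000 * sampling_rate)
  if (w %% 2 == 0) w <- w + 1L
  if (w < 3L) return(as.numeric(trace))
  half <- (w - 1L) %/% 2L
  padded <- reflect_pad(trace, half)
  out <- stats::runmed(padded, w, endrule = "keep")
  as.numeric(out[(half + 1):(half + length(trace))])
}

#' Smooth a current trace with a running mean filter
#'
#' Replaces each sample by the mean over a 40 ms (by default) window. For a
#' window of W samples the output at position i averages samples
#' \code{i - floor((W-1)/2)} through \code{i + ceiling((W-1)/2)}, with
#' reflect padding at the edges. Implemented via cumulative sums, O(n).
#'
#' @param trace membrane-current samples (pA, voltage clamp).
#' @param sampling_rate Hz.
#' @param window_ms mean window (default 40 ms).
#' @return smoothed trace, same length as the input.
#' @export
smooth_current <- function(trace, sampling_rate, window_ms = 40) {
  w <- round(window_ms / 1000 * sampling_rate)
  if (w < 2L) return(as.numeric(trace))
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  padded <- reflect_pad(trace, half_l, half_r)
  cs <- cumsum(c(0, padded))
  n <- length(trace)
  i <- seq_len(n) + half_l      # position in padded coordinates
  (cs[i + half_r + 1] - cs[i - half_l]) / w
}

#' Cycle-average a preprocessed trace
#'
#' Extracts, for each grating cycle, the response window
#' \code{[cycle onset + cycle_window_start, cycle onset + cycle_window_end]}
#' and averages the windows. If the third cycle's peak-to-baseline amplitude
#' falls below \code{adaptation_ratio_threshold} times the mean amplitude of
#' the first two cycles (response adaptation), only the first two cycles are
#' averaged.
#'
#' Amplitude polarity: \code{polarity = +1} measures depolarization peaks
#' (current clamp); \code{polarity = -1} measures inward-current peaks
#' (voltage clamp). When no \code{baseline} is supplied, the mean of up to
#' 200 ms of trace immediately before stimulus onset is used for the
#' adaptation check.
#'
#' @param trace preprocessed samples covering the whole stimulus.
#' @param protocol a \code{\link{stim_protocol}}.
#' @param stimulus_onset seconds from trace start.
#' @param adaptation_ratio_threshold fraction (default 0.5).
#' @param baseline baseline level for the adaptation amplitude check
#'   (same units as the trace), or \code{NULL}.
#' @param polarity +1 (depolarizing, mV) or -1 (inward current, pA).
#' @param force_n_cycles if 2 or 3, bypass the adaptation rule and average
#'   exactly that many cycles (used to keep LED-on/off windows commensurate
#'   before subtraction).
#' @return list of class \code{cycle_avg} with elements \code{waveform},
#'   \code{n_cycles_used}, \code{cycle_amplitudes}, \code{adapted}.
#' @export
cycle_average <- function(trace, protocol, stimulus_onset,
                          adaptation_ratio_threshold = 0.5,
                          baseline = NULL, polarity = 1,
                          force_n_cycles = NULL) {
  if (any(!is.finite(trace))) abort("trace contains non-finite samples")
  rate <- protocol$sampling_rate
  period <- cycle_period(protocol)
  len <- round((protocol$cycle_window_end - protocol$cycle_window_start) * rate)
  nc <- protocol$n_cycles
  starts <- round((stimulus_onset + (seq_len(nc) - 1) * period +
                     protocol$cycle_window_start) * rate) + 1
  if (max(starts) + len - 1 > length(trace))
    abort("trace too short: needs %d samples for cycle windows, has %d",
          max(starts) + len - 1, length(trace))
  windows <- lapply(starts, function(i0) trace[i0:(i0 + len - 1)])

  if (is.null(baseline)) {
    i_on <- round(stimulus_onset * rate)
    pre <- trace[max(1, i_on - round(0.2 * rate)):max(1, i_on)]
    baseline <- mean(pre)
  }
  amps <- vapply(windows, function(w) max(polarity * (w - baseline)), 0)

  if (!is.null(force_n_cycles)) {
    use <- as.integer(force_n_cycles)
    if (!use %in% c(2L, 3L)) abort("force_n_cycles must be 2 or 3")
    adapted <- NA
  } else if (nc >= 3L) {
    ref <- mean(amps[1:2])
    adapted <- is.finite(ref) && ref > 0 &&
      amps[3] < adaptation_ratio_threshold * ref
    use <- if (adapted) 2L else 3L
  } else {
    use <- nc
    adapted <- FALSE
  }
  waveform <- Reduce(`+`, windows[seq_len(use)]) / use
  structure(list(waveform = waveform, n_cycles_used = use,
                 cycle_amplitudes = amps, adapted = adapted,
                 sampling_rate = rate),
            class = "cycle_avg")
}

#' Baseline from blank-stimulus sweeps
#'
#' Averages the preprocessed blank (gray-screen) traces across sweeps, then
#' takes the mean and standard deviation of the averaged trace over the
#' stimulus-period window. The mean is the membrane-potential or
#' holding-current baseline; the SD quantifies spontaneous fluctuations.
#'
#' @param blank_traces list of preprocessed blank traces (equal lengths).
#' @param window two-element numeric, window in seconds from trace start.
#' @param sampling_rate Hz.
#' @return list of class \code{bm_baseline} with \code{mean} and \code{sd}.
#' @export
compute_baseline <- function(blank_traces, window, sampling_rate) {
  if (length(blank_traces) == 0L) abort("no blank sweeps available")
  if (is.numeric(blank_traces)) blank_traces <- list(blank_traces)
  avg <- average_traces(blank_traces)
  i0 <- round(window[1] * sampling_rate) + 1
  i1 <- round(window[2] * sampling_rate)
  if (i1 > length(avg) || i0 < 1)
    abort("baseline window [%g, %g] s outside the trace", window[1], window[2])
  seg <- avg[i0:i1]
  structure(list(mean = mean(seg), sd = stats::sd(seg)),
            class = "bm_baseline")
}

#' Response magnitude of a cycle-averaged trace
#'
#' Subtracts the blank-derived baseline and takes the peak of the resulting
#' waveform: maximal depolarization for current clamp, maximal inward
#' (negative) current — reported positive — for voltage clamp.
#'
#' @param avg a \code{cycle_avg} from \code{\link{cycle_average}}.
#' @param baseline a \code{bm_baseline} (or a bare numeric baseline mean).
#' @param clamp_mode \code{"current_clamp"} or \code{"voltage_clamp"}.
#' @return scalar response magnitude (mV or pA, peak).
#' @export
response_magnitude <- function(avg, baseline, clamp_mode) {
  clamp_mode <- match.arg(clamp_mode, c("current_clamp", "voltage_clamp"))
  b <- if (inherits(baseline, "bm_baseline")) baseline$mean else baseline
  centered <- avg$waveform - b
  if (clamp_mode == "current_clamp") max(centered) else max(-centered)
}
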