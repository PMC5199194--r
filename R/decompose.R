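#' Intracortical EPSC by point-by-point subtraction
#'
#' The intracortical (cortical) EPSC trace is the total EPSC (LED off) minus
#' the thalamic EPSC (cortex optogenetically silenced, LED on), sample for
#' sample. Both inputs must be cycle-averaged, baseline-subtracted waveforms
#' for the same direction with identical lengths and cycle counts.
#'
#' @param total_avg,thalamic_avg \code{cycle_avg} objects whose waveforms
#'   have had their LED-matched baselines removed.
#' @return a \code{cycle_avg} holding the cortical waveform.
#' @export
subtract_thalamic <- function(total_avg, thalamic_avg) {
  if (length(total_avg$waveform) != length(thalamic_avg$waveform))
    abort("waveform length mismatch: %d vs %d",
          length(total_avg$waveform), length(thalamic_avg$waveform))
  dir_t <- attr(total_avg, "direction")
  dir_th <- attr(thalamic_avg, "direction")
  if (!is.null(dir_t) && !is.null(dir_th) && !identical(dir_t, dir_th))
    abort("direction mismatch: %s vs %s", format(dir_t), format(dir_th))
  if (total_avg$n_cycles_used != thalamic_avg$n_cycles_used)
    abort("cycle-count mismatch (%d vs %d); recompute with a common count",
          total_avg$n_cycles_used, thalamic_avg$n_cycles_used)
  out <- total_avg
  out$waveform <- total_avg$waveform - thalamic_avg$waveform
  out$cycle_amplitudes <- NULL
  attr(out, "input_type") <- "cortical"
  out
}

#' Thalamo-cortical scale factor
#'
#' The fraction of visually evoked excitation that is thalamic: the mean
#' thalamic-EPSC tuning-curve amplitude divided by the mean total-EPSC
#' tuning-curve amplitude, across all directions.
#'
#' @param thalamic_curve,total_curve \code{\link{tuning_curve}} objects for
#'   the same eye.
#' @return dimensionless ratio; NA (with a warning) if the total mean is 0.
#' @export
scale_factor <- function(thalamic_curve, total_curve) {
  if (!identical(thalamic_curve$directions, total_curve$directions))
    abort("curves have different direction sets")
  if (!identical(thalamic_curve$eye, total_curve$eye))
    abort("curves come from different eyes")
  mt <- mean(total_curve$magnitudes)
  if (mt == 0) {
    warning("total-EPSC mean is zero; scale factor undefined")
    return(NA_real_)
  }
  mean(thalamic_curve$magnitudes) / mt
}

# preprocess the sweeps of one (eye, led, stimulus) condition:
# average trials, then filter; current-clamp sweeps are de-spiked per trial
# before averaging (spike transients are trial-specific)
condition_trace <- function(sweeps, clamp_mode, config) {
  rate <- sweeps[[1]]$sampling_rate
  if (clamp_mode == "voltage_clamp") {
    avg <- average_traces(lapply(sweeps, `[[`, "trace"))
    smooth_current(avg, rate, config$mean_window_ms)
  } else {
    cleaned <- lapply(sweeps, function(s)
      remove_spikes(s$trace, rate, config$median_window_ms))
    average_traces(cleaned)
  }
}

#' Full per-cell analysis
#'
#' Runs the whole pipeline on one cell's sweeps: preprocesses every
#' (eye, LED, direction) condition, derives blank baselines per LED state,
#' builds total (LED-off) and thalamic (LED-on) tuning curves, derives the
#' cortical curve by point-by-point subtraction, and computes orientation
#' statistics, inter-ocular differences (\eqn{\Delta O}) per input type,
#' thalamic-total and thalamic-cortical preference differences per eye,
#' scale factors per eye, and contra/ipsi amplitude ratios.
#'
#' Current-clamp cells carry no LED conditions; only the per-eye membrane
#' potential ("total") tuning and its \eqn{\Delta O} are computed, and
#' per-sweep spike counts are reported for QC.
#'
#' If the adaptation rule selects different cycle counts for the LED-off
#' and LED-on traces of a direction, both are recomputed with the smaller
#' count before subtraction, so the subtracted windows are commensurate.
#'
#' @param sweeps list of \code{\link{sweep_record}} for one cell.
#' @param protocol a \code{\link{stim_protocol}}.
#' @param config a \code{\link{bm_config}}.
#' @return object of class \code{cell_result}.
#' @export
assemble_cell <- function(sweeps, protocol, config = bm_config()) {
  if (length(sweeps) == 0L) abort("no sweeps supplied")
  cell_id <- sweeps[[1]]$cell_id
  clamp_mode <- sweeps[[1]]$clamp_mode
  rate <- sweeps[[1]]$sampling_rate
  onset <- sweeps[[1]]$stimulus_onset
  dirs <- protocol_directions(protocol)
  leds <- if (clamp_mode == "voltage_clamp") c("off", "on") else "off"
  polarity <- if (clamp_mode == "current_clamp") 1 else -1
  units <- if (clamp_mode == "current_clamp") "mV" else "pA"

  pick <- function(eye = NULL, led = NULL, stim = NULL) {
    Filter(function(s) {
      (is.null(eye) || s$eye == eye) && (is.null(led) || s$led == led) &&
        (is.null(stim) ||
           (identical(stim, "blank") && is_blank(s)) ||
           (!identical(stim, "blank") && !is_blank(s) &&
              abs(s$stimulus - stim) < 1e-9))
    }, sweeps)
  }

  # blank baselines, pooled across eyes, per LED state
  window <- c(onset, onset + protocol$stimulus_duration)
  baselines <- list()
  for (led in leds) {
    bl <- pick(led = led, stim = "blank")
    if (length(bl) == 0L)
      abort("cell %s: no blank sweeps for LED-%s", cell_id, led)
    traces <- if (clamp_mode == "voltage_clamp")
      lapply(bl, function(s) smooth_current(s$trace, rate, config$mean_window_ms))
    else
      lapply(bl, function(s) remove_spikes(s$trace, rate, config$median_window_ms))
    baselines[[led]] <- compute_baseline(traces, window, rate)
  }

  # per-sweep spike counts (current clamp QC)
  n_spikes <- if (clamp_mode == "current_clamp")
    sum(vapply(sweeps, function(s)
      length(detect_spikes(s$trace, rate, config$dvdt_threshold_mv_per_ms,
                           config$refractory_ms)), 0L))
  else NA_integer_

  curves <- list()
  scale <- c(contra = NA_real_, ipsi = NA_real_)
  adapted_dirs <- 0L
  for (eye in c("contra", "ipsi")) {
    mags <- list()
    ncyc <- list()
    for (input in c("total", "thalamic"))
      mags[[input]] <- ncyc[[input]] <- rep(NA_real_, length(dirs))
    cort_mag <- rep(NA_real_, length(dirs))

    for (j in seq_along(dirs)) {
      avg <- list()
      for (led in leds) {
        sw <- pick(eye, led, dirs[j])
        if (length(sw) == 0L)
          abort("cell %s: missing condition eye=%s led=%s direction=%g",
                cell_id, eye, led, dirs[j])
        tr <- condition_trace(sw, clamp_mode, config)
        avg[[led]] <- cycle_average(tr, protocol, onset,
                                    config$adaptation_ratio_threshold,
                                    baseline = baselines[[led]]$mean,
                                    polarity = polarity)
      }
      if (clamp_mode == "voltage_clamp" &&
          avg$off$n_cycles_used != avg$on$n_cycles_used) {
        n_common <- min(avg$off$n_cycles_used, avg$on$n_cycles_used)
        for (led in leds)
          avg[[led]]$waveform <- cycle_average(
            condition_trace(pick(eye, led, dirs[j]), clamp_mode, config),
            protocol, onset, force_n_cycles = n_common,
            baseline = baselines[[led]]$mean, polarity = polarity)$waveform
        for (led in leds) avg[[led]]$n_cycles_used <- n_common
      }
      if (isTRUE(avg$off$adapted)) adapted_dirs <- adapted_dirs + 1L

      mags$total[j] <- response_magnitude(avg$off, baselines$off, clamp_mode)
      ncyc$total[j] <- avg$off$n_cycles_used
      if (clamp_mode == "voltage_clamp") {
        mags$thalamic[j] <- response_magnitude(avg$on, baselines$on, clamp_mode)
        ncyc$thalamic[j] <- avg$on$n_cycles_used
        off_c <- avg$off; off_c$waveform <- off_c$waveform - baselines$off$mean
        on_c <- avg$on;  on_c$waveform  <- on_c$waveform - baselines$on$mean
        cort <- subtract_thalamic(off_c, on_c)
        cort_mag[j] <- response_magnitude(cort, 0, clamp_mode)
      }
    }

    curves[[paste0(eye, ".total")]] <- build_tuning_curve(
      dirs, mags$total, protocol, baselines$off, eye, "total", clamp_mode,
      units, ncyc$total)
    if (clamp_mode == "voltage_clamp") {
      curves[[paste0(eye, ".thalamic")]] <- build_tuning_curve(
        dirs, mags$thalamic, protocol, baselines$on, eye, "thalamic",
        clamp_mode, units, ncyc$thalamic)
      curves[[paste0(eye, ".cortical")]] <- build_tuning_curve(
        dirs, cort_mag, protocol, NULL, eye, "cortical", clamp_mode, units)
      scale[eye] <- scale_factor(curves[[paste0(eye, ".thalamic")]],
                                 curves[[paste0(eye, ".total")]])
    }
  }

  stats <- lapply(curves, orientation_vector)
  pref <- vapply(stats, `[[`, 0, "pref_O")
  gosi <- vapply(stats, `[[`, 0, "gOSI")

  get_pref <- function(key) if (key %in% names(pref)) pref[[key]] else NA_real_
  dO <- c(total = delta_orientation(get_pref("contra.total"), get_pref("ipsi.total")),
          thalamic = delta_orientation(get_pref("contra.thalamic"), get_pref("ipsi.thalamic")),
          cortical = delta_orientation(get_pref("contra.cortical"), get_pref("ipsi.cortical")))
  tt_diff <- c(contra = delta_orientation(get_pref("contra.thalamic"), get_pref("contra.total")),
               ipsi = delta_orientation(get_pref("ipsi.thalamic"), get_pref("ipsi.total")))
  tc_diff <- c(contra = delta_orientation(get_pref("contra.thalamic"), get_pref("contra.cortical")),
               ipsi = delta_orientation(get_pref("ipsi.thalamic"), get_pref("ipsi.cortical")))

  ci_ratio <- function(input) {
    kc <- paste0("contra.", input); ki <- paste0("ipsi.", input)
    if (!kc %in% names(curves)) return(NA_real_)
    mi <- mean(curves[[ki]]$magnitudes)
    if (mi == 0) return(NA_real_)
    mean(curves[[kc]]$magnitudes) / mi
  }

  structure(list(
    cell_id = cell_id, clamp_mode = clamp_mode,
    curves = curves, stats = stats,
    pref_O = pref, gOSI = gosi,
    dO = dO, thal_total_diff = tt_diff, thal_cort_diff = tc_diff,
    scale_factor = scale,
    ci_ratio_total = ci_ratio("total"),
    ci_ratio_thalamic = ci_ratio("thalamic"),
    baselines = baselines,
    qc = list(
      n_spikes = n_spikes,
      adapted_directions = adapted_dirs,
      frac_clipped = vapply(stats, `[[`, 0, "frac_clipped"),
      undefined_pref = names(pref)[is.na(pref)])),
    class = "cell_result")
}

#' @export
print.cell_result <- function(x, ...) {
  cat(sprintf("<cell_result> %s (%s)\n", x$cell_id, x$clamp_mode))
  tab <- data.frame(condition = names(x$pref_O),
                    pref_O = round(x$pref_O, 1),
                    gOSI = round(x$gOSI, 3), row.names = NULL)
  print(tab)
  cat(sprintf("  dO: total=%.1f thalamic=%.1f cortical=%.1f\n",
              x$dO["total"], x$dO["thalamic"], x$dO["cortical"]))
  if (!all(is.na(x$scale_factor)))
    cat(sprintf("  scale factor: contra=%.3f ipsi=%.3f; C/I ratio total=%.2f thal=%.2f\n",
                x$scale_factor["contra"], x$scale_factor["ipsi"],
                x$ci_ratio_total, x$ci_ratio_thalamic))
  invisible(x)
}
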