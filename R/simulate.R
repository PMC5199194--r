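#' Cohort presets for the synthetic generator
#'
#' Target means (degrees) and scale factors for the two developmental
#' stages: "young" (P15-21, before the critical period) and "adult"
#' (P60-90). The inter-ocular thalamic difference and the per-eye
#' thalamic-cortical preference differences are drawn from folded normals
#' calibrated so their analytic means equal these targets; scale factors
#' are the cohort means of the thalamic/total EPSC ratio.
#'
#' @param cohort \code{"adult"} or \code{"young"}.
#' @return named list of preset parameters.
#' @export
cohort_presets <- function(cohort = c("adult", "young")) {
  cohort <- match.arg(cohort)
  switch(cohort,
    adult = list(d_thal_mean = 19.6,
                 tc_diff_mean = c(contra = 17.0, ipsi = 22.4),
                 scale_mean = c(contra = 0.32, ipsi = 0.32)),
    young = list(d_thal_mean = 30.9,
                 tc_diff_mean = c(contra = 35.8, ipsi = 49.0),
                 scale_mean = c(contra = 0.43, ipsi = 0.52)))
}

#' Synthetic-recording generator configuration
#'
#' Assembles all parameters of the synthetic experiment. Cohort presets
#' fill the orientation-difference targets and scale factors; everything
#' else defaults to values chosen for realism at 10 kHz in vivo whole-cell
#' recordings (see the methods vignette).
#'
#' @param cohort \code{"adult"}, \code{"young"} or \code{"custom"} (with
#'   \code{custom} supply the preset fields yourself via \code{...}).
#' @param n_cells number of cells.
#' @param seed master seed; all randomness derives from it.
#' @param clamp_mode \code{"voltage_clamp"} or \code{"current_clamp"}.
#' @param noise_sd trace noise SD (pA for voltage clamp, mV for current
#'   clamp); defaults 10 pA / 0.5 mV.
#' @param n_trials repeats per condition (default 2).
#' @param ci_ratio contralateral/ipsilateral amplitude ratio (default 2).
#' @param ... overrides for any field (e.g. \code{d_thal_mean},
#'   \code{tc_diff_mean}, \code{scale_mean}, \code{scale_sd}, \code{kappa},
#'   \code{tune_offset}, \code{amp_mean_pa}, \code{amp_mean_mv},
#'   \code{amp_sdlog}, \code{spike_threshold_mv}, \code{adapt_factor},
#'   \code{phase_jitter_sd}).
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(cohort = c("adult", "young", "custom"),
                             n_cells = 15L, seed = 1L,
                             clamp_mode = c("voltage_clamp", "current_clamp"),
                             noise_sd = NULL, n_trials = 2L,
                             ci_ratio = 2.0, ...) {
  cohort <- match.arg(cohort)
  clamp_mode <- match.arg(clamp_mode)
  cfg <- list(
    cohort = cohort, n_cells = as.integer(n_cells), seed = as.integer(seed),
    clamp_mode = clamp_mode, n_trials = as.integer(n_trials),
    ci_ratio = ci_ratio,
    # tuning shape: von-Mises-style bump on the orientation cycle
    kappa = 1.0, tune_offset = 0.1,
    # amplitudes
    amp_mean_pa = 100, amp_mean_mv = 15, amp_sdlog = 0.3,
    scale_sd = 0.1,
    # trace layout
    stimulus_onset = 0.2, tail_s = 0.15,
    hold_off_pa = -50, hold_on_pa = -80, rest_mv = -60,
    spike_threshold_mv = -50,
    adapt_factor = 1.0, phase_jitter_sd = 0,
    # membrane-like low-pass on the noise (ms; 0 = white). Current-clamp
    # noise is filtered by default: the membrane time constant makes Vm
    # fluctuations slow, and white noise at 10 kHz would swamp any dV/dt
    # spike detector with unphysical derivatives.
    noise_filter_ms = if (clamp_mode == "current_clamp") 15 else 0,
    noise_sd = noise_sd %||%
      (if (clamp_mode == "voltage_clamp") 10 else 2))
  if (cohort != "custom") cfg <- c(cfg, cohort_presets(cohort))
  dots <- list(...)
  cfg[names(dots)] <- dots
  need <- c("d_thal_mean", "tc_diff_mean", "scale_mean")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    abort("custom cohort requires fields: %s", paste(miss, collapse = ", "))
  if (cfg$ci_ratio <= 0 || any(unlist(cfg[c("kappa", "amp_mean_pa")]) <= 0))
    abort("scale parameters and ci_ratio must be positive")
  class(cfg) <- "generator_config"
  cfg
}

# mean of |N(0, sigma)| folded onto [0, 90] along the 180-degree cycle
folded_wrap_mean <- function(sigma) {
  stats::integrate(function(x) {
    y <- x %% 180
    pmin(y, 180 - y) * 2 * stats::dnorm(x, 0, sigma)
  }, 0, Inf, subdivisions = 2000L, rel.tol = 1e-10)$value
}

# sigma such that folded_wrap_mean(sigma) == target; the family's mean
# saturates at 45 (uniform limit), so targets >= 44.5 map to Inf and the
# draw falls back to Uniform(0, 90)
fold_scale_for_mean <- function(target) {
  if (target <= 0) return(0)
  if (target >= 44.5) return(Inf)
  stats::uniroot(function(s) folded_wrap_mean(s) - target,
                 c(1e-3, 500), tol = 1e-8)$root
}

# draw n orientation differences with analytic mean `target`
sample_delta <- function(n, target) {
  if (target <= 0) return(rep(0, n))
  s <- fold_scale_for_mean(target)
  if (!is.finite(s)) return(stats::runif(n, 0, 90))
  x <- abs(stats::rnorm(n, 0, s)) %% 180
  pmin(x, 180 - x)
}

# von-Mises-style tuning bump on the 180-degree orientation cycle,
# peak 1 at pref, floor `offset`
tune_shape <- function(theta, pref, kappa, offset) {
  offset + (1 - offset) *
    exp(kappa * (cos(2 * (theta - pref) * pi / 180) - 1))
}

# half-rectified 2 Hz modulation over the stimulus period, with optional
# third-cycle adaptation factor and phase offset (radians)
modulation <- function(t, onset, protocol, adapt_factor = 1, phase = 0) {
  tf <- protocol$temporal_frequency
  rel <- t - onset
  m <- pmax(0, sin(2 * pi * tf * rel + phase))
  m[rel < 0 | rel >= protocol$stimulus_duration] <- 0
  if (adapt_factor != 1) {
    third <- rel >= 2 / tf & rel < protocol$stimulus_duration
    m[third] <- m[third] * adapt_factor
  }
  m
}

#' Generate one synthetic cell
#'
#' Draws the cell's ground truth (thalamic preferred orientation per eye,
#' cortical preferred orientation per eye, amplitude, scale factor) and
#' synthesizes every sweep: for each eye, direction and trial, the
#' thalamic component \eqn{T_e(\theta) = A_e s_e \mathrm{tune}(\theta)} and
#' cortical component \eqn{C_e(\theta) = A_e (1 - s_e) \mathrm{tune}(\theta)}
#' modulate a half-rectified 2 Hz sinusoid; LED-off sweeps carry T + C,
#' LED-on sweeps carry T only, blanks carry baseline + noise. Current-clamp
#' cells express the summed input as depolarization and get stereotyped
#' 1.5 ms spike waveforms injected wherever the noiseless trace crosses the
#' spike threshold (injection times recorded in the ground truth).
#'
#' @param config a \code{\link{generator_config}}.
#' @param cell_seed integer seed for this cell.
#' @param cell_id identifier.
#' @return list with \code{sweeps} (list of \code{\link{sweep_record}}) and
#'   \code{truth} (one-row data frame).
#' @export
generate_cell <- function(config, cell_seed, cell_id = "cell") {
  set.seed(cell_seed)
  protocol <- stim_protocol()
  dirs <- protocol_directions(protocol)
  rate <- protocol$sampling_rate
  onset <- config$stimulus_onset
  dur <- onset + (protocol$n_cycles - 1) * cycle_period(protocol) +
    protocol$cycle_window_end + config$tail_s
  n_samp <- round(dur * rate)
  t <- (seq_len(n_samp) - 1) / rate
  vc <- config$clamp_mode == "voltage_clamp"

  # ground-truth draws
  th <- c(contra = stats::runif(1, -90, 90), ipsi = NA)
  d_th <- sample_delta(1, config$d_thal_mean) * sample(c(-1, 1), 1)
  th["ipsi"] <- wrap_orientation(th["contra"] + d_th)
  cort <- c(contra = NA_real_, ipsi = NA_real_)
  for (eye in c("contra", "ipsi"))
    cort[eye] <- wrap_orientation(
      th[eye] + sample_delta(1, config$tc_diff_mean[[eye]]) * sample(c(-1, 1), 1))
  A <- c(contra = if (vc) stats::rlnorm(1, log(config$amp_mean_pa), config$amp_sdlog)
                  else stats::rlnorm(1, log(config$amp_mean_mv), config$amp_sdlog))
  A["ipsi"] <- A["contra"] / config$ci_ratio
  s <- c(contra = NA_real_, ipsi = NA_real_)
  for (eye in c("contra", "ipsi"))
    s[eye] <- min(1, max(0.02,
      stats::rnorm(1, config$scale_mean[[eye]], config$scale_sd)))

  # analytic preferred orientation of the summed (total) input: the tuning
  # shapes are identical up to placement, so the vector sum reduces to a
  # weighted mean in doubled-angle space
  total_pref <- vapply(c("contra", "ipsi"), function(eye) {
    z <- s[eye] * exp(2i * th[eye] * pi / 180) +
      (1 - s[eye]) * exp(2i * cort[eye] * pi / 180)
    wrap_orientation(Arg(z) / 2 * 180 / pi)
  }, 0)

  leds <- if (vc) c("off", "on") else "off"
  sweeps <- list()
  spike_times <- list()
  spike_wave <- local({  # 1.5 ms triangular transient, 55 mV peak
    n_up <- round(0.0005 * rate); n_dn <- round(0.0010 * rate)
    55 * c(seq_len(n_up) / n_up, rev(seq_len(n_dn)) / n_dn)
  })

  add_sweep <- function(eye, led, stim, trial, trace)
    sweeps[[length(sweeps) + 1]] <<- sweep_record(
      cell_id, config$clamp_mode, eye, led, stim, trial, trace, onset, rate)

  m_fixed <- if (config$phase_jitter_sd > 0) NULL else
    modulation(t, onset, protocol, config$adapt_factor)

  draw_noise <- function() {
    if (config$noise_sd <= 0) return(0)
    n <- stats::rnorm(n_samp, 0, config$noise_sd)
    if (config$noise_filter_ms > 0) {
      n <- smooth_current(n, rate, config$noise_filter_ms)
      n <- n * config$noise_sd / stats::sd(n)  # restore the target SD
    }
    n
  }

  for (eye in c("contra", "ipsi")) {
    # drawn preferences are orientations (pref_O convention); the response
    # peaks at the drift directions perpendicular to them (pref_O + 90 and
    # pref_O + 270, identical in the doubled-angle space)
    amp_T <- A[eye] * s[eye] *
      tune_shape(dirs, th[eye] + 90, config$kappa, config$tune_offset)
    amp_C <- A[eye] * (1 - s[eye]) *
      tune_shape(dirs, cort[eye] + 90, config$kappa, config$tune_offset)
    for (led in leds) {
      amp <- if (led == "off") amp_T + amp_C else amp_T
      for (j in seq_along(dirs)) {
        for (trial in seq_len(config$n_trials)) {
          m <- m_fixed %||% modulation(t, onset, protocol, config$adapt_factor,
                                       stats::rnorm(1, 0, config$phase_jitter_sd))
          noise <- draw_noise()
          if (vc) {
            hold <- if (led == "off") config$hold_off_pa else config$hold_on_pa
            trace <- hold - amp[j] * m + noise
          } else {
            clean <- config$rest_mv + amp[j] * m
            trace <- clean + noise
            cross <- which(clean >= config$spike_threshold_mv &
                             c(-Inf, clean[-n_samp]) < config$spike_threshold_mv)
            for (i0 in cross) {
              idx <- i0:min(n_samp, i0 + length(spike_wave) - 1)
              trace[idx] <- trace[idx] + spike_wave[seq_along(idx)]
            }
            if (length(cross))
              spike_times[[length(spike_times) + 1]] <- (cross - 1) / rate
          }
          add_sweep(eye, led, dirs[j], trial, trace)
        }
      }
    }
  }
  # blanks: baseline + noise, per LED state
  for (led in leds) {
    base <- if (vc) {
      if (led == "off") config$hold_off_pa else config$hold_on_pa
    } else config$rest_mv
    for (trial in seq_len(config$n_trials)) {
      add_sweep("contra", led, "blank", trial, rep(base, n_samp) + draw_noise())
    }
  }

  truth <- data.frame(
    cell_id = cell_id, clamp_mode = config$clamp_mode,
    thal_pref_contra = unname(th["contra"]), thal_pref_ipsi = unname(th["ipsi"]),
    cort_pref_contra = unname(cort["contra"]), cort_pref_ipsi = unname(cort["ipsi"]),
    total_pref_contra = unname(total_pref["contra"]),
    total_pref_ipsi = unname(total_pref["ipsi"]),
    amp_contra = unname(A["contra"]), amp_ipsi = unname(A["ipsi"]),
    scale_contra = unname(s["contra"]), scale_ipsi = unname(s["ipsi"]),
    dO_thal = delta_orientation(th[["contra"]], th[["ipsi"]]),
    dO_total = delta_orientation(total_pref[["contra"]], total_pref[["ipsi"]]),
    n_spikes = length(unlist(spike_times)),
    stringsAsFactors = FALSE)
  attr(truth, "spike_times") <- unlist(spike_times)
  list(sweeps = sweeps, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Deterministically derives one seed per cell from the master seed, calls
#' \code{\link{generate_cell}} for each, and packs the sweeps into a
#' \code{\link{bm_dataset}} alongside the ground-truth table. The ground
#' truth is never consulted by the analysis pipeline.
#'
#' @param config a \code{\link{generator_config}}.
#' @return list with \code{dataset} (\code{bm_dataset}) and \code{truth}
#'   (data frame, one row per cell).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cells <- list()
  truths <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    cid <- sprintf("cell_%03d", i)
    cell_seed <- (config$seed + i * 10007L) %% .Machine$integer.max
    g <- generate_cell(config, cell_seed, cid)
    cells[[cid]] <- g$sweeps
    truths[[i]] <- g$truth
  }
  dataset <- bm_dataset(stim_protocol(), cells,
                        provenance = list(cohort = config$cohort,
                                          seed = config$seed,
                                          clamp_mode = config$clamp_mode,
                                          synthetic = TRUE))
  truth <- if (config$n_cells > 0) do.call(rbind, truths) else
    data.frame()
  list(dataset = dataset, truth = truth)
}

#' Random preference pairs under the uniform null
#'
#' Independent preferred-orientation pairs, each coordinate uniform on
#' \code{[-90, 90)} — the null model of unmatched binocular tuning. The
#' circular difference of such a pair is Uniform(0, 90) with mean 45
#' degrees.
#'
#' @param n number of pairs.
#' @param seed optional integer seed.
#' @return n x 2 matrix of preferred orientations in degrees.
#' @export
random_preference_pairs <- function(n, seed = NULL) {
  if (!is_count(n) || n < 1) abort("n must be a positive count")
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(2 * n, -90, 90), ncol = 2,
         dimnames = list(NULL, c("contra", "ipsi")))
}
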