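rate <- 10000

test_that("spike detection finds injected spikes and ignores slow signals", {
  # constant trace: zero derivative everywhere
  expect_length(detect_spikes(rep(-60, 5000), rate), 0)

  # pure 2 Hz, 5 mV sinusoid: max dV/dt = 5 * 2*pi*2 / 1000 ~ 0.063 mV/ms
  t <- (0:19999) / rate
  expect_length(detect_spikes(-60 + 5 * sin(2 * pi * 2 * t), rate, 10), 0)

  # three stereotyped spikes at known times
  spike <- 60 * c(seq(0, 1, length.out = 5), seq(1, 0, length.out = 10)[-1])
  tr <- rep(-60, 20000)
  inject_at <- c(0.30, 0.85, 1.44)
  for (ti in inject_at) {
    i0 <- round(ti * rate) + 1
    tr[i0:(i0 + length(spike) - 1)] <- tr[i0:(i0 + length(spike) - 1)] + spike
  }
  got <- detect_spikes(tr, rate, 10)
  expect_length(got, 3)
  expect_true(all(abs(got - inject_at) < 0.001))
})

test_that("detect_spikes validates its inputs", {
  expect_error(detect_spikes(rep(0, 100), rate, -1), "positive")
  expect_error(detect_spikes(c(1), rate, 10), "2 samples")
})

test_that("median filter removes spikes but preserves slow structure", {
  # constants and linear ramps are fixed points (interior)
  expect_equal(remove_spikes(rep(-60, 1000), rate), rep(-60, 1000))
  ramp <- seq(-70, -50, length.out = 2000)
  out <- remove_spikes(ramp, rate)
  expect_equal(out[100:1900], ramp[100:1900], tolerance = 1e-12)

  # a 1.5 ms, 50 mV transient is erased to < 1 mV residue
  t <- (0:9999) / rate
  base <- -60 + 3 * sin(2 * pi * 2 * t)
  tr <- base
  i0 <- 4000
  tr[i0:(i0 + 14)] <- tr[i0:(i0 + 14)] + 50
  cleaned <- remove_spikes(tr, rate)
  expect_lt(max(abs(cleaned - base)), 1)
})

test_that("mean filter averages white noise down by sqrt(W)", {
  expect_equal(smooth_current(rep(-50, 2000), rate), rep(-50, 2000))

  # unit impulse -> rectangle of height 1/W
  w <- round(0.040 * rate)
  x <- rep(0, 5000); x[2500] <- 1
  y <- smooth_current(x, rate)
  expect_equal(max(y), 1 / w, tolerance = 1e-12)
  expect_equal(sum(y > 1e-15), w)

  set.seed(1)
  x <- rnorm(200000, 0, 4)
  y <- smooth_current(x, rate)
  expect_equal(sd(y), 4 / sqrt(w), tolerance = 0.1)
})

test_that("filters match the brute-force definitions on random traces", {
  set.seed(7)
  for (rep_i in 1:25) {
    n <- sample(200:600, 1)
    r2 <- sample(c(1000, 2000, 5000), 1)  # shorter windows for small traces
    x <- rnorm(n)
    wm <- round(0.006 * r2); if (wm %% 2 == 0) wm <- wm + 1
    expect_equal(remove_spikes(x, r2), brute_median_filter(x, wm),
                 tolerance = 1e-12)
    wmu <- round(0.040 * r2)
    expect_equal(smooth_current(x, r2), brute_mean_filter(x, wmu),
                 tolerance = 1e-12)
  }
})

test_that("filters commute with additive offsets", {
  set.seed(2)
  x <- rnorm(3000)
  expect_equal(remove_spikes(x + 7, rate), remove_spikes(x, rate) + 7,
               tolerance = 1e-12)
  expect_equal(smooth_current(x + 7, rate), smooth_current(x, rate) + 7,
               tolerance = 1e-12)
})

make_cycle_trace <- function(amps, onset = 0.2, baseline = 0) {
  n <- round((onset + 1.7) * rate)
  t <- (seq_len(n) - 1) / rate
  tr <- rep(baseline, n)
  for (k in 0:2) {
    seg <- t >= onset + k * 0.5 & t < onset + (k + 1) * 0.5
    tr[seg] <- baseline + amps[k + 1] * pmax(0, sin(2 * pi * 2 * (t[seg] - onset)))
  }
  tr
}

test_that("cycle averaging implements the adaptation rule", {
  p <- stim_protocol()

  # three identical cycles (periodic trace): waveform equals any single
  # cycle's window, 3 cycles used
  t <- (seq_len(round(1.9 * rate)) - 1) / rate
  tr <- pmax(0, sin(2 * pi * 2 * (t - 0.2)))
  ca <- cycle_average(tr, p, 0.2, baseline = 0, polarity = 1)
  expect_equal(ca$n_cycles_used, 3L)
  ref <- brute_cycle_average(tr, rate, 0.2, 2, 3)
  expect_equal(ca$waveform, ref$windows[[1]], tolerance = 1e-12)
  expect_equal(ca$waveform, ref$windows[[3]], tolerance = 1e-12)
  expect_equal(max(ca$waveform), 1, tolerance = 0.01)

  # third-cycle amplitude 0.3 < 0.5 * mean(1, 1): adaptation, 2 cycles
  tr <- make_cycle_trace(c(1, 1, 0.3))
  ca <- cycle_average(tr, p, 0.2, adaptation_ratio_threshold = 0.5,
                      baseline = 0, polarity = 1)
  expect_equal(ca$n_cycles_used, 2L)
  ref <- brute_cycle_average(tr, rate, 0.2, 2, 3)
  expect_equal(ca$waveform, ref$avg2, tolerance = 1e-12)
  expect_equal(max(ca$waveform), 1, tolerance = 0.01)

  # amplitude 0.6 >= threshold: all three cycles averaged
  tr <- make_cycle_trace(c(1, 1, 0.6))
  ca <- cycle_average(tr, p, 0.2, adaptation_ratio_threshold = 0.5,
                      baseline = 0, polarity = 1)
  expect_equal(ca$n_cycles_used, 3L)
  expect_equal(ca$waveform, brute_cycle_average(tr, rate, 0.2, 2, 3)$avg3,
               tolerance = 1e-12)
})

test_that("cycle averaging is linear at fixed cycle count and validates input", {
  p <- stim_protocol()
  tr1 <- make_cycle_trace(c(1, 0.9, 0.8))
  tr2 <- make_cycle_trace(c(0.5, 0.7, 1))
  w12 <- cycle_average(tr1 + tr2, p, 0.2, force_n_cycles = 3)$waveform
  w1 <- cycle_average(tr1, p, 0.2, force_n_cycles = 3)$waveform
  w2 <- cycle_average(tr2, p, 0.2, force_n_cycles = 3)$waveform
  expect_equal(w12, w1 + w2, tolerance = 1e-12)

  expect_error(cycle_average(tr1[1:1000], p, 0.2), "too short")
  tr1[5] <- NA
  expect_error(cycle_average(tr1, p, 0.2), "non-finite")
})

test_that("blank-derived baselines have the expected moments", {
  b <- compute_baseline(list(rep(-60, 20000)), c(0.2, 1.7), rate)
  expect_equal(b$mean, -60)
  expect_equal(b$sd, 0)

  # unit sinusoid over whole cycles: mean -60, sd 1/sqrt(2)
  t <- (0:19999) / rate
  tr <- -60 + sin(2 * pi * 2 * (t - 0.2))
  b <- compute_baseline(list(tr), c(0.2, 1.7), rate)
  expect_equal(b$mean, -60, tolerance = 0.01)
  expect_equal(b$sd, 1 / sqrt(2), tolerance = 0.02 / sqrt(2))

  # two constant blanks average to a constant: sd of the average is 0
  b <- compute_baseline(list(rep(-58, 20000), rep(-62, 20000)),
                        c(0.2, 1.7), rate)
  expect_equal(b$mean, -60)
  expect_equal(b$sd, 0)

  expect_error(compute_baseline(list(), c(0, 1), rate), "no blank")
})

test_that("response magnitude is the baseline-subtracted peak, by polarity", {
  p <- stim_protocol()
  t <- (seq_len(round(1.9 * rate)) - 1) / rate

  flat <- cycle_average(rep(-60, length(t)), p, 0.2, baseline = -60)
  b <- structure(list(mean = -60, sd = 0), class = "bm_baseline")
  expect_equal(response_magnitude(flat, b, "current_clamp"), 0)

  vm <- -60 + 8 * pmax(0, sin(2 * pi * 2 * (t - 0.2))) *
    (t >= 0.2 & t < 1.7)
  ca <- cycle_average(vm, p, 0.2, baseline = -60, polarity = 1)
  expect_equal(response_magnitude(ca, b, "current_clamp"), 8,
               tolerance = 0.01 * 8)

  im <- -10 - 40 * pmax(0, sin(2 * pi * 2 * (t - 0.2))) *
    (t >= 0.2 & t < 1.7)
  bi <- structure(list(mean = -10, sd = 0), class = "bm_baseline")
  ci <- cycle_average(im, p, 0.2, baseline = -10, polarity = -1)
  expect_equal(response_magnitude(ci, bi, "voltage_clamp"), 40,
               tolerance = 0.01 * 40)

  # invariance to common offsets of waveform and baseline
  ca2 <- ca; ca2$waveform <- ca$waveform + 5
  b2 <- structure(list(mean = -55, sd = 0), class = "bm_baseline")
  expect_equal(response_magnitude(ca2, b2, "current_clamp"),
               response_magnitude(ca, b, "current_clamp"), tolerance = 1e-12)
})

test_that("the noiseless filter chain recovers amplitudes within 2%", {
  # 40 ms mean filter attenuates the 2 Hz fundamental by sinc(0.08) ~ 0.989
  p <- stim_protocol()
  amps <- c(3, 10, 40)
  for (a in amps) {
    tr <- -50 - a * make_cycle_trace(c(1, 1, 1)) # inward current bump
    sm <- smooth_current(tr, rate)
    ca <- cycle_average(sm, p, 0.2, baseline = -50, polarity = -1)
    b <- structure(list(mean = -50, sd = 0), class = "bm_baseline")
    got <- response_magnitude(ca, b, "voltage_clamp")
    expect_equal(got, a, tolerance = 0.02 * a)
  }
})
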