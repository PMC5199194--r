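p12 <- stim_protocol()
dirs <- protocol_directions(p12)

test_that("point-by-point subtraction obeys the additive identities", {
  w <- sin(seq(0, pi, length.out = 5000))
  mk <- function(wave) structure(list(waveform = wave, n_cycles_used = 3L),
                                 class = "cycle_avg")
  total <- mk(-3 * w)
  zero <- mk(rep(0, 5000))
  expect_equal(subtract_thalamic(total, zero)$waveform, total$waveform)
  expect_equal(subtract_thalamic(total, total)$waveform, rep(0, 5000))
  expect_error(subtract_thalamic(total, mk(rep(0, 10))), "length")
  bad <- mk(-w); bad$n_cycles_used <- 2L
  expect_error(subtract_thalamic(total, bad), "cycle-count")
})

test_that("subtraction recovers the generator's cortical component exactly", {
  cfg <- generator_config("adult", n_cells = 1, seed = 59, noise_sd = 0)
  g <- generate_cell(cfg, 59, "c1")
  proto <- stim_protocol()
  sweeps <- g$sweeps
  pickd <- function(led, d) Filter(function(s)
    s$eye == "contra" && s$led == led && identical(s$stimulus, d), sweeps)
  blank <- function(led) Filter(function(s)
    s$led == led && identical(s$stimulus, "blank"), sweeps)

  for (d in c(0, 90, 240)) {
    off_raw <- Reduce(`+`, lapply(pickd("off", d), `[[`, "trace")) /
      length(pickd("off", d))
    on_raw <- Reduce(`+`, lapply(pickd("on", d), `[[`, "trace")) /
      length(pickd("on", d))
    # noiseless: cortical raw component = off - on + (hold_off - hold_on)
    cort_truth <- off_raw - on_raw - (cfg$hold_off_pa - cfg$hold_on_pa)

    ca_off <- cycle_average(off_raw, proto, 0.2, baseline = cfg$hold_off_pa,
                            polarity = -1)
    ca_on <- cycle_average(on_raw, proto, 0.2, baseline = cfg$hold_on_pa,
                           polarity = -1)
    ca_off$waveform <- ca_off$waveform - cfg$hold_off_pa
    ca_on$waveform <- ca_on$waveform - cfg$hold_on_pa
    cort <- subtract_thalamic(ca_off, ca_on)
    ref <- cycle_average(cort_truth, proto, 0.2, baseline = 0, polarity = -1)
    peak <- max(abs(ref$waveform))
    expect_lt(max(abs(cort$waveform - ref$waveform)),
              1e-9 * max(peak, 1))
  }
})

test_that("scale factor is the ratio of tuning-curve means", {
  total <- build_tuning_curve(dirs, runif(12, 5, 50), p12,
                              input_type = "total")
  thal <- build_tuning_curve(dirs, 0.32 * total$magnitudes, p12,
                             input_type = "thalamic")
  expect_equal(scale_factor(thal, total), 0.32, tolerance = 1e-12)
  expect_equal(scale_factor(total, total), 1)

  set.seed(61)
  for (i in 1:20) {
    a <- runif(12, 0, 30); b <- runif(12, 1, 30)
    ca <- build_tuning_curve(dirs, a, p12, input_type = "thalamic")
    cb <- build_tuning_curve(dirs, b, p12, input_type = "total")
    expect_equal(scale_factor(ca, cb), mean(a) / mean(b), tolerance = 1e-12)
    # joint rescaling leaves the ratio unchanged
    ca2 <- build_tuning_curve(dirs, 5.5 * a, p12, input_type = "thalamic")
    cb2 <- build_tuning_curve(dirs, 5.5 * b, p12, input_type = "total")
    expect_equal(scale_factor(ca2, cb2), scale_factor(ca, cb),
                 tolerance = 1e-12)
  }

  zero <- build_tuning_curve(dirs, rep(0, 12), p12, input_type = "total")
  expect_warning(sf <- scale_factor(thal, zero), "zero")
  expect_true(is.na(sf))
})

test_that("assemble_cell recovers ground truth on noiseless cells", {
  cfg <- generator_config("young", n_cells = 3, seed = 67, noise_sd = 0)
  sim <- generate_cohort(cfg)
  for (i in seq_len(3)) {
    cid <- sprintf("cell_%03d", i)
    r <- assemble_cell(sim$dataset$cells[[cid]], sim$dataset$protocol)
    tr <- sim$truth[i, ]
    expect_lt(delta_orientation(r$pref_O[["contra.thalamic"]],
                                tr$thal_pref_contra), 1)
    expect_lt(delta_orientation(r$pref_O[["ipsi.thalamic"]],
                                tr$thal_pref_ipsi), 1)
    expect_lt(delta_orientation(r$pref_O[["contra.cortical"]],
                                tr$cort_pref_contra), 1)
    expect_lt(delta_orientation(r$pref_O[["contra.total"]],
                                tr$total_pref_contra), 1)
    expect_lt(abs(r$dO[["thalamic"]] - tr$dO_thal), 1)
    expect_lt(abs(r$dO[["total"]] - tr$dO_total), 1)
    expect_lt(abs(r$scale_factor[["contra"]] - tr$scale_contra), 0.02)
    expect_lt(abs(r$scale_factor[["ipsi"]] - tr$scale_ipsi), 0.02)
    expect_equal(r$ci_ratio_total, cfg$ci_ratio, tolerance = 0.05)
  }
})

test_that("a matched noiseless cell has all inter-ocular differences at 0", {
  cfg <- generator_config("custom", n_cells = 1, seed = 71, noise_sd = 0,
                          d_thal_mean = 0,
                          tc_diff_mean = c(contra = 0, ipsi = 0),
                          scale_mean = c(contra = 0.4, ipsi = 0.4),
                          scale_sd = 0)
  sim <- generate_cohort(cfg)
  r <- assemble_cell(sim$dataset$cells[[1]], sim$dataset$protocol)
  expect_lt(r$dO[["total"]], 1)
  expect_lt(r$dO[["thalamic"]], 1)
  expect_lt(r$dO[["cortical"]], 1)
  expect_lt(r$thal_cort_diff[["contra"]], 1)
})

test_that("an all-thalamic cell yields a vanishing cortical component", {
  cfg <- generator_config("custom", n_cells = 1, seed = 73, noise_sd = 0,
                          d_thal_mean = 10,
                          tc_diff_mean = c(contra = 20, ipsi = 20),
                          scale_mean = c(contra = 0.95, ipsi = 0.95),
                          scale_sd = 0)
  sim <- generate_cohort(cfg)
  r <- assemble_cell(sim$dataset$cells[[1]], sim$dataset$protocol)
  expect_equal(r$scale_factor[["contra"]], 0.95, tolerance = 0.02)
  # cortical magnitudes are ~5% of total
  cort <- r$curves[["contra.cortical"]]$magnitudes
  tot <- r$curves[["contra.total"]]$magnitudes
  expect_lt(max(cort) / max(tot), 0.1)
})

test_that("assemble_cell reports missing conditions", {
  cfg <- generator_config("adult", n_cells = 1, seed = 79, noise_sd = 0)
  sweeps <- generate_cohort(cfg)$dataset$cells[[1]]
  no_on <- Filter(function(s) s$led == "off", sweeps)
  expect_error(assemble_cell(no_on, stim_protocol()), "no blank|missing condition")
  drop_dir <- Filter(function(s) !(!is.na(suppressWarnings(as.numeric(s$stimulus))) &&
                                     identical(s$stimulus, 90)), sweeps)
  expect_error(assemble_cell(drop_dir, stim_protocol()),
               "missing condition.*90")
})
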