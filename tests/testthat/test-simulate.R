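test_that("cohort generation is seed-deterministic", {
  cfg <- generator_config("adult", n_cells = 2, seed = 101)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$dataset$cells, b$dataset$cells)
  expect_identical(a$truth, b$truth)

  c2 <- generate_cohort(generator_config("adult", n_cells = 2, seed = 102))
  expect_false(identical(a$dataset$cells[[1]][[1]]$trace,
                         c2$dataset$cells[[1]][[1]]$trace))
})

test_that("an empty cohort is a valid empty dataset", {
  cfg <- generator_config("adult", n_cells = 0, seed = 1)
  sim <- generate_cohort(cfg)
  expect_length(sim$dataset$cells, 0)
  expect_equal(nrow(sim$truth), 0)
})

test_that("LED-off minus LED-on equals the cortical component when noiseless", {
  cfg <- generator_config("young", n_cells = 1, seed = 103, noise_sd = 0)
  sweeps <- generate_cell(cfg, 103, "c")$sweeps
  for (eye in c("contra", "ipsi")) {
    off <- Filter(function(s) s$eye == eye && s$led == "off" &&
                    identical(s$stimulus, 60) && s$trial_index == 1, sweeps)[[1]]
    on <- Filter(function(s) s$eye == eye && s$led == "on" &&
                   identical(s$stimulus, 60) && s$trial_index == 1, sweeps)[[1]]
    cortical <- (off$trace - cfg$hold_off_pa) - (on$trace - cfg$hold_on_pa)
    # the cortical component is a non-positive (inward) scaled modulation
    expect_lte(max(cortical), 1e-12)
    expect_gt(max(abs(cortical)), 0)
  }
})

test_that("an all-thalamic cell has identical LED-on and LED-off responses", {
  cfg <- generator_config("custom", n_cells = 1, seed = 104, noise_sd = 0,
                          d_thal_mean = 15,
                          tc_diff_mean = c(contra = 20, ipsi = 20),
                          scale_mean = c(contra = 1, ipsi = 1), scale_sd = 0,
                          hold_off_pa = -50, hold_on_pa = -50)
  sweeps <- generate_cell(cfg, 104, "c")$sweeps
  off <- Filter(function(s) s$led == "off" && identical(s$stimulus, 0) &&
                  s$eye == "contra" && s$trial_index == 1, sweeps)[[1]]
  on <- Filter(function(s) s$led == "on" && identical(s$stimulus, 0) &&
                 s$eye == "contra" && s$trial_index == 1, sweeps)[[1]]
  expect_equal(off$trace, on$trace, tolerance = 1e-12)
})

test_that("generated amplitudes respect the contra/ipsi ratio by construction", {
  cfg <- generator_config("adult", n_cells = 5, seed = 105, noise_sd = 0)
  tr <- generate_cohort(cfg)$truth
  expect_equal(tr$amp_contra / tr$amp_ipsi, rep(2, 5), tolerance = 1e-12)
})

test_that("matched-construction cells give zero inter-ocular difference", {
  cfg <- generator_config("custom", n_cells = 4, seed = 106, noise_sd = 0,
                          d_thal_mean = 0,
                          tc_diff_mean = c(contra = 0, ipsi = 0),
                          scale_mean = c(contra = 0.4, ipsi = 0.4))
  sim <- generate_cohort(cfg)
  an <- analyze_dataset(sim$dataset)
  tab <- cell_results_table(an)
  expect_true(all(tab$dO_total < 1))
  expect_true(all(tab$dO_thalamic < 1))
})

test_that("delta draws are calibrated to their analytic mean", {
  set.seed(107)
  for (target in c(17, 19.6, 30.9, 35.8)) {
    d <- binocmatch:::sample_delta(20000, target)
    expect_true(all(d >= 0 & d <= 90))
    expect_equal(mean(d), target, tolerance = 0.02 * target)
  }
  # targets at or beyond the family's 45-degree limit fall back to uniform
  d <- binocmatch:::sample_delta(20000, 49)
  expect_equal(mean(d), 45, tolerance = 0.02 * 45)
})

test_that("uniform preference pairs have mean circular difference 45", {
  pp <- random_preference_pairs(1e5, seed = 108)
  expect_true(all(pp >= -90 & pp < 90))
  d <- delta_orientation(pp[, 1], pp[, 2])
  expect_equal(mean(d), 45, tolerance = 0.5 / 45)
  # reproducible
  expect_identical(pp, random_preference_pairs(1e5, seed = 108))
  # the difference distribution itself is Uniform(0, 90)
  expect_gt(ks_vs_uniform(d[1:5000])$p, 0.01)
})

test_that("current-clamp cells record and expose injected spikes", {
  cfg <- generator_config("adult", n_cells = 6, seed = 109,
                          clamp_mode = "current_clamp", noise_sd = 0)
  sim <- generate_cohort(cfg)
  spiking <- which(sim$truth$n_spikes > 0)
  expect_gt(length(spiking), 0)  # defaults must produce some spiking cells
  i <- spiking[1]
  sweeps <- sim$dataset$cells[[sprintf("cell_%03d", i)]]
  n_det <- sum(vapply(sweeps, function(s)
    length(detect_spikes(s$trace, s$sampling_rate, 10)), 0L))
  expect_equal(n_det, sim$truth$n_spikes[i])
})
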