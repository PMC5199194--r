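# Shared fixtures built in code.

default_protocol <- stim_protocol()

# a short synthetic sweep set for one fake cell: constant baselines plus a
# half-rectified 2 Hz bump with per-direction amplitude `amp[j]`
make_vc_sweeps <- function(amps_off, amps_on, cell_id = "c1",
                           eye = "contra", onset = 0.2,
                           hold_off = -50, hold_on = -80,
                           protocol = default_protocol) {
  rate <- protocol$sampling_rate
  n <- round((onset + 1.55 + 0.15) * rate)
  t <- (seq_len(n) - 1) / rate
  m <- pmax(0, sin(2 * pi * 2 * (t - onset)))
  m[t < onset | t >= onset + 1.5] <- 0
  dirs <- protocol_directions(protocol)
  sweeps <- list()
  for (j in seq_along(dirs)) {
    sweeps[[length(sweeps) + 1]] <- sweep_record(
      cell_id, "voltage_clamp", eye, "off", dirs[j], 1,
      hold_off - amps_off[j] * m, onset, rate)
    sweeps[[length(sweeps) + 1]] <- sweep_record(
      cell_id, "voltage_clamp", eye, "on", dirs[j], 1,
      hold_on - amps_on[j] * m, onset, rate)
  }
  sweeps[[length(sweeps) + 1]] <- sweep_record(
    cell_id, "voltage_clamp", eye, "off", "blank", 1,
    rep(hold_off, n), onset, rate)
  sweeps[[length(sweeps) + 1]] <- sweep_record(
    cell_id, "voltage_clamp", eye, "on", "blank", 1,
    rep(hold_on, n), onset, rate)
  sweeps
}

# tiny dataset for IO tests: short traces, still protocol-conformant
make_tiny_dataset <- function(n_cells = 1, seed = 42) {
  set.seed(seed)
  protocol <- default_protocol
  rate <- protocol$sampling_rate
  n <- round(1.6 * rate)
  cells <- list()
  for (i in seq_len(n_cells)) {
    cid <- sprintf("tiny_%02d", i)
    sweeps <- list(
      sweep_record(cid, "voltage_clamp", "contra", "off", 0, 1,
                   rnorm(n, -50, 5), 0.05, rate),
      sweep_record(cid, "voltage_clamp", "ipsi", "on", 30, 2,
                   rnorm(n, -80, 5), 0.05, rate),
      sweep_record(cid, "voltage_clamp", "contra", "off", "blank", 1,
                   rnorm(n, -50, 5), 0.05, rate))
    cells[[cid]] <- sweeps
  }
  bm_dataset(protocol, cells, provenance = list(note = "tiny", seed = seed))
}
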