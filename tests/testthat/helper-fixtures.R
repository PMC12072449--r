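# Shared fixtures: random compositions over CHNOPS and a tiny hand-built run.

random_composition <- function(max_count = 30L) {
  syms <- c("C", "H", "N", "O", "P", "S")
  pick <- sample(syms, sample(2:6, 1))
  counts <- sample.int(max_count, length(pick), replace = TRUE)
  names(counts) <- pick
  element_counts(counts)
}

# A three-scan, two-ion run: ion A at m/z 200 with a triangular profile,
# ion B at m/z 500 flat.
tiny_run <- function(voltage = 10) {
  ms_run(data.frame(
    scan_time_min = rep(c(1, 2, 3), each = 2),
    cone_voltage_V = voltage,
    polarity = "+",
    mz = rep(c(200, 500), 3),
    intensity = c(0, 10, 100, 10, 0, 10)
  ))
}

one_compound_sim <- function(seed, noise_cv = 0.05) {
  cmp <- reference_panel()[2]  # the dehydrokawain glycoside, delta = 1 path
  cfg <- sim_config(noise_cv = noise_cv,
                    seed = if (noise_cv > 0) seed else NULL)
  sim <- simulate_run_set(cmp, cfg)
  list(cmp = cmp, cfg = cfg, sim = sim, panel = sim_panel(cmp, cfg))
}
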