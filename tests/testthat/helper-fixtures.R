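# Shared fixtures: tiny hand-built sensorgrams and generator shortcuts.

# A minimal one-cycle sensorgram trace with explicit phases.
toy_trace <- function(cycle_id = "c1", flow_cell = "active",
                      analyte_id = "toy", conc = 1e-6,
                      times = 0:5,
                      responses = c(0, 0, 5, 9, 7, 5),
                      phases = c("baseline", "baseline", "association",
                                 "association", "dissociation",
                                 "dissociation")) {
  tibble::tibble(cycle_id = cycle_id, flow_cell = flow_cell,
                 analyte_id = analyte_id, concentration_M = conc,
                 phase = phases, time_s = times, response_RU = responses)
}

# Fast small cycle set for fitting tests: fewer concentrations and a
# coarser clock than the full screening design.
quick_cycle_set <- function(k_on = 1e5, k_off = 0.5, R_max = 200,
                            noise_sd = 0, seed = NULL, ...) {
  simulate_cycle_set("quick", k_on = k_on, k_off = k_off, R_max = R_max,
                     noise_sd = noise_sd, seed = seed, ...)
}

# Reference mechanism pair built from the two P2X4 antagonist probes'
# published kinetics (Rmax chosen at a plausible assay scale).
probe_mechanism <- function(kind) {
  competition_mechanism(
    kind,
    params_a = c(k_on = 1.099e5, k_off = 0.4947, R_max = 100),
    params_b = c(k_on = 2.882e4, k_off = 0.2246, R_max = 100))
}
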