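# Small deterministic circuits and schedules for fast tests.

# Two-region toy circuit: AI (exc RS + inh FS, all-to-all intra coupling)
# projecting to aMCC exc. All probabilities 1 so the synapse set does not
# depend on the connectivity stream; heterogeneity off.
toy_config <- function(n_exc = 40, n_inh = 10, w_ei = 5, w_ie = 6,
                       w_out = 4, delay_max = 1) {
  list(
    heterogeneous = FALSE,
    regions = list(
      list(name = "AI", n_exc = n_exc, n_inh = n_inh,
           type_exc = "RS", type_inh = "FS"),
      list(name = "aMCC", n_exc = n_exc, n_inh = 0, type_exc = "RS")),
    gradient = list(close = list(r = 7, p = 0.0025),
                    distant = list(r = 14, p = 0.035),
                    orientation = "ventral_at_high_index"),
    projections = list(
      list(source = "AI", source_pop = "exc", target = "AI",
           target_pop = "inh", sign = "excitatory", probability = 1,
           weight = w_ei, delay_max = delay_max),
      list(source = "AI", source_pop = "inh", target = "AI",
           target_pop = "exc", sign = "inhibitory", probability = 1,
           weight = w_ie, delay_max = delay_max),
      list(source = "AI", source_pop = "exc", target = "aMCC",
           target_pop = "exc", sign = "excitatory", probability = 1,
           weight = w_out, delay_max = delay_max)))
}

toy_circuit <- function(...) {
  empathynet:::build_circuit(toy_config(...), "toy")
}

# One-region schedule with a fixed band rule in all three phases.
toy_schedule <- function(low = 0.1, high = 0.15, phase_len = 200,
                         perturb = 0.1, amplitude = 90) {
  rules <- empathynet:::schedule_rule("AI", 1:3, "band", low, high)
  empathynet:::new_schedule("toy", stim_levels(), rules, amplitude, perturb,
                            phase_len)
}
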