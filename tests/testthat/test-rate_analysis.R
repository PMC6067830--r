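# Hand-built simulation_result for rate checks.
fake_result <- function(spike_time, spike_neuron, regions, pops, n,
                        total = 3000) {
  pop_tab <- data.frame(region = regions, pop = pops, n = n,
                        type = "RS", sign = "excitatory",
                        offset = cumsum(c(0, head(n, -1))))
  structure(list(
    spike_time = as.integer(spike_time),
    spike_neuron = as.integer(spike_neuron),
    neuron_region = rep(regions, n), neuron_pop = rep(pops, n),
    pop_tab = pop_tab, total_iterations = as.integer(total),
    phase_len = as.integer(total / 3), model = "fake", seed = 1,
    config_hash = "x", inj_counts = NULL, wall_time_s = 0),
    class = "simulation_result")
}

test_that("windowed mean firing rates follow the definition", {
  # empty raster -> 0 Hz
  r0 <- fake_result(integer(0), integer(0), "AI", "exc", 100)
  expect_equal(compute_mfr(r0, "AI", "exc", 1000), 0)

  # 100 neurons, one spike each inside a 1000-ms window -> 1 Hz
  r1 <- fake_result(seq(10, 1000, length.out = 100), 1:100,
                    "AI", "exc", 100)
  expect_equal(compute_mfr(r1, "AI", "exc", 1000), 1)

  # hand-built 5-neuron raster: window (1000, 2000] holds 7 spikes
  times <- c(500, 1001, 1200, 1500, 1500, 1999, 2000, 2000, 2001)
  ids <- c(1, 1, 2, 3, 4, 5, 1, 2, 3)
  r2 <- fake_result(times, ids, "VP", "inh", 5)
  expect_equal(compute_mfr(r2, "VP", "inh", 2000), 7 / 5)

  expect_error(compute_mfr(r2, "VP", "inh", 500), "outside")
  expect_error(compute_mfr(r2, "NAc", "inh", 2000), "no neurons")
})

test_that("rate summaries cover every population at every report time", {
  r <- fake_result(c(100, 1100, 2100), c(1, 1, 11),
                   c("AI", "AI"), c("exc", "inh"), c(10, 5))
  s <- rate_summary(r, report_times = c(1000, 2000, 3000))
  expect_s3_class(s, "rate_summary")
  expect_equal(nrow(s), 6)
  expect_equal(s$mfr_hz[s$subpop == "exc"], c(0.1, 0.1, 0))
  expect_equal(s$mfr_hz[s$subpop == "inh"], c(0, 0, 0.2))

  avg <- average_rate_summaries(list(s, s))
  expect_equal(avg$mfr_hz, s$mfr_hz)
})

# Minimal summary data frame for the classifier.
fake_summary <- function(vp, blma, mofc = NULL, ai = c(1, 0.2, 0.2)) {
  times <- c(10000, 20000, 30000)
  df <- rbind(
    data.frame(region = "VP", subpop = "inh", time_ms = times, mfr_hz = vp),
    data.frame(region = "BLMA_neg", subpop = "exc", time_ms = times,
               mfr_hz = blma),
    data.frame(region = "AI", subpop = "exc", time_ms = times, mfr_hz = ai))
  if (!is.null(mofc))
    df <- rbind(df, data.frame(region = "mOFC", subpop = "exc",
                               time_ms = times, mfr_hz = mofc))
  structure(df, class = c("rate_summary", "data.frame"), window_ms = 1000)
}

test_that("state classification follows the rule set", {
  # empathy-style run: silent VP, then moderate, then high
  lab <- classify_states(fake_summary(vp = c(0, 1, 2.4),
                                      blma = c(0.9, 0.75, 0.7)))
  expect_equal(lab$label, c("personal_distress", "weak_empathic_concern",
                            "strong_empathic_concern"))

  # self-attachment-style run: compassion needs an active mOFC and a
  # suppressed negatively valent amygdala
  lab <- classify_states(fake_summary(vp = c(0, 2.6, 3.6),
                                      blma = c(0.9, 0.6, 0.5),
                                      mofc = c(0, 0.1, 1.8)))
  expect_equal(lab$label, c("personal_distress", "strong_empathic_concern",
                            "compassion"))

  # without mOFC activation the same VP/BLMA pattern is strong concern
  lab <- classify_states(fake_summary(vp = c(0, 2.6, 3.6),
                                      blma = c(0.9, 0.6, 0.5),
                                      mofc = c(0, 0.1, 0.2)))
  expect_equal(lab$label[3], "strong_empathic_concern")

  expect_error(classify_states(fake_summary(vp = c(0, 0, 0),
                                            blma = c(0, 0, 0),
                                            ai = c(0, 0, 0))),
               "insufficient activity")
})

test_that("reference comparison tolerances behave at the boundaries", {
  ref <- reference_mfr("empathy")
  self <- structure(data.frame(region = ref$region, subpop = ref$subpop,
                               time_ms = ref$time_ms, mfr_hz = ref$mfr_hz),
                    class = c("rate_summary", "data.frame"))
  cmp <- compare_to_reference(self, ref)
  expect_equal(attr(cmp, "pass_fraction"), 1)

  shifted <- self
  shifted$mfr_hz <- shifted$mfr_hz + 10 * pmax(0.3, 0.25 * shifted$mfr_hz)
  cmp <- compare_to_reference(shifted, ref)
  expect_equal(attr(cmp, "pass_fraction"), 0)

  expect_error(compare_to_reference(self[-1, ], ref), "cover")
})

test_that("the packaged reference tables transcribe both models", {
  emp <- reference_mfr("empathy")
  sa <- reference_mfr("self_attachment")
  expect_equal(nrow(emp), 30)
  expect_equal(nrow(sa), 32)
  expect_true(all(emp$mfr_hz >= 0) && all(sa$mfr_hz >= 0))
  # spot values quoted in the results
  expect_equal(emp$mfr_hz[emp$region == "AI" & emp$subpop == "exc" &
                            emp$time_ms == 10000], 1.08)
  expect_equal(sa$mfr_hz[sa$region == "VP" & sa$time_ms == 30000], 3.56)
})
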