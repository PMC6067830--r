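test_that("runs are reproducible bit-for-bit under a fixed seed", {
  cir <- toy_circuit()
  sch <- toy_schedule(phase_len = 300)
  r1 <- run_simulation(cir, sch, seed = 5, total_iterations = 900)
  r2 <- run_simulation(cir, sch, seed = 5, total_iterations = 900)
  expect_identical(r1$spike_time, r2$spike_time)
  expect_identical(r1$spike_neuron, r2$spike_neuron)
  expect_identical(r1$inj_counts, r2$inj_counts)
  r3 <- run_simulation(cir, sch, seed = 6, total_iterations = 900)
  expect_false(identical(r1$spike_time, r3$spike_time))
})

test_that("spike times stay inside the simulated range and silence holds", {
  cir <- toy_circuit()
  sch <- toy_schedule(phase_len = 300)
  r <- run_simulation(cir, sch, seed = 1, total_iterations = 900)
  expect_true(all(r$spike_time >= 1 & r$spike_time <= 900))
  expect_gt(length(r$spike_time), 0)

  # a population with no injection and no incoming projections stays silent:
  # aMCC receives AI input; cut it and stimulate nothing else
  cfg <- toy_config(w_out = 0)
  cfg$projections[[3]]$probability <- 0
  cir0 <- empathynet:::build_circuit(cfg, "toy")
  r0 <- run_simulation(cir0, sch, seed = 1, total_iterations = 900)
  st <- spike_table(r0)
  expect_equal(sum(st$region == "aMCC"), 0)
})

test_that("logged injection counts obey the band and ramp rules", {
  cir <- toy_circuit(n_exc = 200)
  rules <- rbind(
    empathynet:::schedule_rule("AI", 1, "band", 0.1, 0.15),
    empathynet:::schedule_rule("AI", 2, "ramp", 0.15, 0.05),
    empathynet:::schedule_rule("AI", 3, "off"))
  sch <- empathynet:::new_schedule("toy", stim_levels(), rules, 90, 0.1, 300)
  r <- run_simulation(cir, sch, seed = 2, total_iterations = 900)
  cnt <- r$inj_counts[, "AI"]
  # phase 1: uniform integer counts in [floor(200*0.1), floor(200*0.15)]
  expect_true(all(cnt[1:300] >= 20 & cnt[1:300] <= 30))
  # counts never exceed |g| = floor(0.15 * 200)
  expect_true(all(cnt <= 30))
  # phase 2: the decreasing ramp formula, clipped to |g|, floored
  expected <- vapply(301:600, function(t)
    as.integer(min(ramp_count(200, 0.15, 0.05, t, 300), 30)), 0L)
  expect_identical(cnt[301:600], as.integer(expected))
  # phase 3: off
  expect_true(all(cnt[601:900] == 0))
})

test_that("the engine matches an R-level composition of the public operations", {
  # deterministic protocol: degenerate band (H, H) selects all of g, no
  # perturbation, all-to-all synapses with unit delays -> the whole run is
  # reproducible from the R-level operations alone
  cfg <- toy_config(n_exc = 30, n_inh = 10, w_ei = 4, w_ie = 6, w_out = 3)
  cir <- empathynet:::build_circuit(cfg, "toy")
  rules <- empathynet:::schedule_rule("AI", 1:3, "band", 0.15, 0.15)
  sch <- empathynet:::new_schedule("toy", stim_levels(), rules, 90, 0, 150)
  seed <- 7
  res <- run_simulation(cir, sch, seed = seed, total_iterations = 450)

  seeds <- empathynet:::derive_seeds(seed)
  set.seed(seeds[["connectivity"]])
  net <- empathynet:::realize_circuit(cir)
  set.seed(seeds[["designation"]])
  g0 <- designate_targets(30, stim_levels())  # AI exc pool, |g| = 4

  p_rs <- izhikevich_params("RS")
  p_fs <- izhikevich_params("FS")
  ai_e <- population_state(30, p_rs)
  ai_i <- population_state(10, p_fs)
  mc_e <- population_state(30, p_rs)
  projections <- list(
    list(source = "ai_e", target = "ai_i",
         synapses = expand.grid(source = 1:30, target = 1:10)),
    list(source = "ai_i", target = "ai_e",
         synapses = expand.grid(source = 1:10, target = 1:30)),
    list(source = "ai_e", target = "mc_e",
         synapses = expand.grid(source = 1:30, target = 1:30)))
  projections[[1]]$synapses$weight <- 4
  projections[[2]]$synapses$weight <- -6
  projections[[3]]$synapses$weight <- 3
  spikes_prev <- list(ai_e = integer(0), ai_i = integer(0),
                      mc_e = integer(0))
  raster <- list()
  for (t in 1:450) {
    ext <- list(ai_e = rep(0, 30), ai_i = rep(0, 10), mc_e = rep(0, 30))
    ext$ai_e[g0] <- 90
    I <- accumulate_synaptic_input(spikes_prev, projections, ext)
    ai_e$I <- I$ai_e; ai_i$I <- I$ai_i; mc_e$I <- I$mc_e
    r1 <- step_population(ai_e, p_rs); ai_e <- r1$state
    r2 <- step_population(ai_i, p_fs); ai_i <- r2$state
    r3 <- step_population(mc_e, p_rs); mc_e <- r3$state
    spikes_prev <- list(ai_e = r1$spiked, ai_i = r2$spiked,
                        mc_e = r3$spiked)
    sp <- c(r1$spiked, 30 + r2$spiked, 40 + r3$spiked)
    raster[[t]] <- data.frame(time = rep(t, length(sp)), neuron = sp)
  }
  ref <- do.call(rbind, raster)
  got <- data.frame(time = res$spike_time, neuron = res$spike_neuron)
  got <- got[order(got$time, got$neuron), ]
  ref <- ref[order(ref$time, ref$neuron), ]
  expect_equal(nrow(got), nrow(ref))
  expect_identical(got$time, as.integer(ref$time))
  expect_identical(got$neuron, as.integer(ref$neuron))
})

test_that("run_simulation validates its inputs", {
  cir <- toy_circuit()
  sch <- toy_schedule()
  expect_error(run_simulation(cir, sch, seed = 1, total_iterations = 1000),
               "divisible")
  sch_bad <- toy_schedule()
  sch_bad$rules$region <- "VP"
  expect_error(run_simulation(cir, sch_bad, seed = 1,
                              total_iterations = 900), "absent")
})
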