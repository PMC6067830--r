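test_that("stimulation levels validate their ordering", {
  lv <- stim_levels()
  expect_equal(unlist(lv), c(L = 0.05, M = 0.1, H = 0.15))
  expect_error(stim_levels(L = 0.2, M = 0.1, H = 0.15), "L < M < H")
})

test_that("designated subsets have size floor(|G| * H), uniformly drawn", {
  set.seed(1)
  g <- designate_targets(1000)
  expect_length(g, 150)
  expect_length(unique(g), 150)
  expect_length(designate_targets(0), 0)

  # inclusion frequency per neuron close to H (hypergeometric expectation)
  reps <- 10^4
  counts <- integer(100)
  for (i in seq_len(reps)) {
    g <- designate_targets(100)
    counts[g] <- counts[g] + 1L
  }
  se <- sqrt(0.15 * 0.85 / reps)
  expect_true(all(abs(counts / reps - 0.15) < 4 * se))
})

test_that("perturbation swaps exactly the stated fraction and preserves size", {
  set.seed(2)
  g <- designate_targets(1000)
  g2 <- perturb_targets(g, 1000, 0.1)
  expect_length(g2, 150)
  expect_equal(length(setdiff(g, g2)), 15)
  expect_equal(length(setdiff(g2, g)), 15)
  expect_identical(perturb_targets(g, 1000, 0), g)
  expect_error(perturb_targets(seq_len(10), 10, 0.5), "outside")

  # repeated perturbation visits nearly the whole region
  seen <- rep(FALSE, 1000)
  g <- designate_targets(1000)
  seen[g] <- TRUE
  for (t in seq_len(10^4)) {
    g <- perturb_targets(g, 1000, 0.1)
    seen[g] <- TRUE
  }
  expect_gt(mean(seen), 0.99)
})

test_that("fixed-band selection draws a uniform count from the band", {
  set.seed(3)
  g <- designate_targets(1000)
  counts <- replicate(10^4, length(select_fixed_band(g, 1000, 0.1, 0.15)))
  expect_true(all(counts >= 100 & counts <= 150))
  se <- sd(counts) / 100
  expect_lt(abs(mean(counts) - 125), 4 * se)
  c_t <- select_fixed_band(g, 1000, 0.1, 0.15)
  expect_true(all(c_t %in% g))
  # degenerate band gives a deterministic count
  expect_length(select_fixed_band(g, 1000, 0.12, 0.12), 120)
  expect_error(select_fixed_band(g[1:10], 1000, 0.1, 0.15), "exceeds")
})

test_that("ramp counts hit the printed formulas' endpoints exactly", {
  lv <- stim_levels()
  # phase-2 decreasing form: |G| H at t/p = 1, |G| L at t/p = 2
  expect_equal(ramp_count(1000, lv$H, lv$L, 10000, 10000, phase = 2), 150)
  expect_equal(ramp_count(1000, lv$H, lv$L, 20000, 10000), 50)
  expect_equal(ramp_count(1000, lv$H, lv$L, 15000, 10000), 100)
  # increasing aMCC form
  expect_equal(ramp_count(1000, lv$L, lv$H, 10000, 10000, phase = 2), 50)
  expect_equal(ramp_count(1000, lv$L, lv$H, 20000, 10000), 150)
  # third-phase mOFC form: |G| L at t/p = 2, |G| H at t/p = 3
  expect_equal(ramp_count(1000, lv$L, lv$H, 20000, 10000, phase = 3), 50)
  expect_equal(ramp_count(1000, lv$L, lv$H, 30000, 10000), 150)
  # floored, never negative
  expect_equal(ramp_count(10, lv$H, lv$L, 19000, 10000), 0)
})

test_that("the empathy schedule encodes the three fixed-band phases", {
  sch <- build_protocol_empathy()
  expect_equal(sch$amplitude, 90)
  expect_equal(sch$perturb_fraction, 0.1)
  r <- sch$rules
  pick <- function(region, phase) r[r$region == region & r$phase == phase, ]
  # hand-written phase table
  expect_equal(pick("AI", 1)[, c("rule", "p1", "p2")],
               data.frame(rule = "band", p1 = 0.1, p2 = 0.15),
               ignore_attr = TRUE)
  expect_equal(pick("AI", 2)$p1, 0.05)
  expect_equal(pick("aMCC", 1)$p2, 0.1)
  expect_equal(pick("aMCC", 2)$p1, 0.1)
  expect_equal(pick("mPFC", 1:3)$mode, c("close", "distant", "close"))
  # negatively valent amygdala stimulated at (M, H) in every phase
  blma <- r[r$region == "BLMA_neg", ]
  expect_equal(nrow(blma), 3)
  expect_true(all(blma$rule == "band" & blma$p1 == 0.1 & blma$p2 == 0.15))
})

test_that("the self-attachment schedule mixes bands and the printed ramps", {
  sch <- build_protocol_self_attachment()
  r <- sch$rules
  pick <- function(region, phase) r[r$region == region & r$phase == phase, ]
  expect_equal(pick("AI", 2)[, c("rule", "p1", "p2")],
               data.frame(rule = "ramp", p1 = 0.15, p2 = 0.05),
               ignore_attr = TRUE)
  expect_equal(pick("aMCC", 2)[, c("rule", "p1", "p2")],
               data.frame(rule = "ramp", p1 = 0.05, p2 = 0.15),
               ignore_attr = TRUE)
  expect_equal(pick("mOFC", 3)$rule, "ramp")
  # mPFC targets close-other representations in all three phases
  expect_true(all(pick("mPFC", 1:3)$mode == "close"))
  # phase 1 equals the empathy phase 1 plus the low-band mOFC rule
  emp1 <- build_protocol_empathy()$rules
  emp1 <- emp1[emp1$phase == 1, ]
  sa1 <- r[r$phase == 1, ]
  expect_equal(sa1[sa1$region != "mOFC", ], emp1, ignore_attr = TRUE)
  expect_equal(sa1[sa1$region == "mOFC", c("p1", "p2")],
               data.frame(p1 = 0.05, p2 = 0.1), ignore_attr = TRUE)

  # schedules validate against circuits
  expect_error(validate_schedule(sch, build_empathy_circuit()), "mOFC")
})

test_that("packaged schedule files reproduce the builders", {
  emp_file <- schedule_config("empathy")
  emp <- build_protocol_empathy()
  expect_equal(emp_file$rules, emp$rules, ignore_attr = TRUE)
  expect_equal(emp_file$amplitude, emp$amplitude)
  sa_file <- schedule_config("self_attachment")
  sa <- build_protocol_self_attachment()
  expect_equal(sa_file$rules, sa$rules, ignore_attr = TRUE)
})
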