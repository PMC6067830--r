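#' Weighted squared-error loss against a reference table
#'
#' `sum(w_i * (sim_i - ref_i)^2)` over reference entries; zero iff the
#' summary matches the reference exactly on all weighted entries.
#'
#' @param summary a `rate_summary`.
#' @param reference reference table as from [reference_mfr()].
#' @param weights per-entry non-negative weights (default 1).
#' @return non-negative scalar loss.
#' @export
mfr_loss <- function(summary, reference, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(reference))
  stopifnot(length(weights) == nrow(reference), all(weights >= 0))
  sim <- mapply(function(r, s, t) rate_at(summary, r, s, t),
                reference$region, reference$subpop, reference$time_ms)
  if (any(is.na(sim)))
    stop("summary does not cover all reference entries", call. = FALSE)
  sum(weights * (sim - reference$mfr_hz)^2)
}

#' Calibration specification
#'
#' Declares which projection weights are free, their search bounds, and the
#' search budget. Projections are addressed as
#' `"source.source_pop->target.target_pop"`.
#'
#' @param free named list: `list("AI.exc->aMCC.exc" = c(lower, upper), ...)`.
#' @param budget total number of objective evaluations (>= 1).
#' @param seeds_per_eval simulation seeds averaged per evaluation.
#' @param seed RNG seed of the search itself.
#' @param total_iterations simulation length per evaluation (shorter runs
#'   are legitimate for search; verify at full length).
#' @param weights optional per-entry loss weights.
#' @return an object of class `calibration_spec`.
#' @export
calibration_spec <- function(free = list(), budget = 50, seeds_per_eval = 3,
                             seed = 1, total_iterations = 30000,
                             weights = NULL) {
  for (b in free)
    if (length(b) != 2 || any(b <= 0) || b[1] > b[2])
      stop("each bound must be c(lower, upper) with 0 < lower <= upper",
           call. = FALSE)
  stopifnot(budget >= 1, seeds_per_eval >= 1)
  structure(list(free = free, budget = budget,
                 seeds_per_eval = seeds_per_eval, seed = seed,
                 total_iterations = total_iterations, weights = weights),
            class = "calibration_spec")
}

projection_key <- function(p)
  sprintf("%s.%s->%s.%s", p$source, p$source_pop, p$target, p$target_pop)

#' Apply weight overrides to a circuit
#'
#' @param circuit a `circuit_model`.
#' @param overrides named numeric vector keyed as
#'   `"source.pop->target.pop"`.
#' @return the circuit with the overridden projection weights.
#' @export
apply_weight_overrides <- function(circuit, overrides) {
  keys <- vapply(circuit$projections, projection_key, "")
  for (nm in names(overrides)) {
    i <- which(keys == nm)
    if (length(i) != 1)
      stop(sprintf("override '%s' matches %d projections", nm, length(i)),
           call. = FALSE)
    circuit$projections[[i]]$weight <- unname(overrides[[nm]])
  }
  circuit
}

# Simple maximin-free Latin hypercube on [0,1]^d (base R).
latin_hypercube <- function(n, d)
  matrix(vapply(seq_len(d), function(j) (sample.int(n) - stats::runif(n)) / n,
                numeric(n)), nrow = n)

#' Calibrate projection weights against the reference table
#'
#' Bounded random search: a Latin-hypercube seeding stage over the free
#' weights (log-scale within bounds) followed by coordinate-wise local
#' refinement around the incumbent. Each evaluation simulates
#' `seeds_per_eval` seeds, averages the rate summaries, and scores them
#' with [mfr_loss()]. Deterministic given the specification's seed.
#'
#' @param spec a [calibration_spec()].
#' @param circuit a `circuit_model` (the starting weights).
#' @param schedule an `injection_schedule`.
#' @param reference reference table as from [reference_mfr()].
#' @param loss_threshold warn when the best loss stays above this.
#' @return list of class `calibration_result`: `overrides` (best-found
#'   weights), `loss`, `trace` (one row per evaluation), `warning_flag`.
#' @export
calibrate <- function(spec, circuit, schedule, reference,
                      loss_threshold = Inf) {
  stopifnot(inherits(spec, "calibration_spec"))
  keys <- names(spec$free)
  start <- vapply(keys, function(k) {
    i <- which(vapply(circuit$projections, projection_key, "") == k)
    if (length(i) != 1)
      stop(sprintf("free parameter '%s' does not name a projection", k),
           call. = FALSE)
    circuit$projections[[i]]$weight
  }, 0)
  evaluate <- function(w) {
    cir <- apply_weight_overrides(circuit, stats::setNames(w, keys))
    sums <- lapply(seq_len(spec$seeds_per_eval), function(s)
      rate_summary(run_simulation(cir, schedule, seed = 1000 * spec$seed + s,
                                  total_iterations = spec$total_iterations),
                   report_times = sort(unique(reference$time_ms))))
    mfr_loss(average_rate_summaries(sums), reference, spec$weights)
  }
  trace <- list()
  best_w <- start
  best_loss <- evaluate(start)
  trace[[1]] <- c(loss = best_loss, start)
  used <- 1
  d <- length(keys)
  if (d > 0 && spec$budget > used) {
    set.seed(spec$seed)
    n_lhs <- min(max(floor(spec$budget / 2), 1), spec$budget - used)
    lo <- log(vapply(spec$free, `[`, 0, 1))
    hi <- log(vapply(spec$free, `[`, 0, 2))
    cube <- latin_hypercube(n_lhs, d)
    for (i in seq_len(n_lhs)) {
      w <- exp(lo + cube[i, ] * (hi - lo))
      l <- evaluate(w)
      used <- used + 1
      trace[[used]] <- c(loss = l, w)
      if (l < best_loss) { best_loss <- l; best_w <- w }
    }
    step <- 1.25
    repeat {
      improved <- FALSE
      for (j in seq_len(d)) {
        for (fac in c(1 / step, step)) {
          if (used >= spec$budget) break
          w <- best_w
          w[j] <- min(max(w[j] * fac, exp(lo[j])), exp(hi[j]))
          if (w[j] == best_w[j]) next
          l <- evaluate(w)
          used <- used + 1
          trace[[used]] <- c(loss = l, w)
          if (l < best_loss) { best_loss <- l; best_w <- w; improved <- TRUE }
        }
      }
      if (!improved || used >= spec$budget) break
      step <- sqrt(step)
    }
  }
  flag <- best_loss > loss_threshold
  if (flag)
    warning("calibration budget exhausted with loss above threshold",
            call. = FALSE)
  structure(list(overrides = stats::setNames(best_w, keys),
                 loss = best_loss,
                 trace = do.call(rbind, trace), warning_flag = flag),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration result: loss %.4g after %d evaluations%s\n",
              x$loss, nrow(x$trace),
              if (x$warning_flag) " [above threshold]" else ""))
  if (length(x$overrides)) {
    cat("Best weights:\n")
    for (nm in names(x$overrides))
      cat(sprintf("  %-28s %.4g\n", nm, x$overrides[[nm]]))
  }
  invisible(x)
}
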