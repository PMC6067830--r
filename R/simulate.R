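# Seed derivation: three named RNG sub-streams (connectivity realization,
# target designation, per-step perturbation/selection) from one master
# seed, so resampling one stage never shifts draws in another.
derive_seeds <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(as.integer(seed))
  s <- sample.int(2147483646L, 3L)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  names(s) <- c("connectivity", "designation", "selection")
  s
}

# Build the engine's per-group injection descriptors from a schedule.
# Each stimulated region contributes one group per mPFC targeting mode
# (close/distant) or a single group otherwise. Pools are the excitatory
# (principal) subpopulation in axis order; g_init is drawn from the
# designation RNG stream.
build_injection_groups <- function(circuit, schedule, net) {
  rules <- schedule$rules
  groups <- list()
  for (region in unique(rules$region)) {
    rr <- rules[rules$region == region, , drop = FALSE]
    modes <- unique(ifelse(is.na(rr$mode), "uniform", rr$mode))
    pool_global <- which(net$neuron_region == region &
                           net$neuron_pop %in% c("exc", "da"))
    m <- length(pool_global)
    for (mode in modes) {
      sel <- if (mode == "uniform") is.na(rr$mode) else
        (!is.na(rr$mode) & rr$mode == mode)
      rm <- rr[sel, , drop = FALSE]
      rule_type <- integer(schedule$n_phases)
      p1 <- p2 <- numeric(schedule$n_phases)
      for (i in seq_len(nrow(rm))) {
        ph <- rm$phase[i]
        rule_type[ph] <- switch(rm$rule[i], band = 1L, ramp = 2L, off = 0L)
        p1[ph] <- rm$p1[i]; p2[ph] <- rm$p2[i]
      }
      use_nb <- mode %in% c("close", "distant")
      g_init <- if (use_nb)
        designate_targets_nb(circuit$gradient, mode, m, schedule$levels)
      else designate_targets(m, schedule$levels)
      gr <- circuit$gradient
      par <- if (use_nb) gr[[mode]] else c(r = 1, p = 0.5)
      groups[[paste0(region, if (mode == "uniform") "" else paste0(".", mode))]] <-
        list(pool = as.integer(pool_global - 1L),
             g_init = as.integer(g_init - 1L),
             use_nb = use_nb, nb_r = unname(par[["r"]]),
             nb_p = unname(par[["p"]]),
             ventral_high = gr$orientation == "ventral_at_high_index",
             rule_type = rule_type, rule_p1 = p1, rule_p2 = p2)
    }
  }
  groups
}

#' Run a full seeded simulation
#'
#' Orchestrates one 30-s run (by default 30,000 iterations on the 1-ms
#' grid) of a circuit under an injection schedule: realizes the
#' connectivity, designates the injectable subsets, and hands the per-step
#' loop (perturb targets, draw injected counts, inject, propagate spikes,
#' step all populations) to the compiled engine. Identical inputs and seed
#' give identical rasters.
#'
#' @param circuit a `circuit_model`.
#' @param schedule an `injection_schedule`.
#' @param seed integer master seed; three sub-streams (connectivity,
#'   designation, selection) are derived from it.
#' @param total_iterations simulation length in ms; must be divisible by
#'   the number of phases.
#' @param record_spikes keep the full raster (needed for rate analysis).
#' @param v_floor membrane floor (mV), the effective inhibitory reversal:
#'   current-based synapses admit unbounded hyperpolarization, which both
#'   destabilizes the 0.5-ms Euler half-steps and generates spurious
#'   post-inhibitory rebound; clamping at the GABA-A reversal bounds both.
#' @return an object of class `simulation_result`: spike raster, per-step
#'   injected counts per stimulated group, neuron-to-region map, seed and
#'   config hash.
#' @export
run_simulation <- function(circuit, schedule, seed,
                           total_iterations = 30000, record_spikes = TRUE,
                           v_floor = -80) {
  stopifnot(inherits(circuit, "circuit_model"),
            inherits(schedule, "injection_schedule"))
  validate_schedule(schedule, circuit)
  if (total_iterations %% schedule$n_phases != 0)
    stop("total_iterations must be divisible by the number of phases",
         call. = FALSE)
  phase_len <- as.integer(total_iterations / schedule$n_phases)
  seeds <- derive_seeds(seed)
  t0 <- proc.time()[["elapsed"]]
  set.seed(seeds[["connectivity"]])
  net <- realize_circuit(circuit)
  set.seed(seeds[["designation"]])
  groups <- build_injection_groups(circuit, schedule, net)
  raw <- engine_run(net$a, net$b, net$c, net$d, net$v0, net$u0,
                    net$syn_ptr, net$syn_tgt, net$syn_w, net$syn_delay,
                    as.integer(total_iterations), phase_len,
                    schedule$amplitude * circuit$current_gain,
                    schedule$perturb_fraction, groups,
                    as.integer(seeds[["selection"]]), record_spikes, v_floor)
  colnames(raw$inj_counts) <- names(groups)
  structure(list(
    spike_time = raw$spike_time, spike_neuron = raw$spike_neuron,
    inj_counts = raw$inj_counts, neuron_region = net$neuron_region,
    neuron_pop = net$neuron_pop, pop_tab = net$pop_tab,
    total_iterations = as.integer(total_iterations), phase_len = phase_len,
    model = circuit$model, seed = seed,
    config_hash = circuit$provenance,
    wall_time_s = proc.time()[["elapsed"]] - t0),
    class = "simulation_result")
}

#' Run a packaged model end to end
#'
#' Convenience wrapper: builds the requested packaged circuit and its
#' protocol, then calls [run_simulation()].
#'
#' @param model "empathy" or "self_attachment".
#' @param seed integer master seed.
#' @param config optional circuit configuration (list or YAML path).
#' @param ... passed to [run_simulation()].
#' @return a `simulation_result`.
#' @export
run_model <- function(model = c("empathy", "self_attachment"), seed,
                      config = NULL, ...) {
  model <- match.arg(model)
  circuit <- if (model == "empathy")
    build_empathy_circuit(if (is.null(config)) circuit_config("empathy")
                          else config)
  else
    build_self_attachment_circuit(
      if (is.null(config)) circuit_config("self_attachment") else config)
  schedule <- if (model == "empathy") build_protocol_empathy(circuit = circuit)
  else build_protocol_self_attachment(circuit = circuit)
  run_simulation(circuit, schedule, seed, ...)
}

#' Spike raster as a data frame
#'
#' @param result a `simulation_result`.
#' @return data frame with columns `neuron_id`, `region`, `subpop`,
#'   `time_ms`.
#' @export
spike_table <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  data.frame(neuron_id = result$spike_neuron,
             region = result$neuron_region[result$spike_neuron],
             subpop = result$neuron_pop[result$spike_neuron],
             time_ms = result$spike_time)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "Simulation of '%s' model: %d ms, %d neurons, %d spikes (seed %s)\n",
    x$model, x$total_iterations, length(x$neuron_region),
    length(x$spike_time), format(x$seed)))
  invisible(x)
}

#' @export
summary.simulation_result <- function(object, ...) {
  phases <- ceiling(object$spike_time / object$phase_len)
  cat(sprintf("Simulation of '%s' model (seed %s), %.1f s wall time\n",
              object$model, format(object$seed), object$wall_time_s))
  cat("Spikes per phase:",
      paste(tabulate(phases, nbins = 3), collapse = ", "), "\n\n")
  print(rate_summary(object))
  invisible(object)
}

#' Raster plot of a simulation
#'
#' @param x a `simulation_result`.
#' @param regions optional character vector restricting the plot.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.simulation_result <- function(x, regions = NULL, ...) {
  st <- spike_table(x)
  if (!is.null(regions)) st <- st[st$region %in% regions, , drop = FALSE]
  st$region <- factor(st$region)
  graphics::plot(st$time_ms / 1000, st$neuron_id, pch = ".",
                 col = as.integer(st$region),
                 xlab = "time (s)", ylab = "neuron", ...)
  graphics::abline(v = c(1, 2) * x$phase_len / 1000, lty = 3)
  graphics::legend("topleft", legend = levels(st$region),
                   col = seq_along(levels(st$region)), pch = 15, cex = 0.7)
  invisible(x)
}

#' Command-line entry point
#'
#' Thin shell interface over the packaged models: runs one or more seeded
#' simulations and writes a spike table, a rate summary and a run manifest
#' to the output directory. Used by `inst/scripts/run_model.R`.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit code (0 on success), invisibly.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    optparse::make_option("--model", type = "character", default = NULL,
                          help = "empathy or self-attachment [required]"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "optional circuit config YAML"),
    optparse::make_option("--out", type = "character", default = "out"),
    optparse::make_option("--report-times", type = "character",
                          default = "10,20,30", dest = "report_times",
                          help = "report times in seconds"),
    optparse::make_option("--replicates", type = "integer", default = 1L),
    optparse::make_option("--iterations", type = "integer", default = 30000L,
                          help = "simulation length in ms"),
    optparse::make_option("--summary-only", action = "store_true",
                          default = FALSE, dest = "summary_only"))
  parser <- optparse::OptionParser(option_list = spec,
                                   prog = "empathynet-run")
  opt <- tryCatch(optparse::parse_args(parser, args = argv),
                  error = function(e) e)
  if (inherits(opt, "error") || is.null(opt$model)) {
    optparse::print_help(parser)
    message("error: --model {empathy|self-attachment} is required")
    return(invisible(1L))
  }
  model <- gsub("-", "_", opt$model)
  if (!model %in% c("empathy", "self_attachment")) {
    optparse::print_help(parser)
    message(sprintf("error: unknown model '%s'", opt$model))
    return(invisible(1L))
  }
  report_ms <- as.numeric(strsplit(opt$report_times, ",")[[1]]) * 1000
  dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
  summaries <- list()
  for (rep in seq_len(opt$replicates)) {
    seed <- opt$seed + rep - 1L
    res <- run_model(model, seed = seed, config = opt$config,
                     total_iterations = opt$iterations)
    phases <- ceiling(res$spike_time / res$phase_len)
    message(sprintf("seed %d: phase boundaries at %s ms; spikes per phase %s",
                    seed,
                    paste(seq_len(2) * res$phase_len, collapse = ", "),
                    paste(tabulate(phases, 3), collapse = ", ")))
    rs <- rate_summary(res, report_times = report_ms)
    rs$seed <- seed
    summaries[[rep]] <- rs
    if (!opt$summary_only)
      utils::write.csv(spike_table(res),
                       file.path(opt$out, sprintf("spikes_seed%d.csv", seed)),
                       row.names = FALSE)
  }
  rates <- do.call(rbind, lapply(summaries, as.data.frame))
  utils::write.csv(rates, file.path(opt$out, "rates.csv"), row.names = FALSE)
  manifest <- list(model = model, seed = opt$seed,
                   replicates = opt$replicates,
                   config_hash = unname(res$config_hash),
                   report_times_ms = report_ms,
                   package_version = as.character(
                     utils::packageVersion("empathynet")),
                   r_version = R.version.string)
  yaml::write_yaml(manifest, file.path(opt$out, "manifest.yaml"))
  invisible(0L)
}
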