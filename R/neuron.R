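#' Izhikevich neuron parameters
#'
#' Constructs the parameter set of the two-variable Izhikevich point-neuron
#' model \eqn{v' = 0.04v^2 + 5v + 140 - u + I}, \eqn{u' = a(bv - u)}, with
#' spike-and-reset \eqn{v \ge 30 \Rightarrow v \leftarrow c,\; u \leftarrow
#' u + d}. Named presets follow the canonical published values:
#' regular-spiking (RS), fast-spiking (FS) and intrinsically bursting (IB).
#'
#' @param label one of `"RS"`, `"FS"`, `"IB"`, or `"custom"` (in which case
#'   `a`, `b`, `c`, `d` must all be supplied).
#' @param a recovery time-scale (1/ms); must be positive.
#' @param b recovery sensitivity (dimensionless).
#' @param c reset potential (mV); must lie below the 30 mV spike cutoff.
#' @param d reset recovery increment.
#' @return an object of class `izhikevich_params`.
#' @examples
#' izhikevich_params("RS")
#' izhikevich_params("custom", a = 0.02, b = 0.25, c = -65, d = 2)
#' @export
izhikevich_params <- function(label = c("RS", "FS", "IB", "custom"),
                              a = NULL, b = NULL, c = NULL, d = NULL) {
  label <- match.arg(label)
  presets <- list(
    RS = list(a = 0.02, b = 0.2, c = -65, d = 8),
    FS = list(a = 0.1,  b = 0.2, c = -65, d = 2),
    IB = list(a = 0.02, b = 0.2, c = -55, d = 4)
  )
  if (label == "custom") {
    if (is.null(a) || is.null(b) || is.null(c) || is.null(d))
      stop("custom parameters require a, b, c and d", call. = FALSE)
    p <- list(a = a, b = b, c = c, d = d)
  } else {
    p <- presets[[label]]
    if (!is.null(a) || !is.null(b) || !is.null(c) || !is.null(d))
      stop("named presets are immutable; use label = \"custom\" to override",
           call. = FALSE)
  }
  if (p$a <= 0) stop("recovery time-scale a must be positive", call. = FALSE)
  if (p$c >= 30) stop("reset potential c must lie below the 30 mV threshold",
                      call. = FALSE)
  structure(c(p, list(label = label)), class = "izhikevich_params")
}

#' @export
print.izhikevich_params <- function(x, ...) {
  cat(sprintf("Izhikevich parameters [%s]: a=%g, b=%g, c=%g, d=%g\n",
              x$label, x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Per-neuron state of a population
#'
#' Membrane potentials `v` (mV), recovery variables `u`, and the total input
#' current `I` accumulated for the next step, for `size` neurons. Neurons are
#' initialized at the canonical rest point `v = -65`, `u = b * v`.
#'
#' @param size neuron count.
#' @param params an [izhikevich_params()] object used for initialization.
#' @return an object of class `population_state`.
#' @export
population_state <- function(size, params = izhikevich_params("RS")) {
  stopifnot(inherits(params, "izhikevich_params"), size >= 0)
  structure(list(v = rep(-65, size), u = rep(params$b * -65, size),
                 I = rep(0, size), size = as.integer(size)),
            class = "population_state")
}

#' Advance a population by one 1-ms iteration
#'
#' Reference (vectorized, pure-R) implementation of the Izhikevich update
#' used by the simulation engine: two 0.5-ms half-steps for `v`, one full
#' step for `u`, spike cutoff at 30 mV with reset `v <- c`, `u <- u + d`,
#' and a membrane floor at -80 mV (the inhibitory reversal potential;
#' current-based synapses otherwise admit unbounded hyperpolarization).
#' The compiled engine in `src/` applies the identical scheme; tests hold
#' the two to machine agreement.
#'
#' @param state a [population_state()].
#' @param params an [izhikevich_params()] object (shared by all neurons).
#' @param dt time step in ms; the protocol fixes the 1-ms grid.
#' @return a list with the updated `state` (with `I` cleared) and `spiked`,
#'   the integer indices of neurons that crossed threshold this step.
#' @export
step_population <- function(state, params, dt = 1) {
  stopifnot(inherits(state, "population_state"),
            inherits(params, "izhikevich_params"), dt == 1)
  v <- state$v; u <- state$u; I <- state$I
  if (any(!is.finite(v)) || any(!is.finite(u)) || any(!is.finite(I)))
    stop("non-finite population state", call. = FALSE)
  v1 <- pmax(v + 0.5 * dt * (0.04 * v^2 + 5 * v + 140 - u + I), -80)
  below <- v1 < 30
  v1[below] <- pmax(v1[below] +
    0.5 * dt * (0.04 * v1[below]^2 + 5 * v1[below] + 140 - u[below] +
                  I[below]), -80)
  v1 <- pmin(v1, 30)
  u <- u + dt * params$a * (params$b * v1 - u)
  spiked <- which(v1 >= 30)
  v1[spiked] <- params$c
  u[spiked] <- u[spiked] + params$d
  if (any(!is.finite(v1)) || any(!is.finite(u)))
    stop("non-finite population state after step", call. = FALSE)
  state$v <- v1; state$u <- u; state$I <- rep(0, state$size)
  list(state = state, spiked = spiked)
}

#' Accumulate synaptic input currents
#'
#' Current-based, fixed-weight coupling with a one-step delay: each neuron's
#' input equals its external current plus the signed sum of weights of
#' incoming synapses whose source spiked at the previous step. Inhibitory
#' projections contribute negative current.
#'
#' @param spikes_prev named list of integer index vectors: the neurons of
#'   each source population that spiked at the previous step.
#' @param projections list of realized projections; each element carries
#'   `source`, `target` (population names) and `synapses`, a data frame with
#'   columns `source`, `target`, `weight` (signed, per synapse).
#' @param external named list of per-neuron external current vectors, one
#'   per target population (defines the population sizes).
#' @return named list of per-neuron total input currents.
#' @export
accumulate_synaptic_input <- function(spikes_prev, projections, external) {
  I <- external
  for (pr in projections) {
    if (!pr$target %in% names(I))
      stop(sprintf("projection targets unknown population '%s'", pr$target),
           call. = FALSE)
    sp <- spikes_prev[[pr$source]]
    if (is.null(sp) && !pr$source %in% names(spikes_prev))
      stop(sprintf("projection references unknown population '%s'", pr$source),
           call. = FALSE)
    if (length(sp) == 0L) next
    syn <- pr$synapses[pr$synapses$source %in% sp, , drop = FALSE]
    if (nrow(syn) == 0L) next
    add <- tapply(syn$weight, syn$target, sum)
    idx <- as.integer(names(add))
    I[[pr$target]][idx] <- I[[pr$target]][idx] + as.numeric(add)
  }
  I
}
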