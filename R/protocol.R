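#' Stimulation levels
#'
#' The three proportional stimulation levels of the injection protocol:
#' low, medium and high. Defaults are the protocol's published values
#' L = 0.05, M = 0.1, H = 0.15.
#'
#' @param L,M,H proportions with 0 < L < M < H < 1.
#' @return an object of class `stim_levels`.
#' @export
stim_levels <- function(L = 0.05, M = 0.1, H = 0.15) {
  if (!(0 < L && L < M && M < H && H < 1))
    stop("stimulation levels must satisfy 0 < L < M < H < 1", call. = FALSE)
  structure(list(L = L, M = M, H = H), class = "stim_levels")
}

#' Designate the injectable subset g(G) of a region
#'
#' Uniformly (without replacement) selects the subset of neurons that can
#' ever receive current injection: |g(G)| = floor(|G| * H).
#'
#' @param region_size |G|, size of the injectable pool.
#' @param levels a [stim_levels()] object.
#' @return integer vector of designated indices (possibly empty).
#' @export
designate_targets <- function(region_size, levels = stim_levels()) {
  stopifnot(region_size >= 0)
  k <- floor(region_size * levels$H)
  if (k == 0) return(integer(0))
  sample.int(region_size, k)
}

# Internal: negative-binomial designation of g(mPFC) for one gradient mode:
# distinct truncated-NB draws until |g| = floor(size * H).
designate_targets_nb <- function(spec, which, region_size,
                                 levels = stim_levels()) {
  k <- floor(region_size * levels$H)
  g <- integer(0)
  while (length(g) < k)
    g <- unique(c(g, sample_mpfc_gradient_targets(spec, which, region_size,
                                                  k - length(g) + 16L)))
  g[seq_len(k)]
}

#' Perturb the designated set
#'
#' Random-uniformly switches a fraction of the neurons designated to
#' receive current injection with neurons that previously were not:
#' exactly `round(fraction * |g|)` members are replaced by uniformly chosen
#' neurons from outside the pre-perturbation set. Cardinality is preserved.
#'
#' @param g integer vector, current designated set.
#' @param region_size |G|.
#' @param fraction proportion of `g` to swap (protocol value 0.10).
#' @return the perturbed designated set.
#' @export
perturb_targets <- function(g, region_size, fraction = 0.1) {
  stopifnot(length(g) <= region_size, fraction >= 0, fraction <= 1)
  k <- round(fraction * length(g))
  if (k == 0) return(g)
  outside <- setdiff(seq_len(region_size), g)
  if (length(outside) < k)
    stop("not enough neurons outside g to perform the swap", call. = FALSE)
  drop <- sample.int(length(g), k)
  add <- outside[sample.int(length(outside), k)]
  c(g[-drop], add)
}

#' Draw the injected subset for a fixed stimulation band
#'
#' The injected count is a uniformly distributed integer in the closed band
#' `[floor(|G| * low), floor(|G| * high)]`; the injected subset is then a
#' uniform subset of the (perturbed) designated set of that size.
#'
#' @param g_t integer vector, designated set at this step.
#' @param region_size |G|.
#' @param low_level,high_level band levels (proportions).
#' @return integer vector `c_t(G)`, a subset of `g_t`.
#' @export
select_fixed_band <- function(g_t, region_size, low_level, high_level) {
  lo <- floor(region_size * low_level)
  hi <- floor(region_size * high_level)
  if (hi > length(g_t))
    stop("band upper bound exceeds the designated set size", call. = FALSE)
  count <- lo + sample.int(hi - lo + 1L, 1L) - 1L
  if (count == 0) return(integer(0))
  g_t[sample.int(length(g_t), count)]
}

#' Linear-ramp injected count
#'
#' Evaluates the ramp-phase count formula
#' `floor(|G| * ((to - from) * (t/p) + from - (k - 1) * (to - from)))`,
#' where `k` is the phase index the ramp belongs to and `t` absolute
#' simulation time, so that the endpoints of the ramp equal
#' `|G| * from_level` at `t/p = k - 1` and `|G| * to_level` at `t/p = k`
#' exactly. For the phase-2 decreasing form this reproduces
#' `|G|(L - H)(t/p) + |G|(2H - L)`, and for the third-phase increasing mOFC
#' form `|G|(H - L)(t/p) + |G|(3L - 2H)`.
#'
#' @param region_size |G|.
#' @param from_level,to_level ramp endpoint levels.
#' @param t absolute simulation time (ms).
#' @param p phase length (ms).
#' @param phase phase index of the ramp; defaults to `ceiling(t / p)`
#'   (supply explicitly when evaluating at an exact phase boundary).
#' @return integer count (floored, non-negative).
#' @export
ramp_count <- function(region_size, from_level, to_level, t, p,
                       phase = ceiling(t / p)) {
  slope <- to_level - from_level
  # small epsilon absorbs floating-point error before flooring
  cnt <- floor(region_size * (slope * (t / p) + from_level -
                                (phase - 1) * slope) + 1e-6)
  max(cnt, 0L)
}

schedule_rule <- function(region, phase, rule, p1 = NA, p2 = NA, mode = NA)
  data.frame(region = region, phase = phase, rule = rule, p1 = p1, p2 = p2,
             mode = mode, stringsAsFactors = FALSE)

new_schedule <- function(model, levels, rules, amplitude, perturb_fraction,
                         phase_len) {
  structure(list(model = model, levels = levels, rules = rules,
                 amplitude = amplitude, perturb_fraction = perturb_fraction,
                 phase_len = as.integer(phase_len), n_phases = 3L),
            class = "injection_schedule")
}

#' Injection schedule for the empathy-states model
#'
#' Three equal phases of fixed stimulation bands: personal distress
#' (AI/PI high, aMCC/mPFC low, close-other mPFC targets), weak empathic
#' concern (AI/PI low, aMCC/mPFC high, distant-other targets), strong
#' empathic concern (as weak but close-other targets). The negatively
#' valent BLMA group is stimulated in the medium-high band at every
#' iteration of every phase.
#'
#' @param levels a [stim_levels()] object.
#' @param circuit optional `circuit_model` used to check the stimulated
#'   regions exist.
#' @param amplitude injection amplitude (current units; protocol value 90).
#' @param perturb_fraction per-step designated-set swap fraction (0.10).
#' @param phase_len phase length in ms (10000).
#' @return an object of class `injection_schedule`.
#' @export
build_protocol_empathy <- function(levels = stim_levels(), circuit = NULL,
                                   amplitude = 90, perturb_fraction = 0.1,
                                   phase_len = 10000) {
  L <- levels$L; M <- levels$M; H <- levels$H
  rules <- rbind(
    schedule_rule("BLMA_neg", 1:3, "band", M, H),
    schedule_rule("AI", 1, "band", M, H), schedule_rule("AI", 2:3, "band", L, M),
    schedule_rule("PI", 1, "band", M, H), schedule_rule("PI", 2:3, "band", L, M),
    schedule_rule("aMCC", 1, "band", L, M),
    schedule_rule("aMCC", 2:3, "band", M, H),
    schedule_rule("mPFC", 1, "band", L, M, "close"),
    schedule_rule("mPFC", 2, "band", M, H, "distant"),
    schedule_rule("mPFC", 3, "band", M, H, "close"))
  sch <- new_schedule("empathy", levels, rules, amplitude, perturb_fraction,
                      phase_len)
  if (!is.null(circuit)) validate_schedule(sch, circuit)
  sch
}

#' Injection schedule for the self-attachment model
#'
#' Phase 1 equals the personal-distress phase of the empathy schedule plus
#' a low-band mOFC stimulation; phase 2 ramps AI/PI linearly from high to
#' low and aMCC/mPFC (close-other targets) from low to high while mOFC
#' stays low; phase 3 holds AI/PI low and aMCC/mPFC high and ramps mOFC
#' from low to high (the compassion phase). mPFC targets close-other
#' representations in every phase of this model.
#'
#' @inheritParams build_protocol_empathy
#' @return an object of class `injection_schedule`.
#' @export
build_protocol_self_attachment <- function(levels = stim_levels(),
                                           circuit = NULL, amplitude = 90,
                                           perturb_fraction = 0.1,
                                           phase_len = 10000) {
  L <- levels$L; M <- levels$M; H <- levels$H
  rules <- rbind(
    schedule_rule("BLMA_neg", 1:3, "band", M, H),
    schedule_rule("AI", 1, "band", M, H),
    schedule_rule("AI", 2, "ramp", H, L),
    schedule_rule("AI", 3, "band", L, M),
    schedule_rule("PI", 1, "band", M, H),
    schedule_rule("PI", 2, "ramp", H, L),
    schedule_rule("PI", 3, "band", L, M),
    schedule_rule("aMCC", 1, "band", L, M),
    schedule_rule("aMCC", 2, "ramp", L, H),
    schedule_rule("aMCC", 3, "band", M, H),
    schedule_rule("mPFC", 1, "band", L, M, "close"),
    schedule_rule("mPFC", 2, "ramp", L, H, "close"),
    schedule_rule("mPFC", 3, "band", M, H, "close"),
    schedule_rule("mOFC", 1:2, "band", L, M),
    schedule_rule("mOFC", 3, "ramp", L, H))
  sch <- new_schedule("self_attachment", levels, rules, amplitude,
                      perturb_fraction, phase_len)
  if (!is.null(circuit)) validate_schedule(sch, circuit)
  sch
}

#' Validate a schedule against a circuit
#'
#' @param schedule an `injection_schedule`.
#' @param circuit a `circuit_model`.
#' @return the schedule, invisibly.
#' @export
validate_schedule <- function(schedule, circuit) {
  missing <- setdiff(unique(schedule$rules$region), names(circuit$regions))
  if (length(missing))
    stop(sprintf("schedule stimulates regions absent from the circuit: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (r in unique(schedule$rules$region))
    if (circuit$regions[[r]]$n_exc == 0)
      stop(sprintf("stimulated region %s has no excitatory neurons", r),
           call. = FALSE)
  invisible(schedule)
}

#' @export
print.injection_schedule <- function(x, ...) {
  cat(sprintf(
    "Injection schedule '%s': amplitude %g, levels L=%g M=%g H=%g,\n",
    x$model, x$amplitude, x$levels$L, x$levels$M, x$levels$H))
  cat(sprintf("  %d phases of %d ms, perturbation fraction %g\n",
              x$n_phases, x$phase_len, x$perturb_fraction))
  r <- x$rules
  r$band <- ifelse(r$rule == "band", sprintf("(%g, %g)", r$p1, r$p2),
                   ifelse(r$rule == "ramp", sprintf("%g -> %g", r$p1, r$p2),
                          "off"))
  print(r[, c("region", "phase", "rule", "band", "mode")],
        row.names = FALSE)
  invisible(x)
}

#' Load a packaged injection-schedule configuration
#'
#' Reads one of the packaged schedule files (`protocol_empathy.yaml`,
#' `protocol_self_attachment.yaml`) -- or a user file with the same
#' structure: one block per region per phase with the rule, its levels or
#' ramp endpoints, and the mPFC targeting mode -- and returns the
#' corresponding `injection_schedule`.
#'
#' @param model "empathy" or "self_attachment", or a path to a YAML file.
#' @return an object of class `injection_schedule`.
#' @export
schedule_config <- function(model = c("empathy", "self_attachment")) {
  path <- if (file.exists(model[1])) model[1] else {
    model <- match.arg(model)
    system.file("extdata", paste0("protocol_", model, ".yaml"),
                package = "empathynet", mustWork = TRUE)
  }
  y <- yaml::read_yaml(path)
  rules <- do.call(rbind, lapply(y$rules, function(r)
    schedule_rule(r$region, r$phase, r$rule,
                  if (is.null(r$p1)) NA else r$p1,
                  if (is.null(r$p2)) NA else r$p2,
                  if (is.null(r$mode)) NA else r$mode)))
  lv <- stim_levels(y$levels$L, y$levels$M, y$levels$H)
  new_schedule(y$model, lv, rules, y$amplitude, y$perturb_fraction,
               y$phase_len)
}
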