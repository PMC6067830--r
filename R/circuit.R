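#' Region specification
#'
#' A named neural group with an excitatory and an inhibitory subpopulation.
#' The dopaminergic VTA is declared with `da = TRUE`: its principal
#' subpopulation is then labelled `"da"` for reporting and its outgoing
#' projections are inhibitory-signed (dopamine is modeled as inhibition of
#' the target, not as a separate transmitter dynamic).
#'
#' @param name region name, one of the circuit vocabulary
#'   (BLMA_neg, BLMA_pos, BLMA_i, AI, PI, aMCC, mPFC, mPOA, VTA, NAc, VP,
#'   mOFC).
#' @param n_exc,n_inh subpopulation sizes; at least one must be positive.
#' @param type_exc,type_inh Izhikevich preset labels ("RS", "FS", "IB").
#' @param valence one of "positive", "negative", "interneuron", "none".
#' @param da logical; dopaminergic principal population (VTA).
#' @return an object of class `region_spec`.
#' @export
region_spec <- function(name, n_exc, n_inh, type_exc = "RS", type_inh = "FS",
                        valence = "none", da = FALSE) {
  known <- c("BLMA_neg", "BLMA_pos", "BLMA_i", "AI", "PI", "aMCC", "mPFC",
             "mPOA", "VTA", "NAc", "VP", "mOFC")
  if (!name %in% known)
    stop(sprintf("unknown region name '%s'", name), call. = FALSE)
  if (n_exc + n_inh <= 0)
    stop(sprintf("region %s must contain at least one neuron", name),
         call. = FALSE)
  if (name == "BLMA_i" && n_exc > 0)
    stop("BLMA_i is purely inhibitory", call. = FALSE)
  structure(list(name = name, n_exc = as.integer(n_exc),
                 n_inh = as.integer(n_inh), type_exc = type_exc,
                 type_inh = type_inh, valence = valence, da = isTRUE(da)),
            class = "region_spec")
}

# Subpopulations of a region: label, size, Izhikevich type, sign.
region_pops <- function(rs) {
  pops <- list()
  if (rs$n_exc > 0)
    pops[[length(pops) + 1L]] <- list(
      label = if (rs$da) "da" else "exc", n = rs$n_exc, type = rs$type_exc,
      sign = if (rs$da) "inhibitory" else "excitatory")
  if (rs$n_inh > 0)
    pops[[length(pops) + 1L]] <- list(label = "inh", n = rs$n_inh,
                                      type = rs$type_inh, sign = "inhibitory")
  pops
}

#' Projection specification
#'
#' A signed, weighted, probabilistically sampled projection between two
#' subpopulations. The sign must agree with the source subpopulation
#' (inhibitory or dopaminergic sources only form inhibitory projections).
#'
#' @param source,target region names.
#' @param source_pop,target_pop subpopulation labels ("exc", "inh", "da").
#' @param sign "excitatory" or "inhibitory".
#' @param probability per-pair connection probability in \[0, 1\].
#' @param weight synaptic weight magnitude (current units, positive).
#' @param sampling "uniform" (independent Bernoulli per pair) or
#'   "mpfc_gradient" (sources drawn from the ventral-dorsal
#'   negative-binomial gradient; only valid when the source or target is
#'   mPFC).
#' @param gradient for `sampling = "mpfc_gradient"`, which parameter pair to
#'   use: "close" or "distant".
#' @param delay_min,delay_max per-synapse conduction delay range (ms,
#'   integer steps >= 1); each synapse draws its delay uniformly from the
#'   range. Distributed delays desynchronize the delta-synapse dynamics.
#' @return an object of class `projection`.
#' @export
projection <- function(source, source_pop, target, target_pop, sign,
                       probability, weight, sampling = "uniform",
                       gradient = "close", delay_min = 1, delay_max = 1) {
  if (!sign %in% c("excitatory", "inhibitory"))
    stop("sign must be 'excitatory' or 'inhibitory'", call. = FALSE)
  if (probability < 0 || probability > 1)
    stop(sprintf("connection probability %g outside [0,1] on %s->%s",
                 probability, source, target), call. = FALSE)
  if (weight < 0)
    stop("weight must be non-negative", call. = FALSE)
  if (sampling == "mpfc_gradient" && source != "mPFC" && target != "mPFC")
    stop("mpfc_gradient sampling requires mPFC as source or target",
         call. = FALSE)
  if (delay_min < 1 || delay_max < delay_min ||
      delay_min != round(delay_min) || delay_max != round(delay_max))
    stop("delays must be integer steps with 1 <= delay_min <= delay_max",
         call. = FALSE)
  structure(list(source = source, source_pop = source_pop, target = target,
                 target_pop = target_pop, sign = sign,
                 probability = probability, weight = weight,
                 sampling = sampling, gradient = gradient,
                 delay_min = as.integer(delay_min),
                 delay_max = as.integer(delay_max)),
            class = "projection")
}

#' Ventral-dorsal gradient specification for mPFC
#'
#' Negative-binomial (failures-count) parameterizations for sampling mPFC
#' neurons encoding close-other and distant-other representations along the
#' ventral-dorsal axis. With `ventral_at_high_index`, index 0 is the dorsal
#' end of the excitatory mPFC population and the highest index the ventral
#' end, so close-other draws (r = 7, p = 0.0025) land ventrally.
#'
#' @param close,distant numeric vectors `c(r =, p =)`; defaults are the
#'   model's published parameter pairs.
#' @param orientation `"ventral_at_high_index"` or `"ventral_at_low_index"`.
#' @return an object of class `gradient_spec`.
#' @export
gradient_spec <- function(close = c(r = 7, p = 0.0025),
                          distant = c(r = 14, p = 0.035),
                          orientation = "ventral_at_high_index") {
  for (g in list(close, distant)) {
    if (g[["r"]] <= 0 || g[["r"]] != round(g[["r"]]))
      stop("negative-binomial r must be a positive integer", call. = FALSE)
    if (g[["p"]] <= 0 || g[["p"]] >= 1)
      stop("negative-binomial p must lie in (0,1)", call. = FALSE)
  }
  if (!orientation %in% c("ventral_at_high_index", "ventral_at_low_index"))
    stop("unknown axis orientation", call. = FALSE)
  structure(list(close = close, distant = distant, orientation = orientation),
            class = "gradient_spec")
}

#' Sample mPFC gradient target indices
#'
#' Draws neuron indices along the ventral-dorsal axis of the excitatory mPFC
#' population from the requested truncated negative-binomial distribution.
#' Draws outside `[1, mpfc_size]` are rejected and resampled (not clamped),
#' so no probability mass piles up at the boundary.
#'
#' @param spec a [gradient_spec()].
#' @param which "close" or "distant".
#' @param mpfc_size axis length (excitatory mPFC neuron count).
#' @param n_draws number of indices to draw (a multiset; duplicates allowed).
#' @return integer vector of 1-based mPFC indices.
#' @export
sample_mpfc_gradient_targets <- function(spec, which = c("close", "distant"),
                                         mpfc_size, n_draws) {
  which <- match.arg(which)
  stopifnot(inherits(spec, "gradient_spec"), mpfc_size > 0)
  par <- spec[[which]]
  out <- integer(0)
  while (length(out) < n_draws) {
    x <- stats::rnbinom(max(2L * (n_draws - length(out)), 64L),
                        size = par[["r"]], prob = par[["p"]])
    out <- c(out, x[x < mpfc_size])
  }
  x <- out[seq_len(n_draws)]
  if (spec$orientation == "ventral_at_high_index") x + 1L
  else mpfc_size - x
}

#' Realize one projection as a synapse list
#'
#' Independent Bernoulli realization: each (source, target) pair is
#' connected with the projection's connection probability.
#'
#' @param proj a [projection()].
#' @param source_size,target_size subpopulation sizes.
#' @return data frame with columns `source`, `target` (1-based indices
#'   within the subpopulations) and signed `weight`.
#' @export
sample_projection <- function(proj, source_size, target_size) {
  stopifnot(inherits(proj, "projection"), source_size > 0, target_size > 0)
  sgn <- if (proj$sign == "inhibitory") -1 else 1
  if (proj$probability == 0)
    return(data.frame(source = integer(0), target = integer(0),
                      weight = numeric(0)))
  n_pairs <- source_size * target_size
  hit <- which(stats::runif(n_pairs) < proj$probability)
  data.frame(source = ((hit - 1L) %% source_size) + 1L,
             target = ((hit - 1L) %/% source_size) + 1L,
             weight = rep(sgn * proj$weight, length(hit)),
             delay = sample_delays(proj, length(hit)))
}

sample_delays <- function(proj, n) {
  if (proj$delay_max == proj$delay_min) rep(proj$delay_min, n)
  else proj$delay_min +
    sample.int(proj$delay_max - proj$delay_min + 1L, n, replace = TRUE) - 1L
}

# Internal: realize a gradient-sampled projection. The expected synapse
# count matches a uniform projection of the same probability; sources are
# truncated-NB draws along the axis, targets uniform.
sample_gradient_projection <- function(proj, gradient, source_size,
                                       target_size) {
  sgn <- if (proj$sign == "inhibitory") -1 else 1
  n_syn <- round(proj$probability * source_size * target_size)
  if (n_syn == 0)
    return(data.frame(source = integer(0), target = integer(0),
                      weight = numeric(0)))
  src <- sample_mpfc_gradient_targets(gradient, proj$gradient, source_size,
                                      n_syn)
  data.frame(source = src,
             target = sample.int(target_size, n_syn, replace = TRUE),
             weight = rep(sgn * proj$weight, n_syn),
             delay = sample_delays(proj, n_syn))
}

config_field <- function(cfg, name) {
  if (is.null(cfg[[name]]))
    stop(sprintf("circuit config is missing '%s'", name), call. = FALSE)
  cfg[[name]]
}

#' Load a packaged or user circuit configuration
#'
#' @param model "empathy" or "self_attachment" for the packaged calibrated
#'   configurations, or a path to a YAML file of the same structure.
#' @return a nested list (regions, projections, gradient).
#' @export
circuit_config <- function(model = c("empathy", "self_attachment")) {
  path <- if (file.exists(model[1])) model[1] else {
    model <- match.arg(model)
    system.file("extdata", paste0("model_", model, ".yaml"),
                package = "empathynet", mustWork = TRUE)
  }
  yaml::read_yaml(path)
}

build_circuit <- function(config, model) {
  regions <- lapply(config_field(config, "regions"), function(r)
    region_spec(r$name, r$n_exc, r$n_inh,
                type_exc = if (is.null(r$type_exc)) "RS" else r$type_exc,
                type_inh = if (is.null(r$type_inh)) "FS" else r$type_inh,
                valence = if (is.null(r$valence)) "none" else r$valence,
                da = isTRUE(r$da)))
  names(regions) <- vapply(regions, `[[`, "", "name")
  g <- config_field(config, "gradient")
  gradient <- gradient_spec(close = c(r = g$close$r, p = g$close$p),
                            distant = c(r = g$distant$r, p = g$distant$p),
                            orientation = g$orientation)
  projections <- lapply(config_field(config, "projections"), function(p) {
    if (isFALSE(p$enabled)) return(NULL)
    for (nm in c(p$source, p$target))
      if (!nm %in% names(regions))
        stop(sprintf("projection %s->%s references missing region '%s'",
                     p$source, p$target,
                     setdiff(c(p$source, p$target), names(regions))[1]),
             call. = FALSE)
    projection(p$source, p$source_pop, p$target, p$target_pop, p$sign,
               p$probability, p$weight,
               sampling = if (is.null(p$sampling)) "uniform" else p$sampling,
               gradient = if (is.null(p$gradient)) "close" else p$gradient,
               delay_min = if (is.null(p$delay_min)) 1 else p$delay_min,
               delay_max = if (is.null(p$delay_max)) 1 else p$delay_max)
  })
  projections <- projections[!vapply(projections, is.null, TRUE)]
  gain <- if (is.null(config$current_gain)) 1 else config$current_gain
  if (gain <= 0) stop("current_gain must be positive", call. = FALSE)
  cir <- structure(list(model = model, regions = regions,
                        projections = projections, gradient = gradient,
                        heterogeneous = !isFALSE(config$heterogeneous),
                        current_gain = gain,
                        provenance = config_hash(config)),
                   class = "circuit_model")
  validate_circuit(cir)
  cir
}

#' Build the personal-distress / empathic-concern circuit
#'
#' Constructs the eleven-region model: the BLMA valence-split amygdala
#' groups, the AI-PI-aMCC empathy-for-pain core, the gradient-wired mPFC,
#' and the mPOA-VTA-NAc-VP disinhibitory caregiving pathway. The built edge
#' set is validated against the packaged edge manifest.
#'
#' @param config a configuration list from [circuit_config()]; defaults to
#'   the packaged calibrated configuration.
#' @return an object of class `circuit_model`.
#' @export
build_empathy_circuit <- function(config = circuit_config("empathy")) {
  cir <- build_circuit(config, "empathy")
  if ("mOFC" %in% names(cir$regions))
    stop("the empathy circuit does not include mOFC", call. = FALSE)
  cir
}

#' Build the self-attachment circuit (mOFC extension)
#'
#' The empathy circuit plus a twelfth region, mOFC, with excitatory
#' projections to AI, to the BLMA inhibitory interneurons, and to the
#' positively valent BLMA group.
#'
#' @param config a configuration list from [circuit_config()]; defaults to
#'   the packaged calibrated configuration.
#' @return an object of class `circuit_model`.
#' @export
build_self_attachment_circuit <- function(
    config = circuit_config("self_attachment")) {
  cir <- build_circuit(config, "self_attachment")
  if (!"mOFC" %in% names(cir$regions))
    stop("self-attachment circuit config is missing region mOFC",
         call. = FALSE)
  cir
}

#' Edge table of a circuit
#'
#' @param circuit a `circuit_model`.
#' @return data frame of edges (source, source_pop, target, target_pop,
#'   sign, scope).
#' @export
circuit_edges <- function(circuit) {
  do.call(rbind, lapply(circuit$projections, function(p)
    data.frame(source = p$source, source_pop = p$source_pop,
               target = p$target, target_pop = p$target_pop, sign = p$sign,
               scope = if (p$source == p$target) "intra" else "inter")))
}

#' Packaged edge manifest
#'
#' @param model "empathy" or "self_attachment".
#' @return data frame of the expected edge set with a `required` column
#'   (optional edges may be absent from a built circuit).
#' @export
edge_manifest <- function(model = c("empathy", "self_attachment")) {
  model <- match.arg(model)
  utils::read.csv(system.file("extdata", paste0("edges_", model, ".csv"),
                              package = "empathynet", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

edge_key <- function(df)
  paste(df$source, df$source_pop, df$target, df$target_pop, df$sign,
        sep = "|")

#' Validate a circuit against its edge manifest
#'
#' Checks subpopulation references, sign discipline (inhibitory or
#' dopaminergic sources only form inhibitory projections), gradient-sampling
#' placement, and -- when a manifest is available -- exact agreement of the
#' built edge set with the manifest (no missing required edges, no extras).
#'
#' @param circuit a `circuit_model`.
#' @param manifest optional manifest data frame; defaults to the packaged
#'   manifest for the circuit's model.
#' @return the circuit, invisibly; errors list every offending entry.
#' @export
validate_circuit <- function(circuit, manifest = NULL) {
  probs <- character(0)
  for (p in circuit$projections) {
    for (side in list(c(p$source, p$source_pop), c(p$target, p$target_pop))) {
      rs <- circuit$regions[[side[1]]]
      labels <- vapply(region_pops(rs), `[[`, "", "label")
      if (!side[2] %in% labels)
        probs <- c(probs, sprintf("%s has no subpopulation '%s'",
                                  side[1], side[2]))
    }
    src <- circuit$regions[[p$source]]
    src_sign <- vapply(region_pops(src), `[[`, "", "sign")[
      vapply(region_pops(src), `[[`, "", "label") == p$source_pop]
    if (length(src_sign) == 1 && src_sign == "inhibitory" &&
        p$sign != "inhibitory")
      probs <- c(probs, sprintf(
        "inhibitory source %s.%s cannot form an excitatory projection",
        p$source, p$source_pop))
  }
  if (length(probs))
    stop(paste(c("invalid circuit:", probs), collapse = "\n  "),
         call. = FALSE)
  if (is.null(manifest)) {
    path <- system.file("extdata", paste0("edges_", circuit$model, ".csv"),
                        package = "empathynet")
    if (!nzchar(path)) return(invisible(circuit))
    manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  built <- circuit_edges(circuit)
  missing <- setdiff(edge_key(manifest[manifest$required, , drop = FALSE]),
                     edge_key(built))
  extra <- setdiff(edge_key(built), edge_key(manifest))
  if (length(missing) || length(extra))
    stop(paste(c("circuit does not match edge manifest:",
                 if (length(missing)) paste("missing:", missing),
                 if (length(extra)) paste("unexpected:", extra)),
               collapse = "\n  "), call. = FALSE)
  invisible(circuit)
}

# Internal: flatten a circuit into global neuron arrays plus a
# source-indexed CSC synapse structure for the engine. Uses the current RNG
# state (callers seed the connectivity stream first).
realize_circuit <- function(circuit) {
  pop_tab <- do.call(rbind, lapply(circuit$regions, function(rs)
    do.call(rbind, lapply(region_pops(rs), function(p)
      data.frame(region = rs$name, pop = p$label, n = p$n, type = p$type,
                 sign = p$sign)))))
  pop_tab$offset <- cumsum(c(0, head(pop_tab$n, -1)))
  n_total <- sum(pop_tab$n)
  key <- paste(pop_tab$region, pop_tab$pop)
  a <- b <- cc <- d <- numeric(n_total)
  neuron_region <- character(n_total)
  neuron_pop <- character(n_total)
  for (i in seq_len(nrow(pop_tab))) {
    pr <- izhikevich_params(pop_tab$type[i])
    idx <- pop_tab$offset[i] + seq_len(pop_tab$n[i])
    a[idx] <- pr$a; b[idx] <- pr$b; cc[idx] <- pr$c; d[idx] <- pr$d
    neuron_region[idx] <- pop_tab$region[i]
    neuron_pop[idx] <- pop_tab$pop[i]
  }
  if (isTRUE(circuit$heterogeneous)) {
    # canonical per-neuron randomization of the published network recipe:
    # principal cells jitter (c, d) toward bursting variants, fast-spiking
    # cells jitter (a, b) toward low-threshold variants
    for (i in seq_len(nrow(pop_tab))) {
      idx <- pop_tab$offset[i] + seq_len(pop_tab$n[i])
      r <- stats::runif(pop_tab$n[i])
      if (pop_tab$type[i] == "RS") {
        cc[idx] <- -65 + 15 * r^2
        d[idx] <- 8 - 6 * r^2
      } else if (pop_tab$type[i] == "FS") {
        a[idx] <- 0.02 + 0.08 * r
        b[idx] <- 0.25 - 0.05 * r
      }
    }
  }
  src_l <- tgt_l <- w_l <- dly_l <- vector("list", length(circuit$projections))
  for (j in seq_along(circuit$projections)) {
    p <- circuit$projections[[j]]
    so <- pop_tab$offset[key == paste(p$source, p$source_pop)]
    to <- pop_tab$offset[key == paste(p$target, p$target_pop)]
    ns <- pop_tab$n[key == paste(p$source, p$source_pop)]
    nt <- pop_tab$n[key == paste(p$target, p$target_pop)]
    s <- if (p$sampling == "mpfc_gradient")
      sample_gradient_projection(p, circuit$gradient, ns, nt)
    else sample_projection(p, ns, nt)
    if (p$source == p$target && p$source_pop == p$target_pop)
      s <- s[s$source != s$target, , drop = FALSE]
    if (nrow(s)) {
      src_l[[j]] <- so + s$source
      tgt_l[[j]] <- to + s$target
      w_l[[j]] <- s$weight
      dly_l[[j]] <- s$delay
    }
  }
  src <- unlist(src_l); tgt <- unlist(tgt_l)
  w <- unlist(w_l); dly <- unlist(dly_l)
  if (is.null(src)) src <- tgt <- dly <- integer(0)
  if (is.null(w)) w <- numeric(0)
  ord <- order(src)
  ptr <- cumsum(c(0L, tabulate(src, nbins = n_total)))
  list(n = n_total, a = a, b = b, c = cc, d = d,
       v0 = rep(-65, n_total), u0 = b * -65,
       syn_ptr = as.integer(ptr), syn_tgt = as.integer(tgt[ord] - 1L),
       syn_w = w[ord], syn_delay = as.integer(dly[ord]),
       neuron_region = neuron_region,
       neuron_pop = neuron_pop, pop_tab = pop_tab)
}

# Internal: stable hash of a configuration object (provenance only).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' @export
print.circuit_model <- function(x, ...) {
  sizes <- vapply(x$regions, function(r) r$n_exc + r$n_inh, 0)
  cat(sprintf("Circuit model '%s': %d regions, %d neurons, %d projections\n",
              x$model, length(x$regions), sum(sizes),
              length(x$projections)))
  invisible(x)
}

#' @export
summary.circuit_model <- function(object, ...) {
  cat(sprintf("Circuit model '%s'\n\nRegions:\n", object$model))
  for (r in object$regions)
    cat(sprintf("  %-9s exc %4d (%s)  inh %4d (%s)  valence %s%s\n",
                r$name, r$n_exc, r$type_exc, r$n_inh, r$type_inh, r$valence,
                if (r$da) "  [dopaminergic]" else ""))
  cat("\nEdges:\n")
  print(circuit_edges(object), row.names = FALSE)
  invisible(object)
}
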