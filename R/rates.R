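#' Windowed mean firing rate
#'
#' Spike count of a (sub)population in the window `(at_ms - window_ms,
#' at_ms]`, divided by window length in seconds and by the subpopulation
#' size: spikes per neuron per second (Hz).
#'
#' @param result a `simulation_result`.
#' @param region region name.
#' @param subpop "exc", "inh", "da", or "all".
#' @param at_ms report time (window end), ms.
#' @param window_ms window length, ms (default 1000).
#' @return mean firing rate in Hz.
#' @export
compute_mfr <- function(result, region, subpop = "all", at_ms,
                        window_ms = 1000) {
  stopifnot(inherits(result, "simulation_result"))
  if (at_ms - window_ms < 0 || at_ms > result$total_iterations)
    stop("window extends outside the simulated range", call. = FALSE)
  in_pop <- result$neuron_region == region &
    (subpop == "all" | result$neuron_pop == subpop)
  n <- sum(in_pop)
  if (n == 0)
    stop(sprintf("no neurons in %s/%s", region, subpop), call. = FALSE)
  sel <- result$spike_time > at_ms - window_ms & result$spike_time <= at_ms &
    in_pop[result$spike_neuron]
  sum(sel) / (window_ms / 1000) / n
}

#' Rate summary table
#'
#' Mean firing rates for every (region, subpopulation) at each report time,
#' over a trailing window. This is the reporting convention of the model's
#' results: windowed MFRs at 10, 20 and 30 s, the phase end points.
#'
#' @param result a `simulation_result`.
#' @param report_times window end times in ms.
#' @param window_ms window length in ms.
#' @return a data frame of class `rate_summary` with columns `region`,
#'   `subpop`, `time_ms`, `mfr_hz`.
#' @export
rate_summary <- function(result, report_times = c(10000, 20000, 30000),
                         window_ms = 1000) {
  stopifnot(inherits(result, "simulation_result"))
  pt <- result$pop_tab
  rows <- expand.grid(i = seq_len(nrow(pt)), time_ms = report_times)
  out <- data.frame(region = pt$region[rows$i], subpop = pt$pop[rows$i],
                    time_ms = rows$time_ms, stringsAsFactors = FALSE)
  key <- paste(result$neuron_region[result$spike_neuron],
               result$neuron_pop[result$spike_neuron])
  out$mfr_hz <- vapply(seq_len(nrow(out)), function(j) {
    sel <- result$spike_time > out$time_ms[j] - window_ms &
      result$spike_time <= out$time_ms[j] &
      key == paste(out$region[j], out$subpop[j])
    sum(sel) / (window_ms / 1000) / pt$n[rows$i[j]]
  }, 0)
  structure(out, window_ms = window_ms, model = result$model,
            class = c("rate_summary", "data.frame"))
}

#' Average rate summaries across seeds
#'
#' @param summaries list of `rate_summary` objects on identical grids.
#' @return a `rate_summary` with entrywise mean rates.
#' @export
average_rate_summaries <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  out <- summaries[[1]]
  m <- vapply(summaries, function(s) s$mfr_hz, numeric(nrow(out)))
  out$mfr_hz <- rowMeans(matrix(m, nrow = nrow(out)))
  out
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("Mean firing rates (Hz), %d ms window%s:\n",
              attr(x, "window_ms"),
              if (!is.null(attr(x, "model")))
                sprintf(", '%s' model", attr(x, "model")) else ""))
  wide <- stats::reshape(as.data.frame(x), idvar = c("region", "subpop"),
                         timevar = "time_ms", direction = "wide")
  names(wide) <- sub("mfr_hz.", "t=", names(wide), fixed = TRUE)
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Bar plot of a rate summary
#'
#' @param x a `rate_summary`.
#' @param regions optional subset of regions.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.rate_summary <- function(x, regions = NULL, ...) {
  df <- as.data.frame(x)
  if (!is.null(regions)) df <- df[df$region %in% regions, , drop = FALSE]
  lab <- paste(df$region, df$subpop, sep = ".")
  tab <- tapply(df$mfr_hz, list(factor(df$time_ms), lab), mean)
  graphics::barplot(tab, beside = TRUE, las = 2, ylab = "MFR (Hz)",
                    legend.text = paste0(as.numeric(rownames(tab)) / 1000,
                                         " s"), ...)
  invisible(x)
}

#' Packaged reference firing-rate table
#'
#' The mean firing rates reported for the two models, transcribed as a
#' table keyed by region, subpopulation and report time.
#'
#' @param model "empathy" or "self_attachment".
#' @return data frame with columns `region`, `subpop`, `time_ms`, `mfr_hz`.
#' @export
reference_mfr <- function(model = c("empathy", "self_attachment")) {
  model <- match.arg(model)
  utils::read.csv(system.file("extdata",
                              paste0("reference_mfr_", model, ".csv"),
                              package = "empathynet", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Default thresholds for network-state classification
#'
#' @param vp_low VP rate (Hz) below which caregiving output counts as
#'   silent ("low").
#' @param vp_high VP rate (Hz) at or above which caregiving output counts
#'   as high.
#' @param blma_suppression compassion requires the negatively valent BLMA
#'   group to fall below this fraction of its phase-1 rate.
#' @param mofc_active compassion requires the excitatory mOFC rate to reach
#'   this level (Hz).
#' @return named list of thresholds.
#' @export
state_thresholds <- function(vp_low = 0.5, vp_high = 2,
                             blma_suppression = 0.7, mofc_active = 1) {
  list(vp_low = vp_low, vp_high = vp_high,
       blma_suppression = blma_suppression, mofc_active = mofc_active)
}

rate_at <- function(summary, region, subpop, time_ms) {
  v <- summary$mfr_hz[summary$region == region & summary$subpop == subpop &
                        summary$time_ms == time_ms]
  if (length(v) != 1) NA_real_ else v
}

#' Classify the network state of each phase
#'
#' Rule-based labels from end-of-phase rates: personal distress is a silent
#' VP with the self-pain network active; weak empathic concern is moderate
#' VP output; strong empathic concern is high VP output; compassion is high
#' VP output with an active mOFC and a suppressed negatively valent BLMA
#' group (below a fraction of its phase-1 rate).
#'
#' @param summary a `rate_summary` whose report times are the three phase
#'   ends.
#' @param thresholds a [state_thresholds()] list.
#' @return a data frame of class `state_labels`: `phase`, `label`,
#'   `evidence`.
#' @export
classify_states <- function(summary, thresholds = state_thresholds()) {
  times <- sort(unique(summary$time_ms))
  if (length(times) != 3)
    stop("classification requires rates at the three phase ends",
         call. = FALSE)
  if (all(summary$mfr_hz == 0))
    stop("insufficient activity: all rates are zero", call. = FALSE)
  has_mofc <- "mOFC" %in% summary$region
  blma1 <- rate_at(summary, "BLMA_neg", "exc", times[1])
  out <- lapply(seq_along(times), function(i) {
    tm <- times[i]
    vp <- rate_at(summary, "VP", "inh", tm)
    blma <- rate_at(summary, "BLMA_neg", "exc", tm)
    mofc <- if (has_mofc) rate_at(summary, "mOFC", "exc", tm) else NA_real_
    ev <- c(sprintf("VP=%.2f", vp), sprintf("BLMA_neg=%.2f", blma),
            if (has_mofc) sprintf("mOFC=%.2f", mofc))
    label <- if (vp < thresholds$vp_low) {
      ev <- c(ev, sprintf("VP < %g (silent caregiving output)",
                          thresholds$vp_low))
      "personal_distress"
    } else if (vp >= thresholds$vp_high && has_mofc &&
               !is.na(mofc) && mofc >= thresholds$mofc_active &&
               !is.na(blma1) && blma <= thresholds$blma_suppression * blma1) {
      ev <- c(ev, sprintf("VP >= %g, mOFC >= %g, BLMA_neg <= %g * phase-1",
                          thresholds$vp_high, thresholds$mofc_active,
                          thresholds$blma_suppression))
      "compassion"
    } else if (vp >= thresholds$vp_high) {
      ev <- c(ev, sprintf("VP >= %g", thresholds$vp_high))
      "strong_empathic_concern"
    } else {
      ev <- c(ev, sprintf("VP in [%g, %g)", thresholds$vp_low,
                          thresholds$vp_high))
      "weak_empathic_concern"
    }
    data.frame(phase = i, label = label,
               evidence = paste(ev, collapse = "; "))
  })
  structure(do.call(rbind, out), class = c("state_labels", "data.frame"))
}

#' @export
print.state_labels <- function(x, ...) {
  cat("Network-state labels:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  phase %d: %-24s [%s]\n", x$phase[i], x$label[i],
                x$evidence[i]))
  invisible(x)
}

#' Compare a rate summary to a reference table
#'
#' Entrywise tolerance check: an entry passes when
#' `|sim - ref| <= max(abs_tol, rel_tol * ref)`.
#'
#' @param summary a `rate_summary` (typically seed-averaged).
#' @param reference reference table as from [reference_mfr()].
#' @param rel_tol relative tolerance.
#' @param abs_tol absolute tolerance (Hz).
#' @return a data frame of class `mfr_comparison` with per-entry `sim`,
#'   `ref`, `tol`, `pass`, and attribute `pass_fraction`.
#' @export
compare_to_reference <- function(summary, reference, rel_tol = 0.25,
                                 abs_tol = 0.3) {
  ref <- reference
  ref$sim <- mapply(function(r, s, t) rate_at(summary, r, s, t),
                    ref$region, ref$subpop, ref$time_ms)
  if (any(is.na(ref$sim)))
    stop("summary does not cover all reference entries", call. = FALSE)
  ref$tol <- pmax(abs_tol, rel_tol * ref$mfr_hz)
  ref$pass <- abs(ref$sim - ref$mfr_hz) <= ref$tol
  names(ref)[names(ref) == "mfr_hz"] <- "ref"
  structure(ref, pass_fraction = mean(ref$pass),
            class = c("mfr_comparison", "data.frame"))
}

#' @export
print.mfr_comparison <- function(x, ...) {
  cat(sprintf("Reference comparison: %d/%d entries pass (%.0f%%)\n",
              sum(x$pass), nrow(x), 100 * attr(x, "pass_fraction")))
  print(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}
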