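# Shared cache of full-length packaged-model runs used by the acceptance
# tests: rate summaries for seeds 1..10 of both models, computed once per
# test session (only summaries are retained).
.run_cache <- new.env(parent = emptyenv())

model_summaries <- function(model, seeds = 1:10) {
  key <- paste(model, paste(range(seeds), collapse = "-"))
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- lapply(seeds, function(s)
      rate_summary(run_model(model, seed = s)))
  }
  .run_cache[[key]]
}

rate_of <- function(s, region, subpop, time_ms)
  s$mfr_hz[s$region == region & s$subpop == subpop & s$time_ms == time_ms]
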