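# Shared cohort battery for the qualitative-reproduction checks: 100
# simulated cohorts (n = 10, dwell fractions spanning 0-0.6, full-size
# analysis parameters), each summarized to the per-cohort correlations
# of interest. Computed once and cached for the whole test run.

cohort_battery <- local({
  cache <- NULL
  function(n_cohorts = 100, base_seed = 1000) {
    if (!is.null(cache)) return(cache)
    params <- analysis_params(channels = "SI")
    rows <- lapply(seq_len(n_cohorts), function(i) {
      co <- simulate_cohort(n_participants = 10, seed = base_seed + i,
                            n_trials = 3)
      s <- cohort_summary(co, params)
      data.frame(
        cohort = i,
        det_rho = correlation_test(s$cpi, s$det_SI, "spearman")$r,
        asyn_r = correlation_test(s$cpi, s$asyn_up, "pearson")$r)
    })
    cache <<- do.call(rbind, rows)
    cache
  }
})
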