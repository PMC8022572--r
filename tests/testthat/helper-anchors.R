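# The four-scenario anchor suite (10 replicates x 20,000 ticks each) is the
# most expensive computation in the test run; it is shared by the qualitative
# regime checks and the printed-number anchor comparison, so compute it once.
anchor_suite_results <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_anchor_suite(default_config(), n_replicates = 10L,
                                 quiet = TRUE)
    cache
  }
})
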