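# Shared small simulation fixtures. Panels are generated in code at test
# time; baseline rates are scaled up so the short windows still carry
# informative counts.

small_cfg <- function(n_regions = 3, years = 2001:2004, seed = 42,
                      baseline_rate = 4e-7, ...) {
  sim_config(n_regions = n_regions,
             date_range = c(sprintf("%d-01-01", min(years)),
                            sprintf("%d-12-31", max(years))),
             seed = seed, baseline_rate = baseline_rate, ...)
}

small_panels <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_panels(small_cfg())
    cache
  }
})
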