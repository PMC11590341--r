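# Shared fixtures, generated in code. The full-size cohort is cached because
# several files exercise it.

default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(sim_config(seed = 101L))
    cache
  }
})

# raw panel from plain matrices, for unit tests of single operations
toy_panel <- function(values, creatinine = rep(1, nrow(values)),
                      stage = "raw") {
  metabolite_panel(values, creatinine, stage = stage)
}

# small survival data with a binary covariate and exponential hazards
two_group_exponential <- function(n = 4000, rate_ratio = 2, seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, rate = 0.1 * rate_ratio^x)
  cens <- runif(n, 0, 25)
  data.frame(
    x = x,
    time = pmin(t_event, cens),
    event = as.integer(t_event <= cens)
  )
}
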