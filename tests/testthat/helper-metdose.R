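# Shared fixtures: reduced-but-gated sampler settings and a compact
# two-arm cohort builder used across model tests.

fast_mcmc <- function(seed = 1L, sampling = 2500L, chains = 2L,
                      warmup = 500L) {
  mcmc_config(chains = chains, warmup = warmup, sampling = sampling,
              seed = seed)
}

# Two groups with configurable true per-lift changes and noise.
two_arm_config <- function(ch_a, ch_b, n = 10, sd = 2, slope = 0,
                           seed = 1L) {
  mk <- function(label, ch) {
    group_config(label, n = n, slope = slope, lifts = tibble::tibble(
      lift = c("SQ", "BP", "DL"),
      pre_location = c(180, 120, 210), pre_scale = c(30, 18, 32),
      change_mean = ch, change_sd = rep(sd, 3)
    ))
  }
  cohort_config(list(mk("A", ch_a), mk("B", ch_b)), seed = seed)
}
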