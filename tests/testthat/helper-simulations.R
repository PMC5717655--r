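# Shared, lazily computed default-condition runs (the expensive part of the
# suite): one paired control/learning experiment at the standard settings
# (n = 7, days 0-60, 1000 encounters/day, 10 replicate litters, paired seeds).
.sim_cache <- new.env(parent = emptyenv())

default_runs <- function(seed = 1) {
  key <- paste0("seed", seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- list(
      control = run_development("control", seed = seed),
      learning = run_development("learning", seed = seed)
    )
  }
  .sim_cache[[key]]
}

# Mean long-run group size implied by a tibble of partition-state frequencies
# (state keys are dot-separated group labels, one per pup).
chain_mean_group_size <- function(freqs, n) {
  ngroups <- vapply(strsplit(freqs$state, ".", fixed = TRUE),
                    function(s) length(unique(s)), 1L)
  sum(freqs$frequency * n / ngroups)
}
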