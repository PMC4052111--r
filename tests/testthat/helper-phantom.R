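# Shared fixtures: small phantoms built in code, no files.

clean_spec <- function(seed = 1L, noise_sd = 0) {
  # no noise, no vessels, no rim: the exact forward-model phantom
  phantom_spec(noise_sd = noise_sd,
               artifact = list(n_clusters = 0, amplitude = 0,
                               decay_tc = 1000, extinction_delay = 1000),
               m0_rim = list(factor = 1, cbf_factor = 1),
               seed = seed)
}

default_acq <- function() acq_params(ti1 = 800, ti2_base = 1800)

ti2_ladder <- function() c(50, seq(300, 3300, by = 300))

quiet <- function(expr) suppressMessages(expr)
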