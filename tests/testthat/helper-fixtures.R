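# Shared fixtures: everything is generated in code at test time.

conf_criteria <- c(-1, -0.5, 0, 0.5, 1)

make_conf_params <- function(R_aloud = 0.3, R_silent = 0.3,
                             d_aloud = 1, d_silent = 1, ...) {
  generative_params(R_aloud, R_silent, d_aloud, d_silent,
                    criteria = conf_criteria, ...)
}

make_rk_params <- function(R_aloud = 0.25, R_silent = 0.12,
                           d_aloud = 1.1, d_silent = 0.85,
                           criterion = 0.5, ...) {
  generative_params(R_aloud, R_silent, d_aloud, d_silent,
                    criteria = criterion, ...)
}

# reduced sampler settings for simulation-heavy tests; user-facing defaults
# stay at 4 chains x 1000 retained draws
fast <- list(chains = 2, adapt = 300, burn = 300, iter = 600)

fit_logistic_fast <- function(trials, coding, seed = 1, ...) {
  fit_multilevel_logistic(trials, coding = coding, item_re = FALSE,
                          chains = fast$chains, adapt = fast$adapt,
                          burn = fast$burn, iter = fast$iter,
                          seed = seed, ...)
}
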