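# Shared helpers: deterministic benchmark series and small cohorts.

white_series <- function(n, seed) gen_noise(noise_spec("white", n, seed = seed))

brownian_series <- function(n, seed) gen_noise(noise_spec("brownian", n, seed = seed))

scaled_white <- function(n, seed) zscale(white_series(n, seed))

scaled_brownian <- function(n, seed) zscale(brownian_series(n, seed))

# small cohort config used across inference tests; 2 timepoints keep the
# mixed-model fits fast while every factor still varies
small_cohort <- function(seed, n_chi = c(12L, 8L), n_mci = c(10L, 6L),
                         fixed_effects = default_fixed_effects()) {
  cohort_config(
    counts = matrix(c(n_chi, n_mci), nrow = 2, byrow = TRUE,
                    dimnames = list(c("CHI", "MCI"), NULL)),
    fixed_effects = fixed_effects,
    seed = seed
  )
}

# a constant-force trial wrapper around raw samples
make_trial <- function(samples, rate_hz = 120, mvc_n = 24) {
  force_trial(samples, rate_hz = rate_hz, hand = "left", role = "stabilizing",
              condition = "bimanual_constant", participant_id = "P01",
              timepoint = 1L, mvc_n = mvc_n)
}
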