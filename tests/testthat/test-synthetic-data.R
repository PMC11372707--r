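test_that("gen_noise validates its spec and is deterministic", {
  expect_error(noise_spec("white", 8), class = "forcefluct_invalid_argument")
  expect_error(noise_spec("power_law", 100, target_alpha = 2.0),
               class = "forcefluct_invalid_argument")
  expect_error(noise_spec("power_law", 100),
               class = "forcefluct_invalid_argument")
  expect_error(noise_spec("white", 100, target_alpha = 1),
               class = "forcefluct_invalid_argument")
  for (kind in c("white", "brownian")) {
    a <- gen_noise(noise_spec(kind, 256, seed = 11))
    b <- gen_noise(noise_spec(kind, 256, seed = 11))
    expect_identical(a, b)
    expect_length(a, 256)
  }
  p1 <- gen_noise(noise_spec("power_law", 257, target_alpha = 0.9, seed = 4))
  p2 <- gen_noise(noise_spec("power_law", 257, target_alpha = 0.9, seed = 4))
  expect_identical(p1, p2)
  expect_length(p1, 257)  # odd lengths exercise the non-Nyquist branch
})

test_that("white noise converges to mean 0, SD 1", {
  n <- 1e5
  x <- white_series(n, seed = 21)
  tol <- 3 / sqrt(n)
  expect_lt(abs(mean(x)), tol)
  expect_lt(abs(sd(x) - 1), tol)
  # brownian is the cumulative sum of the same stream
  expect_equal(brownian_series(1000, seed = 5),
               cumsum(white_series(1000, seed = 5)))
})

test_that("power-law noise has the prescribed periodogram slope", {
  # independent spectral oracle: least-squares fit to the raw periodogram;
  # with target alpha = 1 the power-spectrum slope must be beta = -1
  x <- gen_noise(noise_spec("power_law", 4096, target_alpha = 1.0, seed = 9))
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  f <- (1:(n / 2 - 1)) / n
  slope <- coef(lm(log(p[2:(n / 2)]) ~ log(f)))[[2]]
  expect_equal(slope, -1.0, tolerance = 0.02)
})

test_that("DFA recovers the power-law target exponent (reduced sweep)", {
  # full 20-seed sweep over 5 exponents lives in the acceptance suite
  for (a in c(0.7, 1.3)) {
    est <- vapply(1:5, function(s) {
      dfa_alpha(gen_noise(noise_spec("power_law", 4096, a, seed = s)))$alpha
    }, numeric(1))
    expect_lt(abs(mean(est) - a), 0.1)
  }
})

test_that("noise-free trials are exactly on target after the ramp", {
  cfg <- trial_config(noise_sd_pct = 0, measurement_noise_sd = 0,
                      crosstalk_lambda = 0)
  pair <- gen_bimanual_trial(cfg)
  stab <- exclude_ramp(normalize_to_mvc(pair$stabilizing), 6)
  expect_equal(length(stab$values), 1680)
  expect_true(all(abs(stab$values - 12) < 1e-12))
  # manipulating target: peak-to-peak 7 %MVC, period 5 s (600 samples)
  manip <- exclude_ramp(normalize_to_mvc(pair$manipulating), 6)
  expect_equal(max(manip$values) - min(manip$values), 7, tolerance = 1e-6)
  expect_equal(manip$values[1:1080], manip$values[601:1680], tolerance = 1e-9)
})

test_that("trial generator validates geometry", {
  expect_error(trial_config(duration_s = 5, ramp_s = 6),
               class = "forcefluct_invalid_argument")
  expect_error(trial_config(rate_hz = 0.3, sine_freq_hz = 0.2),
               class = "forcefluct_invalid_argument")
  expect_error(trial_config(sine_lo_pct = 12, sine_hi_pct = 5),
               class = "forcefluct_invalid_argument")
  expect_error(trial_config(crosstalk_lambda = -1),
               class = "forcefluct_invalid_argument")
})

test_that("crosstalk leaks oscillation power into the stabilizing channel", {
  band_power <- function(x, rate) {
    n <- length(x)
    p <- Mod(fft(x - mean(x)))^2 / n
    f <- (seq_len(n) - 1) * rate / n
    sum(p[f >= 0.15 & f <= 0.25])
  }
  pw <- vapply(1:10, function(s) {
    get_stab <- function(lambda) {
      cfg <- trial_config(crosstalk_lambda = lambda, seed = s)
      pair <- gen_bimanual_trial(cfg)
      exclude_ramp(normalize_to_mvc(pair$stabilizing), 6)$values
    }
    c(band_power(get_stab(0.5), 120), band_power(get_stab(0), 120))
  }, numeric(2))
  expect_gt(mean(pw[1, ]), mean(pw[2, ]))
  expect_true(all(pw[1, ] > pw[2, ]))
})

test_that("classify_mci implements the two-step screening rule", {
  expect_identical(classify_mci(27, rep(-3, 9)), "CHI")   # MoCA not below 26
  expect_identical(classify_mci(24, rep(-1.5, 9)), "CHI") # no score below -1.5
  expect_identical(classify_mci(24, c(rep(0, 8), -1.6)), "MCI")
  expect_identical(classify_mci(25, c(-1.51, rep(1, 8))), "MCI")
  expect_error(classify_mci(24, rep(0, 8)), class = "forcefluct_invalid_argument")
  expect_error(classify_mci(31, rep(0, 9)), class = "forcefluct_invalid_argument")
  # pure function: permuting the CERAD scores never changes the label
  set.seed(33)
  for (i in 1:20) {
    moca <- sample(0:30, 1)
    z <- rnorm(9, -0.75, 1)
    lab <- classify_mci(moca, z)
    expect_identical(classify_mci(moca, sample(z)), lab)
  }
})

test_that("gen_cohort reproduces the configured cell structure exactly", {
  cfg <- cohort_config(seed = 7)
  cohort <- gen_cohort(cfg)
  sub <- cohort$subjects
  expect_equal(sum(sub$group == "CHI"), 77)
  expect_equal(sum(sub$group == "MCI"), 55)
  # nested dropout: counts at every timepoint match the configured matrix
  for (tp in 1:4) {
    for (g in c("CHI", "MCI")) {
      expect_equal(sum(sub$group == g & sub$t_max >= tp),
                   default_cohort_counts()[g, tp])
    }
  }
  # labels consistent with the screening rule by construction
  cerad <- as.matrix(sub[, paste0("cerad_z", 1:9)])
  relabel <- vapply(seq_len(nrow(sub)),
                    function(i) classify_mci(sub$moca[i], cerad[i, ]),
                    character(1))
  expect_identical(relabel, sub$group)
  # observation table: 4 cells per subject-timepoint
  expect_equal(nrow(cohort$observations),
               4 * sum(default_cohort_counts()))
  expect_true(all(cohort$observations$outcome == "cv"))
})

test_that("gen_cohort is deterministic and respects substreams", {
  cfg <- small_cohort(seed = 19)
  a <- gen_cohort(cfg)
  b <- gen_cohort(cfg)
  expect_identical(a, b)
  c2 <- gen_cohort(small_cohort(seed = 20))
  expect_false(identical(a$observations$value, c2$observations$value))
})

test_that("signal-level cohort synthesis stamps metadata correctly", {
  cfg <- cohort_config(
    counts = matrix(c(2L, 1L), nrow = 2,
                    dimnames = list(c("CHI", "MCI"), "T1")),
    trials_per_cell = c(bimanual_constant = 1L, role_differentiated = 2L),
    seed = 3
  )
  cohort <- gen_cohort(cfg, signals = TRUE)
  # per subject: 1 BC pair + 2 RD pairs per stabilizing hand = 5 pairs
  expect_length(cohort$trials, 3 * 5 * 2)
  conds <- vapply(cohort$trials, function(t) t$condition, character(1))
  expect_equal(sum(conds == "bimanual_constant"), 3 * 2)
  ids <- vapply(cohort$trials, function(t) t$participant_id, character(1))
  expect_setequal(unique(ids), cohort$subjects$id)
  expect_true(all(vapply(cohort$trials, function(t)
    length(t$samples) == 2400, logical(1))))
})
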