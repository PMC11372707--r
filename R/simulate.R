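#' Configure a synthetic bimanual trial
#'
#' Describes one 20-s visuomotor force-tracking trial at 120 Hz. The
#' stabilizing hand ramps from zero to a constant target of 12% MVC over
#' the first 6 s, then holds it with additive colored noise, optional
#' crosstalk leakage from the manipulating hand's oscillation, and white
#' measurement noise. The manipulating hand ramps to the midpoint of a
#' 0.2 Hz sine wave spanning 5-12% MVC and then follows it.
#'
#' @param duration_s trial length in seconds (default 20; must exceed
#'   `ramp_s`).
#' @param ramp_s ramp duration in seconds (default 6).
#' @param rate_hz sampling rate (default 120; must exceed
#'   `2 * sine_freq_hz`).
#' @param mvc_n maximum voluntary contraction in Newtons.
#' @param constant_target_pct constant target, % MVC (default 12).
#' @param sine_freq_hz oscillation frequency (default 0.2 Hz).
#' @param sine_lo_pct,sine_hi_pct oscillation range, % MVC (defaults 5, 12).
#' @param crosstalk_lambda leakage gain (>= 0) of the mean-centered
#'   manipulating oscillation into the stabilizing channel; 0 disables.
#' @param noise a [noise_spec()] for the stabilizing channel's colored
#'   noise; its `n_samples` and `seed` are overridden at generation time to
#'   match the trial. Default: power-law noise with scaling exponent 1.38,
#'   the typical exponent of real constant-force series in this task.
#' @param noise_sd_pct SD of the colored noise, % MVC (default 0.8, which
#'   reproduces realistic CVs around 6-7% at the 12% MVC target).
#' @param measurement_noise_sd SD of the additive white sensor noise,
#'   % MVC (default 0.05).
#' @param seed integer seed.
#' @return object of class `trial_config`.
#' @export
trial_config <- function(duration_s = 20, ramp_s = 6, rate_hz = 120,
                         mvc_n = 24, constant_target_pct = 12,
                         sine_freq_hz = 0.2, sine_lo_pct = 5,
                         sine_hi_pct = 12, crosstalk_lambda = 0,
                         noise = NULL, noise_sd_pct = 0.8,
                         measurement_noise_sd = 0.05, seed = 1L) {
  for (nm in c("duration_s", "ramp_s", "rate_hz", "mvc_n",
               "constant_target_pct", "sine_freq_hz", "sine_lo_pct",
               "sine_hi_pct", "crosstalk_lambda", "noise_sd_pct",
               "measurement_noise_sd", "seed"))
    assert_scalar_number(get(nm), nm)
  if (duration_s <= ramp_s)
    ff_stop("`duration_s` must exceed `ramp_s`", "forcefluct_invalid_argument")
  if (rate_hz <= 2 * sine_freq_hz)
    ff_stop("`rate_hz` must exceed twice `sine_freq_hz`",
            "forcefluct_invalid_argument")
  if (sine_lo_pct >= sine_hi_pct)
    ff_stop("`sine_lo_pct` must be below `sine_hi_pct`",
            "forcefluct_invalid_argument")
  if (crosstalk_lambda < 0)
    ff_stop("`crosstalk_lambda` must be non-negative",
            "forcefluct_invalid_argument")
  if (mvc_n <= 0)
    ff_stop("`mvc_n` must be positive", "forcefluct_invalid_argument")
  n <- as.integer(round(duration_s * rate_hz))
  if (is.null(noise))
    noise <- noise_spec("power_law", n_samples = n, target_alpha = 1.38,
                        seed = seed)
  if (!inherits(noise, "noise_spec"))
    ff_stop("`noise` must be a noise_spec", "forcefluct_invalid_argument")
  structure(list(duration_s = duration_s, ramp_s = ramp_s, rate_hz = rate_hz,
                 mvc_n = mvc_n, constant_target_pct = constant_target_pct,
                 sine_freq_hz = sine_freq_hz, sine_lo_pct = sine_lo_pct,
                 sine_hi_pct = sine_hi_pct,
                 crosstalk_lambda = crosstalk_lambda, noise = noise,
                 noise_sd_pct = noise_sd_pct,
                 measurement_noise_sd = measurement_noise_sd,
                 seed = as.integer(seed)),
            class = "trial_config")
}

# Colored noise for one channel, rescaled to a given SD (in % MVC). A zero
# SD short-circuits to exact zeros so noise-free trials are exactly constant.
channel_noise <- function(cfg, n, seed, sd_pct) {
  if (sd_pct == 0) return(numeric(n))
  spec <- cfg$noise
  spec$n_samples <- n
  spec$seed <- seed
  z <- gen_noise(spec)
  z <- z - mean(z)
  s <- stats::sd(z)
  if (s > 0) z <- z / s
  z * sd_pct
}

#' Generate one synthetic bimanual trial
#'
#' Produces the stabilizing and manipulating channel of a single trial as a
#' pair of [force_trial()] objects (forces in Newtons via `mvc_n`). In the
#' role-differentiated condition the manipulating channel follows the
#' 0.2 Hz sine target; in the bimanual constant condition both channels are
#' constant at the target, each with its own noise stream, and crosstalk is
#' inapplicable.
#'
#' Crosstalk is modeled as additive linear leakage of the mean-centered
#' manipulating target into the stabilizing channel, scaled by
#' `crosstalk_lambda` — the simplest mechanism that produces a mirror-
#' movement signature (excess stabilizing-channel power at the oscillation
#' frequency) without committing to a neural model.
#'
#' @param cfg a [trial_config()].
#' @param condition `"role_differentiated"` (default) or
#'   `"bimanual_constant"`.
#' @param stabilizing_hand which hand stabilizes (default `"left"`); in the
#'   bimanual constant condition this only names the first channel.
#' @param participant_id,timepoint metadata stamped on both trials.
#' @return list with elements `stabilizing` and `manipulating`, each a
#'   [force_trial()].
#' @export
gen_bimanual_trial <- function(cfg,
                               condition = c("role_differentiated",
                                             "bimanual_constant"),
                               stabilizing_hand = c("left", "right"),
                               participant_id = "P01", timepoint = 1L) {
  if (!inherits(cfg, "trial_config"))
    ff_stop("`cfg` must be a trial_config", "forcefluct_invalid_argument")
  condition <- match.arg(condition)
  stabilizing_hand <- match.arg(stabilizing_hand)
  other_hand <- if (stabilizing_hand == "left") "right" else "left"
  n <- as.integer(round(cfg$duration_s * cfg$rate_hz))
  t <- (seq_len(n) - 1L) / cfg$rate_hz
  ramp_frac <- pmin(t / cfg$ramp_s, 1)

  mid <- (cfg$sine_lo_pct + cfg$sine_hi_pct) / 2
  amp <- (cfg$sine_hi_pct - cfg$sine_lo_pct) / 2
  manip_target <-
    if (condition == "role_differentiated")
      ifelse(t < cfg$ramp_s, ramp_frac * mid,
             mid + amp * sin(2 * pi * cfg$sine_freq_hz * (t - cfg$ramp_s)))
    else ramp_frac * cfg$constant_target_pct

  stab_target <- ramp_frac * cfg$constant_target_pct
  stab <- stab_target +
    channel_noise(cfg, n, substream_seed(cfg$seed, "trial-stab"), cfg$noise_sd_pct)
  if (condition == "role_differentiated" && cfg$crosstalk_lambda > 0) {
    post <- t >= cfg$ramp_s
    osc <- manip_target
    osc[post] <- osc[post] - mean(osc[post])
    osc[!post] <- 0
    stab <- stab + cfg$crosstalk_lambda * osc
  }
  manip <- manip_target +
    channel_noise(cfg, n, substream_seed(cfg$seed, "trial-manip"), cfg$noise_sd_pct)
  if (cfg$measurement_noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(substream_seed(cfg$seed, "trial-meas"))
    stab <- stab + stats::rnorm(n, sd = cfg$measurement_noise_sd)
    manip <- manip + stats::rnorm(n, sd = cfg$measurement_noise_sd)
  }

  to_newton <- function(pct) pct * cfg$mvc_n / 100
  list(
    stabilizing = force_trial(to_newton(stab), cfg$rate_hz,
                              hand = stabilizing_hand, role = "stabilizing",
                              condition = condition,
                              participant_id = participant_id,
                              timepoint = timepoint, mvc_n = cfg$mvc_n),
    manipulating = force_trial(to_newton(manip), cfg$rate_hz,
                               hand = other_hand,
                               role = if (condition == "role_differentiated")
                                 "manipulating" else "stabilizing",
                               condition = condition,
                               participant_id = participant_id,
                               timepoint = timepoint, mvc_n = cfg$mvc_n)
  )
}

#' Classify cognitive status from screening scores
#'
#' Two-step screening rule: a participant is labeled MCI if and only if the
#' MoCA sum score is below 26 points AND at least one of the nine CERAD-NP
#' domain z-scores falls below -1.5 SD of the normative mean. Everyone else
#' is a cognitively healthy individual (CHI).
#'
#' @param moca integer MoCA sum score, 0-30.
#' @param cerad_z numeric vector of exactly 9 CERAD-NP z-scores.
#' @return `"MCI"` or `"CHI"`.
#' @examples
#' classify_mci(27, rep(0, 9))        # "CHI": MoCA not below 26
#' classify_mci(24, rep(-1, 9))       # "CHI": no CERAD score below -1.5
#' classify_mci(24, c(-1.6, rep(0, 8)))  # "MCI"
#' @export
classify_mci <- function(moca, cerad_z) {
  assert_scalar_number(moca, "moca")
  if (moca < 0 || moca > 30)
    ff_stop("`moca` must lie in [0, 30]", "forcefluct_invalid_argument")
  if (!is.numeric(cerad_z) || length(cerad_z) != 9L || anyNA(cerad_z))
    ff_stop("`cerad_z` must contain exactly 9 finite z-scores",
            "forcefluct_invalid_argument")
  if (moca < 26 && min(cerad_z) < -1.5) "MCI" else "CHI"
}
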