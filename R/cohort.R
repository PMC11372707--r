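#' Default cohort-sequential cell counts
#'
#' Participants per group at the four measurement points, following the
#' enrolment/dropout pattern of the study the generator emulates: 77/52/33/11
#' cognitively healthy individuals and 55/34/15/3 with MCI at timepoints 1-4.
#' Later timepoints are nested subsets of earlier ones (pure dropout).
#'
#' @return 2 x 4 integer matrix with rows `CHI`, `MCI`.
#' @export
default_cohort_counts <- function() {
  matrix(c(77L, 52L, 33L, 11L,
           55L, 34L, 15L, 3L),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("CHI", "MCI"), paste0("T", 1:4)))
}

#' Default generative fixed effects (CV scale)
#'
#' Term-to-beta map on the coefficient-of-variation scale used as the
#' generative truth for parameter-recovery simulations: intercept 4.33 %CV,
#' condition (role-differentiated vs bimanual constant) +2.40, group (MCI vs
#' CHI) +1.76, hand (right vs left) -0.36, sex (female vs male) +2.20,
#' timepoint slope -0.10 per visit, condition x group -0.42, condition x
#' hand +1.24.
#'
#' @return named numeric vector.
#' @export
default_fixed_effects <- function() {
  c("(Intercept)" = 4.33, condition = 2.40, group = 1.76, hand = -0.36,
    sex = 2.20, timepoint = -0.10, "condition:group" = -0.42,
    "condition:hand" = 1.24)
}

#' Configure a synthetic cohort
#'
#' @param counts group-by-timepoint participant counts; defaults to
#'   [default_cohort_counts()]. Rows `CHI`/`MCI`, one column per timepoint;
#'   columns must be non-increasing (dropout only).
#' @param fixed_effects named numeric vector of generative betas on the
#'   outcome scale; names use the treatment-coded terms of
#'   [fit_mixed_model()] (see [default_fixed_effects()]).
#' @param outcome which measure the betas live on: `"cv"`, `"dfa_alpha"`
#'   or `"sen"`.
#' @param random_intercept_sd SD of the per-participant Gaussian random
#'   intercept, outcome units (default 3.5, matching the between-subject
#'   spread of CV of roughly 4-5 %CV total SD).
#' @param residual_sd SD of the i.i.d. residual, outcome units
#'   (default 2.5).
#' @param trials_per_cell trials per participant x timepoint cell: named
#'   vector with `bimanual_constant` (default 2) and `role_differentiated`
#'   (default 8, per stabilizing hand).
#' @param female_counts number of female participants per group at T1;
#'   default `c(CHI = 42, MCI = 25)`.
#' @param seed integer run seed; all draws flow from it via named
#'   substreams, so the same seed yields a byte-identical dataset.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(counts = default_cohort_counts(),
                          fixed_effects = default_fixed_effects(),
                          outcome = c("cv", "dfa_alpha", "sen"),
                          random_intercept_sd = 3.5, residual_sd = 2.5,
                          trials_per_cell = c(bimanual_constant = 2L,
                                              role_differentiated = 8L),
                          female_counts = NULL, seed = 1L) {
  outcome <- match.arg(outcome)
  if (!is.matrix(counts) || nrow(counts) != 2L || ncol(counts) < 1L ||
      any(counts < 0) || any(counts != round(counts)))
    ff_stop("`counts` must be a 2 x T matrix of non-negative integers",
            "forcefluct_invalid_argument")
  if (is.null(rownames(counts))) rownames(counts) <- c("CHI", "MCI")
  if (ncol(counts) > 1L && any(counts[, -1L, drop = FALSE] >
                               counts[, -ncol(counts), drop = FALSE]))
    ff_stop("`counts` must be non-increasing across timepoints (dropout only)",
            "forcefluct_invalid_argument")
  if (!is.numeric(fixed_effects) || is.null(names(fixed_effects)) ||
      any(!is.finite(fixed_effects)))
    ff_stop("`fixed_effects` must be a named finite numeric vector",
            "forcefluct_invalid_argument")
  assert_scalar_number(random_intercept_sd, "random_intercept_sd")
  assert_scalar_number(residual_sd, "residual_sd")
  if (random_intercept_sd < 0 || residual_sd < 0)
    ff_stop("variance components must be non-negative",
            "forcefluct_invalid_argument")
  if (is.null(female_counts)) {
    frac <- c(CHI = 42 / 77, MCI = 25 / 55)
    female_counts <- round(frac * counts[, 1])
  }
  structure(list(counts = counts, fixed_effects = fixed_effects,
                 outcome = outcome,
                 random_intercept_sd = random_intercept_sd,
                 residual_sd = residual_sd,
                 trials_per_cell = trials_per_cell,
                 female_counts = female_counts, seed = as.integer(seed)),
            class = "cohort_config")
}

# Draw screening scores consistent with a target label by rejection
# sampling, so labels and scores can never contradict each other.
draw_screening <- function(group) {
  repeat {
    if (group == "CHI") {
      moca <- round(stats::rnorm(1, 27.7, 1.2))
      cerad <- stats::rnorm(9, 0, 1)
    } else {
      moca <- round(stats::rnorm(1, 22.6, 1.8))
      cerad <- stats::rnorm(9, -0.5, 1)
    }
    moca <- max(0, min(30, moca))
    if (classify_mci(moca, cerad) == group)
      return(list(moca = as.integer(moca), cerad_z = cerad))
  }
}

#' Generate a synthetic cohort-sequential dataset
#'
#' Builds a full cohort with the configured group-by-timepoint structure:
#' per-subject attributes (sex, age, MVC, MoCA and CERAD-NP scores drawn so
#' the screening rule reproduces the assigned group label, and a Gaussian
#' random intercept), plus a long-format observation table on the measure
#' scale where each participant x timepoint x condition x hand cell receives
#' `outcome = X beta + b_i + e` under treatment coding (references: bimanual
#' constant, CHI, left hand, male; timepoint numeric 1-4).
#'
#' Outcomes are generated directly on the measure scale because the
#' generative betas are defined there; full signal-level trials (through
#' [gen_bimanual_trial()]) are synthesized only on request via
#' `signals = TRUE`, intended for end-to-end smoke tests on reduced cohorts.
#'
#' @param cfg a [cohort_config()].
#' @param signals if `TRUE`, also synthesize per-trial force signals for
#'   every cell (expensive; meant for small cohorts).
#' @return list with `subjects` (data frame), `observations` (long-format
#'   data frame usable by [fit_mixed_model()]), and `trials` (list of
#'   [force_trial()], empty unless `signals = TRUE`).
#' @export
gen_cohort <- function(cfg, signals = FALSE) {
  if (!inherits(cfg, "cohort_config"))
    ff_stop("`cfg` must be a cohort_config", "forcefluct_invalid_argument")
  assert_flag(signals, "signals")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  groups <- rownames(cfg$counts)
  n_tp <- ncol(cfg$counts)
  subjects <- list()
  set.seed(substream_seed(cfg$seed, "cohort-subjects"))
  for (g in groups) {
    n1 <- cfg$counts[g, 1]
    if (n1 == 0) next
    n_f <- min(n1, cfg$female_counts[[g]])
    sexes <- sample(c(rep("female", n_f), rep("male", n1 - n_f)))
    for (i in seq_len(n1)) {
      scr <- draw_screening(g)
      # subjects present at T_k are the first counts[g, k] enrolled (nested
      # dropout, matching a cohort-sequential design)
      t_max <- max(which(cfg$counts[g, ] >= i))
      age_mu <- if (g == "CHI") 82.0 else 82.9
      age_sd <- if (g == "CHI") 2.3 else 2.8
      mvc_mu <- if (g == "CHI") 23.9 else 22.1
      subjects[[length(subjects) + 1L]] <- data.frame(
        id = sprintf("%s%03d", g, i), group = g, sex = sexes[i],
        age_y = max(80, round(stats::rnorm(1, age_mu, age_sd), 1)),
        mvc_n = max(5, round(stats::rnorm(1, mvc_mu, 8), 1)),
        moca = scr$moca,
        t(stats::setNames(scr$cerad_z, paste0("cerad_z", 1:9))),
        t_max = t_max, stringsAsFactors = FALSE
      )
    }
  }
  subjects <- do.call(rbind, subjects)
  set.seed(substream_seed(cfg$seed, "cohort-intercepts"))
  subjects$random_intercept <- stats::rnorm(nrow(subjects),
                                            sd = cfg$random_intercept_sd)

  grid <- expand.grid(
    condition = c("bimanual_constant", "role_differentiated"),
    hand = c("left", "right"), stringsAsFactors = FALSE
  )
  obs <- list()
  for (s in seq_len(nrow(subjects))) {
    sub <- subjects[s, ]
    for (tp in seq_len(sub$t_max)) {
      o <- grid
      o$participant_id <- sub$id
      o$group <- sub$group
      o$sex <- sub$sex
      o$timepoint <- tp
      obs[[length(obs) + 1L]] <- o
    }
  }
  obs <- do.call(rbind, obs)

  # linear predictor under treatment coding
  x_cond <- as.numeric(obs$condition == "role_differentiated")
  x_group <- as.numeric(obs$group == "MCI")
  x_hand <- as.numeric(obs$hand == "right")
  x_sex <- as.numeric(obs$sex == "female")
  cols <- list("(Intercept)" = rep(1, nrow(obs)), condition = x_cond,
               group = x_group, hand = x_hand, sex = x_sex,
               timepoint = obs$timepoint,
               "condition:group" = x_cond * x_group,
               "condition:hand" = x_cond * x_hand,
               "condition:sex" = x_cond * x_sex,
               "condition:timepoint" = x_cond * obs$timepoint,
               "group:hand" = x_group * x_hand,
               "group:sex" = x_group * x_sex,
               "group:timepoint" = x_group * obs$timepoint,
               "hand:sex" = x_hand * x_sex,
               "hand:timepoint" = x_hand * obs$timepoint,
               "sex:timepoint" = x_sex * obs$timepoint,
               "condition:group:timepoint" = x_cond * x_group * obs$timepoint,
               "condition:group:hand" = x_cond * x_group * x_hand,
               "condition:group:sex" = x_cond * x_group * x_sex,
               "condition:hand:sex" = x_cond * x_hand * x_sex,
               "group:hand:sex" = x_group * x_hand * x_sex)
  unknown <- setdiff(names(cfg$fixed_effects), names(cols))
  if (length(unknown))
    ff_stop(paste("unknown fixed-effect term(s):",
                  paste(unknown, collapse = ", ")),
            "forcefluct_invalid_argument")
  eta <- rep(0, nrow(obs))
  for (term in names(cfg$fixed_effects))
    eta <- eta + cfg$fixed_effects[[term]] * cols[[term]]

  set.seed(substream_seed(cfg$seed, "cohort-residuals"))
  b <- subjects$random_intercept[match(obs$participant_id, subjects$id)]
  obs$outcome <- cfg$outcome
  obs$value <- eta + b + stats::rnorm(nrow(obs), sd = cfg$residual_sd)
  obs <- obs[, c("participant_id", "outcome", "value", "condition", "group",
                 "hand", "sex", "timepoint")]

  trials <- list()
  if (signals) {
    idx <- 0L
    for (s in seq_len(nrow(subjects))) {
      sub <- subjects[s, ]
      for (tp in seq_len(sub$t_max)) {
        n_bc <- cfg$trials_per_cell[["bimanual_constant"]]
        n_rd <- cfg$trials_per_cell[["role_differentiated"]]
        for (k in seq_len(n_bc)) {
          idx <- idx + 1L
          tcfg <- trial_config(mvc_n = sub$mvc_n,
                               seed = substream_seed(cfg$seed, "cohort-trial", idx))
          pair <- gen_bimanual_trial(tcfg, condition = "bimanual_constant",
                                     stabilizing_hand = "left",
                                     participant_id = sub$id, timepoint = tp)
          trials <- c(trials, pair)
        }
        for (h in c("left", "right")) {
          for (k in seq_len(n_rd)) {
            idx <- idx + 1L
            tcfg <- trial_config(mvc_n = sub$mvc_n,
                                 seed = substream_seed(cfg$seed, "cohort-trial", idx))
            pair <- gen_bimanual_trial(tcfg, condition = "role_differentiated",
                                       stabilizing_hand = h,
                                       participant_id = sub$id, timepoint = tp)
            trials <- c(trials, pair)
          }
        }
      }
    }
  }

  list(subjects = subjects, observations = obs, trials = trials)
}
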