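#' Coefficient of variation of a series
#'
#' Magnitude of variability: `CV = 100 * SD(x) / mean(x)` with the sample SD
#' (n-1 denominator). Unit-free, so it is identical on the Newton and %MVC
#' scales. Undefined for zero-mean series.
#'
#' @param series an [analysis_series()] or numeric vector.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(1, 3))  # 70.71068
#' @export
coefficient_of_variation <- function(series) {
  x <- as_series_values(series)
  m <- mean(x)
  if (m == 0)
    ff_stop("CV is undefined for a zero-mean series", "forcefluct_undefined_cv")
  if (length(x) == 1L) return(0)
  100 * stats::sd(x) / m
}

#' Default DFA window grid
#'
#' Thirty window sizes spaced evenly on the log scale between 10 and 200
#' samples, rounded to integers, de-duplicated and sorted. The endpoints 10
#' and 200 are always included.
#'
#' @param min_m smallest window (>= 4).
#' @param max_m largest window (> `min_m`).
#' @param count number of grid points before rounding.
#' @return strictly increasing integer vector.
#' @export
default_window_grid <- function(min_m = 10L, max_m = 200L, count = 30L) {
  assert_scalar_number(min_m, "min_m")
  assert_scalar_number(max_m, "max_m")
  assert_scalar_number(count, "count")
  if (min_m < 4)
    ff_stop("`min_m` must be at least 4", "forcefluct_invalid_argument")
  if (max_m <= min_m)
    ff_stop("`max_m` must exceed `min_m`", "forcefluct_invalid_argument")
  if (count < 2)
    ff_stop("`count` must be at least 2", "forcefluct_invalid_argument")
  g <- round(exp(seq(log(min_m), log(max_m), length.out = count)))
  sort(unique(as.integer(g)))
}

#' Detrended fluctuation analysis scaling exponent
#'
#' The series is integrated (cumulative sum of the mean-centered values) and
#' partitioned, for each window size `m`, into `floor(N/m)` non-overlapping
#' segments taken forward from the start; the trailing remainder is
#' discarded. A least-squares line is fitted to each segment and the
#' root-mean-square deviation from it computed. The fluctuation `F(m)` is
#' the mean of the per-segment RMS values (`aggregate = "mean_rms"`; the
#' canonical pooled-RMS variant is available and yields an asymptotically
#' identical slope). `alpha` is the OLS slope of `log F(m)` on `log m`.
#' White noise gives `alpha ~ 0.5`; Brownian noise `alpha ~ 1.5`.
#'
#' @param series an [analysis_series()] or numeric vector; length must be at
#'   least `2 * max(window_sizes)`.
#' @param window_sizes integer window sizes, at least 4 distinct values,
#'   all >= 4.
#' @param aggregate `"mean_rms"` (mean over per-segment RMS, default) or
#'   `"pooled_rms"` (RMS over all pooled residuals).
#' @return object of class `dfa_result`: `window_sizes`, `fluctuation`,
#'   `alpha`, `fit_r2`, `n_windows_used`.
#' @export
dfa_alpha <- function(series, window_sizes = default_window_grid(),
                      aggregate = c("mean_rms", "pooled_rms")) {
  aggregate <- match.arg(aggregate)
  x <- as_series_values(series)
  ms <- sort(unique(as.integer(window_sizes)))
  if (length(ms) < 4L)
    ff_stop("at least 4 distinct window sizes are required",
            "forcefluct_invalid_argument")
  if (any(ms < 4L))
    ff_stop("window sizes must all be at least 4", "forcefluct_invalid_argument")
  N <- length(x)
  if (N < 2L * max(ms))
    ff_stop("series too short: length must be at least twice the largest window",
            "forcefluct_invalid_argument")
  profile <- cumsum(x - mean(x))
  Fm <- vapply(ms, function(m) {
    k <- N %/% m
    seg <- matrix(profile[seq_len(k * m)], nrow = m)
    tc <- seq_len(m) - (m + 1) / 2         # centered time within segment
    stt <- sum(tc^2)
    slope <- colSums(seg * tc) / stt
    resid <- seg - outer(tc, slope) - rep(colMeans(seg), each = m)
    if (aggregate == "mean_rms") mean(sqrt(colMeans(resid^2)))
    else sqrt(mean(resid^2))
  }, numeric(1))
  if (any(Fm == 0))
    ff_stop("fluctuation is zero at some window size (series is deterministic after detrending)",
            "forcefluct_degenerate_fluctuation")
  lx <- log(ms)
  ly <- log(Fm)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  alpha <- unname(fit$coefficients[2])
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  structure(list(window_sizes = ms, fluctuation = Fm, alpha = alpha,
                 fit_r2 = r2, n_windows_used = length(ms)),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("DFA: alpha = %.4f (R^2 = %.4f, %d windows %d..%d)\n",
              x$alpha, x$fit_r2, x$n_windows_used,
              min(x$window_sizes), max(x$window_sizes)))
  invisible(x)
}

#' Sample entropy configuration
#'
#' @param m template length (default 2).
#' @param r similarity radius, in units of the z-scaled series' SD
#'   (default 0.25; z-scaling makes the absolute and SD-relative readings
#'   coincide).
#' @param norm segment distance: `"euclidean"` (default, matching the
#'   measure's definition here) or `"chebyshev"` (the Richman-Moorman
#'   maximum-norm convention used by most reference implementations).
#' @return object of class `sen_config`.
#' @export
sen_config <- function(m = 2L, r = 0.25, norm = c("euclidean", "chebyshev")) {
  norm <- match.arg(norm)
  assert_scalar_number(m, "m")
  assert_scalar_number(r, "r")
  if (m < 1) ff_stop("`m` must be at least 1", "forcefluct_invalid_argument")
  if (r <= 0) ff_stop("`r` must be positive", "forcefluct_invalid_argument")
  structure(list(m = as.integer(m), r = r, norm = norm), class = "sen_config")
}

#' Sample entropy of a z-scaled series
#'
#' `SEn = ln(Cm / Cm+1)` where `Cm` counts ordered pairs of distinct
#' templates of length `m` whose distance is below the radius `r`, and
#' `Cm+1` likewise for length `m + 1`. Both template sets are taken at the
#' same `N - m` starting positions, so the ratio is a conditional
#' probability: the chance that segments similar for `m` points remain
#' similar for one more. Self-matches are excluded. Predictable signals give
#' low values; white noise exceeds 2, Brownian noise stays below 0.5 (at
#' `m = 2`, `r = 0.25`, n = 1680).
#'
#' The input must already be z-scaled (mean 0, SD 1; see [zscale()]) because
#' `r` is an absolute radius on that scale.
#'
#' @param series a z-scaled [analysis_series()] or numeric vector.
#' @param cfg a [sen_config()].
#' @return object of class `sen_result`: `sen` (nats), match counts `cm` and
#'   `cm1`, and the config used.
#' @export
sample_entropy <- function(series, cfg = sen_config()) {
  if (!inherits(cfg, "sen_config"))
    ff_stop("`cfg` must be a sen_config", "forcefluct_invalid_argument")
  x <- as_series_values(series)
  scaled_flag <- inherits(series, "analysis_series") && isTRUE(series$scaled)
  if (!scaled_flag && (abs(mean(x)) > 1e-6 || abs(stats::sd(x) - 1) > 1e-6))
    ff_stop("`series` must be z-scaled (mean 0, SD 1) before sample entropy; see zscale()",
            "forcefluct_invalid_argument")
  m <- cfg$m
  N <- length(x)
  if (N <= m + 1L)
    ff_stop("series too short for the requested template length",
            "forcefluct_invalid_argument")
  nt <- N - m                              # template count for both lengths
  counts <- vapply(c(m, m + 1L), function(len) {
    emb <- vapply(0:(len - 1L), function(k) x[seq_len(nt) + k], numeric(nt))
    method <- if (cfg$norm == "euclidean") "euclidean" else "maximum"
    d <- stats::dist(emb, method = method)
    2 * sum(d < cfg$r)                     # ordered pairs, self-matches excluded
  }, numeric(1))
  cm <- counts[1]
  cm1 <- counts[2]
  if (cm1 == 0)
    ff_stop("sample entropy undefined: no template matches at length m + 1",
            "forcefluct_undefined_entropy")
  structure(list(sen = log(cm / cm1), cm = cm, cm1 = cm1, config = cfg),
            class = "sen_result")
}

#' @export
print.sen_result <- function(x, ...) {
  cat(sprintf("SEn = %.4f nats (m = %d, r = %g, %s; Cm = %.0f, Cm+1 = %.0f)\n",
              x$sen, x$config$m, x$config$r, x$config$norm, x$cm, x$cm1))
  invisible(x)
}

#' Sample entropy robustness grid
#'
#' Recomputes sample entropy over the neighborhood of the default
#' parameters, `m` in {2, 3, 4} crossed with `r` in {0.2, 0.25, 0.3},
#' to verify that conclusions are not an artifact of one parameter choice.
#' Cells where the entropy is undefined (no length-`m+1` matches) are
#' reported as `NA`, never imputed, and never abort the remaining cells.
#'
#' @param series a z-scaled [analysis_series()] or numeric vector.
#' @param m_values template lengths (rows).
#' @param r_values radii (columns).
#' @param norm distance norm passed to [sen_config()].
#' @return numeric matrix `length(m_values)` x `length(r_values)` with
#'   dimnames giving the parameters.
#' @export
sen_robustness_grid <- function(series, m_values = 2:4,
                                r_values = c(0.2, 0.25, 0.3),
                                norm = "euclidean") {
  out <- matrix(NA_real_, nrow = length(m_values), ncol = length(r_values),
                dimnames = list(paste0("m=", m_values), paste0("r=", r_values)))
  for (i in seq_along(m_values)) {
    for (j in seq_along(r_values)) {
      out[i, j] <- tryCatch(
        sample_entropy(series, sen_config(m_values[i], r_values[j], norm))$sen,
        forcefluct_undefined_entropy = function(e) NA_real_
      )
    }
  }
  out
}

#' Bundle the three complexity measures for one analysis cell
#'
#' @param cv coefficient of variation in percent.
#' @param dfa_alpha DFA scaling exponent.
#' @param sen sample entropy in nats (`NA` when undefined).
#' @param participant_id,condition,hand,timepoint,group,sex cell keys.
#' @param diagnostics optional list (e.g. the `dfa_result`, match counts).
#' @param n_trials number of trials this value summarizes.
#' @return object of class `complexity_result`.
#' @export
complexity_result <- function(cv, dfa_alpha, sen, participant_id = NA_character_,
                              condition = NA_character_, hand = NA_character_,
                              timepoint = NA_integer_, group = NA_character_,
                              sex = NA_character_, diagnostics = NULL,
                              n_trials = 1L) {
  structure(list(cv = cv, dfa_alpha = dfa_alpha, sen = sen,
                 participant_id = participant_id, condition = condition,
                 hand = hand, timepoint = timepoint, group = group, sex = sex,
                 diagnostics = diagnostics, n_trials = as.integer(n_trials)),
            class = "complexity_result")
}

#' Compute all three measures for one trial
#'
#' Convenience wrapper running the standard per-trial pipeline: normalize to
#' %MVC, drop the ramp, then CV and DFA on the %MVC series and sample
#' entropy on its z-scaled version. An undefined entropy becomes `NA` with
#' a warning rather than an error so that batch runs continue.
#'
#' @param trial a [force_trial()].
#' @param ramp_s ramp duration to exclude (seconds).
#' @param window_sizes DFA window grid.
#' @param sen_cfg a [sen_config()].
#' @param group,sex optional cell keys carried into the result.
#' @return a [complexity_result()].
#' @export
analyze_trial <- function(trial, ramp_s = 6,
                          window_sizes = default_window_grid(),
                          sen_cfg = sen_config(), group = NA_character_,
                          sex = NA_character_) {
  series <- exclude_ramp(normalize_to_mvc(trial), ramp_s)
  cv <- coefficient_of_variation(series)
  dfa <- dfa_alpha(series, window_sizes)
  sen_res <- tryCatch(sample_entropy(zscale(series), sen_cfg),
                      forcefluct_undefined_entropy = function(e) {
                        warning(conditionMessage(e), call. = FALSE)
                        NULL
                      })
  complexity_result(
    cv = cv, dfa_alpha = dfa$alpha,
    sen = if (is.null(sen_res)) NA_real_ else sen_res$sen,
    participant_id = trial$participant_id, condition = trial$condition,
    hand = trial$hand, timepoint = trial$timepoint, group = group, sex = sex,
    diagnostics = list(dfa = dfa,
                       cm = if (is.null(sen_res)) NA_real_ else sen_res$cm,
                       cm1 = if (is.null(sen_res)) NA_real_ else sen_res$cm1)
  )
}
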