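#' Construct a force trial record
#'
#' One hand's sampled force for one trial, in Newtons, together with the
#' metadata the downstream analysis keys on. Force plates in the task sample
#' at 120 Hz; any positive rate is accepted.
#'
#' @param samples numeric vector of forces in Newtons; finite, non-empty.
#' @param rate_hz sampling rate in samples/second.
#' @param hand `"left"` or `"right"`.
#' @param role `"stabilizing"` or `"manipulating"`.
#' @param condition `"bimanual_constant"` or `"role_differentiated"`.
#' @param participant_id opaque identifier.
#' @param timepoint measurement point, 1-4.
#' @param mvc_n maximum voluntary contraction in Newtons (> 0).
#' @return object of class `force_trial`.
#' @export
force_trial <- function(samples, rate_hz, hand = c("left", "right"),
                        role = c("stabilizing", "manipulating"),
                        condition = c("bimanual_constant", "role_differentiated"),
                        participant_id = "P01", timepoint = 1L, mvc_n = 24) {
  hand <- match.arg(hand)
  role <- match.arg(role)
  condition <- match.arg(condition)
  if (!is.numeric(samples) || length(samples) == 0L || !all(is.finite(samples)))
    ff_stop("`samples` must be a non-empty finite numeric vector",
            "forcefluct_invalid_argument")
  assert_scalar_number(rate_hz, "rate_hz")
  if (rate_hz <= 0)
    ff_stop("`rate_hz` must be positive", "forcefluct_invalid_argument")
  assert_scalar_number(mvc_n, "mvc_n", finite = TRUE)
  assert_scalar_number(timepoint, "timepoint")
  if (!timepoint %in% 1:4)
    ff_stop("`timepoint` must be 1, 2, 3 or 4", "forcefluct_invalid_argument")
  structure(list(samples = as.numeric(samples), rate_hz = rate_hz, hand = hand,
                 role = role, condition = condition,
                 participant_id = as.character(participant_id),
                 timepoint = as.integer(timepoint), mvc_n = mvc_n),
            class = "force_trial")
}

#' Construct an analysis series
#'
#' The dimensionless (or %MVC) series the complexity measures operate on,
#' carrying its sampling rate, originating-trial metadata, and a flag
#' recording whether it has been z-scaled.
#'
#' @param values numeric samples.
#' @param rate_hz sampling rate.
#' @param source list of metadata from the originating [force_trial()] (may
#'   be empty).
#' @param scaled logical; `TRUE` once [zscale()] has been applied.
#' @return object of class `analysis_series`.
#' @export
analysis_series <- function(values, rate_hz = 120, source = list(),
                            scaled = FALSE) {
  if (!is.numeric(values) || length(values) == 0L || !all(is.finite(values)))
    ff_stop("`values` must be a non-empty finite numeric vector",
            "forcefluct_invalid_argument")
  assert_flag(scaled, "scaled")
  structure(list(values = as.numeric(values), rate_hz = rate_hz,
                 source = source, scaled = scaled),
            class = "analysis_series")
}

# Accept either a numeric vector or an analysis_series.
as_series_values <- function(x) {
  if (inherits(x, "analysis_series")) x$values
  else if (is.numeric(x)) as.numeric(x)
  else ff_stop("expected a numeric vector or analysis_series",
               "forcefluct_invalid_argument")
}

trial_source <- function(trial) {
  trial[c("hand", "role", "condition", "participant_id", "timepoint",
          "mvc_n", "rate_hz")]
}

#' Drop the initial ramp phase of a trial
#'
#' Each 20-s trial opens with a 6-s ramp during which force rises to the
#' target; the ramp is excluded from all analyses. The first retained sample
#' is the one at `t = ramp_s` exactly (0-based start index
#' `floor(ramp_s * rate_hz)`), so a 2400-sample trial at 120 Hz keeps 1680
#' samples for a 6-s ramp.
#'
#' @param trial a [force_trial()] or an [analysis_series()].
#' @param ramp_s ramp duration in seconds (>= 0).
#' @return an [analysis_series()] with the ramp removed.
#' @export
exclude_ramp <- function(trial, ramp_s = 6) {
  assert_scalar_number(ramp_s, "ramp_s")
  if (ramp_s < 0)
    ff_stop("`ramp_s` must be non-negative", "forcefluct_invalid_argument")
  if (inherits(trial, "force_trial")) {
    values <- trial$samples
    rate <- trial$rate_hz
    src <- trial_source(trial)
    scaled <- FALSE
  } else if (inherits(trial, "analysis_series")) {
    values <- trial$values
    rate <- trial$rate_hz
    src <- trial$source
    scaled <- trial$scaled
  } else {
    ff_stop("`trial` must be a force_trial or analysis_series",
            "forcefluct_invalid_argument")
  }
  start <- floor(ramp_s * rate)           # 0-based index of first kept sample
  if (start >= length(values))
    ff_stop("nothing remains after ramp exclusion", "forcefluct_empty_series")
  analysis_series(values[(start + 1L):length(values)], rate_hz = rate,
                  source = src, scaled = scaled)
}

#' Express a trial in percent of maximum voluntary contraction
#'
#' Targets in the task are defined relative to each participant's MVC, so
#' all magnitude comparisons are made on the %MVC scale:
#' `100 * force / mvc_n`. Order-preserving, and commutes with
#' [exclude_ramp()] (an [analysis_series()] input takes its MVC from the
#' originating trial's metadata).
#'
#' @param trial a [force_trial()], or an [analysis_series()] whose `source`
#'   carries `mvc_n`.
#' @return an [analysis_series()] in %MVC.
#' @export
normalize_to_mvc <- function(trial) {
  if (inherits(trial, "force_trial")) {
    values <- trial$samples
    mvc <- trial$mvc_n
    rate <- trial$rate_hz
    src <- trial_source(trial)
  } else if (inherits(trial, "analysis_series")) {
    values <- trial$values
    mvc <- trial$source$mvc_n
    rate <- trial$rate_hz
    src <- trial$source
    if (is.null(mvc))
      ff_stop("analysis_series carries no `mvc_n` in its source metadata",
              "forcefluct_invalid_argument")
  } else {
    ff_stop("`trial` must be a force_trial or analysis_series",
            "forcefluct_invalid_argument")
  }
  if (mvc <= 0)
    ff_stop("`mvc_n` must be positive", "forcefluct_invalid_argument")
  analysis_series(100 * values / mvc, rate_hz = rate, source = src,
                  scaled = FALSE)
}

#' Z-scale a series to mean 0 and unit SD
#'
#' Sample entropy compares segments against an absolute radius, so series
#' are first scaled to share mean 0 and SD 1 (sample SD, n-1 denominator).
#' Idempotent; errors on constant input.
#'
#' @param series an [analysis_series()] or numeric vector.
#' @return an [analysis_series()] with `scaled = TRUE`.
#' @export
zscale <- function(series) {
  s <- if (inherits(series, "analysis_series")) series else analysis_series(series)
  sdv <- stats::sd(s$values)
  if (!is.finite(sdv) || sdv == 0)
    ff_stop("cannot z-scale a constant series", "forcefluct_zero_variance")
  analysis_series((s$values - mean(s$values)) / sdv, rate_hz = s$rate_hz,
                  source = s$source, scaled = TRUE)
}

#' Average complexity results within one analysis cell
#'
#' The mixed model takes one observation per participant x condition x hand
#' x timepoint cell; when several trials fall in one cell their measures are
#' combined as the unweighted arithmetic mean. Undefined values (`NA`, e.g.
#' sample entropy with no `m+1` matches) are dropped from the mean of that
#' measure only; a cell where every trial is undefined stays `NA`.
#'
#' @param results list of [complexity_result()] objects sharing identical
#'   cell keys.
#' @return a single [complexity_result()] with `n_trials` recording how many
#'   trials were combined.
#' @export
aggregate_cell <- function(results) {
  if (!is.list(results) || length(results) == 0L ||
      inherits(results, "complexity_result"))
    ff_stop("`results` must be a non-empty list of complexity_result objects",
            "forcefluct_invalid_argument")
  if (!all(vapply(results, inherits, logical(1), "complexity_result")))
    ff_stop("`results` must contain complexity_result objects",
            "forcefluct_invalid_argument")
  keys <- c("participant_id", "condition", "hand", "timepoint", "group", "sex")
  ref <- results[[1]][keys]
  for (r in results[-1]) {
    if (!identical(r[keys], ref))
      ff_stop("cannot aggregate results from different cells",
              "forcefluct_invalid_argument")
  }
  mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  out <- results[[1]]
  for (field in c("cv", "dfa_alpha", "sen")) {
    out[[field]] <- mean_or_na(vapply(results, function(r) r[[field]] %||% NA_real_,
                                      numeric(1)))
  }
  out$n_trials <- sum(vapply(results, function(r) r$n_trials %||% 1L, numeric(1)))
  out$diagnostics <- NULL  # per-trial diagnostics do not average meaningfully
  out
}
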