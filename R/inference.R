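#' Build the stepwise model sequence
#'
#' Produces the ordered list of nested fixed-effect specifications used for
#' stepwise model building: intercept-only, then the main effects added one
#' at a time in the fixed order condition, group, hand, sex, timepoint, then
#' the ten 2-way interactions one at a time, then the condition x group x
#' timepoint 3-way term, then the set of 3-way interactions among condition,
#' group, hand and sex (their 4-way product optionally on top). Every
#' specification's term set is a superset of its predecessor's and respects
#' marginality (interactions only appear once all parents are present).
#'
#' @param factors the five design factors; only the default set is
#'   supported.
#' @param include_four_way also append the condition x group x hand x sex
#'   4-way product as a final step.
#' @param reml logical; stamped on each spec (model comparison should use
#'   `FALSE`).
#' @return list of `model_spec` objects (fields `terms`, `reml`).
#' @export
build_model_sequence <- function(factors = c("condition", "group", "hand",
                                             "sex", "timepoint"),
                                 include_four_way = FALSE, reml = FALSE) {
  canonical <- c("condition", "group", "hand", "sex", "timepoint")
  if (!identical(sort(factors), sort(canonical)))
    ff_stop("`factors` must be the design factors condition, group, hand, sex, timepoint",
            "forcefluct_invalid_argument")
  assert_flag(include_four_way, "include_four_way")
  spec <- function(terms) model_spec(terms, reml = reml)
  seq_specs <- list(spec(character(0)))
  terms <- character(0)
  for (f in canonical) {
    terms <- c(terms, f)
    seq_specs[[length(seq_specs) + 1L]] <- spec(terms)
  }
  pairs <- utils::combn(canonical, 2, paste, collapse = ":")
  for (p in pairs) {
    terms <- c(terms, p)
    seq_specs[[length(seq_specs) + 1L]] <- spec(terms)
  }
  terms <- c(terms, "condition:group:timepoint")
  seq_specs[[length(seq_specs) + 1L]] <- spec(terms)
  three_way <- utils::combn(c("condition", "group", "hand", "sex"), 3,
                            paste, collapse = ":")
  terms <- c(terms, three_way)
  seq_specs[[length(seq_specs) + 1L]] <- spec(terms)
  if (include_four_way) {
    terms <- c(terms, "condition:group:hand:sex")
    seq_specs[[length(seq_specs) + 1L]] <- spec(terms)
  }
  seq_specs
}

#' Construct a fixed-effect model specification
#'
#' @param terms character vector of fixed-effect terms (main effects and
#'   `:`-separated interactions); `character(0)` gives the intercept-only
#'   model. Interaction terms require all their parent main effects
#'   (marginality).
#' @param reml fit by REML (`TRUE`) or maximum likelihood (`FALSE`).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(terms = character(0), reml = FALSE) {
  assert_flag(reml, "reml")
  terms <- as.character(terms)
  for (tm in terms[grepl(":", terms)]) {
    parents <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (!all(parents %in% terms))
      ff_stop(sprintf("interaction `%s` requires all parent main effects", tm),
              "forcefluct_invalid_argument")
  }
  structure(list(terms = terms, reml = reml), class = "model_spec")
}

# Prepare an observation table for fitting: validate, set treatment-coding
# reference levels (bimanual constant, CHI, left, male), timepoint numeric.
prepare_observations <- function(data) {
  needed <- c("participant_id", "value", "condition", "group", "hand", "sex",
              "timepoint")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    ff_stop(paste("observation table lacks column(s):",
                  paste(missing_cols, collapse = ", ")),
            "forcefluct_invalid_argument")
  if (nrow(data) == 0L)
    ff_stop("observation table is empty", "forcefluct_empty_input")
  if ("outcome" %in% names(data) && length(unique(data$outcome)) > 1L)
    ff_stop("observation table mixes outcomes; fit one outcome at a time",
            "forcefluct_invalid_argument")
  if (anyNA(data$value)) data <- data[!is.na(data$value), , drop = FALSE]
  if (!all(data$timepoint %in% 1:4))
    ff_stop("`timepoint` must lie in 1..4", "forcefluct_invalid_argument")
  data$participant_id <- factor(data$participant_id)
  data$condition <- factor(data$condition,
                           levels = c("bimanual_constant", "role_differentiated"))
  data$group <- factor(data$group, levels = c("CHI", "MCI"))
  data$hand <- factor(data$hand, levels = c("left", "right"))
  data$sex <- factor(data$sex, levels = c("male", "female"))
  data$timepoint <- as.numeric(data$timepoint)
  if (anyNA(data$condition) || anyNA(data$group) || anyNA(data$hand) ||
      anyNA(data$sex))
    ff_stop("unknown factor level in observation table",
            "forcefluct_invalid_argument")
  data
}

spec_formula <- function(spec, response = "value") {
  rhs <- if (length(spec$terms) == 0L) "1" else paste(spec$terms, collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

# Containment-style denominator df, stratified by whether a fixed-effect
# column varies within participants. Between-participant columns (constant
# within every participant) are tested against the participant stratum:
#   df_between = n_participants - n_between_columns - 1.
# Columns that vary within participants -- and the intercept, which is
# estimated at the innermost level -- use the observation stratum:
#   df_within = n_obs - n_participants - n_within_columns.
containment_df <- function(X, participant) {
  n_obs <- nrow(X)
  n_sub <- length(unique(participant))
  is_between <- apply(X, 2, function(col) {
    all(tapply(col, participant, function(v) max(v) - min(v)) == 0)
  })
  has_int <- "(Intercept)" %in% colnames(X)
  p_b <- sum(is_between) - as.integer(has_int)   # intercept not counted here
  p_w <- sum(!is_between)
  df_b <- max(1L, n_sub - p_b - 1L)
  df_w <- max(1L, n_obs - n_sub - p_w)
  df <- ifelse(is_between, df_b, df_w)
  if (has_int) df[["(Intercept)"]] <- df_w
  df
}

#' Fit the linear mixed model for one outcome
#'
#' Gaussian linear mixed model with the requested fixed effects and one
#' random intercept per participant (accounting for the repeated-measures,
#' cohort-sequential design), fitted with `lme4::lmer`. Treatment coding
#' with reference levels bimanual constant, CHI, left hand, male; timepoint
#' enters as a numeric covariate 1-4. Denominator degrees of freedom use a
#' containment-style rule with two strata (between- vs within-participant
#' terms); `t = beta / SE` and two-sided p-values come from the t
#' distribution on those df.
#'
#' @param data long-format observation table: columns `participant_id`,
#'   `value`, `condition`, `group`, `hand`, `sex`, `timepoint` (and
#'   optionally `outcome`, which must be constant). Rows with missing
#'   `value` are dropped listwise.
#' @param spec a [model_spec()].
#' @return object of class `fit_result`: `coefficients` (data frame with
#'   `term`, `beta`, `se`, `df`, `t`, `p`), `log_likelihood`, `aic`,
#'   `n_parameters`, `varcomp` (intercept and residual SD), `n_obs`,
#'   `n_participants`, `converged`, `reml`, `spec`, and the underlying
#'   `lmerMod` in `$model`.
#' @export
fit_mixed_model <- function(data, spec) {
  if (!inherits(spec, "model_spec"))
    ff_stop("`spec` must be a model_spec", "forcefluct_invalid_argument")
  data <- prepare_observations(data)
  n_sub <- length(unique(data$participant_id))
  if (n_sub < 2L || min(table(data$participant_id)) < 2L)
    ff_stop("need at least 2 participants with at least 2 observations each",
            "forcefluct_invalid_argument")

  fixed <- spec_formula(spec)
  X <- stats::model.matrix(fixed, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    ff_stop(paste("rank-deficient fixed-effect design; aliased term(s):",
                  paste(aliased, collapse = ", ")),
            "forcefluct_rank_deficient")
  }

  full_formula <- stats::update.formula(fixed, . ~ . + (1 | participant_id))
  warnings_seen <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(full_formula, data = data, REML = spec$reml,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  converged <- !any(grepl("failed to converge", warnings_seen, fixed = TRUE))

  beta <- lme4::fixef(fit)
  # vcov can fail on boundary fits with (numerically) zero residual
  # variance; the fixed-effect covariance is then the zero matrix
  V <- tryCatch(
    suppressWarnings(as.matrix(stats::vcov(fit))),
    error = function(e) NULL
  )
  se <- if (is.null(V) || anyNA(V)) rep(0, length(beta)) else sqrt(diag(V))
  df <- containment_df(X, data$participant_id)[names(beta)]
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  coefs <- data.frame(term = names(beta), beta = unname(beta),
                      se = unname(se), df = as.integer(unname(df)),
                      t = unname(tval), p = unname(pval),
                      stringsAsFactors = FALSE, row.names = NULL)

  vc <- as.data.frame(lme4::VarCorr(fit))
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  structure(list(coefficients = coefs, log_likelihood = ll,
                 aic = 2 * k - 2 * ll, n_parameters = k,
                 varcomp = c(intercept_sd = vc$sdcor[vc$grp == "participant_id"],
                             residual_sd = vc$sdcor[vc$grp == "Residual"]),
                 n_obs = nrow(data), n_participants = n_sub,
                 converged = converged, reml = spec$reml, spec = spec,
                 warnings = warnings_seen, model = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s): %d obs, %d participants\n",
              if (x$reml) "REML" else "ML", x$n_obs, x$n_participants))
  cat(sprintf("logLik = %.2f, AIC = %.2f, k = %d%s\n", x$log_likelihood,
              x$aic, x$n_parameters,
              if (x$converged) "" else "  [did not converge]"))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Select the best-fitting model by AIC
#'
#' Returns the index of the fit with the lowest AIC; exact ties are broken
#' toward the model with fewer estimated parameters (and then toward the
#' earlier fit in the list).
#'
#' @param fits non-empty list of [fit_mixed_model()] results on the same
#'   data and likelihood scale.
#' @return integer index into `fits`.
#' @export
select_best_model <- function(fits) {
  if (!is.list(fits) || length(fits) == 0L)
    ff_stop("`fits` must be a non-empty list of fit_result objects",
            "forcefluct_invalid_argument")
  if (!all(vapply(fits, inherits, logical(1), "fit_result")))
    ff_stop("`fits` must contain fit_result objects",
            "forcefluct_invalid_argument")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  k <- vapply(fits, function(f) f$n_parameters, numeric(1))
  best <- which(aic == min(aic))
  if (length(best) > 1L) best <- best[which.min(k[best])]
  best[1L]
}

#' Likelihood-ratio test between nested fits
#'
#' `LR = 2 * (logLik_full - logLik_reduced)`, referred to a chi-square
#' distribution with `df_diff` degrees of freedom. Both fits must come from
#' maximum likelihood (not REML) on the same data; a full-model
#' log-likelihood below the reduced one (beyond numerical tolerance)
#' signals a nesting violation.
#'
#' @param reduced,full [fit_mixed_model()] results, reduced nested in full.
#' @param df_diff positive integer difference in parameter count.
#' @param tol numerical tolerance for the nesting check.
#' @return list with `lr` and `p`.
#' @export
likelihood_ratio_test <- function(reduced, full, df_diff, tol = 1e-6) {
  if (!inherits(reduced, "fit_result") || !inherits(full, "fit_result"))
    ff_stop("`reduced` and `full` must be fit_result objects",
            "forcefluct_invalid_argument")
  assert_scalar_number(df_diff, "df_diff")
  if (df_diff < 1 || df_diff != round(df_diff))
    ff_stop("`df_diff` must be a positive integer",
            "forcefluct_invalid_argument")
  if (reduced$reml || full$reml)
    ff_stop("likelihood-ratio tests require maximum-likelihood fits (reml = FALSE)",
            "forcefluct_invalid_argument")
  lr <- 2 * (full$log_likelihood - reduced$log_likelihood)
  if (lr < -tol)
    ff_stop("full model has lower log-likelihood than reduced model: fits are not nested",
            "forcefluct_nesting_violation")
  lr <- max(lr, 0)
  list(lr = lr, p = stats::pchisq(lr, df = df_diff, lower.tail = FALSE))
}

#' Effect size r from a t statistic
#'
#' `r = sqrt(t^2 / (t^2 + df))`, the t-to-r conversion used alongside mixed
#' model contrasts; the sign of `t` is discarded, so `0 <= r < 1`.
#' Vectorized over `t` and `df`.
#'
#' @param t t statistic(s).
#' @param df denominator degrees of freedom (> 0).
#' @return effect size(s) r.
#' @examples
#' effect_size_r(5.13, 129)   # 0.41 at 2 dp
#' effect_size_r(-7.50, 129)  # 0.55
#' @export
effect_size_r <- function(t, df) {
  if (!is.numeric(t) || !is.numeric(df) || anyNA(t) || anyNA(df))
    ff_stop("`t` and `df` must be numeric", "forcefluct_invalid_argument")
  if (any(df <= 0))
    ff_stop("`df` must be positive", "forcefluct_invalid_argument")
  sqrt(t^2 / (t^2 + df))
}

# Pretty term labels mirroring the conventional contrast table layout.
# Accepts raw model.matrix column names such as
# "conditionrole_differentiated:groupMCI".
pretty_term <- function(term) {
  lab <- c(condition = "Condition (RD-BC)",
           group = "Group (MCI-CHI)",
           hand = "Hand (right-left)",
           sex = "Sex (female-male)",
           timepoint = "Timepoint",
           "(Intercept)" = "Intercept")
  one <- function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    parts <- vapply(parts, function(p) {
      p0 <- sub("(role_differentiated|MCI|right|female)$", "", p)
      if (p0 %in% names(lab)) lab[[p0]] else p
    }, character(1))
    paste(parts, collapse = " x ")
  }
  vapply(unname(term), one, character(1))
}

#' Contrast table with effect sizes
#'
#' One row per fixed-effect term of a converged fit: beta, standard error,
#' containment df, t, two-sided p, and the effect size
#' `r = sqrt(t^2/(t^2+df))`. The contrast coding (treatment coding;
#' reference levels bimanual constant, CHI, left hand, male; timepoint
#' numeric) is recorded in the `coding` attribute.
#'
#' @param fit a [fit_mixed_model()] result.
#' @return data frame with columns `term`, `label`, `beta`, `se`, `df`,
#'   `t`, `p`, `r`.
#' @export
summarize_contrasts <- function(fit) {
  if (!inherits(fit, "fit_result"))
    ff_stop("`fit` must be a fit_result", "forcefluct_invalid_argument")
  if (!isTRUE(fit$converged))
    ff_stop("cannot summarize a non-converged fit", "forcefluct_not_converged")
  out <- fit$coefficients
  out$label <- pretty_term(out$term)
  out$r <- effect_size_r(out$t, out$df)
  out <- out[, c("term", "label", "beta", "se", "df", "t", "p", "r")]
  attr(out, "coding") <-
    paste("treatment coding; reference levels: condition = bimanual_constant,",
          "group = CHI, hand = left, sex = male; timepoint numeric 1-4")
  out
}

#' Run the full stepwise inference for one outcome
#'
#' Fits the whole [build_model_sequence()] by maximum likelihood, records
#' the selection trace (terms, log-likelihood, AIC, likelihood-ratio test
#' against the previous step), selects the lowest-AIC model, refits it by
#' REML and returns its contrast table. This mirrors standard practice:
#' ML for model comparison, REML for the reported coefficient table.
#'
#' @param data observation table for a single outcome (see
#'   [fit_mixed_model()]).
#' @param include_four_way passed to [build_model_sequence()].
#' @return list with `trace` (data frame: step, terms, n_parameters,
#'   log_likelihood, aic, lr, lr_df, lr_p), `best_index`, `best_fit`
#'   (REML refit), and `contrasts` ([summarize_contrasts()] of the best
#'   fit).
#' @export
stepwise_inference <- function(data, include_four_way = FALSE) {
  specs <- build_model_sequence(include_four_way = include_four_way,
                                reml = FALSE)
  # On small designs the later interaction-heavy specs can be aliased;
  # those steps are skipped (NA in the trace), not fatal.
  fits <- lapply(specs, function(sp) {
    tryCatch(fit_mixed_model(data, sp),
             forcefluct_rank_deficient = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    ff_stop("no model in the sequence could be fitted", "forcefluct_error")
  num_or_na <- function(f, field) if (is.null(f)) NA_real_ else f[[field]]
  trace <- data.frame(
    step = seq_along(fits),
    terms = vapply(specs, function(sp)
      if (length(sp$terms)) paste(sp$terms, collapse = " + ") else "1",
      character(1)),
    n_parameters = vapply(fits, num_or_na, numeric(1), "n_parameters"),
    log_likelihood = vapply(fits, num_or_na, numeric(1), "log_likelihood"),
    aic = vapply(fits, num_or_na, numeric(1), "aic"),
    lr = NA_real_, lr_df = NA_real_, lr_p = NA_real_,
    stringsAsFactors = FALSE
  )
  prev <- NULL
  for (i in seq_along(fits)) {
    if (is.null(fits[[i]])) next
    if (!is.null(prev)) {
      dk <- fits[[i]]$n_parameters - prev$n_parameters
      if (dk >= 1) {
        lrt <- likelihood_ratio_test(prev, fits[[i]], dk)
        trace$lr[i] <- lrt$lr
        trace$lr_df[i] <- dk
        trace$lr_p[i] <- lrt$p
      }
    }
    prev <- fits[[i]]
  }
  best <- which(ok)[select_best_model(fits[ok])]
  best_spec <- specs[[best]]
  best_spec$reml <- TRUE
  best_fit <- fit_mixed_model(data, best_spec)
  list(trace = trace, best_index = best, best_fit = best_fit,
       contrasts = summarize_contrasts(best_fit))
}
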