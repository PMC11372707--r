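test_that("build_model_sequence is a nested, hierarchy-respecting ladder", {
  specs <- build_model_sequence()
  expect_equal(specs[[1]]$terms, character(0))        # intercept-only first
  full <- specs[[length(specs)]]$terms
  expect_equal(sum(vapply(strsplit(full, ":"), length, integer(1)) == 2), 10)
  expect_equal(sum(vapply(strsplit(full, ":"), length, integer(1)) == 3), 5)
  for (i in seq_along(specs)[-1]) {
    expect_true(all(specs[[i - 1]]$terms %in% specs[[i]]$terms))
    expect_gt(length(specs[[i]]$terms), length(specs[[i - 1]]$terms))
  }
  with4 <- build_model_sequence(include_four_way = TRUE)
  expect_true("condition:group:hand:sex" %in% with4[[length(with4)]]$terms)
  expect_error(build_model_sequence(c("condition", "group")),
               class = "forcefluct_invalid_argument")
  expect_error(model_spec("condition:group"),
               class = "forcefluct_invalid_argument")  # parents missing
})

test_that("fit_mixed_model handles degenerate inputs per contract", {
  d <- data.frame(participant_id = rep(sprintf("P%02d", 1:10), each = 4),
                  value = 3.25, condition = "bimanual_constant",
                  group = "CHI", hand = "left", sex = "male", timepoint = 1L)
  fit <- fit_mixed_model(d, model_spec())
  expect_equal(fit$coefficients$beta[1], 3.25, tolerance = 1e-8)
  expect_lt(fit$varcomp[["residual_sd"]]^2, 1e-12)
  # fewer than 2 participants
  expect_error(fit_mixed_model(d[d$participant_id == "P01", ], model_spec()),
               class = "forcefluct_invalid_argument")
  # rank deficiency names the aliased term (sex never varies here)
  d$value <- rnorm(nrow(d))
  expect_error(fit_mixed_model(d, model_spec(c("sex"))),
               class = "forcefluct_rank_deficient")
  err <- tryCatch(fit_mixed_model(d, model_spec(c("sex"))),
                  error = function(e) conditionMessage(e))
  expect_match(err, "sexfemale")
})

test_that("zero between-participant variance reduces to OLS", {
  set.seed(77)
  d <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:20), each = 8),
    condition = rep(c("bimanual_constant", "role_differentiated"), 80),
    group = "CHI", hand = rep(c("left", "left", "right", "right"), 40),
    sex = "male", timepoint = 1L
  )
  d$value <- 2 + 1.5 * (d$condition == "role_differentiated") + rnorm(160)
  fit <- fit_mixed_model(d, model_spec(c("condition", "hand")))
  expect_lt(fit$varcomp[["intercept_sd"]], 0.3)
  ols <- coef(lm(value ~ condition + hand, data = d))
  expect_equal(fit$coefficients$beta, unname(ols), tolerance = 1e-3)
  # AIC identity 2k - 2 logLik holds by construction
  expect_equal(fit$aic, 2 * fit$n_parameters - 2 * fit$log_likelihood)
  # containment df: condition/hand vary within participants
  cf <- fit$coefficients
  expect_equal(cf$df[cf$term == "handright"], 160 - 20 - 2)
  expect_true(all(cf$df > 0))
})

test_that("model selection picks the lowest AIC with ties to the smaller model", {
  fake <- function(aic, k) structure(list(aic = aic, n_parameters = k),
                                     class = "fit_result")
  expect_equal(select_best_model(list(fake(100, 3), fake(98, 4), fake(99, 5))), 2)
  expect_equal(select_best_model(list(fake(98, 5), fake(98, 3))), 2)
  expect_equal(select_best_model(list(fake(42, 2))), 1)
  expect_error(select_best_model(list()), class = "forcefluct_invalid_argument")
})

test_that("likelihood_ratio_test follows the chi-square contract", {
  fake <- function(ll, reml = FALSE)
    structure(list(log_likelihood = ll, reml = reml), class = "fit_result")
  same <- likelihood_ratio_test(fake(10), fake(10), 1)
  expect_equal(same$lr, 0)
  expect_equal(same$p, 1)
  lrt <- likelihood_ratio_test(fake(10), fake(12), 1)
  expect_equal(lrt$lr, 4)
  expect_equal(lrt$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(lrt$p, 4), 0.0455)
  expect_error(likelihood_ratio_test(fake(10), fake(12), 0),
               class = "forcefluct_invalid_argument")
  expect_error(likelihood_ratio_test(fake(10), fake(12, reml = TRUE), 1),
               class = "forcefluct_invalid_argument")
  expect_error(likelihood_ratio_test(fake(12), fake(10), 1),
               class = "forcefluct_nesting_violation")
})

test_that("effect_size_r matches the t-to-r conversion and is monotone", {
  expect_equal(round(effect_size_r(5.13, 129), 2), 0.41)
  expect_equal(round(effect_size_r(6.81, 128), 2), 0.52)
  expect_equal(round(effect_size_r(-7.50, 129), 2), 0.55)
  expect_equal(effect_size_r(0, 100), 0)
  expect_error(effect_size_r(1, 0), class = "forcefluct_invalid_argument")
  ts <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(effect_size_r(ts, 50)) > 0))       # increasing in |t|
  dfs <- seq(10, 500, by = 10)
  expect_true(all(diff(effect_size_r(2, dfs)) < 0))       # decreasing in df
  expect_equal(effect_size_r(-3, 40), effect_size_r(3, 40))
})

test_that("summarize_contrasts labels terms and appends r", {
  cohort <- gen_cohort(small_cohort(seed = 4))
  fit0 <- fit_mixed_model(cohort$observations, model_spec())
  tab0 <- summarize_contrasts(fit0)
  expect_equal(nrow(tab0), 1)
  expect_equal(tab0$label, "Intercept")
  fit <- fit_mixed_model(cohort$observations,
                         model_spec(c("condition", "group", "hand", "sex",
                                      "timepoint", "condition:group")))
  tab <- summarize_contrasts(fit)
  expect_equal(tab$r, effect_size_r(tab$t, tab$df))
  expect_true("Condition (RD-BC)" %in% tab$label)
  expect_true("Condition (RD-BC) x Group (MCI-CHI)" %in% tab$label)
  expect_match(attr(tab, "coding"), "treatment coding")
  expect_true(all(tab$r >= 0 & tab$r < 1))
})

test_that("a single cohort recovers its generative betas within 4 SE", {
  cohort <- gen_cohort(small_cohort(seed = 12))
  truth <- default_fixed_effects()
  fit <- fit_mixed_model(cohort$observations,
                         model_spec(c("condition", "group", "hand", "sex",
                                      "timepoint", "condition:group",
                                      "condition:hand")))
  est <- fit$coefficients
  # map raw design-matrix names back to generative term names
  est$clean <- gsub("role_differentiated|MCI|right|female", "", est$term)
  for (nm in names(truth)) {
    row <- est[est$clean == nm, ]
    expect_equal(nrow(row), 1)
    expect_lt(abs(row$beta - truth[[nm]]), 4 * row$se)
  }
})

test_that("adding null terms does not inflate AIC beyond 2 per parameter", {
  deltas <- vapply(1:12, function(s) {
    cohort <- gen_cohort(small_cohort(
      seed = 600 + s,
      fixed_effects = c("(Intercept)" = 4.33, condition = 2.4)))
    reduced <- fit_mixed_model(cohort$observations, model_spec("condition"))
    full <- fit_mixed_model(cohort$observations,
                            model_spec(c("condition", "group", "hand", "sex")))
    c(aic = reduced$aic - full$aic,
      dk = full$n_parameters - reduced$n_parameters)
  }, numeric(2))
  # in expectation AIC(reduced) - AIC(full) <= 2 * df_diff when the extra
  # betas are zero; allow generous simulation slack
  expect_lt(mean(deltas["aic", ]), 2 * deltas["dk", 1] / 2)
})

test_that("stepwise_inference selects a model and reports a trace", {
  cohort <- gen_cohort(small_cohort(seed = 31))
  inf <- stepwise_inference(cohort$observations)
  expect_s3_class(inf$trace, "data.frame")
  expect_equal(nrow(inf$trace), length(build_model_sequence()))
  fitted_rows <- !is.na(inf$trace$aic)
  expect_gt(sum(fitted_rows), 5)
  # ML log-likelihood never decreases along the nested ladder
  lls <- inf$trace$log_likelihood[fitted_rows]
  expect_true(all(diff(lls) > -1e-6))
  expect_true(inf$best_fit$reml)
  expect_equal(inf$contrasts$r,
               effect_size_r(inf$contrasts$t, inf$contrasts$df))
})
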