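# Orchestration: CSV I/O with provenance headers, the three pipeline
# stages (simulate -> measure -> infer), run manifests and fixtures.

write_csv_with_header <- function(df, path, seed, cfg_hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# forcefluct v%s | seed=%d | config=%s",
                     as.character(utils::packageVersion("forcefluct")),
                     as.integer(seed), cfg_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
}

read_csv_skip_header <- function(path) {
  if (!file.exists(path))
    ff_stop(paste("input file does not exist:", path), "forcefluct_config_error")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Long-format trial table: one row per sample.
trials_to_df <- function(trials, subjects) {
  pieces <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    sub <- subjects[subjects$id == tr$participant_id, , drop = FALSE]
    data.frame(participant_id = tr$participant_id,
               timepoint = tr$timepoint, condition = tr$condition,
               hand = tr$hand, role = tr$role,
               sex = if (nrow(sub)) sub$sex else NA_character_,
               group = if (nrow(sub)) sub$group else NA_character_,
               mvc_n = tr$mvc_n, rate_hz = tr$rate_hz,
               trial_index = i, sample_index = seq_along(tr$samples),
               force_n = tr$samples, stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

df_to_trials <- function(df) {
  key <- interaction(df$participant_id, df$timepoint, df$condition, df$hand,
                     df$trial_index, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$sample_index), ]
    list(trial = force_trial(d$force_n, d$rate_hz[1], hand = d$hand[1],
                             role = d$role[1], condition = d$condition[1],
                             participant_id = d$participant_id[1],
                             timepoint = d$timepoint[1], mvc_n = d$mvc_n[1]),
         group = d$group[1], sex = d$sex[1])
  })
}

#' Configure a pipeline run
#'
#' @param stages which stages to run: `"all"` or any of `"simulate"`,
#'   `"measure"`, `"infer"`.
#' @param out_dir directory for all output artifacts.
#' @param cohort a [cohort_config()].
#' @param ramp_s ramp exclusion in seconds.
#' @param window_grid DFA window sizes.
#' @param sen_cfg a [sen_config()].
#' @param aggregate_trials average measures across trials within each
#'   participant x condition x hand x timepoint cell (`TRUE`, default) or
#'   pass trial-level observations through to the model.
#' @param seed run seed; recorded in every output header.
#' @param log_level `"INFO"` (per-stage counts), `"WARN"` (undefined-SEn
#'   cells only) or `"QUIET"`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = "all", out_dir = tempfile("forcefluct-"),
                            cohort = cohort_config(), ramp_s = 6,
                            window_grid = default_window_grid(),
                            sen_cfg = sen_config(), aggregate_trials = TRUE,
                            seed = 1L, log_level = c("INFO", "WARN", "QUIET")) {
  log_level <- match.arg(log_level)
  valid <- c("all", "simulate", "measure", "infer")
  if (!all(stages %in% valid))
    ff_stop("`stages` must be 'all' or a subset of simulate/measure/infer",
            "forcefluct_config_error")
  if ("all" %in% stages) stages <- c("simulate", "measure", "infer")
  if (!inherits(cohort, "cohort_config"))
    ff_stop("`cohort` must be a cohort_config", "forcefluct_config_error")
  assert_flag(aggregate_trials, "aggregate_trials")
  cohort$seed <- as.integer(seed)
  structure(list(stages = stages, out_dir = out_dir, cohort = cohort,
                 ramp_s = ramp_s, window_grid = window_grid,
                 sen_cfg = sen_cfg, aggregate_trials = aggregate_trials,
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

pipeline_paths <- function(cfg) {
  list(trials = file.path(cfg$out_dir, "trials.csv"),
       subjects = file.path(cfg$out_dir, "subjects.csv"),
       measures = file.path(cfg$out_dir, "measures.csv"),
       contrasts = file.path(cfg$out_dir, "contrasts_%s.csv"),
       trace = file.path(cfg$out_dir, "model_trace_%s.json"),
       manifest = file.path(cfg$out_dir, "manifest.json"))
}

log_msg <- function(cfg, level, ...) {
  levels <- c(QUIET = 0, WARN = 1, INFO = 2)
  if (levels[[cfg$log_level]] >= levels[[level]])
    message(sprintf("[%s] ", level), sprintf(...))
}

stage_simulate <- function(cfg, paths, hash) {
  cohort <- gen_cohort(cfg$cohort, signals = TRUE)
  trials_df <- trials_to_df(cohort$trials, cohort$subjects)
  write_csv_with_header(cohort$subjects, paths$subjects, cfg$seed, hash)
  write_csv_with_header(trials_df, paths$trials, cfg$seed, hash)
  log_msg(cfg, "INFO", "simulate: %d subjects, %d trials (%d samples)",
          nrow(cohort$subjects), length(cohort$trials), nrow(trials_df))
  c(subjects = nrow(cohort$subjects), trial_rows = nrow(trials_df))
}

stage_measure <- function(cfg, paths, hash) {
  df <- read_csv_skip_header(paths$trials)
  if (nrow(df) == 0L)
    ff_stop("trials file is empty", "forcefluct_empty_input")
  records <- df_to_trials(df)
  warnings_seen <- character(0)
  results <- list()
  for (rec in records) {
    tr <- rec$trial
    # constant-force series only: both hands in the bimanual constant
    # condition, the stabilizing hand in the role-differentiated condition
    if (tr$condition == "role_differentiated" && tr$role != "stabilizing") next
    res <- withCallingHandlers(
      analyze_trial(tr, ramp_s = cfg$ramp_s, window_sizes = cfg$window_grid,
                    sen_cfg = cfg$sen_cfg, group = rec$group, sex = rec$sex),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            sprintf("%s/%s/%s/t%d: %s", tr$participant_id,
                                    tr$condition, tr$hand, tr$timepoint,
                                    conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    results[[length(results) + 1L]] <- res
  }
  if (cfg$aggregate_trials) {
    keyfun <- function(r) paste(r$participant_id, r$condition, r$hand,
                                r$timepoint, sep = "|")
    keys <- vapply(results, keyfun, character(1))
    results <- lapply(split(results, keys), aggregate_cell)
  }
  out <- do.call(rbind, lapply(results, function(r) {
    data.frame(participant_id = r$participant_id, timepoint = r$timepoint,
               condition = r$condition, hand = r$hand, group = r$group,
               sex = r$sex, cv = r$cv, dfa_alpha = r$dfa_alpha, sen = r$sen,
               n_trials = r$n_trials, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$participant_id, out$timepoint, out$condition, out$hand), ]
  rownames(out) <- NULL
  write_csv_with_header(out, paths$measures, cfg$seed, hash)
  for (w in warnings_seen) log_msg(cfg, "WARN", "measure: %s", w)
  log_msg(cfg, "INFO", "measure: %d cells written", nrow(out))
  res <- c(measure_cells = nrow(out), undefined_sen = length(warnings_seen))
  attr(res, "warnings") <- warnings_seen
  res
}

stage_infer <- function(cfg, paths, hash) {
  meas <- read_csv_skip_header(paths$measures)
  if (nrow(meas) == 0L)
    ff_stop("measures file is empty", "forcefluct_empty_input")
  counts <- c()
  for (outcome in c("cv", "dfa_alpha", "sen")) {
    obs <- meas[, c("participant_id", "timepoint", "condition", "hand",
                    "group", "sex")]
    obs$value <- meas[[outcome]]
    obs$outcome <- outcome
    obs <- obs[!is.na(obs$value), ]
    inf <- stepwise_inference(obs)
    write_csv_with_header(inf$contrasts, sprintf(paths$contrasts, outcome),
                          cfg$seed, hash)
    jsonlite::write_json(inf$trace, sprintf(paths$trace, outcome),
                         dataframe = "rows", na = "null", auto_unbox = TRUE,
                         digits = NA)
    log_msg(cfg, "INFO", "infer[%s]: best model step %d (AIC %.2f)",
            outcome, inf$best_index, inf$best_fit$aic)
    counts[paste0("contrast_rows_", outcome)] <- nrow(inf$contrasts)
  }
  counts
}

#' Run the pipeline
#'
#' Executes the requested stages in order simulate -> measure -> infer,
#' writing all artifacts under `cfg$out_dir` with a provenance header
#' (package version, seed, config hash) on every CSV, plus a JSON run
#' manifest. Deterministic for a fixed seed: two runs produce byte-identical
#' outputs. A stage failure is recorded in the manifest and re-raised.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest, invisibly (list: config hash, seed, package
#'   version, per-stage row counts, warnings, status).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config"))
    ff_stop("`cfg` must be a pipeline_config", "forcefluct_config_error")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- pipeline_paths(cfg)
  if (!"simulate" %in% cfg$stages) {
    need <- c(if ("measure" %in% cfg$stages) paths$trials,
              if ("infer" %in% cfg$stages && !"measure" %in% cfg$stages)
                paths$measures)
    for (p in need) if (!file.exists(p))
      ff_stop(paste("required input missing for non-simulate run:", p),
              "forcefluct_config_error")
  }
  hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  manifest <- list(package_version =
                     as.character(utils::packageVersion("forcefluct")),
                   seed = cfg$seed, config_hash = hash, stages = cfg$stages,
                   counts = list(), warnings = character(0), status = "ok",
                   failed_stage = NULL)
  runner <- list(simulate = stage_simulate, measure = stage_measure,
                 infer = stage_infer)
  for (st in c("simulate", "measure", "infer")) {
    if (!st %in% cfg$stages) next
    res <- tryCatch(runner[[st]](cfg, paths, hash), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$status <- "failed"
      manifest$failed_stage <- st
      manifest$error <- conditionMessage(res)
      jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                           null = "null")
      stop(res)
    }
    manifest$warnings <- c(manifest$warnings, attr(res, "warnings"))
    manifest$counts <- c(manifest$counts, as.list(c(res)))
  }
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Write the bundled test fixtures
#'
#' Generates the small deterministic inputs used by the test-suite and
#' documentation: a 64-sample series with its step-by-step DFA reference
#' output (window sizes 4, 8, 16), the alternating +1/-1 sample-entropy
#' fixture, and a 6-subject mini cohort that exercises the full pipeline in
#' a few seconds. Reference values are computed at write time with the
#' loop-based oracles ([dfa_brute_force()], [sen_brute_force()]), not with
#' the production routines. Repeated calls overwrite deterministically.
#'
#' @param out_dir writable directory.
#' @return invisibly, the named vector of files written.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  # 64-sample DFA fixture
  set.seed(substream_seed(424242L, "fixture-dfa"))
  x <- round(stats::rnorm(64), 6)
  dfa_path <- file.path(out_dir, "dfa_fixture_64.csv")
  utils::write.csv(data.frame(value = x), dfa_path, row.names = FALSE)
  oracle <- dfa_brute_force(x, c(4L, 8L, 16L, 32L))
  oracle_path <- file.path(out_dir, "dfa_fixture_64_oracle.json")
  jsonlite::write_json(list(window_sizes = oracle$window_sizes,
                            fluctuation = oracle$fluctuation,
                            alpha = oracle$alpha),
                       oracle_path, digits = NA)

  # alternating sample-entropy fixture
  alt <- rep(c(1, -1), 50)
  alt_scaled <- (alt - mean(alt)) / stats::sd(alt)
  alt_path <- file.path(out_dir, "sen_alternating_100.csv")
  utils::write.csv(data.frame(value = alt), alt_path, row.names = FALSE)
  alt_oracle <- sen_brute_force(alt_scaled, m = 2L, r = 0.25)
  alt_oracle_path <- file.path(out_dir, "sen_alternating_100_oracle.json")
  jsonlite::write_json(alt_oracle, alt_oracle_path, digits = NA)

  # 6-subject mini cohort (signals included)
  mini <- cohort_config(
    counts = matrix(c(3L, 2L, 3L, 2L), nrow = 2, byrow = TRUE,
                    dimnames = list(c("CHI", "MCI"), c("T1", "T2"))),
    trials_per_cell = c(bimanual_constant = 1L, role_differentiated = 1L),
    seed = 424242L
  )
  cohort <- gen_cohort(mini, signals = TRUE)
  sub_path <- file.path(out_dir, "mini_cohort_subjects.csv")
  trial_path <- file.path(out_dir, "mini_cohort_trials.csv")
  utils::write.csv(cohort$subjects, sub_path, row.names = FALSE)
  utils::write.csv(trials_to_df(cohort$trials, cohort$subjects), trial_path,
                   row.names = FALSE)

  invisible(c(dfa = dfa_path, dfa_oracle = oracle_path, sen = alt_path,
              sen_oracle = alt_oracle_path, subjects = sub_path,
              trials = trial_path))
}
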