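# Trial-table CSV IO, fMRI-style regressor export, and the end-to-end
# pipeline.

.TRIAL_SCHEMA <- c("subject_id", "group", "condition", "block",
                   "trial_in_block", "trial_overall", "chosen", "outcome",
                   "correct", "rt", "switch")

#' Write a trial table to CSV
#'
#' Writes the canonical schema (`subject_id, group, condition, block,
#' trial_in_block, trial_overall, chosen, outcome, correct, rt, switch`);
#' missing reaction times become empty fields.
#'
#' @param tables Long trial data frame or named list of per-subject tables.
#' @param path Output CSV path.
#' @export
write_trials <- function(tables, path) {
  df <- as_cohort_df(tables)
  if (!"group" %in% names(df)) df$group <- NA_character_
  if (!"rt" %in% names(df)) df$rt <- NA_real_
  miss <- setdiff(.TRIAL_SCHEMA, names(df))
  if (length(miss)) {
    stop("cannot write trials; missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- df[, .TRIAL_SCHEMA]
  out$correct <- as.integer(out$correct)
  out$switch <- as.integer(out$switch)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial table CSV
#'
#' Validates the canonical schema, reporting offending row numbers; blank
#' `rt` fields are parsed as missing.
#'
#' @param path CSV path.
#' @return Long trial data frame ordered by subject, block, trial.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.TRIAL_SCHEMA, names(df))
  if (length(miss)) {
    stop("trial CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$outcome))))
  if (length(bad)) {
    stop("non-numeric outcome at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  df$outcome <- as.numeric(df$outcome)
  df$correct <- as.logical(df$correct)
  df$switch <- as.logical(df$switch)
  df$rt <- suppressWarnings(as.numeric(df$rt))
  key <- interaction(df$subject_id, df$condition, df$block, drop = TRUE)
  disorder <- unlist(lapply(split(seq_len(nrow(df)), key), function(idx) {
    t <- df$trial_in_block[idx]
    idx[c(FALSE, diff(t) != 1L)]
  }), use.names = FALSE)
  if (length(disorder)) {
    stop("unordered or gapped trials within block at row(s): ",
         paste(utils::head(sort(disorder), 5L), collapse = ", "),
         call. = FALSE)
  }
  df[order(df$subject_id, df$block, df$trial_in_block), , drop = FALSE]
}

#' Export z-scored trial-by-trial regressors
#'
#' For each fitted subject, builds the parametric-modulator table used in
#' model-based imaging analyses: the softmax probability of the chosen
#' option at the cue event, and the outcome amount, prediction error, and
#' associability value at the outcome event — all computed from the
#' subject's individually estimated parameters at trial t prior to
#' updating, and z-scored within subject. A zero-variance modulator is
#' exported unscaled with a warning and `scaled = FALSE`.
#'
#' @param fits A `two_stage_fit` or named list of `fit_result`s.
#' @param cohort_tables Matching trial data.
#' @param out_dir Optional directory; one `<subject_id>_regressors.csv` per
#'   subject is written when given.
#' @return Named list of per-subject regressor data frames (`trial`,
#'   `event`, `modulator`, `value`, `scaled`).
#' @export
export_regressors <- function(fits, cohort_tables, out_dir = NULL) {
  if (inherits(fits, "two_stage_fit")) fits <- fits$fits
  df <- as_cohort_df(cohort_tables)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  out <- list()
  for (f in fits) {
    id <- f$subject_id
    tab <- df[df$subject_id == id, , drop = FALSE]
    if (nrow(tab) == 0L) stop("no trials for fitted subject ", id,
                              call. = FALSE)
    tr <- latent_trace(f$estimates, tab)
    mods <- list(
      cue = list(choice_probability = tr$p_chosen),
      outcome = list(outcome_amount = tr$outcome,
                     prediction_error = tr$delta,
                     associability_value = tr$kappa_chosen))
    rows <- list()
    for (event in names(mods)) {
      for (nm in names(mods[[event]])) {
        z <- zscore_safe(mods[[event]][[nm]])
        if (!z$scaled) {
          warning(sprintf("subject %s: zero-variance modulator '%s' left %s",
                          id, nm, "unscaled"))
          z$values <- mods[[event]][[nm]]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          trial = tr$trial_overall, event = event, modulator = nm,
          value = z$values, scaled = z$scaled, stringsAsFactors = FALSE)
      }
    }
    reg <- do.call(rbind, rows)
    out[[id]] <- reg
    if (!is.null(out_dir)) {
      utils::write.csv(reg, file.path(out_dir,
                                      paste0(id, "_regressors.csv")),
                       row.names = FALSE)
    }
  }
  out
}

#' Pipeline configuration
#'
#' @param seed Master seed; every stage's randomness derives from it.
#' @param group_specs Synthetic study specification (ignored if
#'   `trials_csv` given).
#' @param trials_csv Optional path to an existing trial CSV to analyze
#'   instead of simulating.
#' @param scope Conditions to analyze.
#' @param fit_cfg A [fit_config()].
#' @param run_sweep Include the associability-weight performance sweep.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, group_specs = default_study_spec(),
                            trials_csv = NULL, scope = c("loss", "gain"),
                            fit_cfg = fit_config(), run_sweep = TRUE) {
  structure(list(seed = as.integer(seed), group_specs = group_specs,
                 trials_csv = trials_csv, scope = scope, fit_cfg = fit_cfg,
                 run_sweep = run_sweep), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) a cohort, applies the low-switching exclusion
#' filter, runs the two-stage fits for both model variants in every scoped
#' condition, performs AICc-based model selection with protected exceedance
#' probabilities, the behavioral validation suite (learning curve,
#' calibration, reaction-time regression, switching models, optional
#' performance sweep), the group contrasts on the associability weight and
#' learning rate, and regressor export.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory: writes `trials.csv`,
#'   `parameters.csv`, `report.json`, and per-subject regressors.
#' @return List of class `study_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  set.seed(config$seed)
  scope <- config$scope

  if (!is.null(config$trials_csv)) {
    trials <- read_trials(config$trials_csv)
    covariates <- NULL
    true_params <- NULL
  } else {
    bundle <- make_cohort(config$group_specs,
                          config = session_config(conditions = scope))
    trials <- bundle$trials
    covariates <- bundle$covariates
    true_params <- bundle$true_params
  }

  # condition-specific analyses use condition-specific exclusion (subjects
  # excluded only for low gain switching still contribute loss analyses);
  # cross-condition analyses require adequate switching in both conditions
  excl <- lapply(stats::setNames(scope, scope), function(cond) {
    exclusion_filter(trials, scope = cond)
  })
  excl_both <- exclusion_filter(
    trials, scope = if (length(scope) > 1L) "both" else scope)

  fits <- list()
  comparison <- list()
  all_tabs <- list()
  for (cond in scope) {
    ct <- trials[trials$condition == cond &
                   trials$subject_id %in% excl[[cond]]$included, ,
                 drop = FALSE]
    fits[[cond]] <- list(
      basic = two_stage_fit(ct, "basic", config$fit_cfg),
      associability = two_stage_fit(ct, "associability", config$fit_cfg))
    tb <- rbind(fits_table(fits[[cond]]$basic),
                fits_table(fits[[cond]]$associability))
    all_tabs[[cond]] <- tb
    comparison[[cond]] <- compare_variants(tb, seed = config$seed)[[cond]]
  }

  loss_cond <- if ("loss" %in% scope) "loss" else scope[1L]
  loss_fit <- fits[[loss_cond]]$associability
  loss_trials <- trials[trials$condition == loss_cond &
                          trials$subject_id %in%
                            excl[[loss_cond]]$included, , drop = FALSE]

  # latents under each subject's individually estimated parameters
  traced <- do.call(rbind, lapply(loss_fit$fits, function(f) {
    latent_trace(f$estimates,
                 loss_trials[loss_trials$subject_id == f$subject_id, ,
                             drop = FALSE])
  }))

  calib <- calibration_bins(loss_fit, loss_trials)
  rt_coefs <- if (any(is.finite(traced$rt))) rt_regression(traced) else NULL
  rt_test <- if (!is.null(rt_coefs) && nrow(rt_coefs) >= 3L) {
    group_rt_test(rt_coefs)
  } else NULL
  switching <- switching_models(traced)
  curve <- running_accuracy(loss_trials, condition = loss_cond)
  sweep <- if (isTRUE(config$run_sweep)) {
    eta_performance_sweep(seed = config$seed + 1L)
  } else NULL
  cond_interaction <- if (length(scope) > 1L) {
    condition_interaction_test(
      trials[trials$subject_id %in% excl_both$included, , drop = FALSE])
  } else NULL

  group_stats <- NULL
  if (!is.null(covariates) && length(unique(covariates$group)) > 1L) {
    ptab <- fits_table(loss_fit)
    group_stats <- list(
      eta = group_parameter_regression(ptab, covariates, "eta"),
      alpha = group_parameter_regression(ptab, covariates, "alpha"))
  }

  regressors <- export_regressors(loss_fit, loss_trials,
                                  out_dir = if (!is.null(out_dir)) {
                                    file.path(out_dir, "regressors")
                                  } else NULL)

  report <- structure(list(
    manifest = list(seed = config$seed, scope = scope,
                    n_subjects_input = length(unique(trials$subject_id)),
                    n_subjects_analyzed =
                      length(excl[[loss_cond]]$included),
                    n_starts = config$fit_cfg$n_starts),
    exclusion = list(per_condition = excl, both = excl_both),
    group_mean_beta = lapply(fits, lapply, `[[`, "group_mean_beta"),
    comparison = comparison,
    calibration = calib,
    rt = list(coefficients = rt_coefs, group_test = rt_test),
    switching = switching,
    condition_interaction = cond_interaction,
    learning_curve = curve,
    sweep = sweep,
    group_stats = group_stats,
    fits = fits,
    true_params = true_params,
    regressors = regressors), class = "study_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(do.call(rbind, all_tabs),
                     file.path(out_dir, "parameters.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_summary(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Machine-readable summary of a study report
#'
#' @param report A `study_report` from [run_pipeline()].
#' @return Nested list of plain numbers/strings suitable for JSON export.
#' @export
report_summary <- function(report) {
  comp <- lapply(report$comparison, function(x) {
    list(pep = as.list(x$pep), ep = as.list(x$ep), bor = x$bor,
         best_fraction = as.list(x$best_fraction),
         expected_frequencies = as.list(x$expected_frequencies))
  })
  gs <- if (!is.null(report$group_stats)) {
    lapply(report$group_stats, function(g) {
      grp <- g$coefficients[grep("^group", g$coefficients$term), ]
      list(estimate = grp$estimate[1L], t = grp$t[1L], p = grp$p[1L],
           vif = g$vif_group)
    })
  } else NULL
  list(
    manifest = report$manifest,
    n_excluded = vapply(report$exclusion$per_condition,
                        function(e) length(e$excluded), numeric(1)),
    condition_interaction_z =
      if (!is.null(report$condition_interaction)) {
        report$condition_interaction$z
      } else NULL,
    comparison = comp,
    calibration_r = report$calibration$r,
    rt_group_test = report$rt$group_test,
    switching = list(report = report$switching$report,
                     lrt = report$switching$lrt),
    sweep_r = if (!is.null(report$sweep)) report$sweep$r else NULL,
    group_stats = gs)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  %d/%d subjects analyzed (seed %d)\n",
              x$manifest$n_subjects_analyzed, x$manifest$n_subjects_input,
              x$manifest$seed))
  for (cond in names(x$comparison)) {
    pep <- x$comparison[[cond]]$pep
    cat(sprintf("  %s: PEP(%s) = %.3f\n", cond, names(pep)[which.max(pep)],
                max(pep)))
  }
  cat(sprintf("  calibration r = %.4f\n", x$calibration$r))
  invisible(x)
}
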