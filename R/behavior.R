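# Behavioral validation and group statistics: exclusion rules, learning
# curves, associability-weight performance sweep, calibration, reaction-time
# and switching regressions, jackknife SEs, and group contrasts on fitted
# parameters.

as_cohort_df <- function(cohort_tables) {
  if (is.data.frame(cohort_tables)) {
    stopifnot("subject_id" %in% names(cohort_tables))
    return(cohort_tables)
  }
  ids <- names(cohort_tables) %||% as.character(seq_along(cohort_tables))
  do.call(rbind, Map(function(tb, id) {
    if (!"subject_id" %in% names(tb)) tb$subject_id <- id
    tb
  }, cohort_tables, ids))
}

#' Low-switching exclusion filter
#'
#' Subjects who switch options less than 10% of the time (per condition) do
#' not provide behavior suitable for model fitting and are excluded. For
#' analyses spanning both conditions (`scope = "both"`) the criterion
#' applies to each condition; for condition-specific analyses only that
#' condition's switch rate matters. A switch rate of exactly 10% is
#' retained (strict "less than").
#'
#' @param cohort_tables Long trial data frame (with `subject_id`) or named
#'   list of per-subject tables; `switch` flags must be present (NA on the
#'   first trial of each block).
#' @param scope `"both"`, `"loss"`, or `"gain"`.
#' @param threshold Minimum switch rate (default 0.10).
#' @return List: `included` (subject ids), `excluded`, `report` (data frame
#'   of per-subject, per-condition switch rates with an `excluded` flag).
#' @export
exclusion_filter <- function(cohort_tables, scope = c("both", "loss", "gain"),
                             threshold = 0.10) {
  scope <- match.arg(scope)
  df <- as_cohort_df(cohort_tables)
  rates <- stats::aggregate(switch ~ subject_id + condition, data = df,
                            FUN = mean, na.rm = TRUE, na.action = NULL)
  names(rates)[names(rates) == "switch"] <- "switch_rate"
  conds <- if (scope == "both") unique(df$condition) else scope
  bad <- unique(rates$subject_id[
    rates$condition %in% conds & rates$switch_rate < threshold])
  rates$excluded <- rates$subject_id %in% bad
  all_ids <- unique(df$subject_id)
  list(included = setdiff(all_ids, bad), excluded = bad, report = rates)
}

running_mean <- function(x, window) {
  n <- length(x)
  out <- numeric(n)
  cs <- cumsum(x)
  for (t in seq_len(n)) {
    lo <- max(1L, t - window + 1L)
    out[t] <- (cs[t] - if (lo > 1L) cs[lo - 1L] else 0) / (t - lo + 1L)
  }
  out
}

#' Group learning curve
#'
#' Within-block running accuracy (window of 5 trials, partial at block
#' start), averaged over blocks within subject and then across subjects,
#' by trial position in block.
#'
#' @param cohort_tables Trial data (see [exclusion_filter()]).
#' @param window Running-average window (default 5).
#' @param condition Optional condition filter.
#' @return Data frame: `trial_in_block`, `mean`, `se`, `n_subjects`.
#' @export
running_accuracy <- function(cohort_tables, window = 5L, condition = NULL) {
  df <- as_cohort_df(cohort_tables)
  if (!is.null(condition)) df <- df[df$condition == condition, , drop = FALSE]
  df <- df[order(df$subject_id, df$block, df$trial_in_block), , drop = FALSE]
  key <- interaction(df$subject_id, df$block, drop = TRUE)
  df$runacc <- unlist(lapply(split(as.numeric(df$correct), key),
                             running_mean, window = window),
                      use.names = FALSE)
  subj <- stats::aggregate(runacc ~ subject_id + trial_in_block, data = df,
                           FUN = mean)
  agg_m <- stats::aggregate(runacc ~ trial_in_block, data = subj, FUN = mean)
  agg_s <- stats::aggregate(runacc ~ trial_in_block, data = subj,
                            FUN = function(x) {
                              if (length(x) > 1) {
                                stats::sd(x) / sqrt(length(x))
                              } else NA_real_
                            })
  agg_n <- stats::aggregate(runacc ~ trial_in_block, data = subj,
                            FUN = length)
  data.frame(trial_in_block = agg_m$trial_in_block, mean = agg_m$runacc,
             se = agg_s$runacc, n_subjects = agg_n$runacc)
}

#' Associability-weight / performance simulation sweep
#'
#' Simulates agents at each associability weight on a grid (default 0.05 to
#' 0.95 in steps of 0.05; 50 agents of two 25-trial blocks per value, other
#' parameters fixed) and summarizes accuracy per weight together with the
#' pooled Pearson correlation between the assigned weight and accuracy
#' across all simulated agents.
#'
#' @param base_params Named list of the non-swept parameters
#'   (`alpha`, `rho`, `gamma`, `beta`); defaults are the synthetic cohort's
#'   generating means.
#' @param etas Associability-weight grid.
#' @param n_agents,n_blocks,n_trials Simulation size per grid value.
#' @param condition Simulated condition (default `"loss"`).
#' @param seed Integer seed.
#' @return List of class `sweep_result`: `grid` (per-eta mean accuracy and
#'   SE), `agents` (per-agent accuracies), `r` (pooled across agents),
#'   `r_means` (across per-eta means).
#' @export
eta_performance_sweep <- function(base_params = list(alpha = 0.5, rho = 1,
                                                     gamma = 0.9, beta = 10),
                                  etas = seq(0.05, 0.95, by = 0.05),
                                  n_agents = 50L, n_blocks = 2L,
                                  n_trials = 25L, condition = "loss",
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- session_config(conditions = condition)
  rows <- vector("list", length(etas) * n_agents)
  k <- 0L
  for (eta in etas) {
    params <- model_params(alpha = base_params$alpha, beta = base_params$beta,
                           eta = eta, rho = base_params$rho,
                           gamma = base_params$gamma,
                           variant = "associability", condition = condition)
    for (a in seq_len(n_agents)) {
      tab <- simulate_subject(stats::setNames(list(params), condition),
                              config = cfg, mode = "sim",
                              sim_blocks = n_blocks, sim_trials = n_trials)
      k <- k + 1L
      rows[[k]] <- data.frame(eta = eta, agent = a,
                              accuracy = mean(tab$correct))
    }
  }
  agents <- do.call(rbind, rows)
  grid <- do.call(rbind, lapply(split(agents, agents$eta), function(g) {
    data.frame(eta = g$eta[1L], mean_accuracy = mean(g$accuracy),
               se = stats::sd(g$accuracy) / sqrt(nrow(g)))
  }))
  rownames(grid) <- NULL
  structure(list(
    grid = grid, agents = agents,
    r = stats::cor(agents$eta, agents$accuracy),
    r_means = stats::cor(grid$eta, grid$mean_accuracy)),
    class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d eta values x %d agents; pooled r = %.4f\n",
              nrow(x$grid), nrow(x$agents) / nrow(x$grid), x$r))
  invisible(x)
}

#' Calibration of model-predicted choice probabilities
#'
#' Per subject, bins trials into `n_bins` equal-width bins of the
#' model-predicted probability of choosing the correct (better) option and
#' tabulates the observed proportion correct per bin; bin summaries are
#' averaged across subjects and the predicted/observed bin means are
#' correlated.
#'
#' @param fits A `two_stage_fit` or named list of `fit_result`s.
#' @param cohort_tables Matching trial data.
#' @param n_bins Number of equal-width probability bins (default 5).
#' @return List of class `calibration`: `bins` (bin center, mean predicted,
#'   mean observed, subject count), `r` (predicted-vs-observed Pearson r
#'   over occupied bins), `r_centers` (same with bin centers as the
#'   predictor), `n_dropped_bins`.
#' @export
calibration_bins <- function(fits, cohort_tables, n_bins = 5L) {
  if (inherits(fits, "two_stage_fit")) fits <- fits$fits
  df <- as_cohort_df(cohort_tables)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  centers <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  pred <- obs <- matrix(NA_real_, length(fits), n_bins)
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    tab <- df[df$subject_id == f$subject_id, , drop = FALSE]
    tr <- latent_trace(f$estimates, tab)
    p_correct <- ifelse(tr$correct, tr$p_chosen, 1 - tr$p_chosen)
    bin <- cut(p_correct, breaks = breaks, include.lowest = TRUE,
               labels = FALSE)
    for (b in unique(bin)) {
      idx <- bin == b
      pred[i, b] <- mean(p_correct[idx])
      obs[i, b] <- mean(tr$correct[idx])
    }
  }
  bins <- data.frame(
    bin = seq_len(n_bins), center = centers,
    predicted = colMeans(pred, na.rm = TRUE),
    observed = colMeans(obs, na.rm = TRUE),
    n_subjects = colSums(!is.na(pred)))
  occupied <- bins$n_subjects > 0
  n_dropped <- sum(!occupied)
  if (n_dropped > 0) {
    warning(n_dropped, " empty calibration bin(s) dropped")
  }
  ob <- bins[occupied, , drop = FALSE]
  r <- r_centers <- NA_real_
  if (nrow(ob) >= 2L && stats::sd(ob$predicted) > 0) {
    r <- stats::cor(ob$predicted, ob$observed)
    r_centers <- stats::cor(ob$center, ob$observed)
  } else {
    warning("fewer than 2 occupied bins or constant predictions; ",
            "calibration correlation undefined")
  }
  structure(list(bins = bins, r = r, r_centers = r_centers,
                 n_dropped_bins = n_dropped), class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> r = %.4f over %d occupied bins\n",
              x$r, sum(x$bins$n_subjects > 0)))
  invisible(x)
}

#' Per-subject reaction-time regressions on associability
#'
#' Ordinary least squares per subject of reaction time on the chosen cue's
#' associability value, the chosen cue's expected value, and the trial
#' number (optionally also the previous trial's prediction error). Trials
#' with RT < 0.333 s or > 5 s are excluded first; subjects with fewer than
#' `min_trials` usable trials are skipped.
#'
#' @param cohort_tables Trial data carrying latent columns (`kappa_chosen`,
#'   `Q_chosen`, `delta`) and `rt`.
#' @param include_prev_delta Add the previous trial's prediction error as a
#'   regressor.
#' @param rt_min,rt_max RT exclusion window in seconds.
#' @param min_trials Minimum usable trials per subject (default 10).
#' @return Data frame of per-subject coefficients (`kappa`, `q`, `trial`,
#'   and `prev_delta` if requested) with attribute `"skipped"` listing
#'   skipped subject ids.
#' @export
rt_regression <- function(cohort_tables, include_prev_delta = FALSE,
                          rt_min = 0.333, rt_max = 5, min_trials = 10L) {
  df <- as_cohort_df(cohort_tables)
  stopifnot(all(c("rt", "kappa_chosen", "Q_chosen") %in% names(df)))
  rows <- list()
  skipped <- character(0)
  for (id in unique(df$subject_id)) {
    tab <- df[df$subject_id == id, , drop = FALSE]
    tab <- tab[order(tab$block, tab$trial_in_block), , drop = FALSE]
    if (include_prev_delta) {
      tab$prev_delta <- ave(tab$delta, tab$block,
                            FUN = function(x) c(NA, x[-length(x)]))
    }
    use <- !is.na(tab$rt) & tab$rt >= rt_min & tab$rt <= rt_max
    if (include_prev_delta) use <- use & !is.na(tab$prev_delta)
    tab <- tab[use, , drop = FALSE]
    if (nrow(tab) < min_trials) {
      skipped <- c(skipped, id)
      next
    }
    fml <- if (include_prev_delta) {
      rt ~ kappa_chosen + Q_chosen + trial_overall + prev_delta
    } else {
      rt ~ kappa_chosen + Q_chosen + trial_overall
    }
    cf <- stats::coef(stats::lm(fml, data = tab))
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = id, kappa = cf[["kappa_chosen"]], q = cf[["Q_chosen"]],
      trial = cf[["trial_overall"]],
      prev_delta = if (include_prev_delta) cf[["prev_delta"]] else NA_real_,
      n_trials = nrow(tab), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Group test of the associability-RT coefficients
#'
#' One-sample t-test of the per-subject associability coefficients against
#' zero.
#'
#' @param coefs Output of [rt_regression()].
#' @return List: `mean`, `t`, `df`, `p`.
#' @export
group_rt_test <- function(coefs) {
  tt <- stats::t.test(coefs$kappa, mu = 0)
  list(mean = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

# Build the per-trial switching design: previous-outcome binary codes
# (1 = better previous outcome: small loss / large gain), previous-trial
# latents, lags 2 and 3 within block.
switch_design <- function(df, n_lags = 1L, with_latents = FALSE) {
  df <- df[order(df$subject_id, df$block, df$trial_in_block), , drop = FALSE]
  better <- ifelse(df$condition == "loss",
                   as.integer(round(abs(df$outcome), 6) ==
                                round(df$mag_small, 6)),
                   as.integer(round(abs(df$outcome), 6) ==
                                round(df$mag_large, 6)))
  key <- interaction(df$subject_id, df$block, drop = TRUE)
  lag_by <- function(x, k) {
    ave(x, key, FUN = function(v) c(rep(NA, k), v[seq_len(length(v) - k)]))
  }
  out <- data.frame(subject_id = df$subject_id, condition = df$condition,
                    switch = as.integer(df$switch),
                    out1 = lag_by(better, 1L), stringsAsFactors = FALSE)
  if (n_lags >= 2L) out$out2 <- lag_by(better, 2L)
  if (n_lags >= 3L) out$out3 <- lag_by(better, 3L)
  if (with_latents) {
    out$prev_delta <- lag_by(df$delta, 1L)
    out$prev_kappa <- lag_by(df$kappa_chosen, 1L)
  }
  stats::na.omit(out)
}

#' Nested switching models with associability-modulated prediction error
#'
#' Fits three nested random-intercept logistic regressions of trial-wise
#' switching (loss condition): (i) previous outcome (1 = small loss) only;
#' (ii) plus its interaction with the previous trial's prediction error;
#' (iii) plus the three-way interaction with the previous trial's
#' associability value. Reports each model's AIC, its AIC improvement over
#' the baseline, and the likelihood-ratio test of (iii) against (ii).
#'
#' @param cohort_tables Loss-condition trial data with latent columns
#'   (`delta`, `kappa_chosen`) computed from individually fitted
#'   parameters.
#' @return List of class `switch_models`: `report` (per-model AIC and
#'   delta-AIC), `lrt` (chisq, df, p for model iii vs ii), `n_obs`,
#'   `models` (fitted `glmer` objects).
#' @export
switching_models <- function(cohort_tables) {
  df <- as_cohort_df(cohort_tables)
  stopifnot(all(c("delta", "kappa_chosen") %in% names(df)))
  d <- switch_design(df, n_lags = 1L, with_latents = TRUE)
  m1 <- lme4::glmer(switch ~ out1 + (1 | subject_id), data = d,
                    family = stats::binomial)
  m2 <- lme4::glmer(switch ~ out1 * prev_delta + (1 | subject_id),
                    data = d, family = stats::binomial)
  m3 <- lme4::glmer(switch ~ out1 * prev_delta * prev_kappa +
                      (1 | subject_id), data = d, family = stats::binomial)
  aics <- c(outcome_only = stats::AIC(m1),
            outcome_x_pe = stats::AIC(m2),
            outcome_x_pe_x_assoc = stats::AIC(m3))
  lrt <- stats::anova(m2, m3)
  structure(list(
    report = data.frame(model = names(aics), aic = unname(aics),
                        delta_aic = unname(aics["outcome_only"] - aics),
                        stringsAsFactors = FALSE),
    lrt = list(chisq = lrt$Chisq[2L], df = lrt$Df[2L],
               p = lrt$`Pr(>Chisq)`[2L]),
    n_obs = nrow(d),
    models = list(m1 = m1, m2 = m2, m3 = m3)), class = "switch_models")
}

#' @export
print.switch_models <- function(x, ...) {
  print(x$report, row.names = FALSE)
  cat(sprintf("LRT (assoc vs pe): chisq = %.2f, df = %d, p = %.3g\n",
              x$lrt$chisq, x$lrt$df, x$lrt$p))
  invisible(x)
}

#' Jackknife standard error of a cohort statistic
#'
#' Leave-one-subject-out recomputation of `statistic`;
#' `SE = sqrt((n - 1) / n * sum((theta_(-i) - mean)^2))`.
#'
#' @param data List (or vector) with one element per subject.
#' @param statistic `function(data_subset)` returning a scalar.
#' @return List: `se`, `loo` (leave-one-out values), `theta` (full-sample
#'   value).
#' @export
jackknife_se <- function(data, statistic) {
  n <- length(data)
  if (n < 3L) stop("jackknife needs at least 3 subjects", call. = FALSE)
  loo <- vapply(seq_len(n), function(i) statistic(data[-i]), numeric(1))
  list(se = sqrt((n - 1) / n * sum((loo - mean(loo))^2)),
       loo = loo, theta = statistic(data))
}

#' Loss/gain interaction in switching behavior
#'
#' Random-intercept logistic regression of switching on the previous three
#' outcomes with a condition (loss/gain) interaction on the previous
#' outcome; reports the interaction estimate and z statistic.
#'
#' @param cohort_tables Trial data containing both conditions per subject.
#' @return List: `estimate`, `z`, `p`, `model`.
#' @export
condition_interaction_test <- function(cohort_tables) {
  df <- as_cohort_df(cohort_tables)
  if (length(unique(df$condition)) < 2L) {
    stop("both loss and gain trials are required", call. = FALSE)
  }
  d <- switch_design(df, n_lags = 3L)
  d$condition <- factor(d$condition)
  m <- lme4::glmer(switch ~ out1 * condition + out2 + out3 +
                     (1 | subject_id), data = d, family = stats::binomial)
  cf <- summary(m)$coefficients
  row <- grep(":", rownames(cf), value = TRUE)[1L]
  list(estimate = cf[row, "Estimate"], z = cf[row, "z value"],
       p = cf[row, "Pr(>|z|)"], model = m)
}

#' Group regression of a fitted parameter on diagnosis with covariates
#'
#' Linear model of a per-subject parameter estimate on group membership
#' plus covariates (e.g. depression score, combat-exposure score, age,
#' gender), reporting the coefficient table and the group term's variance
#' inflation factor.
#'
#' @param param_table Data frame with `subject_id` and the target parameter
#'   column (e.g. from [fits_table()]).
#' @param covariate_table Data frame with `subject_id`, `group`, and
#'   covariate columns.
#' @param target_param Name of the parameter column to model.
#' @return List of class `group_regression`: `coefficients` (term,
#'   estimate, se, t, p), `vif_group`, `n`, `model`.
#' @export
group_parameter_regression <- function(param_table, covariate_table,
                                       target_param) {
  stopifnot(target_param %in% names(param_table),
            all(c("subject_id", "group") %in% names(covariate_table)))
  d <- merge(param_table[, c("subject_id", target_param)], covariate_table,
             by = "subject_id")
  covars <- setdiff(names(covariate_table), c("subject_id", "group"))
  # a covariate constant over the analyzed subjects carries no information
  # and would break the model matrix (e.g. single-gender subsamples)
  constant <- vapply(covars, function(v) length(unique(d[[v]])) < 2L,
                     logical(1))
  covars <- covars[!constant]
  fml <- stats::reformulate(c("group", covars), response = target_param)
  m <- stats::lm(fml, data = d)
  al <- stats::alias(m)
  if (!is.null(al$Complete)) {
    stop("rank-deficient design; collinear columns: ",
         paste(rownames(al$Complete), collapse = ", "), call. = FALSE)
  }
  cf <- summary(m)$coefficients
  vifs <- car::vif(m)
  vif_group <- unname(if (is.matrix(vifs)) vifs["group", 1L] else {
    vifs[grep("^group", names(vifs))][1L]
  })
  structure(list(
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1L],
                              se = cf[, 2L], t = cf[, 3L], p = cf[, 4L],
                              row.names = NULL, stringsAsFactors = FALSE),
    vif_group = vif_group, n = nrow(d), model = m),
    class = "group_regression")
}

#' @export
print.group_regression <- function(x, ...) {
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("group VIF = %.3f (n = %d)\n", x$vif_group, x$n))
  invisible(x)
}

#' Switching model with a per-subject covariate x severity interaction
#'
#' Random-intercept logistic regression of switching on the previous
#' outcome interacting with a per-subject scalar covariate (e.g. an ROI
#' beta value) and a severity measure (diagnosis or symptom score), plus
#' outcomes at lags 2 and 3 and all lower-order terms. A likelihood-ratio
#' test compares this against the model without any severity terms.
#'
#' @param cohort_tables Trial data (single condition).
#' @param covariate Data frame `subject_id`, `covariate` (or named vector).
#' @param severity Data frame `subject_id`, `severity` (or named vector).
#' @param alpha Significance threshold for the `significant` flag
#'   (default 0.006, a Bonferroni-style correction level).
#' @return List: `chisq`, `df`, `p`, `significant`, `models`.
#' @export
covariate_interaction_switch_model <- function(cohort_tables, covariate,
                                               severity, alpha = 0.006) {
  df <- as_cohort_df(cohort_tables)
  as_lookup <- function(x, what) {
    if (is.data.frame(x)) {
      stats::setNames(x[[2L]], x$subject_id)
    } else if (!is.null(names(x))) x
    else stop(what, " must be a data frame or named vector", call. = FALSE)
  }
  cov <- as_lookup(covariate, "covariate")
  sev <- as_lookup(severity, "severity")
  d <- switch_design(df, n_lags = 3L)
  ids <- unique(d$subject_id)
  if (!all(ids %in% names(cov))) {
    stop("covariate missing for subject(s): ",
         paste(setdiff(ids, names(cov)), collapse = ", "), call. = FALSE)
  }
  if (!all(ids %in% names(sev))) {
    stop("severity missing for subject(s): ",
         paste(setdiff(ids, names(sev)), collapse = ", "), call. = FALSE)
  }
  d$covariate <- as.numeric(cov[d$subject_id])
  d$severity <- as.numeric(sev[d$subject_id])
  if (stats::sd(d$severity) < 1e-12) {
    stop("severity is constant across subjects; interaction model ill-posed",
         call. = FALSE)
  }
  full <- lme4::glmer(switch ~ out1 * covariate * severity + out2 + out3 +
                        (1 | subject_id), data = d,
                      family = stats::binomial)
  reduced <- lme4::glmer(switch ~ out1 * covariate + out2 + out3 +
                           (1 | subject_id), data = d,
                         family = stats::binomial)
  lrt <- stats::anova(reduced, full)
  chisq <- lrt$Chisq[2L]
  dof <- lrt$Df[2L]
  p <- lrt$`Pr(>Chisq)`[2L]
  list(chisq = chisq, df = dof, p = p, significant = p < alpha,
       alpha = alpha, models = list(reduced = reduced, full = full))
}
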