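# Synthetic cohort generation.
#
# Emulates the study's structure: two groups (39 PTSD-like, 29 control)
# playing the adaptive loss/gain task, with per-subject learning parameters
# drawn from group distributions (Gaussian on scaled-logit transforms,
# respecting the parameter boxes), a higher mean associability weight in
# the PTSD-like group during loss learning and eta = 0 (basic model) in the
# gain condition, reaction times positively coupled to the chosen cue's
# associability, subject-level covariates, and a planted fraction of
# low-switching subjects to exercise the exclusion filter.

#' Group specification for synthetic cohorts
#'
#' Parameter distributions are Gaussian on each parameter's scaled-logit
#' transform (so samples respect the boxes in [param_bounds()]); means are
#' given on the natural scale, spreads on the transformed scale.
#'
#' @param label Group label (becomes the `group` column).
#' @param n_subjects Number of subjects.
#' @param eta_mean_loss,eta_sd Mean (natural scale) and transformed-scale SD
#'   of the loss-condition associability weight. The gain condition is
#'   generated from the basic model (`eta = 0`).
#' @param eta_range_loss Optional length-2 vector: draw the loss eta
#'   uniformly on this range instead of the logit-normal (used for
#'   recovery-style cohorts).
#' @param alpha_mean,alpha_sd,rho_mean,rho_sd,gamma_mean,gamma_sd,beta_mean,beta_sd
#'   Remaining parameter distributions (same convention); `beta_mean` is the
#'   loss-condition inverse temperature.
#' @param beta_mean_gain Mean gain-condition inverse temperature. Gain
#'   choices are less value-deterministic than loss choices (gain sessions
#'   produce the study's characteristic low switch rates), so the gain
#'   default is lower.
#' @param rt_model Reaction-time coefficients (seconds):
#'   `intercept + kappa * kappa_chosen + q * Q_chosen + trial *
#'   trial_overall + N(0, sd)`, truncated to (0.1, 6) s.
#' @param covariates List of covariate generators: `depression_mean/sd`,
#'   `exposure_mean/sd`, `age_mean/sd`, `p_male`.
#' @param low_switcher_fraction Fraction of subjects generated as
#'   near-non-switchers (perseveration 0.97).
#' @return List of class `group_spec`.
#' @export
group_spec <- function(label, n_subjects,
                       eta_mean_loss = 0.25, eta_sd = 0.4,
                       eta_range_loss = NULL,
                       alpha_mean = 0.50, alpha_sd = 0.4,
                       rho_mean = 1.0, rho_sd = 0.3,
                       gamma_mean = 0.90, gamma_sd = 0.4,
                       beta_mean = 10.0, beta_sd = 0.3,
                       beta_mean_gain = 6.0,
                       rt_model = list(intercept = 0.9, kappa = 0.232,
                                       q = -0.08, trial = -0.002, sd = 0.35),
                       covariates = list(depression_mean = 8,
                                         depression_sd = 6,
                                         exposure_mean = 16, exposure_sd = 8,
                                         age_mean = 38, age_sd = 9,
                                         p_male = 0.9),
                       low_switcher_fraction = 0) {
  stopifnot(n_subjects >= 1, low_switcher_fraction >= 0,
            low_switcher_fraction < 1)
  structure(as.list(environment()), class = "group_spec")
}

#' Default two-group study specification
#'
#' 39 PTSD-like and 29 control subjects; the PTSD-like group has a higher
#' mean loss-condition associability weight (0.70 vs 0.25) and equal mean
#' learning rate, moderately higher depression and exposure scores (group
#' collinearity with the covariates kept near the study's reported variance
#' inflation, VIF about 1.5), and a planted fraction of low-switching
#' subjects in both groups.
#'
#' @param low_switcher_fraction Fraction of planted near-non-switchers
#'   (default 0.05).
#' @return List of two `group_spec`s.
#' @export
default_study_spec <- function(low_switcher_fraction = 0.05) {
  list(
    ptsd = group_spec("ptsd", 39L, eta_mean_loss = 0.70,
                      covariates = list(depression_mean = 20,
                                        depression_sd = 10,
                                        exposure_mean = 24, exposure_sd = 8,
                                        age_mean = 38, age_sd = 9,
                                        p_male = 0.9),
                      low_switcher_fraction = low_switcher_fraction),
    control = group_spec("control", 29L, eta_mean_loss = 0.25,
                         covariates = list(depression_mean = 10,
                                           depression_sd = 6,
                                           exposure_mean = 18,
                                           exposure_sd = 8,
                                           age_mean = 38, age_sd = 9,
                                           p_male = 0.9),
                         low_switcher_fraction = low_switcher_fraction)
  )
}

draw_bounded <- function(n, mean_natural, sd_trans, bounds) {
  mu <- to_unconstrained(mean_natural, bounds[1], bounds[2])
  from_unconstrained(stats::rnorm(n, mu, sd_trans), bounds[1], bounds[2])
}

#' Sample per-subject true parameters and covariates
#'
#' @param group_specs List of [group_spec()]s.
#' @param seed Optional integer seed.
#' @return List: `params` (one row per subject x condition: the generating
#'   parameters, variant, `low_switcher` flag), `covariates` (one row per
#'   subject: group, depression, exposure, age, gender).
#' @export
sample_cohort <- function(group_specs = default_study_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(group_specs, "group_spec")) group_specs <- list(group_specs)
  prows <- list()
  crows <- list()
  counter <- 0L
  for (gs in group_specs) {
    for (i in seq_len(gs$n_subjects)) {
      counter <- counter + 1L
      id <- sprintf("S%03d", counter)
      alpha <- draw_bounded(1, gs$alpha_mean, gs$alpha_sd,
                            .PARAM_BOUNDS$alpha)
      if (!is.null(gs$eta_range_loss)) {
        eta <- stats::runif(1, gs$eta_range_loss[1], gs$eta_range_loss[2])
      } else {
        eta <- draw_bounded(1, gs$eta_mean_loss, gs$eta_sd,
                            .PARAM_BOUNDS$eta)
      }
      rho <- draw_bounded(1, gs$rho_mean, gs$rho_sd, .PARAM_BOUNDS$rho)
      gamma <- draw_bounded(1, gs$gamma_mean, gs$gamma_sd,
                            .PARAM_BOUNDS$gamma)
      beta <- draw_bounded(1, gs$beta_mean, gs$beta_sd, .PARAM_BOUNDS$beta)
      beta_g <- draw_bounded(1, gs$beta_mean_gain, gs$beta_sd,
                             .PARAM_BOUNDS$beta)
      low <- stats::runif(1) < gs$low_switcher_fraction
      prows[[length(prows) + 1L]] <- data.frame(
        subject_id = id, group = gs$label,
        condition = c("loss", "gain"),
        variant = c("associability", "basic"),
        alpha = alpha, eta = c(eta, 0), rho = rho, gamma = gamma,
        beta = c(beta, beta_g), low_switcher = low,
        stringsAsFactors = FALSE)
      cv <- gs$covariates
      crows[[length(crows) + 1L]] <- data.frame(
        subject_id = id, group = gs$label,
        depression = max(0, stats::rnorm(1, cv$depression_mean,
                                         cv$depression_sd)),
        exposure = max(0, stats::rnorm(1, cv$exposure_mean,
                                       cv$exposure_sd)),
        age = min(64, max(22, stats::rnorm(1, cv$age_mean, cv$age_sd))),
        gender = if (stats::runif(1) < cv$p_male) "M" else "F",
        stringsAsFactors = FALSE)
    }
  }
  prms <- do.call(rbind, prows)
  rownames(prms) <- NULL
  list(params = prms, covariates = do.call(rbind, crows),
       rt_models = stats::setNames(
         lapply(group_specs, `[[`, "rt_model"),
         vapply(group_specs, `[[`, character(1), "label")))
}

#' Generate a full synthetic cohort
#'
#' Simulates every subject's adaptive task session from their true
#' parameters (associability model in loss, basic model in gain unless the
#' sampled `variant` says otherwise), attaching reaction times coupled to
#' the chosen cue's associability and applying the planted perseveration to
#' low-switching subjects.
#'
#' @param truth Output of [sample_cohort()] (or a compatible list with
#'   `params`, `covariates`, `rt_models`).
#' @param config A [session_config()] (its `conditions` decide whether
#'   sessions contain both conditions or one).
#' @param seed Optional integer seed.
#' @param perseveration Perseveration probability for planted low
#'   switchers.
#' @return List of class `cohort_bundle`: `trials` (long trial table with
#'   latents and `rt`), `true_params`, `covariates`, `seed`.
#' @export
generate_cohort <- function(truth, config = session_config(), seed = NULL,
                            perseveration = 0.97) {
  if (!is.null(seed)) set.seed(seed)
  params <- truth$params
  ids <- unique(params$subject_id)
  tabs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    pr <- params[params$subject_id == id, , drop = FALSE]
    group <- pr$group[1L]
    plist <- list()
    for (j in seq_len(nrow(pr))) {
      if (!pr$condition[j] %in% config$conditions) next
      plist[[pr$condition[j]]] <- model_params(
        alpha = pr$alpha[j], beta = pr$beta[j], eta = pr$eta[j],
        rho = pr$rho[j], gamma = pr$gamma[j],
        variant = pr$variant[j], condition = pr$condition[j])
    }
    rt_model <- truth$rt_models[[group]] %||% truth$rt_models[[1L]]
    tab <- simulate_subject(
      plist, config = config, mode = "task",
      perseveration = if (pr$low_switcher[1L]) perseveration else 0,
      rt_model = rt_model)
    tab$subject_id <- id
    tab$group <- group
    tabs[[i]] <- tab
  }
  trials <- do.call(rbind, tabs)
  front <- c("subject_id", "group")
  trials <- trials[, c(front, setdiff(names(trials), front))]
  structure(list(trials = trials, true_params = params,
                 covariates = truth$covariates, seed = seed),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d subjects, %d trials (%s)\n",
              length(unique(x$trials$subject_id)), nrow(x$trials),
              paste(unique(x$trials$condition), collapse = "/")))
  invisible(x)
}

#' One-call synthetic cohort
#'
#' Convenience wrapper: sample true parameters and generate the trials in
#' one seeded step.
#'
#' @inheritParams sample_cohort
#' @inheritParams generate_cohort
#' @return A `cohort_bundle`.
#' @export
make_cohort <- function(group_specs = default_study_spec(),
                        config = session_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- sample_cohort(group_specs)
  generate_cohort(truth, config = config)
}
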