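# Per-subject maximum-likelihood estimation.
#
# Parameters are optimized on an unconstrained (scaled-logit) scale with
# multi-start quasi-Newton search. The study's two-stage procedure handles
# the weak joint identifiability of inverse temperature and reward
# sensitivity: beta is first estimated with rho fixed at 1, then every
# subject is refit with beta fixed at the stage-1 group mean and rho free.

#' Fitting configuration
#'
#' @param n_starts Number of random optimizer starts (default 20).
#' @param tol Relative convergence tolerance on the objective.
#' @param start_range Starts are drawn uniformly on
#'   `[-start_range, start_range]` per free parameter on the unconstrained
#'   (scaled-logit) scale; 2.5 covers roughly the central 85% of each box.
#' @param seed Seed for the start-point stream (per-subject streams are
#'   derived from it, so cohort fits are reproducible).
#'
#' @return List of class `fit_config`.
#' @export
fit_config <- function(n_starts = 20L, tol = 1e-6, start_range = 2.5,
                       seed = 101L) {
  stopifnot(n_starts >= 1, tol > 0, start_range > 0)
  structure(list(n_starts = as.integer(n_starts), tol = tol,
                 start_range = start_range, seed = as.integer(seed)),
            class = "fit_config")
}

free_param_names <- function(variant, fixed) {
  nms <- c("alpha", "eta", "rho", "gamma", "beta")
  if (variant == "basic") nms <- setdiff(nms, "eta")
  setdiff(nms, names(fixed))
}

params_from_vector <- function(x, free, fixed, variant, condition, rho_all) {
  vals <- list(alpha = NA_real_, eta = 0, rho = 1, gamma = 1,
               beta = NA_real_)
  for (nm in free) {
    b <- .PARAM_BOUNDS[[nm]]
    # clamp the search space so back-transformed values stay inside the
    # open box (plogis underflows to an exact bound beyond ~ +-37)
    vals[[nm]] <- from_unconstrained(min(max(x[[nm]], -30), 30), b[1], b[2])
  }
  for (nm in names(fixed)) vals[[nm]] <- fixed[[nm]]
  model_params(alpha = vals$alpha, beta = vals$beta, eta = vals$eta,
               rho = vals$rho, gamma = vals$gamma, variant = variant,
               condition = condition, rho_all = rho_all)
}

#' Fit one subject's choices by maximum likelihood
#'
#' Minimizes the negative log-likelihood over the free parameters via
#' multi-start bounded optimization (scaled-logit transform +
#' `stats::nlminb`). Any parameter may be held fixed at a supplied value.
#'
#' @param trial_table Single-subject, single-condition trial table (at
#'   least 20 trials).
#' @param variant `"basic"` or `"associability"`.
#' @param config A [fit_config()].
#' @param fixed Named list of parameters to hold fixed (e.g.
#'   `list(beta = 5.1)`).
#' @param rho_all Passed to [model_params()].
#' @return List of class `fit_result`: `subject_id`, `condition`,
#'   `variant`, `estimates` (a `model_params`), `nll`, `n_trials`,
#'   `k_free`, `converged`, `n_starts`, `best_start`, `start_nlls`.
#' @export
fit_subject <- function(trial_table, variant = c("basic", "associability"),
                        config = fit_config(), fixed = list(),
                        rho_all = FALSE) {
  variant <- match.arg(variant)
  prep <- prepare_trials(trial_table)
  n <- nrow(prep$table)
  if (n < 20L) {
    stop("fewer than 20 trials; refusing to fit", call. = FALSE)
  }
  condition <- prep$table$condition[1L]
  subject_id <- if ("subject_id" %in% names(prep$table)) {
    prep$table$subject_id[1L]
  } else NA_character_
  free <- free_param_names(variant, fixed)
  if (!length(free)) stop("no free parameters to fit", call. = FALSE)

  objective <- function(x) {
    names(x) <- free
    nll <- tryCatch({
      p <- params_from_vector(as.list(x), free, fixed, variant, condition,
                              rho_all)
      rl_forward(p, prep, want_trace = FALSE)$nll
    }, error = function(e) Inf)
    if (!is.finite(nll)) 1e10 else nll
  }

  starts <- with_local_seed(config$seed, {
    matrix(stats::runif(config$n_starts * length(free),
                        -config$start_range, config$start_range),
           nrow = config$n_starts)
  })

  best <- NULL
  start_nlls <- rep(NA_real_, config$n_starts)
  best_start <- NA_integer_
  for (s in seq_len(config$n_starts)) {
    res <- tryCatch(
      stats::nlminb(starts[s, ], objective,
                    control = list(rel.tol = config$tol, iter.max = 500L)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    start_nlls[s] <- res$objective
    if (is.null(best) || res$objective < best$objective) {
      best <- res
      best_start <- s
    }
  }
  if (is.null(best)) {
    return(structure(list(
      subject_id = subject_id, condition = condition, variant = variant,
      estimates = NULL, nll = NA_real_, n_trials = n,
      k_free = length(free), converged = FALSE,
      n_starts = config$n_starts, best_start = NA_integer_,
      start_nlls = start_nlls), class = "fit_result"))
  }
  est <- params_from_vector(stats::setNames(as.list(best$par), free),
                            free, fixed, variant, condition, rho_all)
  structure(list(
    subject_id = subject_id, condition = condition, variant = variant,
    estimates = est, nll = best$objective, n_trials = n,
    k_free = length(free), converged = best$convergence == 0L,
    n_starts = config$n_starts, best_start = best_start,
    start_nlls = start_nlls), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s %s %s> nll=%.3f k=%d n=%d converged=%s\n",
              x$subject_id %||% "?", x$condition, x$variant, x$nll,
              x$k_free, x$n_trials, x$converged))
  invisible(x)
}

split_cohort <- function(cohort_tables) {
  if (is.data.frame(cohort_tables)) {
    if (!"subject_id" %in% names(cohort_tables)) {
      stop("cohort data frame needs a subject_id column", call. = FALSE)
    }
    split(cohort_tables, cohort_tables$subject_id)
  } else {
    cohort_tables
  }
}

#' Two-stage cohort fit with fixed inverse temperature
#'
#' Stage 1 fits every subject with reward sensitivity fixed at 1 and beta
#' free; stage 2 refits each subject with beta fixed at the stage-1 group
#' mean and rho free. Stage-2 `k_free` excludes beta. Per-subject failures
#' are collected, not propagated.
#'
#' @param cohort_tables Either a named list of per-subject
#'   single-condition trial tables, or one long data frame with a
#'   `subject_id` column.
#' @param variant `"basic"` or `"associability"` (used for both stages).
#' @param config A [fit_config()].
#' @param rho_all Passed through to the likelihood.
#' @return List of class `two_stage_fit`: `fits` (named list of stage-2
#'   `fit_result`s), `group_mean_beta`, `stage1`, `variant`, `failures`
#'   (character vector of subject ids).
#' @export
two_stage_fit <- function(cohort_tables,
                          variant = c("basic", "associability"),
                          config = fit_config(), rho_all = FALSE) {
  variant <- match.arg(variant)
  tabs <- split_cohort(cohort_tables)
  if (length(tabs) < 2L) {
    stop("two-stage fitting needs at least 2 subjects (group mean beta)",
         call. = FALSE)
  }
  ids <- names(tabs) %||% as.character(seq_along(tabs))

  subj_config <- function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    cfg
  }
  run_stage <- function(fixed) {
    res <- vector("list", length(tabs))
    for (i in seq_along(tabs)) {
      res[[i]] <- tryCatch(
        fit_subject(tabs[[i]], variant, subj_config(i), fixed = fixed,
                    rho_all = rho_all),
        error = function(e) e)
    }
    stats::setNames(res, ids)
  }

  stage1 <- run_stage(fixed = list(rho = 1))
  ok1 <- vapply(stage1, function(f) inherits(f, "fit_result") &&
                  !is.null(f$estimates), logical(1))
  if (!any(ok1)) stop("all stage-1 fits failed", call. = FALSE)
  betas <- vapply(stage1[ok1], function(f) f$estimates$beta, numeric(1))
  group_mean_beta <- mean(betas)

  stage2 <- run_stage(fixed = list(beta = group_mean_beta))
  ok2 <- vapply(stage2, function(f) inherits(f, "fit_result") &&
                  !is.null(f$estimates), logical(1))
  structure(list(
    fits = stage2[ok2],
    group_mean_beta = group_mean_beta,
    stage1 = stage1,
    variant = variant,
    failures = ids[!ok2]), class = "two_stage_fit")
}

#' @export
print.two_stage_fit <- function(x, ...) {
  cat(sprintf(
    "<two_stage_fit: %s> %d subjects, group mean beta = %.3f (%d failed)\n",
    x$variant, length(x$fits), x$group_mean_beta, length(x$failures)))
  invisible(x)
}

#' Tabulate fit results
#'
#' @param fits A `two_stage_fit`, or a list of `fit_result`s.
#' @return Data frame with one row per subject: `subject_id`, `condition`,
#'   `variant`, the five parameter estimates, `beta_fixed`, `nll`, `aicc`,
#'   `n_trials`, `converged`.
#' @export
fits_table <- function(fits) {
  beta_fixed <- FALSE
  if (inherits(fits, "two_stage_fit")) {
    beta_fixed <- TRUE
    fits <- fits$fits
  }
  if (inherits(fits, "fit_result")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    e <- f$estimates
    data.frame(subject_id = as.character(f$subject_id %||% NA),
               condition = f$condition, variant = f$variant,
               alpha = e$alpha, eta = e$eta, rho = e$rho, gamma = e$gamma,
               beta = e$beta, beta_fixed = beta_fixed, nll = f$nll,
               aicc = aicc(f$nll, f$k_free, f$n_trials),
               n_trials = f$n_trials, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
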