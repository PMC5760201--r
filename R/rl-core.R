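# Value-learning models for the bandit task.
#
# Basic model: delta-rule update of the chosen option's expected value Q
# with static learning rate alpha, decay gamma of the unchosen option, and
# reward sensitivity rho scaling the large-magnitude outcome. Hybrid model:
# the learning rate is additionally gated trial-by-trial by the chosen
# stimulus's associability kappa, itself updated from unsigned prediction
# errors with static weight eta. Choices follow a softmax with inverse
# temperature beta. Q and kappa reset to 0 and 1 at every block start
# (novel stimuli); kappa is floored at 0.05.

#' Model parameters for the bandit learning models
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param beta Softmax inverse temperature in \[0, 20\] (per dollar).
#' @param eta Associability weight in \[0, 1\]; ignored when
#'   `variant = "basic"`.
#' @param rho Reward sensitivity in (0, 3\]: multiplier on the block's
#'   large-magnitude outcome (the loss or gain further from zero) before
#'   value updating. With `rho_all = TRUE` it multiplies every outcome.
#' @param gamma Decay of the unchosen option's value in \[0, 1\].
#' @param variant `"basic"` or `"associability"`.
#' @param condition Optional condition label (`"loss"`/`"gain"`).
#' @param rho_all Apply `rho` to both outcome magnitudes rather than the
#'   large one only (default `FALSE`, following the model's definition of
#'   sensitivity to the outcome further from zero).
#'
#' @return A list of class `model_params`.
#' @export
model_params <- function(alpha, beta, eta = 0, rho = 1, gamma = 1,
                         variant = c("basic", "associability"),
                         condition = NA_character_, rho_all = FALSE) {
  variant <- match.arg(variant)
  vals <- list(alpha = alpha, eta = eta, rho = rho, gamma = gamma,
               beta = beta)
  for (nm in names(vals)) {
    b <- .PARAM_BOUNDS[[nm]]
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v < b[1] || v > b[2]) {
      stop(sprintf("%s must be a finite scalar in [%g, %g]", nm, b[1], b[2]),
           call. = FALSE)
    }
  }
  if (rho <= 0) stop("rho must be strictly positive", call. = FALSE)
  structure(c(vals, list(variant = variant, condition = condition,
                         rho_all = isTRUE(rho_all))),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params: %s%s>\n", x$variant,
              if (is.na(x$condition)) "" else paste0(", ", x$condition)))
  cat(sprintf("  alpha=%.3f eta=%.3f rho=%.3f gamma=%.3f beta=%.3f\n",
              x$alpha, x$eta, x$rho, x$gamma, x$beta))
  invisible(x)
}

#' Reward-sensitivity scaling of an outcome
#'
#' Returns `rho * outcome` when `|outcome|` equals the block pair's large
#' magnitude, and the outcome unchanged otherwise; with `rho_all = TRUE`
#' the multiplier applies unconditionally.
#'
#' @param outcome Signed outcome (one of the block's two magnitudes).
#' @param rho Reward sensitivity.
#' @param outcome_pair Length-2 numeric `c(small, large)` magnitudes.
#' @param rho_all Scale both magnitudes.
#' @return Scaled outcome.
#' @export
scale_outcome <- function(outcome, rho, outcome_pair, rho_all = FALSE) {
  pair <- round(sort(as.numeric(outcome_pair)), 6)
  mag <- round(abs(outcome), 6)
  if (!all(mag %in% pair)) {
    stop("outcome magnitude not in the block's outcome pair", call. = FALSE)
  }
  if (rho_all) return(rho * outcome)
  ifelse(mag == pair[2], rho * outcome, outcome)
}

#' Fresh learner state at a block start
#'
#' Expected values start at 0 and associability values at 1 for both
#' stimuli.
#'
#' @return List with numeric vectors `Q` and `kappa`, named `A`/`B`.
#' @export
learner_state <- function() {
  list(Q = c(A = 0, B = 0), kappa = c(A = 1, B = 1))
}

#' One learning update
#'
#' Computes the prediction error `delta = scaled_outcome - Q[chosen]` and
#' updates the state: the chosen option's value moves by `alpha * delta`
#' (basic) or `alpha * kappa[chosen] * delta` (associability variant, using
#' the pre-update kappa), the chosen option's associability becomes
#' `max(0.05, (1 - eta) * kappa + eta * |delta|)` (associability variant
#' only), and the unchosen option's value decays by `gamma`. The unchosen
#' option's associability is unchanged.
#'
#' @param state A learner state (see [learner_state()]).
#' @param chosen,unchosen `"A"`/`"B"`, the chosen and unchosen options.
#' @param scaled_outcome Outcome after reward-sensitivity scaling.
#' @param params A `model_params`.
#' @return List with `state` (updated) and `latents` (pre-update
#'   `Q_chosen`, `Q_unchosen`, `kappa_chosen`, plus `delta` and
#'   `scaled_outcome`).
#' @export
learner_update <- function(state, chosen, unchosen, scaled_outcome, params) {
  stopifnot(chosen %in% c("A", "B"), unchosen %in% c("A", "B"),
            chosen != unchosen)
  q_c <- state$Q[[chosen]]
  q_u <- state$Q[[unchosen]]
  k_c <- state$kappa[[chosen]]
  delta <- scaled_outcome - q_c
  if (params$variant == "associability") {
    state$Q[[chosen]] <- q_c + params$alpha * k_c * delta
    state$kappa[[chosen]] <-
      max(0.05, (1 - params$eta) * k_c + params$eta * abs(delta))
  } else {
    state$Q[[chosen]] <- q_c + params$alpha * delta
  }
  state$Q[[unchosen]] <- params$gamma * q_u
  list(state = state,
       latents = list(Q_chosen = q_c, Q_unchosen = q_u, kappa_chosen = k_c,
                      delta = delta, scaled_outcome = scaled_outcome))
}

#' Softmax choice probability
#'
#' `P(A) = exp(beta * Q_A) / (exp(beta * Q_A) + exp(beta * Q_B))`,
#' computed stably for large `beta * |Q|`.
#'
#' @param Q_A,Q_B Expected values of the two options.
#' @param beta Inverse temperature (>= 0).
#' @return Probability of choosing A.
#' @export
choice_prob <- function(Q_A, Q_B, beta) {
  stopifnot(beta >= 0)
  stats::plogis(beta * (Q_A - Q_B))
}

# Validate and order a single-condition trial table; derive the per-trial
# quantities the C++ recursion needs. Returns a list of aligned vectors.
prepare_trials <- function(trial_table) {
  req <- c("condition", "block", "trial_in_block", "chosen", "outcome")
  miss <- setdiff(req, names(trial_table))
  if (nrow(trial_table) == 0L) stop("empty trial table", call. = FALSE)
  if (length(miss)) {
    stop("trial table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(trial_table$condition)) != 1L) {
    stop("trial table must contain a single condition", call. = FALSE)
  }
  tt <- trial_table[order(trial_table$block, trial_table$trial_in_block), ,
                    drop = FALSE]
  chosen <- match(tt$chosen, c("A", "B"))
  if (anyNA(chosen)) stop("chosen must be 'A' or 'B'", call. = FALSE)
  new_block <- c(TRUE, tt$block[-1L] != tt$block[-nrow(tt)])

  if (all(c("mag_small", "mag_large") %in% names(tt))) {
    mag_large <- tt$mag_large
  } else {
    mag_large <- numeric(nrow(tt))
    for (b in unique(tt$block)) {
      idx <- tt$block == b
      pair <- infer_outcome_pair(abs(tt$outcome[idx]))
      mag_large[idx] <- pair["large"]
    }
  }
  is_large <- as.integer(round(abs(tt$outcome), 6) == round(mag_large, 6))
  list(table = tt, chosen = chosen, outcome = as.numeric(tt$outcome),
       is_large = is_large, new_block = as.integer(new_block))
}

rl_forward <- function(params, prep, want_trace) {
  cpp_rl_forward(prep$chosen, prep$outcome, prep$is_large, prep$new_block,
                 params$alpha, params$eta, params$rho, params$gamma,
                 params$beta,
                 as.integer(params$variant == "associability"),
                 as.integer(isTRUE(params$rho_all)),
                 as.integer(want_trace))
}

#' Negative log-likelihood of observed choices
#'
#' Runs the model's forward recursion over a single-subject,
#' single-condition trial table (state resetting at every block start) and
#' returns `-sum(log P(chosen_t))` under the softmax choice rule.
#'
#' @param params A `model_params`.
#' @param trial_table Ordered single-condition trial table with columns
#'   `condition`, `block`, `trial_in_block`, `chosen`, `outcome` (and
#'   optionally `mag_small`/`mag_large`; otherwise the block's magnitude
#'   pair is inferred from the observed outcomes).
#' @return Nonnegative scalar.
#' @export
neg_log_likelihood <- function(params, trial_table) {
  prep <- prepare_trials(trial_table)
  rl_forward(params, prep, want_trace = FALSE)$nll
}

#' Trial-by-trial latent trace
#'
#' Returns the trial table with the model's latent quantities at the
#' outcome event of each trial, prior to that trial's updates: `Q_chosen`,
#' `Q_unchosen`, `kappa_chosen`, prediction error `delta`, softmax
#' `p_chosen`, and the sensitivity-scaled outcome.
#'
#' @inheritParams neg_log_likelihood
#' @return Data frame: the (ordered) trial table plus latent columns, with
#'   attribute `"nll"`.
#' @export
latent_trace <- function(params, trial_table) {
  prep <- prepare_trials(trial_table)
  res <- rl_forward(params, prep, want_trace = TRUE)
  out <- prep$table
  for (nm in c("Q_chosen", "Q_unchosen", "kappa_chosen", "delta",
               "p_chosen", "scaled_outcome")) {
    out[[nm]] <- res[[nm]]
  }
  attr(out, "nll") <- res$nll
  out
}

# Inner simulation of one block given a live learner; returns rows +
# updated counters. Used by simulate_subject for both adaptive and
# fixed-length blocks.
simulate_block <- function(params, block, n_fixed = NULL, config = NULL,
                           is_first_block = FALSE, trial_offset = 0L,
                           perseveration = 0) {
  cap <- n_fixed %||% config$max_block_trials
  chosen <- character(cap)
  outcome <- numeric(cap)
  correct <- logical(cap)
  q_c <- q_u <- k_c <- delta <- p_ch <- r_scaled <- numeric(cap)
  Q <- c(A = 0, B = 0)
  K <- c(A = 1, B = 1)
  assoc <- params$variant == "associability"
  rho_sign <- if (block$condition == "loss") -1 else 1
  mag_better <- if (block$condition == "loss") block$mag_small else {
    block$mag_large
  }
  mag_worse <- if (block$condition == "loss") block$mag_large else {
    block$mag_small
  }
  nr <- 0L
  repeat {
    t_in <- nr + 1L
    p_A <- stats::plogis(params$beta * (Q[["A"]] - Q[["B"]]))
    ch <- if (perseveration > 0 && t_in > 1L &&
              stats::runif(1L) < perseveration) {
      chosen[t_in - 1L]
    } else if (stats::runif(1L) < p_A) "A" else "B"
    un <- if (ch == "A") "B" else "A"
    p_better <- if (ch == block$better_option) 0.75 else 0.25
    got_better <- stats::runif(1L) < p_better
    out <- rho_sign * if (got_better) mag_better else mag_worse
    rp <- if (abs(out) == block$mag_large || params$rho_all) {
      params$rho * out
    } else out
    nr <- nr + 1L
    chosen[nr] <- ch
    outcome[nr] <- out
    correct[nr] <- ch == block$better_option
    q_c[nr] <- Q[[ch]]
    q_u[nr] <- Q[[un]]
    k_c[nr] <- K[[ch]]
    d <- rp - Q[[ch]]
    delta[nr] <- d
    p_ch[nr] <- if (ch == "A") p_A else 1 - p_A
    r_scaled[nr] <- rp
    if (assoc) {
      Q[[ch]] <- Q[[ch]] + params$alpha * K[[ch]] * d
      K[[ch]] <- max(0.05, (1 - params$eta) * K[[ch]] + params$eta * abs(d))
    } else {
      Q[[ch]] <- Q[[ch]] + params$alpha * d
    }
    Q[[un]] <- params$gamma * Q[[un]]
    if (!is.null(n_fixed)) {
      if (nr >= n_fixed) break
    } else if (should_end_block(correct[seq_len(nr)], is_first_block,
                                config) ||
               nr >= config$max_block_trials) {
      break
    }
  }
  idx <- seq_len(nr)
  data.frame(
    condition = block$condition, block = block$block_index,
    trial_in_block = idx, trial_overall = trial_offset + idx,
    chosen = chosen[idx], outcome = outcome[idx], correct = correct[idx],
    switch = c(NA, chosen[idx][-1L] != chosen[idx][-nr]),
    mag_small = block$mag_small, mag_large = block$mag_large,
    better_option = block$better_option,
    Q_chosen = q_c[idx], Q_unchosen = q_u[idx], kappa_chosen = k_c[idx],
    delta = delta[idx], p_chosen = p_ch[idx],
    scaled_outcome = r_scaled[idx], stringsAsFactors = FALSE)
}

#' Simulate a subject playing the task under a learning model
#'
#' Choices are sampled from the softmax over the model's running expected
#' values; outcomes come from the task environment. In `"task"` mode the
#' session uses the adaptive block/session termination rules; in `"sim"`
#' mode blocks have fixed length (`sim_blocks` x `sim_trials` blocks of the
#' single configured condition), as used for parameter sweeps.
#'
#' @param params_by_condition Named list of `model_params`, one entry per
#'   condition appearing in the session (`loss`, `gain`).
#' @param config A [session_config()].
#' @param mode `"task"` (adaptive) or `"sim"` (fixed-length blocks).
#' @param sim_blocks,sim_trials Number and length of fixed blocks in
#'   `"sim"` mode.
#' @param perseveration Probability of repeating the previous choice
#'   regardless of value, used to generate low-switching subjects
#'   (default 0).
#' @param rt_model Optional list `(intercept, kappa, q, trial, sd)` of
#'   reaction-time coefficients (seconds): RT = intercept + kappa *
#'   kappa_chosen + q * Q_chosen + trial * trial_overall + Gaussian noise,
#'   truncated to (0.1, 6) s. `NULL` leaves `rt` as `NA`.
#' @param seed Optional integer seed.
#' @return Trial table with latent columns (`Q_chosen`, `Q_unchosen`,
#'   `kappa_chosen`, `delta`, `p_chosen`, `scaled_outcome`) and `rt`.
#' @export
simulate_subject <- function(params_by_condition, config = session_config(),
                             mode = c("task", "sim"), sim_blocks = 2L,
                             sim_trials = 25L, perseveration = 0,
                             rt_model = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(params_by_condition, "model_params")) {
    params_by_condition <-
      stats::setNames(list(params_by_condition), config$conditions[1L])
  }

  rows <- list()
  trial_offset <- 0L
  if (mode == "sim") {
    cond <- config$conditions[1L]
    params <- params_by_condition[[cond]]
    if (is.null(params)) stop("no parameters for condition ", cond)
    for (b in seq_len(sim_blocks)) {
      block <- make_block(cond, b)
      tab <- simulate_block(params, block, n_fixed = sim_trials,
                            trial_offset = trial_offset,
                            perseveration = perseveration)
      trial_offset <- trial_offset + nrow(tab)
      rows[[b]] <- tab
    }
  } else {
    conds <- config$conditions
    start <- sample.int(length(conds), 1L)
    counts <- stats::setNames(
      replicate(length(conds), list(correct = 0L, incorrect = 0L),
                simplify = FALSE), conds)
    block_index <- 0L
    repeat {
      block_index <- block_index + 1L
      if (block_index > config$max_blocks) break
      cond <- conds[((start + block_index - 2L) %% length(conds)) + 1L]
      params <- params_by_condition[[cond]]
      if (is.null(params)) stop("no parameters for condition ", cond)
      block <- make_block(cond, block_index)
      tab <- simulate_block(params, block, config = config,
                            is_first_block = block_index == 1L,
                            trial_offset = trial_offset,
                            perseveration = perseveration)
      trial_offset <- trial_offset + nrow(tab)
      rows[[block_index]] <- tab
      counts[[cond]]$correct <- counts[[cond]]$correct + sum(tab$correct)
      counts[[cond]]$incorrect <-
        counts[[cond]]$incorrect + sum(!tab$correct)
      if (should_end_session(counts, config)) break
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(rt_model)) {
    rt <- rt_model$intercept + rt_model$kappa * out$kappa_chosen +
      rt_model$q * out$Q_chosen + rt_model$trial * out$trial_overall +
      stats::rnorm(nrow(out), 0, rt_model$sd)
    out$rt <- pmin(pmax(rt, 0.1), 6)
  } else {
    out$rt <- NA_real_
  }
  out
}
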