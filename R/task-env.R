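# Adaptive probabilistic loss/gain learning task (two-armed bandit).
#
# Sessions consist of alternating loss and gain blocks. Within a block, one
# of two novel stimuli leads to the better monetary outcome with probability
# 0.75 (the other with 0.25). Blocks end once running accuracy over the last
# 10 choices reaches 70% (first block at least 15 trials); the session ends,
# at a block boundary, once each condition has accrued at least 25 correct
# and 25 incorrect choices.

#' Session configuration for the adaptive bandit task
#'
#' @param termination_accuracy Running-accuracy threshold that ends a block
#'   (fraction, default 0.70).
#' @param running_window Number of most recent choices in the running
#'   average (default 10).
#' @param first_block_min Minimum length of the first block (default 15).
#' @param correct_min,incorrect_min Per-condition counts of correct and
#'   incorrect choices required before the session may end (default 25 each).
#' @param conditions Conditions cycled over blocks; `c("loss", "gain")` for
#'   the full task, a single condition for condition-only sessions.
#' @param max_block_trials Safety cap on block length so that non-learning
#'   choice policies cannot stall a block forever (default 60).
#' @param max_blocks Safety cap on the number of blocks per session.
#'
#' @return A list of class `session_config`.
#' @export
session_config <- function(termination_accuracy = 0.70,
                           running_window = 10L,
                           first_block_min = 15L,
                           correct_min = 25L,
                           incorrect_min = 25L,
                           conditions = c("loss", "gain"),
                           max_block_trials = 60L,
                           max_blocks = 40L) {
  stopifnot(termination_accuracy > 0, termination_accuracy < 1,
            running_window >= 1, first_block_min >= 1,
            correct_min >= 1, incorrect_min >= 1,
            max_block_trials >= running_window, max_blocks >= 1)
  conditions <- match.arg(conditions, c("loss", "gain"), several.ok = TRUE)
  structure(list(
    termination_accuracy = termination_accuracy,
    running_window = as.integer(running_window),
    first_block_min = as.integer(first_block_min),
    correct_min = as.integer(correct_min),
    incorrect_min = as.integer(incorrect_min),
    conditions = conditions,
    max_block_trials = as.integer(max_block_trials),
    max_blocks = as.integer(max_blocks)
  ), class = "session_config")
}

#' Create a task block
#'
#' Draws a block specification: the outcome-magnitude pair is sampled
#' uniformly from \{(0.20, 0.70), (0.25, 0.75), (0.30, 0.80)\} dollars, the
#' better option is assigned uniformly at random, and the block receives a
#' fresh pair of stimulus identifiers. Loss blocks sign outcomes negative;
#' in a loss block the "better" outcome is the smaller-magnitude loss.
#'
#' Uses the session RNG stream; seed upstream for reproducibility.
#'
#' @param condition `"loss"` or `"gain"`.
#' @param block_index Positive integer block counter within the session.
#' @return A list of class `block_spec` with fields `condition`,
#'   `block_index`, `better_option`, `mag_small`, `mag_large`,
#'   `stimulus_ids`.
#' @export
make_block <- function(condition, block_index) {
  condition <- match.arg(condition, c("loss", "gain"))
  stopifnot(is.numeric(block_index), block_index >= 1)
  pair <- .OUTCOME_PAIRS[sample.int(nrow(.OUTCOME_PAIRS), 1L), ]
  structure(list(
    condition = condition,
    block_index = as.integer(block_index),
    better_option = sample(c("A", "B"), 1L),
    mag_small = unname(pair["small"]),
    mag_large = unname(pair["large"]),
    stimulus_ids = paste0("blk", block_index, "_", c("s1", "s2"))
  ), class = "block_spec")
}

#' Sample the monetary outcome of one choice
#'
#' The better outcome occurs with probability 0.75 when the chosen option is
#' the block's better option and 0.25 otherwise. In gain blocks the better
#' outcome is `+mag_large`; in loss blocks it is `-mag_small` (the loss
#' closer to zero).
#'
#' @param block A `block_spec`.
#' @param chosen `"A"` or `"B"`.
#' @return Signed outcome in dollars.
#' @export
sample_outcome <- function(block, chosen) {
  chosen <- match.arg(chosen, c("A", "B"))
  p_better <- if (chosen == block$better_option) 0.75 else 0.25
  got_better <- stats::runif(1L) < p_better
  if (block$condition == "gain") {
    if (got_better) block$mag_large else block$mag_small
  } else {
    if (got_better) -block$mag_small else -block$mag_large
  }
}

#' Block termination rule
#'
#' A block ends once at least `running_window` choices have been made and
#' the mean of the last `running_window` correct/incorrect flags reaches
#' `termination_accuracy`; the first block must additionally be at least
#' `first_block_min` trials long.
#'
#' @param correct_history Logical vector of correct flags for the block so far.
#' @param is_first_block Is this the session's first block?
#' @param config A `session_config`.
#' @return Logical.
#' @export
should_end_block <- function(correct_history, is_first_block, config) {
  n <- length(correct_history)
  if (n < config$running_window) return(FALSE)
  if (is_first_block && n < config$first_block_min) return(FALSE)
  recent <- correct_history[(n - config$running_window + 1L):n]
  mean(recent) >= config$termination_accuracy
}

#' Session termination rule
#'
#' The session ends (evaluated at block boundaries) once every configured
#' condition has at least `correct_min` correct and `incorrect_min`
#' incorrect choices.
#'
#' @param counts Named list, one entry per condition, each with integer
#'   fields `correct` and `incorrect`.
#' @param config A `session_config`.
#' @return Logical.
#' @export
should_end_session <- function(counts, config) {
  all(vapply(config$conditions, function(cond) {
    cc <- counts[[cond]]
    !is.null(cc) && cc$correct >= config$correct_min &&
      cc$incorrect >= config$incorrect_min
  }, logical(1)))
}

#' Run one adaptive session under an arbitrary choice policy
#'
#' Blocks strictly alternate over `config$conditions`, with the starting
#' condition drawn uniformly per session. The policy is called before every
#' trial with the state of the current block and must return `"A"` or
#' `"B"`.
#'
#' @param policy `function(state)` returning `"A"` or `"B"`; `state` is a
#'   list with `condition`, `block_index`, `trial_in_block`, and the block's
#'   `choices`, `outcomes`, `correct` histories.
#' @param config A `session_config`.
#' @param seed Optional integer seed.
#' @return Data frame of trial records: `condition`, `block`,
#'   `trial_in_block`, `trial_overall`, `chosen`, `outcome`, `correct`,
#'   `switch`, `mag_small`, `mag_large`, `better_option`.
#' @export
run_session <- function(policy, config = session_config(), seed = NULL) {
  stopifnot(is.function(policy))
  if (!is.null(seed)) set.seed(seed)

  conds <- config$conditions
  start <- sample.int(length(conds), 1L)
  counts <- stats::setNames(
    replicate(length(conds), list(correct = 0L, incorrect = 0L),
              simplify = FALSE), conds)

  rows <- list()
  trial_overall <- 0L
  block_index <- 0L
  repeat {
    block_index <- block_index + 1L
    if (block_index > config$max_blocks) break
    cond <- conds[((start + block_index - 2L) %% length(conds)) + 1L]
    block <- make_block(cond, block_index)
    choices <- character(0)
    outcomes <- numeric(0)
    corrects <- logical(0)
    repeat {
      t_in <- length(choices) + 1L
      state <- list(condition = cond, block_index = block_index,
                    trial_in_block = t_in, choices = choices,
                    outcomes = outcomes, correct = corrects)
      ch <- policy(state)
      if (!is.character(ch) || length(ch) != 1L || !ch %in% c("A", "B")) {
        stop(sprintf("policy returned an invalid choice at block %d trial %d",
                     block_index, t_in), call. = FALSE)
      }
      out <- sample_outcome(block, ch)
      ok <- ch == block$better_option
      trial_overall <- trial_overall + 1L
      choices <- c(choices, ch)
      outcomes <- c(outcomes, out)
      corrects <- c(corrects, ok)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, block = block_index, trial_in_block = t_in,
        trial_overall = trial_overall, chosen = ch, outcome = out,
        correct = ok,
        switch = if (t_in == 1L) NA else ch != choices[t_in - 1L],
        mag_small = block$mag_small, mag_large = block$mag_large,
        better_option = block$better_option,
        stringsAsFactors = FALSE)
      if (should_end_block(corrects, block_index == 1L, config) ||
          t_in >= config$max_block_trials) break
    }
    counts[[cond]]$correct <- counts[[cond]]$correct + sum(corrects)
    counts[[cond]]$incorrect <- counts[[cond]]$incorrect + sum(!corrects)
    if (should_end_session(counts, config)) break
  }
  do.call(rbind, rows)
}

#' Uniformly random choice policy
#'
#' @param state Ignored.
#' @return `"A"` or `"B"` with equal probability.
#' @export
random_policy <- function(state) {
  sample(c("A", "B"), 1L)
}
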