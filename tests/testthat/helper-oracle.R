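# Independent forward-recursion oracle for the learning models, written as
# a plain spreadsheet-style loop with named locals. Deliberately avoids the
# package's recursion code paths so it can serve as a reference.

oracle_trace <- function(alpha, eta, rho, gamma, beta, variant, table,
                         rho_all = FALSE) {
  table <- table[order(table$block, table$trial_in_block), , drop = FALSE]
  n <- nrow(table)
  out <- data.frame(delta = numeric(n), kappa = numeric(n),
                    p_chosen = numeric(n), Q_chosen = numeric(n),
                    Q_unchosen = numeric(n))
  nll <- 0
  prev_block <- NA
  qa <- qb <- ka <- kb <- NA
  for (t in seq_len(n)) {
    if (!identical(table$block[t], prev_block)) {
      qa <- 0; qb <- 0; ka <- 1; kb <- 1
      prev_block <- table$block[t]
    }
    a_chosen <- table$chosen[t] == "A"
    q_c <- if (a_chosen) qa else qb
    q_u <- if (a_chosen) qb else qa
    k_c <- if (a_chosen) ka else kb
    p <- exp(beta * q_c) / (exp(beta * q_c) + exp(beta * q_u))
    r <- table$outcome[t]
    if (rho_all || abs(r) == table$mag_large[t]) r <- rho * r
    d <- r - q_c
    out$delta[t] <- d
    out$kappa[t] <- k_c
    out$p_chosen[t] <- p
    out$Q_chosen[t] <- q_c
    out$Q_unchosen[t] <- q_u
    nll <- nll - log(p)
    if (variant == "associability") {
      q_c_new <- q_c + alpha * k_c * d
      k_c_new <- max(0.05, (1 - eta) * k_c + eta * abs(d))
    } else {
      q_c_new <- q_c + alpha * d
      k_c_new <- k_c
    }
    q_u_new <- gamma * q_u
    if (a_chosen) {
      qa <- q_c_new; qb <- q_u_new; ka <- k_c_new
    } else {
      qb <- q_c_new; qa <- q_u_new; kb <- k_c_new
    }
  }
  attr(out, "nll") <- nll
  out
}

# Hand-buildable toy trial table (single condition).
toy_table <- function(chosen, outcome, block = rep(1L, length(chosen)),
                      condition = "loss", mag_small = 0.25,
                      mag_large = 0.75) {
  data.frame(condition = condition, block = block,
             trial_in_block = stats::ave(block, block, FUN = seq_along),
             chosen = chosen, outcome = outcome,
             mag_small = mag_small, mag_large = mag_large,
             stringsAsFactors = FALSE)
}

# Random toy table with canonical magnitudes and valid signed outcomes.
random_toy_table <- function(n_trials, n_blocks = 1L, condition = "loss") {
  pairs <- matrix(c(0.2, 0.7, 0.25, 0.75, 0.3, 0.8), ncol = 2, byrow = TRUE)
  rows <- lapply(seq_len(n_blocks), function(b) {
    pr <- pairs[sample.int(3, 1), ]
    mag <- sample(pr, n_trials, replace = TRUE)
    sgn <- if (condition == "loss") -1 else 1
    toy_table(sample(c("A", "B"), n_trials, replace = TRUE), sgn * mag,
              block = rep(b, n_trials), condition = condition,
              mag_small = pr[1], mag_large = pr[2])
  })
  do.call(rbind, rows)
}

# Quick single-condition simulated subject with latents.
sim_loss_subject <- function(params, seed = NULL, id = "s1") {
  tab <- simulate_subject(list(loss = params),
                          session_config(conditions = "loss"),
                          mode = "task", seed = seed)
  tab$subject_id <- id
  tab
}
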