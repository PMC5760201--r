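# Value-learning models: updates, likelihood, latent traces, simulation.

test_that("reward sensitivity scales only the large-magnitude outcome", {
  expect_equal(scale_outcome(-0.75, 1.2, c(0.25, 0.75)), -0.9)
  expect_equal(scale_outcome(-0.25, 1.2, c(0.25, 0.75)), -0.25)
  expect_equal(scale_outcome(0.7, 1, c(0.2, 0.7)), 0.7)
  # unconditional variant scales both
  expect_equal(scale_outcome(-0.25, 1.2, c(0.25, 0.75), rho_all = TRUE),
               -0.3)
  expect_error(scale_outcome(-0.4, 1.2, c(0.25, 0.75)), "outcome magnitude")
})

test_that("learner update follows the hybrid equations with the kappa floor", {
  p <- model_params(alpha = 0.5, beta = 5, eta = 0.6, rho = 1, gamma = 0.9,
                    variant = "associability")
  st <- learner_state()
  up <- learner_update(st, "A", "B", -0.75, p)
  expect_equal(up$latents$delta, -0.75)
  expect_equal(up$state$Q[["A"]], -0.375)       # alpha * kappa * delta
  expect_equal(up$state$kappa[["A"]], 0.4 * 1 + 0.6 * 0.75)
  expect_equal(up$state$kappa[["B"]], 1)        # unchosen kappa unchanged

  # zero prediction error: Q unchanged, kappa decays toward |delta| = 0
  st2 <- list(Q = c(A = -0.5, B = 0), kappa = c(A = 0.8, B = 1))
  up2 <- learner_update(st2, "A", "B", -0.5, p)
  expect_equal(up2$state$Q[["A"]], -0.5)
  expect_equal(up2$state$kappa[["A"]], max(0.05, 0.4 * 0.8))
  expect_equal(up2$state$Q[["B"]], 0 * 0.9)

  # kappa floor binds
  st3 <- list(Q = c(A = -0.5, B = -0.4), kappa = c(A = 0.06, B = 1))
  up3 <- learner_update(st3, "A", "B", -0.5, p)
  expect_equal(up3$state$kappa[["A"]], 0.05)

  # gamma decay of the unchosen option
  st4 <- list(Q = c(A = 0, B = -0.4), kappa = c(A = 1, B = 1))
  up4 <- learner_update(st4, "A", "B", -0.25, p)
  expect_equal(up4$state$Q[["B"]], -0.36)

  # eta = 0 keeps kappa at its initial value forever
  p0 <- model_params(alpha = 0.5, beta = 5, eta = 0, rho = 1, gamma = 1,
                     variant = "associability")
  st5 <- learner_state()
  for (i in 1:5) st5 <- learner_update(st5, "A", "B", -0.75, p0)$state
  expect_equal(st5$kappa[["A"]], 1)
})

test_that("softmax choice probability is symmetric, flat at beta 0, and logistic", {
  expect_equal(choice_prob(0.3, 0.3, 4), 0.5)
  expect_equal(choice_prob(2, -3, 0), 0.5)
  expect_equal(choice_prob(1, 0, 3), 1 / (1 + exp(-3)))
  # numerically stable at extreme products
  expect_equal(choice_prob(10, -10, 20), 1, tolerance = 1e-12)
  expect_gt(choice_prob(-10, 10, 20), 0)
  p <- choice_prob(0.4, -0.2, 7)
  expect_equal(p + choice_prob(-0.2, 0.4, 7), 1, tolerance = 1e-12)
})

test_that("negative log-likelihood matches closed forms and nests the basic model", {
  set.seed(3)
  tab <- random_toy_table(30, n_blocks = 2)
  p0 <- model_params(alpha = 0.4, beta = 0, eta = 0.3, rho = 1.1,
                     gamma = 0.9, variant = "associability")
  expect_equal(neg_log_likelihood(p0, tab), nrow(tab) * log(2),
               tolerance = 1e-12)

  for (i in 1:20) {
    tab <- random_toy_table(sample(20:40, 1), n_blocks = sample(1:3, 1))
    a <- runif(1); r <- runif(1, 0.5, 2); g <- runif(1); b <- runif(1, 0, 12)
    nll_assoc0 <- neg_log_likelihood(
      model_params(a, b, eta = 0, rho = r, gamma = g,
                   variant = "associability"), tab)
    nll_basic <- neg_log_likelihood(
      model_params(a, b, rho = r, gamma = g, variant = "basic"), tab)
    expect_lt(abs(nll_assoc0 - nll_basic), 1e-10)
  }

  expect_error(neg_log_likelihood(p0, tab[0, ]), "empty")
})

test_that("likelihood and trace reproduce the independent forward-recursion oracle", {
  set.seed(4)
  for (i in 1:30) {
    n <- sample(2:5, 1)
    tab <- random_toy_table(n, condition = sample(c("loss", "gain"), 1))
    a <- runif(1); e <- runif(1); r <- runif(1, 0.4, 2.5)
    g <- runif(1); b <- runif(1, 0, 15)
    v <- sample(c("basic", "associability"), 1)
    p <- model_params(a, b, eta = e, rho = r, gamma = g, variant = v)
    orc <- oracle_trace(a, e, r, g, b, v, tab)
    tr <- latent_trace(p, tab)
    expect_equal(tr$delta, orc$delta, tolerance = 1e-12)
    expect_equal(tr$kappa_chosen, orc$kappa, tolerance = 1e-12)
    expect_equal(tr$p_chosen, orc$p_chosen, tolerance = 1e-12)
    expect_equal(tr$Q_chosen, orc$Q_chosen, tolerance = 1e-12)
    expect_equal(neg_log_likelihood(p, tab), attr(orc, "nll"),
                 tolerance = 1e-10)
  }
  # and on a longer multi-block table
  tab <- random_toy_table(40, n_blocks = 3)
  p <- model_params(0.55, 6, eta = 0.45, rho = 1.2, gamma = 0.85,
                    variant = "associability")
  orc <- oracle_trace(0.55, 0.45, 1.2, 0.85, 6, "associability", tab)
  expect_equal(neg_log_likelihood(p, tab), attr(orc, "nll"),
               tolerance = 1e-10)
})

test_that("latent traces reset at block starts and respect kappa bounds", {
  p <- model_params(0.5, 8, eta = 0.5, rho = 1.1, gamma = 0.9,
                    variant = "associability", condition = "loss")
  tab <- sim_loss_subject(p, seed = 11)
  tr <- latent_trace(p, tab)
  first <- tr$trial_in_block == 1
  expect_true(all(tr$Q_chosen[first] == 0))
  expect_true(all(tr$Q_unchosen[first] == 0))
  expect_true(all(tr$kappa_chosen[first] == 1))
  expect_equal(tr$delta[first], tr$scaled_outcome[first])
  expect_true(all(tr$kappa_chosen >= 0.05))
  expect_true(all(tr$kappa_chosen <= max(1, 1.1 * 0.8 + max(abs(tr$Q_chosen)))))
  expect_true(all(tr$p_chosen > 0 & tr$p_chosen < 1))

  p0 <- model_params(0.5, 8, eta = 0, rho = 1, gamma = 1,
                     variant = "associability", condition = "loss")
  tr0 <- latent_trace(p0, tab)
  expect_true(all(tr0$kappa_chosen == 1))
})

test_that("simulated latents equal the trace recomputed from the trial table", {
  p <- model_params(0.45, 9, eta = 0.4, rho = 1.2, gamma = 0.92,
                    variant = "associability", condition = "loss")
  tab <- sim_loss_subject(p, seed = 13)
  tr <- latent_trace(p, tab)
  for (col in c("Q_chosen", "Q_unchosen", "kappa_chosen", "delta",
                "p_chosen", "scaled_outcome")) {
    expect_equal(tr[[col]], tab[[col]], tolerance = 1e-12, label = col)
  }
})

test_that("agents behave at chance for beta 0 and above chance when learning", {
  cfg <- session_config(conditions = "loss")
  p_rand <- model_params(0.5, 0, eta = 0.3, rho = 1, gamma = 1,
                         variant = "associability", condition = "loss")
  set.seed(21)
  acc <- replicate(30, mean(simulate_subject(list(loss = p_rand), cfg,
                                             mode = "sim", sim_blocks = 2,
                                             sim_trials = 25)$correct))
  expect_lt(abs(mean(acc) - 0.5), 3 * sqrt(0.25 / (30 * 50)))

  p_learn <- model_params(0.6, 8, eta = 0, rho = 1, gamma = 1,
                          variant = "associability", condition = "loss")
  set.seed(22)
  late <- unlist(replicate(100, {
    tab <- simulate_subject(list(loss = p_learn), cfg, mode = "sim",
                            sim_blocks = 1, sim_trials = 25)
    tab$correct[tab$trial_in_block > 15]
  }, simplify = FALSE))
  bt <- binom.test(sum(late), length(late), p = 0.5, alternative = "greater")
  expect_lt(bt$p.value, 1e-6)

  # determinism under seed
  t1 <- simulate_subject(list(loss = p_learn), cfg, mode = "task", seed = 5)
  t2 <- simulate_subject(list(loss = p_learn), cfg, mode = "task", seed = 5)
  expect_identical(t1, t2)
})
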