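# Per-subject MLE and the two-stage procedure.

test_that("fitting refuses short tables and honors fixed parameters", {
  p <- model_params(0.5, 8, eta = 0.4, rho = 1, gamma = 0.9,
                    variant = "associability", condition = "loss")
  tab <- sim_loss_subject(p, seed = 31)
  expect_error(fit_subject(tab[1:15, ], "associability"),
               "fewer than 20 trials")

  f <- fit_subject(tab, "associability", fit_config(n_starts = 4),
                   fixed = list(beta = 5.1))
  expect_identical(f$estimates$beta, 5.1)
  expect_equal(f$k_free, 4)  # alpha, eta, rho, gamma

  fb <- fit_subject(tab, "basic", fit_config(n_starts = 4),
                    fixed = list(beta = 5.1))
  expect_equal(fb$k_free, 3)
})

test_that("reported NLL is the best across starts and is reproducible at the optimum", {
  p <- model_params(0.5, 8, eta = 0.4, rho = 1.1, gamma = 0.9,
                    variant = "associability", condition = "loss")
  tab <- sim_loss_subject(p, seed = 32)
  f <- fit_subject(tab, "associability", fit_config(n_starts = 8))
  expect_lte(f$nll, min(f$start_nlls, na.rm = TRUE))
  # evaluating the likelihood at the reported estimates reproduces the NLL
  expect_equal(neg_log_likelihood(f$estimates, tab), f$nll,
               tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("a degenerate all-same-choice subject fits without crashing", {
  tab <- toy_table(rep("A", 30),
                   rep(c(-0.25, -0.25, -0.25, -0.75), length.out = 30))
  f <- fit_subject(tab, "basic", fit_config(n_starts = 5))
  expect_s3_class(f, "fit_result")
  expect_true(is.finite(f$nll))
  # all-loss perseveration is best explained by value-blind choice: the
  # optimum sits at the beta = 0 boundary with NLL = n log 2
  expect_lte(f$nll, 30 * log(2) + 1e-3)
  expect_lt(f$estimates$beta, 0.1)
})

test_that("two-stage fitting fixes beta at the stage-1 group mean", {
  p <- model_params(0.5, 8, eta = 0.4, rho = 1, gamma = 0.9,
                    variant = "associability", condition = "loss")
  tabs <- lapply(1:4, function(i) sim_loss_subject(p, seed = 40 + i,
                                                   id = paste0("s", i)))
  names(tabs) <- paste0("s", 1:4)
  ts <- two_stage_fit(tabs, "associability", fit_config(n_starts = 4))
  s1_betas <- vapply(ts$stage1, function(f) f$estimates$beta, numeric(1))
  expect_equal(ts$group_mean_beta, mean(s1_betas))
  for (f in ts$fits) {
    expect_identical(f$estimates$beta, ts$group_mean_beta)
    expect_equal(f$k_free, 4)  # beta excluded from stage-2 free count
  }
  # stage 1 holds rho at 1
  expect_true(all(vapply(ts$stage1, function(f) f$estimates$rho,
                         numeric(1)) == 1))
  expect_error(two_stage_fit(tabs[1], "associability"),
               "at least 2 subjects")
})

test_that("stage-2 associability fits beat basic fits on eta > 0 cohorts for most subjects", {
  set.seed(50)
  tabs <- list()
  for (i in 1:10) {
    p <- model_params(0.5, 10, eta = runif(1, 0.3, 0.7), rho = 1,
                      gamma = 0.9, variant = "associability",
                      condition = "loss")
    tabs[[paste0("s", i)]] <- sim_loss_subject(p, id = paste0("s", i))
  }
  fa <- two_stage_fit(tabs, "associability", fit_config(n_starts = 6))
  fb <- two_stage_fit(tabs, "basic", fit_config(n_starts = 6))
  nll_a <- vapply(fa$fits, `[[`, numeric(1), "nll")
  nll_b <- vapply(fb$fits, `[[`, numeric(1), "nll")
  expect_gte(mean(nll_a <= nll_b + 0.5), 0.7)
})

test_that("fits table carries the parameters CSV schema", {
  p <- model_params(0.5, 8, eta = 0.4, rho = 1, gamma = 0.9,
                    variant = "associability", condition = "loss")
  tabs <- lapply(1:2, function(i) sim_loss_subject(p, seed = 60 + i,
                                                   id = paste0("s", i)))
  names(tabs) <- paste0("s", 1:2)
  ts <- two_stage_fit(tabs, "associability", fit_config(n_starts = 3))
  tb <- fits_table(ts)
  expect_setequal(
    names(tb),
    c("subject_id", "condition", "variant", "alpha", "eta", "rho", "gamma",
      "beta", "beta_fixed", "nll", "aicc", "n_trials", "converged"))
  expect_true(all(tb$beta_fixed))
  expect_equal(tb$aicc, aicc(tb$nll, 4, tb$n_trials))
})
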