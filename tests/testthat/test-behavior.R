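# Behavioral validation and group statistics.

make_switch_table <- function(id, cond, rates, n = 40) {
  # two blocks of n/2 trials with a controlled switch rate
  chosen <- character(n)
  chosen[1] <- "A"
  sw <- runif(n) < rates
  for (t in 2:n) chosen[t] <- if (sw[t]) setdiff(c("A", "B"), chosen[t - 1]) else chosen[t - 1]
  blk <- rep(1:2, each = n / 2)
  data.frame(subject_id = id, condition = cond, block = blk,
             trial_in_block = ave(blk, blk, FUN = seq_along),
             chosen = chosen, outcome = ifelse(cond == "loss", -0.25, 0.25),
             correct = TRUE, mag_small = 0.25, mag_large = 0.75,
             switch = ave(seq_len(n), blk, FUN = function(i) {
               c(NA, chosen[i][-1] != chosen[i][-length(i)])
             }) == 1,
             stringsAsFactors = FALSE)
}

test_that("low-switch exclusion respects scope and the strict threshold", {
  set.seed(70)
  tabs <- rbind(make_switch_table("lowgain", "gain", 0.04),
                make_switch_table("lowgain", "loss", 0.3),
                make_switch_table("ok", "gain", 0.3),
                make_switch_table("ok", "loss", 0.3))
  both <- exclusion_filter(tabs, scope = "both")
  expect_true("lowgain" %in% both$excluded)
  loss_only <- exclusion_filter(tabs, scope = "loss")
  expect_false("lowgain" %in% loss_only$excluded)

  # a switch rate exactly at the threshold is retained (strict "less than")
  tb <- make_switch_table("edge", "loss", 0.5)
  tb$switch[!is.na(tb$switch)] <- rep(c(TRUE, FALSE, FALSE, FALSE, FALSE),
                                      length.out = sum(!is.na(tb$switch)))
  rate <- mean(tb$switch, na.rm = TRUE)
  res <- exclusion_filter(tb, scope = "loss", threshold = rate)
  expect_false("edge" %in% res$excluded)
  res2 <- exclusion_filter(tb, scope = "loss", threshold = rate + 1e-9)
  expect_true("edge" %in% res2$excluded)
})

test_that("running accuracy is flat for perfect and random responders and rises for learners", {
  n <- 30
  perfect <- data.frame(subject_id = "p", condition = "loss", block = 1,
                        trial_in_block = 1:n, correct = TRUE)
  ra <- running_accuracy(perfect)
  expect_true(all(ra$mean == 1))

  set.seed(71)
  rand <- do.call(rbind, lapply(1:30, function(i) {
    data.frame(subject_id = paste0("r", i), condition = "loss",
               block = rep(1:2, each = n), trial_in_block = rep(1:n, 2),
               correct = runif(2 * n) < 0.5)
  }))
  rar <- running_accuracy(rand)
  expect_true(all(abs(rar$mean - 0.5) < 0.1))

  p <- model_params(0.8, 14, eta = 0.3, rho = 1, gamma = 0.95,
                    variant = "associability", condition = "loss")
  set.seed(72)
  strong <- do.call(rbind, lapply(1:30, function(i) {
    tab <- simulate_subject(list(loss = p),
                            session_config(conditions = "loss"),
                            mode = "sim", sim_blocks = 2, sim_trials = 25)
    tab$subject_id <- paste0("s", i)
    tab
  }))
  ras <- running_accuracy(strong)
  expect_lt(ras$mean[ras$trial_in_block == 1], 0.62)
  expect_gt(ras$mean[ras$trial_in_block == 15], 0.75)
})

test_that("the associability-weight sweep has the documented grid shape", {
  sw <- eta_performance_sweep(n_agents = 4, seed = 73)
  expect_equal(nrow(sw$grid), 19)
  expect_equal(sw$grid$eta, seq(0.05, 0.95, by = 0.05))
  expect_true(all(sw$agents$accuracy >= 0 & sw$agents$accuracy <= 1))
  expect_true(all(sw$grid$se > 0))
  expect_equal(nrow(sw$agents), 19 * 4)
})

test_that("calibration flags degenerate predictions and tracks observed accuracy", {
  p <- model_params(0.5, 10, eta = 0.4, rho = 1, gamma = 0.9,
                    variant = "associability", condition = "loss")
  tabs <- do.call(rbind, lapply(1:8, function(i) {
    sim_loss_subject(p, seed = 80 + i, id = paste0("s", i))
  }))
  fits <- lapply(paste0("s", 1:8), function(id) {
    list(subject_id = id, estimates = p)
  })
  names(fits) <- paste0("s", 1:8)
  cal <- calibration_bins(fits, tabs)
  expect_gt(cal$r, 0.9)
  expect_true(all(diff(cal$bins$observed[cal$bins$n_subjects > 0]) > -0.2))

  # beta = 0 predictions are constant at 0.5: single occupied bin
  p0 <- model_params(0.5, 0, eta = 0.4, rho = 1, gamma = 0.9,
                     variant = "associability", condition = "loss")
  fits0 <- list(s1 = list(subject_id = "s1", estimates = p0))
  w <- testthat::capture_warnings(
    cal0 <- calibration_bins(fits0, tabs[tabs$subject_id == "s1", ]))
  expect_true(any(grepl("empty calibration bin", w)))
  expect_true(any(grepl("correlation undefined", w)))
  expect_true(is.na(cal0$r))
})

test_that("reaction-time regressions recover the planted associability coefficient", {
  spec <- group_spec("g", 5, eta_range_loss = c(0.4, 0.6),
                     rt_model = list(intercept = 0.9, kappa = 0.232,
                                     q = -0.08, trial = -0.002, sd = 0))
  bundle <- generate_cohort(sample_cohort(list(spec), seed = 85),
                            session_config(conditions = "loss"), seed = 86)
  coefs <- rt_regression(bundle$trials)
  expect_equal(coefs$kappa, rep(0.232, 5), tolerance = 1e-8)

  # trials outside the RT window are excluded from the design
  tab <- bundle$trials[bundle$trials$subject_id == "S001", ]
  n_all <- nrow(tab)
  tab$rt[3] <- 0.2
  tab$rt[4] <- 5.5
  c2 <- rt_regression(tab)
  expect_equal(c2$n_trials, n_all - 2)

  # noisy version: group t strongly positive
  spec_n <- group_spec("g", 12, eta_range_loss = c(0.4, 0.6))
  bn <- generate_cohort(sample_cohort(list(spec_n), seed = 87),
                        session_config(conditions = "loss"), seed = 88)
  gt <- group_rt_test(rt_regression(bn$trials))
  expect_gt(gt$t, 2)
  expect_equal(gt$df, 11)
})

test_that("switching models rank associability-modulated data correctly", {
  spec <- group_spec("g", 25, eta_range_loss = c(0.4, 0.7))
  bundle <- generate_cohort(sample_cohort(list(spec), seed = 90),
                            session_config(conditions = "loss"), seed = 91)
  sm <- switching_models(bundle$trials)  # latents from generating params
  rep <- sm$report
  aic <- setNames(rep$aic, rep$model)
  expect_lt(aic[["outcome_x_pe_x_assoc"]], aic[["outcome_x_pe"]])
  expect_lt(aic[["outcome_x_pe_x_assoc"]], aic[["outcome_only"]])
  # the pe-only increment is small by construction: given the binary
  # previous-outcome code, the previous prediction error adds little until
  # it is modulated by associability
  expect_lt(aic[["outcome_x_pe"]], aic[["outcome_only"]] + 4)
  expect_lt(sm$lrt$p, 0.001)

  # previous-outcome coding: 1 = small loss in the loss condition
  d <- assoclearn:::switch_design(bundle$trials, n_lags = 1L)
  tab <- bundle$trials[order(bundle$trials$subject_id, bundle$trials$block,
                             bundle$trials$trial_in_block), ]
  i <- which(tab$subject_id == "S001" & tab$block == 1)
  small_prev <- abs(tab$outcome[i[1]]) == tab$mag_small[i[1]]
  expect_equal(d$out1[d$subject_id == "S001"][1], as.integer(small_prev))
})

test_that("outcome-only switching data give the baseline model the best AIC-per-penalty", {
  set.seed(92)
  spec <- group_spec("g", 12, eta_range_loss = c(0.4, 0.6))
  bundle <- generate_cohort(sample_cohort(list(spec), seed = 93),
                            session_config(conditions = "loss"), seed = 94)
  tab <- bundle$trials[order(bundle$trials$subject_id, bundle$trials$block,
                             bundle$trials$trial_in_block), ]
  key <- interaction(tab$subject_id, tab$block, drop = TRUE)
  better <- as.integer(abs(tab$outcome) == tab$mag_small)
  out1 <- ave(better, key, FUN = function(v) c(NA, v[-length(v)]))
  tab$switch <- ifelse(is.na(out1), NA,
                       runif(nrow(tab)) < plogis(-1 + 1.2 * out1))
  sm <- switching_models(tab)
  rep <- setNames(sm$report$delta_aic, sm$report$model)
  # richer models gain at most a small amount over the outcome-only model
  expect_lt(rep[["outcome_x_pe_x_assoc"]], 10)
  expect_gt(sm$lrt$p, 0.001)
})

test_that("jackknife SE matches the closed form for a mean and rejects tiny n", {
  set.seed(95)
  x <- rnorm(25)
  jk <- jackknife_se(x, mean)
  expect_equal(jk$se, sd(x) / sqrt(25), tolerance = 1e-10)
  expect_equal(length(jk$loo), 25)
  expect_equal(jackknife_se(rep(3, 10), mean)$se, 0)
  expect_error(jackknife_se(1:2, mean), "at least 3")
})

test_that("condition interaction detects differing loss/gain switching policies", {
  set.seed(96)
  tabs <- list()
  for (i in 1:14) {
    id <- sprintf("s%02d", i)
    # loss: switch after a large loss; gain: outcome-insensitive switching
    tl <- random_toy_table(40, n_blocks = 2, condition = "loss")
    big_prev <- c(NA, abs(tl$outcome[-nrow(tl)]) == tl$mag_large[1])
    big_prev[tl$trial_in_block == 1] <- NA
    tl$switch <- ifelse(is.na(big_prev), NA,
                        runif(40) < ifelse(big_prev, 0.7, 0.15))
    tg <- random_toy_table(40, n_blocks = 2, condition = "gain")
    tg$block <- tg$block + 2
    tg$switch <- c(NA, runif(39) < 0.4)
    tg$switch[tg$trial_in_block == 1] <- NA
    tl$subject_id <- tg$subject_id <- id
    tabs[[id]] <- rbind(tl, tg)
  }
  ci <- condition_interaction_test(do.call(rbind, tabs))
  expect_gt(abs(ci$z), 2)
  expect_error(condition_interaction_test(tabs[[1]][tabs[[1]]$condition == "loss", ]),
               "both loss and gain")
})

test_that("group regression reports covariate-adjusted effects and VIF", {
  set.seed(97)
  n <- 60
  cov <- data.frame(subject_id = sprintf("s%02d", 1:n),
                    group = rep(c("a", "b"), each = n / 2),
                    depression = rnorm(n), exposure = rnorm(n),
                    age = rnorm(n, 40, 8),
                    gender = sample(c("M", "F"), n, replace = TRUE))
  par <- data.frame(subject_id = cov$subject_id,
                    eta = 0.3 + 0.25 * (cov$group == "b") + rnorm(n, 0, 0.1),
                    alpha = 0.5 + rnorm(n, 0, 0.1))
  ge <- group_parameter_regression(par, cov, "eta")
  grp <- ge$coefficients[grep("^group", ge$coefficients$term), ]
  expect_lt(grp$p, 0.001)
  expect_equal(grp$estimate, 0.25, tolerance = 0.1)
  # orthogonal covariates: VIF near 1
  expect_lt(ge$vif_group, 1.3)

  ga <- group_parameter_regression(par, cov, "alpha")
  expect_gt(ga$coefficients[grep("^group", ga$coefficients$term), "p"], 0.05)

  cov2 <- cov
  cov2$dup <- as.numeric(cov2$group == "b")
  expect_error(group_parameter_regression(par, cov2, "eta"),
               "rank-deficient|collinear")
})

test_that("covariate x severity switching interaction is recoverable and validated", {
  set.seed(98)
  spec <- group_spec("g", 16, eta_range_loss = c(0.4, 0.6))
  bundle <- generate_cohort(sample_cohort(list(spec), seed = 99),
                            session_config(conditions = "loss"), seed = 100)
  tab <- bundle$trials[order(bundle$trials$subject_id, bundle$trials$block,
                             bundle$trials$trial_in_block), ]
  ids <- unique(tab$subject_id)
  cov <- data.frame(subject_id = ids, roi = rnorm(length(ids)))
  sev <- data.frame(subject_id = ids, severity = rnorm(length(ids)))
  key <- interaction(tab$subject_id, tab$block, drop = TRUE)
  better <- as.integer(abs(tab$outcome) == tab$mag_small)
  out1 <- ave(better, key, FUN = function(v) c(NA, v[-length(v)]))
  lin <- -1 + 0.7 * out1 * cov$roi[match(tab$subject_id, cov$subject_id)] *
    sev$severity[match(tab$subject_id, sev$subject_id)]
  tab$switch <- ifelse(is.na(out1), NA, runif(nrow(tab)) < plogis(lin))
  cm <- covariate_interaction_switch_model(tab, cov, sev)
  expect_lt(cm$p, 0.005)
  expect_true(cm$significant)

  sev0 <- data.frame(subject_id = ids, severity = 1)
  expect_error(covariate_interaction_switch_model(tab, cov, sev0),
               "constant")
  expect_error(covariate_interaction_switch_model(tab, cov[-1, ], sev),
               "covariate missing")
})
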