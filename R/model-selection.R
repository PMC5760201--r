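# Random-effects Bayesian model selection over per-subject AICc evidence.
#
# Per-subject approximate log model evidence is -AICc/2. A variational
# Dirichlet-multinomial scheme estimates the population frequencies of the
# candidate models; exceedance probability is the posterior probability
# that a model is the most frequent; the Bayes omnibus risk (posterior
# probability that all models are equally frequent, via a free-energy
# comparison) protects the exceedance probability against the
# equal-frequency null: PEP_k = EP_k * (1 - BOR) + BOR / K.

#' Corrected Akaike information criterion
#'
#' `AICc = 2 * nll + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param nll Negative log-likelihood at the optimum.
#' @param k_free Number of free parameters.
#' @param n_trials Number of observations; must exceed `k_free + 1`.
#' @return Scalar AICc.
#' @export
aicc <- function(nll, k_free, n_trials) {
  if (any(n_trials <= k_free + 1)) {
    stop("AICc undefined: n_trials must exceed k_free + 1", call. = FALSE)
  }
  2 * nll + 2 * k_free + 2 * k_free * (k_free + 1) / (n_trials - k_free - 1)
}

#' Subjects x models evidence matrix from fit tables
#'
#' @param ... Named fit tables (from [fits_table()]) or `fit_result` lists,
#'   one per model; all must cover the same subjects.
#' @return Matrix of approximate log evidences (-AICc/2), subjects in rows.
#' @export
evidence_matrix <- function(...) {
  models <- list(...)
  if (length(models) == 1L && is.list(models[[1L]]) &&
      !is.data.frame(models[[1L]]) && !inherits(models[[1L]], "fit_result")) {
    models <- models[[1L]]
  }
  if (length(models) < 2L) stop("need at least 2 models", call. = FALSE)
  labs <- names(models) %||% paste0("model", seq_along(models))
  tabs <- lapply(models, function(m) {
    if (is.data.frame(m)) m else fits_table(m)
  })
  ids <- sort(tabs[[1L]]$subject_id)
  for (tb in tabs[-1L]) {
    if (!identical(sort(tb$subject_id), ids)) {
      stop("models were fit on different subject sets", call. = FALSE)
    }
  }
  L <- vapply(tabs, function(tb) {
    -tb$aicc[match(ids, tb$subject_id)] / 2
  }, numeric(length(ids)))
  dimnames(L) <- list(ids, labs)
  if (!all(is.finite(L))) stop("non-finite evidence entries", call. = FALSE)
  L
}

#' Variational random-effects Bayesian model selection
#'
#' Iterates the mean-field fixed point for the Dirichlet-multinomial
#' random-effects model: responsibilities
#' `u_nk` proportional to `exp(L_nk + digamma(alpha_k) - digamma(sum(alpha)))`
#' and `alpha_k = alpha0 + sum_n u_nk`, until the concentration
#' parameters change by less than `tol`.
#'
#' @param evidence Subjects x models matrix of log evidences
#'   (see [evidence_matrix()]).
#' @param prior_alpha Dirichlet prior concentration (default 1).
#' @param tol Convergence threshold on `max |delta alpha|` (default 1e-4).
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return List of class `bms_result`: `dirichlet_alpha`,
#'   `subject_posteriors` (subjects x models), `expected_frequencies`,
#'   `evidence`, `prior_alpha`, `n_iter`.
#' @export
variational_bms <- function(evidence, prior_alpha = 1, tol = 1e-4,
                            max_iter = 10000L) {
  L <- as.matrix(evidence)
  stopifnot(nrow(L) >= 2L, ncol(L) >= 2L, all(is.finite(L)))
  K <- ncol(L)
  alpha <- rep(prior_alpha, K)
  u <- matrix(NA_real_, nrow(L), K, dimnames = dimnames(L))
  for (iter in seq_len(max_iter)) {
    w <- sweep(L, 2L, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- w - apply(w, 1L, max)
    u <- exp(w) / rowSums(exp(w))
    alpha_new <- prior_alpha + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      return(structure(list(
        dirichlet_alpha = stats::setNames(alpha, colnames(L)),
        subject_posteriors = u,
        expected_frequencies = stats::setNames(alpha / sum(alpha),
                                               colnames(L)),
        evidence = L, prior_alpha = prior_alpha, n_iter = iter),
        class = "bms_result"))
    }
    alpha <- alpha_new
  }
  stop("variational BMS did not converge after ", max_iter, " iterations; ",
       "last alpha: ", paste(signif(alpha, 6), collapse = ", "),
       call. = FALSE)
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result>\n  expected frequencies: ",
      paste(sprintf("%s=%.3f", names(x$expected_frequencies),
                    x$expected_frequencies), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Exceedance probability of each model
#'
#' Posterior probability, under `r ~ Dirichlet(alpha)`, that each model's
#' frequency exceeds all others'. For two models this is a Beta tail
#' probability (regularized incomplete beta function); for more, Monte
#' Carlo over Dirichlet draws with a fixed seed.
#'
#' @param dirichlet_alpha Posterior concentration vector (length >= 2).
#' @param n_draws Monte-Carlo draws for K > 2 (default 1e6).
#' @param seed Monte-Carlo seed.
#' @return Named probability vector summing to 1.
#' @export
exceedance_prob <- function(dirichlet_alpha, n_draws = 1e6, seed = 1L) {
  a <- dirichlet_alpha
  K <- length(a)
  stopifnot(K >= 2L, all(a > 0))
  if (K == 2L) {
    ep1 <- stats::pbeta(0.5, a[1L], a[2L], lower.tail = FALSE)
    out <- c(ep1, 1 - ep1)
  } else {
    out <- with_local_seed(seed, {
      g <- matrix(stats::rgamma(n_draws * K, shape = rep(a, each = n_draws)),
                  ncol = K)
      tabulate(max.col(g), nbins = K) / n_draws
    })
  }
  stats::setNames(as.numeric(out), names(a))
}

# Free energy (ELBO) of the fitted random-effects model H1.
bms_free_energy <- function(bms) {
  L <- bms$evidence
  u <- bms$subject_posteriors
  a0 <- rep(bms$prior_alpha, ncol(L))
  a <- bms$dirichlet_alpha
  dg <- digamma(a) - digamma(sum(a))
  ulogu <- sum(ifelse(u > 0, u * log(u), 0))
  sum(u * L) - ulogu +
    lgamma(sum(a0)) - sum(lgamma(a0)) - lgamma(sum(a)) + sum(lgamma(a)) +
    sum((a0 - a + colSums(u)) * dg)
}

# Log evidence of the equal-frequency null H0 (r fixed at 1/K).
bms_null_evidence <- function(L) {
  K <- ncol(L)
  m <- apply(L, 1L, max)
  sum(m + log(rowSums(exp(L - m)) / K))
}

#' Protected exceedance probability
#'
#' Computes the Bayes omnibus risk — the posterior probability of the
#' equal-frequency null, `BOR = 1 / (1 + exp(F1 - F0))` with `F1` the
#' variational free energy of the fitted model and `F0` the null's log
#' evidence — and protects the exceedance probabilities:
#' `PEP_k = EP_k * (1 - BOR) + BOR / K`.
#'
#' @param bms A `bms_result` (carries its evidence matrix).
#' @param n_draws,seed Passed to [exceedance_prob()] for K > 2.
#' @return List: `ep`, `bor`, `pep`.
#' @export
protected_ep <- function(bms, n_draws = 1e6, seed = 1L) {
  stopifnot(inherits(bms, "bms_result"))
  ep <- exceedance_prob(bms$dirichlet_alpha, n_draws = n_draws, seed = seed)
  f1 <- bms_free_energy(bms)
  f0 <- bms_null_evidence(bms$evidence)
  bor <- 1 / (1 + exp(f1 - f0))
  K <- length(ep)
  list(ep = ep, bor = bor, pep = ep * (1 - bor) + bor / K)
}

#' Compare fitted model variants per condition
#'
#' Runs AICc-based random-effects model selection within each condition:
#' per-subject AICc per model, fraction of subjects favoring each model,
#' expected model frequencies, exceedance probability, Bayes omnibus risk,
#' and protected exceedance probability. Accepts any number of model
#' variants (e.g. basic vs associability, combined vs per-condition
#' parameterizations).
#'
#' @param fits Data frame concatenating [fits_table()] outputs for every
#'   variant (columns `subject_id`, `condition`, `variant`, `aicc`), or a
#'   named list of `two_stage_fit`s.
#' @param prior_alpha,n_draws,seed Passed to the BMS machinery.
#' @return Named list (one element per condition) of class
#'   `variant_comparison` elements: `per_subject`, `best_fraction`,
#'   `expected_frequencies`, `ep`, `bor`, `pep`, `bms`.
#' @export
compare_variants <- function(fits, prior_alpha = 1, n_draws = 1e6,
                             seed = 1L) {
  if (!is.data.frame(fits)) {
    fits <- do.call(rbind, lapply(fits, fits_table))
  }
  req <- c("subject_id", "condition", "variant", "aicc")
  stopifnot(all(req %in% names(fits)))
  out <- list()
  for (cond in unique(fits$condition)) {
    fc <- fits[fits$condition == cond, , drop = FALSE]
    variants <- unique(fc$variant)
    if (length(variants) < 2L) {
      stop("condition ", cond, " has fewer than 2 variants", call. = FALSE)
    }
    ids <- sort(unique(fc$subject_id))
    A <- sapply(variants, function(v) {
      sub <- fc[fc$variant == v, , drop = FALSE]
      if (!identical(sort(sub$subject_id), ids)) {
        stop("variant ", v, " in condition ", cond,
             " covers a different subject set", call. = FALSE)
      }
      sub$aicc[match(ids, sub$subject_id)]
    })
    rownames(A) <- ids
    L <- -A / 2
    bms <- variational_bms(L, prior_alpha = prior_alpha)
    pep <- protected_ep(bms, n_draws = n_draws, seed = seed)
    best <- table(factor(variants[max.col(L)], levels = variants))
    out[[cond]] <- structure(list(
      condition = cond,
      per_subject = data.frame(subject_id = ids, A,
                               check.names = FALSE, row.names = NULL),
      best_fraction = as.numeric(best) / length(ids),
      expected_frequencies = bms$expected_frequencies,
      ep = pep$ep, bor = pep$bor, pep = pep$pep, bms = bms),
      class = "variant_comparison")
    names(out[[cond]]$best_fraction) <- variants
  }
  out
}

#' @export
print.variant_comparison <- function(x, ...) {
  cat(sprintf("<variant_comparison: %s>\n", x$condition))
  cat("  PEP: ", paste(sprintf("%s=%.4f", names(x$pep), x$pep),
                       collapse = ", "),
      sprintf("  (BOR=%.4f)\n", x$bor), sep = "")
  invisible(x)
}
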