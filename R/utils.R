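# Internal helpers: parameter transforms, RNG hygiene, outcome-pair lookup.

# Canonical outcome magnitude pairs (dollars). Small and large magnitudes
# identify each other uniquely, so a block's pair can be inferred from any
# observed |outcome|.
.OUTCOME_PAIRS <- matrix(
  c(0.20, 0.70,
    0.25, 0.75,
    0.30, 0.80),
  ncol = 2, byrow = TRUE,
  dimnames = list(NULL, c("small", "large"))
)

# Box constraints used both by the optimizer and by parameter validation.
.PARAM_BOUNDS <- list(
  alpha = c(0, 1),
  eta   = c(0, 1),
  rho   = c(0, 3),
  gamma = c(0, 1),
  beta  = c(0, 20)
)

#' Parameter box constraints
#'
#' Lower/upper bounds applied to the learning-model parameters during
#' validation and optimization: learning rate `alpha` and associability
#' weight `eta` in \[0, 1\], decay `gamma` in \[0, 1\], reward sensitivity
#' `rho` in (0, 3\], inverse temperature `beta` in \[0, 20\].
#'
#' @return Named list of length-2 numeric vectors `c(lower, upper)`.
#' @export
param_bounds <- function() .PARAM_BOUNDS

# Map a bounded parameter to the real line (scaled logit) and back.
to_unconstrained <- function(p, lo, hi) {
  stats::qlogis(pmin(pmax((p - lo) / (hi - lo), 1e-12), 1 - 1e-12))
}

from_unconstrained <- function(x, lo, hi) {
  lo + (hi - lo) * stats::plogis(x)
}

# Infer the block outcome-magnitude pair from observed |outcome| values.
# Errors if a magnitude is not one of the canonical task values.
infer_outcome_pair <- function(abs_outcomes) {
  mags <- round(abs_outcomes, 6)
  hit <- rep(NA_integer_, length(mags))
  for (i in seq_len(nrow(.OUTCOME_PAIRS))) {
    hit[mags %in% .OUTCOME_PAIRS[i, ]] <- i
  }
  if (anyNA(hit)) {
    stop("outcome magnitude not in the task's outcome pairs: ",
         paste(unique(mags[is.na(hit)]), collapse = ", "), call. = FALSE)
  }
  if (length(unique(hit)) > 1L) {
    stop("outcomes within one block map to different magnitude pairs",
         call. = FALSE)
  }
  .OUTCOME_PAIRS[hit[1L], ]
}

# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG stream afterwards. Used so fitting and Monte-Carlo helpers
# are reproducible without disturbing the session RNG.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# z-score a vector; returns list(values, scaled). Zero-variance input is
# returned unscaled with scaled = FALSE so callers can warn.
zscore_safe <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) {
    return(list(values = x - mean(x), scaled = FALSE))
  }
  list(values = (x - mean(x)) / s, scaled = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
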