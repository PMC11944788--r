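# Shared vocabularies and small numeric helpers.

sex_levels <- c("male", "female", "unknown")
region_levels <- c("Americas", "Europe", "Asia", "Oceania", "Africa", "unknown")
serious_levels <- c("yes", "no", "unknown")
notifier_levels <- c(
  "physician", "pharmacist", "other health professional",
  "consumer/non-health professional", "lawyer", "unknown"
)
report_type_levels <- c("spontaneous", "from_study", "unknown")
drug_roles <- c("suspected", "interacting", "concomitant")

#' Nervous-system SOC label
#'
#' The system organ class used to define neurological adverse events.
#' @export
nervous_system_soc <- "Nervous system disorders"

#' Round half away from zero
#'
#' Published pharmacovigilance tables use conventional half-up rounding;
#' base R's `round()` rounds half to even, which disagrees at e.g. 2.465.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded, ties going away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
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
  force(expr)
}

# Validation error with a consistent class so callers (and the CLI) can
# distinguish bad input from bugs.
pv_abort <- function(msg, class = "pvsignal_validation_error") {
  rlang::abort(msg, class = class)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
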