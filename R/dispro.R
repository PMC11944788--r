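# Disproportionality statistics on 2x2 tables: proportional reporting ratio
# (PRR), reporting odds ratio (ROR), and the shrinkage information component
# (IC) of the BCPNN family, plus the joint signal rule
#   n >= 3  AND  PRR >= 2  AND  ROR >= 2  AND  IC interval lower bound >= 0.
#
# All three accept the tibble layout produced by build_tables() /
# reconstruct_marginal() (columns A, B, C, D, N) and are vectorised over rows.
# Cell counts may be non-integral (reconstructed tables).

#' Proportional reporting ratio
#'
#' PRR = \[A/(A+B)\] / \[C/(C+D)\] with the log-scale Wald 95% interval
#' `exp(log PRR -/+ 1.96 s)`, `s = sqrt(1/A - 1/(A+B) + 1/C - 1/(C+D))`.
#' With `C = 0` the statistic is undefined and flagged, not dropped; with
#' `A = 0` the point is 0 and no interval is produced.
#'
#' @param tables tibble with columns `A`, `B`, `C`, `D`.
#' @return tibble with columns `prr`, `prr_low`, `prr_high`, `prr_defined`.
#' @export
prr <- function(tables) {
  A <- tables$A; B <- tables$B; C <- tables$C; D <- tables$D
  defined <- (A + B) > 0 & (C + D) > 0 & C > 0
  point <- ifelse(defined, (A / (A + B)) / (C / (C + D)), NA_real_)
  point[defined & A == 0] <- 0
  s <- suppressWarnings(sqrt(1 / A - 1 / (A + B) + 1 / C - 1 / (C + D)))
  ok_ci <- defined & A > 0 & is.finite(s)
  tibble::tibble(
    prr = point,
    prr_low = ifelse(ok_ci, exp(log(point) - 1.96 * s), NA_real_),
    prr_high = ifelse(ok_ci, exp(log(point) + 1.96 * s), NA_real_),
    prr_defined = defined
  )
}

#' Reporting odds ratio
#'
#' ROR = (A/B) / (C/D) = AD/BC with the log-scale Wald 95% interval using
#' `s = sqrt(1/A + 1/B + 1/C + 1/D)`. A zero among `B`, `C`, `D` triggers the
#' Haldane-Anscombe continuity correction (0.5 added to all four cells),
#' flagged in `ror_corrected`.
#'
#' @param tables tibble with columns `A`, `B`, `C`, `D`.
#' @return tibble with columns `ror`, `ror_low`, `ror_high`, `ror_corrected`.
#' @export
ror <- function(tables) {
  A <- tables$A; B <- tables$B; C <- tables$C; D <- tables$D
  corrected <- B == 0 | C == 0 | D == 0
  A2 <- A + 0.5 * corrected; B2 <- B + 0.5 * corrected
  C2 <- C + 0.5 * corrected; D2 <- D + 0.5 * corrected
  point <- (A2 * D2) / (B2 * C2)
  s <- sqrt(1 / A2 + 1 / B2 + 1 / C2 + 1 / D2)
  ok_ci <- A2 > 0 & is.finite(s) & point > 0
  tibble::tibble(
    ror = point,
    ror_low = ifelse(ok_ci, exp(log(point) - 1.96 * s), NA_real_),
    ror_high = ifelse(ok_ci, exp(log(point) + 1.96 * s), NA_real_),
    ror_corrected = corrected
  )
}

#' Shrinkage information component
#'
#' IC = log2((A + 0.5) / (E + 0.5)) with expected count
#' E = (A+B)(A+C)/N - the observed-to-expected log-ratio with a +0.5
#' shrinkage on both terms that stabilises small counts (BCPNN family).
#' The 95% credibility interval is either the closed-form approximation
#'   low  = IC - 3.3 (A+0.5)^-1/2 - 2   (A+0.5)^-3/2
#'   high = IC + 2.4 (A+0.5)^-1/2 - 0.5 (A+0.5)^-3/2
#' or Monte-Carlo 2.5%/97.5% quantiles of log2 of a
#' Gamma(A + 0.5, rate = E + 0.5) posterior sample (seeded).
#'
#' @param tables tibble with columns `A`, `B`, `C`, `D`, `N`.
#' @param method `"approx"` (closed form, default) or `"mc"` (Monte Carlo).
#' @param nsim posterior draws per table for `method = "mc"`.
#' @param seed RNG seed for `method = "mc"`; the caller's RNG state is left
#'   untouched.
#' @return tibble with columns `ic`, `ic_low`, `ic_high`, `E`.
#' @export
ic <- function(tables, method = c("approx", "mc"), nsim = 10000, seed = 1L) {
  method <- match.arg(method)
  A <- tables$A
  E <- (tables$A + tables$B) * (tables$A + tables$C) / tables$N
  point <- log2((A + 0.5) / (E + 0.5))
  if (method == "approx") {
    low <- point - 3.3 * (A + 0.5)^(-0.5) - 2 * (A + 0.5)^(-1.5)
    high <- point + 2.4 * (A + 0.5)^(-0.5) - 0.5 * (A + 0.5)^(-1.5)
  } else {
    qs <- with_local_seed(seed, {
      vapply(seq_along(A), function(i) {
        draws <- log2(rgamma(nsim, shape = A[i] + 0.5, rate = E[i] + 0.5))
        quantile(draws, c(0.025, 0.975), names = FALSE)
      }, numeric(2))
    })
    low <- qs[1, ]
    high <- qs[2, ]
  }
  tibble::tibble(ic = point, ic_low = low, ic_high = high, E = E)
}

#' Signal thresholds
#'
#' The joint signal rule's tunable thresholds. Defaults: at least 3 reports,
#' PRR and ROR point estimates at least 2, IC interval lower bound at least 0.
#'
#' @param min_count minimum pair report count `n`.
#' @param min_prr minimum PRR point estimate.
#' @param min_ror minimum ROR point estimate.
#' @param min_ic_low minimum IC 95% interval lower bound (log2 units).
#' @return a named list of thresholds.
#' @export
signal_thresholds <- function(min_count = 3, min_prr = 2, min_ror = 2,
                              min_ic_low = 0) {
  list(min_count = min_count, min_prr = min_prr, min_ror = min_ror,
       min_ic_low = min_ic_low)
}

#' Classify drug-event pairs as signals
#'
#' TRUE iff all criteria hold simultaneously: `n >= min_count`,
#' `prr >= min_prr`, `ror >= min_ror`, `ic_low >= min_ic_low`. A pair with
#' any undefined component statistic is not a signal.
#'
#' @param results tibble with columns `n`, `prr`, `ror`, `ic_low`.
#' @param thresholds a [signal_thresholds()] list.
#' @return logical vector.
#' @export
classify_signal <- function(results, thresholds = signal_thresholds()) {
  with(results,
       !is.na(prr) & !is.na(ror) & !is.na(ic_low) &
         n >= thresholds$min_count &
         prr >= thresholds$min_prr &
         ror >= thresholds$min_ror &
         ic_low >= thresholds$min_ic_low)
}

signal_reason <- function(results, thresholds) {
  dplyr::case_when(
    is.na(results$prr) | is.na(results$ror) | is.na(results$ic_low) ~ "undefined_statistic",
    results$n < thresholds$min_count ~ "below_min_count",
    results$prr < thresholds$min_prr ~ "prr_below_threshold",
    results$ror < thresholds$min_ror ~ "ror_below_threshold",
    results$ic_low < thresholds$min_ic_low ~ "ic_lower_bound_below_threshold",
    TRUE ~ "signal"
  )
}

#' Compute all disproportionality statistics for a set of tables
#'
#' @param tables tibble from [build_tables()] or [reconstruct_marginal()].
#' @param thresholds a [signal_thresholds()] list.
#' @param ic_method interval method passed to [ic()].
#' @param ic_seed seed for the Monte-Carlo IC interval.
#' @return tibble: the input identifiers and cells plus `n`, the PRR/ROR/IC
#'   columns, `signal` and `reason`.
#' @export
dispro_stats <- function(tables, thresholds = signal_thresholds(),
                         ic_method = "approx", ic_seed = 1L) {
  out <- dplyr::bind_cols(
    tables,
    prr(tables),
    ror(tables),
    ic(tables, method = ic_method, seed = ic_seed)
  )
  out$n <- out$A
  out$signal <- classify_signal(out, thresholds)
  out$reason <- signal_reason(out, thresholds)
  out
}

#' Run a disproportionality analysis
#'
#' Builds all report-level 2x2 tables (optionally restricted to given drugs,
#' a drug role, or one system organ class), computes PRR, ROR and IC with
#' intervals, and applies the joint signal rule.
#'
#' @param x an `icsr_set`.
#' @param dict a `meddra_dictionary`; required when `soc_filter` is used.
#' @param drugs optional character vector of drugs of interest (`NULL`: all).
#' @param soc_filter optional SOC name, e.g. [nervous_system_soc], to
#'   restrict results to PTs whose primary SOC matches. PTs absent from the
#'   dictionary are dropped with a warning.
#' @param role optional drug role to restrict to (`"suspected"`,
#'   `"interacting"` or `"concomitant"`); default keeps all roles.
#' @param thresholds a [signal_thresholds()] list.
#' @param ic_method,ic_seed interval method and seed passed to [ic()].
#' @return tibble of per-pair results (one row per pair with `A >= 1`),
#'   with a `stratum` column (`"all"`).
#' @export
run_dispro <- function(x, dict = NULL, drugs = NULL, soc_filter = NULL,
                       role = NULL, thresholds = signal_thresholds(),
                       ic_method = "approx", ic_seed = 1L) {
  stopifnot(inherits(x, "icsr_set"))
  if (!is.null(role)) x <- filter_reports(x, role = role)
  tables <- build_tables(x, drugs = drugs)
  if (!is.null(soc_filter)) {
    if (is.null(dict)) pv_abort("soc_filter requires a dictionary")
    path <- primary_path(dict, tables$pt)
    unknown <- is.na(path$soc)
    if (any(unknown)) {
      warning(sum(unknown), " PT(s) absent from the dictionary dropped from ",
              "the SOC-filtered analysis", call. = FALSE)
    }
    tables <- tables[!unknown & path$soc == soc_filter, ]
  }
  out <- dispro_stats(tables, thresholds = thresholds,
                      ic_method = ic_method, ic_seed = ic_seed)
  out$stratum <- "all"
  out
}
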