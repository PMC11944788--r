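# Stratified disproportionality: recompute the 2x2 table and statistics for
# one drug-event pair within demographic strata. The analysis is fully
# stratified - both the drug and the comparator marginals are restricted to
# the stratum, so expected counts are stratum-specific. Reports with an
# unknown stratum value are excluded from the stratum rows but kept in "all".

#' Stratified disproportionality for one drug-event pair
#'
#' @param x an `icsr_set`.
#' @param drug drug of interest.
#' @param pt preferred term of interest.
#' @param axes stratification axes, a subset of `c("age", "sex")`.
#' @param thresholds a [signal_thresholds()] list.
#' @param ic_method,ic_seed interval method and seed passed to [ic()].
#' @return tibble of per-stratum results: an overall `"all"` row (axis
#'   `"none"`) followed by one row per age band (excluding `"unknown"`)
#'   and/or sex. An empty stratum yields a row with `n = 0` and undefined
#'   statistics, flagged in `reason`.
#' @export
stratified_dispro <- function(x, drug, pt, axes = c("age", "sex"),
                              thresholds = signal_thresholds(),
                              ic_method = "approx", ic_seed = 1L) {
  stopifnot(inherits(x, "icsr_set"))
  bad <- setdiff(axes, c("age", "sex"))
  if (length(bad)) {
    pv_abort(paste0("unknown axis: ", paste(bad, collapse = ", ")))
  }
  if (!drug %in% x$drugs$drug) pv_abort(paste0("drug not in data: ", drug))
  if (!pt %in% x$reactions$pt) pv_abort(paste0("pt not in data: ", pt))

  one <- function(sub, axis, stratum) {
    if (nrow(sub$reports) == 0) {
      res <- tibble::tibble(
        drug = drug, pt = pt, A = 0, B = 0, C = 0, D = 0, N = 0,
        prr = NA_real_, prr_low = NA_real_, prr_high = NA_real_,
        prr_defined = FALSE, ror = NA_real_, ror_low = NA_real_,
        ror_high = NA_real_, ror_corrected = FALSE, ic = NA_real_,
        ic_low = NA_real_, ic_high = NA_real_, E = NA_real_, n = 0,
        signal = FALSE, reason = "empty_stratum"
      )
    } else {
      tables <- build_tables(sub, drugs = drug, pts = pt)
      res <- dispro_stats(tables, thresholds = thresholds,
                          ic_method = ic_method, ic_seed = ic_seed)
    }
    res$axis <- axis
    res$stratum <- stratum
    res
  }

  out <- list(one(x, "none", "all"))
  if ("age" %in% axes) {
    bands <- age_band(x$reports$age_years)
    for (band in setdiff(age_band_levels(), "unknown")) {
      sub <- subset_reports(x, x$reports$report_id[bands == band])
      out[[length(out) + 1L]] <- one(sub, "age", band)
    }
  }
  if ("sex" %in% axes) {
    for (s in c("male", "female")) {
      sub <- subset_reports(x, x$reports$report_id[x$reports$sex == s])
      out[[length(out) + 1L]] <- one(sub, "sex", s)
    }
  }
  bind_rows(out)
}

#' Check stratum counts against the overall analysis
#'
#' For each axis, the stratum pair counts (which exclude unknown-stratum
#' reports) must sum to at most the overall `A`, with equality exactly when
#' no report has an unknown value on that axis. The difference is the pair
#' count carried by unknown-stratum reports.
#'
#' @param results tibble from [stratified_dispro()] for one (drug, pt) run.
#' @return tibble with one row per axis: `axis`, `strata_A`, `overall_A`,
#'   `unknown_A` (= overall - sum over strata) and `consistent`
#'   (`unknown_A >= 0`).
#' @export
stratum_consistency_check <- function(results) {
  if (nrow(results) == 0) {
    return(tibble::tibble(axis = character(), strata_A = numeric(),
                          overall_A = numeric(), unknown_A = numeric(),
                          consistent = logical()))
  }
  overall <- filter(results, .data$stratum == "all")
  if (nrow(overall) != 1) {
    pv_abort("results must contain exactly one 'all' row")
  }
  results %>%
    filter(.data$stratum != "all") %>%
    group_by(.data$axis) %>%
    summarise(strata_A = sum(.data$A), .groups = "drop") %>%
    mutate(
      overall_A = overall$A,
      unknown_A = .data$overall_A - .data$strata_A,
      consistent = .data$unknown_A >= 0
    )
}
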