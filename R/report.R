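# Reporting layer: demographic summary tables, formatted signal-table
# exports, and treemap node export for hierarchical signal visualisation.

#' Demographic summary for one drug's reports
#'
#' Tabulates the reports mentioning a drug by sex, age band, seriousness,
#' notifier, region, report year, report type and indication group, for all
#' of the drug's reports and for its neurological subset (reports listing at
#' least one PT whose primary SOC is the nervous-system SOC). Percentages
#' are of the respective totals, rounded half-up to 1 decimal.
#'
#' Single-valued axes partition the reports, so their counts sum to the
#' total; the indication axis does not (one report may carry indications in
#' several groups).
#'
#' @param x an `icsr_set`.
#' @param dict a `meddra_dictionary` (used to define the neurological subset;
#'   PTs absent from the dictionary count as non-neurological).
#' @param drug drug of interest.
#' @param indications_of_interest optional character vector defining the
#'   named indication group; remaining named indications fall in `"other"`,
#'   reports without indications in `"missing"`.
#' @return tibble with columns `axis`, `level`, `n_total`, `pct_total`,
#'   `n_neuro`, `pct_neuro`.
#' @export
demographic_summary <- function(x, dict, drug, indications_of_interest = NULL) {
  stopifnot(inherits(x, "icsr_set"))
  ids <- unique(x$drugs$report_id[x$drugs$drug == drug])
  if (length(ids) == 0) pv_abort(paste0("drug not in data: ", drug))
  sub <- subset_reports(x, ids)

  neuro_pt <- unique(sub$reactions$pt)
  neuro_pt <- neuro_pt[is_neurological(neuro_pt, dict, on_missing = "false")]
  neuro_ids <- unique(sub$reactions$report_id[sub$reactions$pt %in% neuro_pt])

  n_all <- nrow(sub$reports)
  n_neu <- length(neuro_ids)
  rep_tbl <- mutate(sub$reports,
                    age_band = age_band(.data$age_years),
                    year = ifelse(is.na(.data$year), "unknown",
                                  as.character(.data$year)),
                    neuro = .data$report_id %in% neuro_ids)

  one_axis <- function(field, levels) {
    vals <- rep_tbl[[field]]
    lv <- union(levels, unique(vals))
    lv <- lv[lv %in% vals | lv %in% levels]
    tibble::tibble(
      axis = field,
      level = lv,
      n_total = vapply(lv, function(l) sum(vals == l), numeric(1),
                       USE.NAMES = FALSE),
      n_neuro = vapply(lv, function(l) sum(vals == l & rep_tbl$neuro),
                       numeric(1), USE.NAMES = FALSE)
    )
  }
  axes <- bind_rows(
    one_axis("sex", sex_levels),
    one_axis("age_band", age_band_levels()),
    one_axis("serious", serious_levels),
    one_axis("notifier", notifier_levels),
    one_axis("region", region_levels),
    one_axis("year", sort(unique(rep_tbl$year))),
    one_axis("report_type", report_type_levels)
  )

  ind <- sub$indications
  of_interest_ids <- unique(ind$report_id[ind$indication %in%
                                            (indications_of_interest %||% character())])
  other_ids <- unique(ind$report_id[!ind$indication %in%
                                      (indications_of_interest %||% character())])
  missing_ids <- setdiff(sub$reports$report_id, unique(ind$report_id))
  ind_axis <- tibble::tibble(
    axis = "indication",
    level = c("of_interest", "other", "missing"),
    n_total = c(length(of_interest_ids), length(other_ids), length(missing_ids)),
    n_neuro = c(sum(of_interest_ids %in% neuro_ids),
                sum(other_ids %in% neuro_ids),
                sum(missing_ids %in% neuro_ids))
  )

  bind_rows(axes, ind_axis) %>%
    mutate(
      pct_total = round_half_up(100 * .data$n_total / n_all, 1),
      pct_neuro = if (n_neu > 0) round_half_up(100 * .data$n_neuro / n_neu, 1)
                  else 0,
      .after = "n_total"
    ) %>%
    select("axis", "level", "n_total", "pct_total", "n_neuro", "pct_neuro")
}

#' Export treemap nodes for detected signals
#'
#' Groups signal rows by their primary (SOC, HLGT) path. Node size is the
#' number of signals in the group, colour the total report count, matching
#' the usual treemap encoding for signal profiles.
#'
#' @param results a [run_dispro()] result tibble.
#' @param dict a `meddra_dictionary`.
#' @return tibble with columns `soc`, `hlgt`, `n_signals`, `n_reports`,
#'   ordered by descending `n_signals`, ties broken by label. Zero signals
#'   give an empty tibble with a warning.
#' @export
treemap_export <- function(results, dict) {
  sig <- filter(results, .data$signal)
  if (nrow(sig) == 0) {
    warning("no signals to export", call. = FALSE)
    return(tibble::tibble(soc = character(), hlgt = character(),
                          n_signals = integer(), n_reports = numeric()))
  }
  rollup(select(sig, "pt", n_reports = "n"), dict, level = "hlgt")
}

#' Write treemap nodes as JSON
#'
#' @param nodes tibble from [treemap_export()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_treemap_json <- function(nodes, path) {
  jsonlite::write_json(nodes, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Draw a treemap of signal nodes
#'
#' Best-effort slice-and-dice layout (SOC columns, HLGT tiles within each,
#' area proportional to the number of signals, fill mapped to the report
#' count). The node export is the tested artifact; this figure is a
#' convenience.
#'
#' @param nodes tibble from [treemap_export()].
#' @return a ggplot object.
#' @export
treemap_plot <- function(nodes) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    pv_abort("treemap_plot requires ggplot2")
  }
  if (nrow(nodes) == 0) pv_abort("no nodes to plot")
  total <- sum(nodes$n_signals)
  soc_tot <- nodes %>%
    group_by(.data$soc) %>%
    summarise(w = sum(.data$n_signals), .groups = "drop") %>%
    arrange(dplyr::desc(.data$w), .data$soc) %>%
    mutate(xmax = cumsum(.data$w) / total, xmin = dplyr::lag(.data$xmax, default = 0))
  rects <- nodes %>%
    inner_join(soc_tot, by = "soc") %>%
    arrange(.data$soc, dplyr::desc(.data$n_signals), .data$hlgt) %>%
    group_by(.data$soc) %>%
    mutate(ymax = cumsum(.data$n_signals) / .data$w,
           ymin = dplyr::lag(.data$ymax, default = 0)) %>%
    ungroup()
  ggplot2::ggplot(rects) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$n_reports),
                       colour = "white", linewidth = 0.6) +
    ggplot2::geom_text(ggplot2::aes(x = (.data$xmin + .data$xmax) / 2,
                                    y = (.data$ymin + .data$ymax) / 2,
                                    label = .data$hlgt),
                       size = 2.6, check_overlap = TRUE) +
    ggplot2::scale_fill_viridis_c(name = "reports") +
    ggplot2::theme_void() +
    ggplot2::labs(caption = "size: number of signals; colour: number of reports")
}

fmt_est_ci <- function(point, low, high) {
  ifelse(is.na(point), "",
         sprintf("%.2f (%.2f–%.2f)",
                 round_half_up(point, 2), round_half_up(low, 2),
                 round_half_up(high, 2)))
}

#' Write a formatted signal table
#'
#' One row per pair with both display columns ("3.42 (3.23-3.61)" style,
#' values rounded half-up to 2 decimals) and full-precision machine columns.
#' When a dictionary is given, the primary HLGT is included.
#'
#' @param results a [run_dispro()] or [stratified_dispro()] result tibble.
#' @param path output file path.
#' @param dict optional `meddra_dictionary` for the HLGT column.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(results, path, dict = NULL) {
  out <- results
  if (!is.null(dict)) {
    out$hlgt <- primary_path(dict, out$pt)$hlgt
  }
  out <- out %>%
    mutate(
      prr_fmt = fmt_est_ci(.data$prr, .data$prr_low, .data$prr_high),
      ror_fmt = fmt_est_ci(.data$ror, .data$ror_low, .data$ror_high),
      ic_fmt = fmt_est_ci(.data$ic, .data$ic_low, .data$ic_high)
    )
  front <- intersect(c("drug", "hlgt", "pt", "axis", "stratum", "n",
                       "prr_fmt", "ror_fmt", "ic_fmt", "signal", "reason"),
                     names(out))
  machine <- c("A", "B", "C", "D", "N", "prr", "prr_low", "prr_high",
               "ror", "ror_low", "ror_high", "ror_corrected",
               "ic", "ic_low", "ic_high", "E")
  readr::write_tsv(out[c(front, intersect(machine, names(out)))], path)
  invisible(path)
}

#' Write a demographic summary table
#'
#' @param summary tibble from [demographic_summary()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_demographics <- function(summary, path) {
  readr::write_tsv(summary, path)
  invisible(path)
}
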