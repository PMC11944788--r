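# Report-level 2x2 contingency tables for drug x adverse-event pairs, and
# reconstruction of a table from published summary statistics.
#
# Counting unit is the REPORT: a report listing a drug twice (two roles) or a
# PT twice still contributes exactly 1 to each cell, and A+B+C+D equals the
# number of reports for every table, so the database total N is shared by all
# tables from one dataset.

#' Build 2x2 tables for drug-event pairs
#'
#' For each (drug, PT) pair, `A` counts reports listing both, `B` reports
#' listing the drug without the PT, `C` reports listing the PT under other
#' drugs and `D` the remainder.
#'
#' @param x an `icsr_set`.
#' @param drugs optional character vector restricting the drugs considered;
#'   `NULL` means all drugs in the data.
#' @param pts optional character vector restricting the PTs; `NULL` means all.
#' @return tibble with columns `drug`, `pt`, `A`, `B`, `C`, `D`, `N`. Pairs
#'   with `A = 0` are emitted only when both `drugs` and `pts` are given
#'   explicitly (the full grid is then returned).
#' @export
build_tables <- function(x, drugs = NULL, pts = NULL) {
  stopifnot(inherits(x, "icsr_set"))
  N <- nrow(x$reports)
  if (N == 0) pv_abort("empty dataset: no reports to tabulate")

  drug_links <- distinct(x$drugs, .data$report_id, .data$drug)
  pt_links <- distinct(x$reactions, .data$report_id, .data$pt)
  if (!is.null(drugs)) drug_links <- filter(drug_links, .data$drug %in% drugs)
  if (!is.null(pts)) pt_links <- filter(pt_links, .data$pt %in% pts)

  n_drug <- count(drug_links, .data$drug, name = "n_drug")
  n_pt <- count(pt_links, .data$pt, name = "n_pt")
  a_counts <- drug_links %>%
    inner_join(pt_links, by = "report_id", relationship = "many-to-many") %>%
    count(.data$drug, .data$pt, name = "A")

  if (!is.null(drugs) && !is.null(pts)) {
    grid <- tidyr::expand_grid(drug = unique(drugs), pt = unique(pts))
    a_counts <- grid %>%
      left_join(a_counts, by = c("drug", "pt")) %>%
      mutate(A = tidyr::replace_na(.data$A, 0L))
  }

  a_counts %>%
    left_join(n_drug, by = "drug") %>%
    left_join(n_pt, by = "pt") %>%
    mutate(
      n_drug = tidyr::replace_na(.data$n_drug, 0L),
      n_pt = tidyr::replace_na(.data$n_pt, 0L),
      A = as.numeric(.data$A),
      B = .data$n_drug - .data$A,
      C = .data$n_pt - .data$A,
      D = N - .data$n_drug - .data$C,
      N = as.numeric(N)
    ) %>%
    select("drug", "pt", "A", "B", "C", "D", "N") %>%
    arrange(.data$drug, .data$pt)
}

#' Reconstruct a 2x2 table from published marginals and PRR
#'
#' Published disproportionality tables print the pair count `A`, the drug's
#' total report count, the database total and the PRR, but not the comparator
#' cell `C`. Inverting PRR = [A/(A+B)] / [C/(C+D)] gives
#' `C = (A/n_drug)/PRR * (N - n_drug)`, which determines the full table and
#' lets ROR and IC be recomputed from print. `C` is kept continuous by
#' default; inversion from a 2-decimal PRR is already approximate and
#' premature rounding compounds the error.
#'
#' @param A reports listing both drug and event.
#' @param n_drug total reports listing the drug (`A + B`).
#' @param N database total report count.
#' @param prr the published PRR point estimate.
#' @param drug,pt labels for the output row.
#' @param round_c round `C` to the nearest integer.
#' @return one-row tibble with columns `drug`, `pt`, `A`, `B`, `C`, `D`, `N`.
#' @export
reconstruct_marginal <- function(A, n_drug, N, prr, drug = "drug", pt = "event",
                                 round_c = FALSE) {
  if (!(A > 0 && A <= n_drug && n_drug < N)) {
    pv_abort("need 0 < A <= n_drug < N")
  }
  if (prr <= 0) pv_abort("prr must be positive")
  C <- (A / n_drug) / prr * (N - n_drug)
  if (round_c) C <- round(C)
  if (C > N - n_drug) {
    pv_abort(paste0("impossible PRR: implied C (", format(C),
                    ") exceeds the non-drug total (", N - n_drug, ")"))
  }
  tibble::tibble(drug = drug, pt = pt, A = as.numeric(A),
                 B = n_drug - as.numeric(A), C = C,
                 D = (N - n_drug) - C, N = as.numeric(N))
}

#' Export contingency tables as delimited text
#'
#' @param tables tibble from [build_tables()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tables <- function(tables, path) {
  readr::write_tsv(select(tables, "drug", "pt", "A", "B", "C", "D"), path)
  invisible(path)
}
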