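# Individual case safety reports: in-memory model, TSV I/O, demographic
# binning and predicate filtering.
#
# An `icsr_set` holds one ICSR dataset as four normalised tibbles:
#   reports     one row per report (report_id, sex, age_years, region,
#               serious, notifier, report_type, year)
#   drugs       one row per (report_id, drug, role)
#   reactions   one row per (report_id, pt)
#   indications one row per (report_id, indication), possibly empty
# The on-disk format is a flat long table, one row per report-drug-PT triple
# with report-level fields repeated (see `write_reports()`).

icsr_columns <- c(
  "report_id", "sex", "age_years", "region", "serious", "notifier",
  "report_type", "year", "drug", "role", "pt", "indication"
)

#' Assemble an ICSR dataset
#'
#' Builds a validated `icsr_set` from its component tables. Duplicate rows in
#' `drugs`, `reactions` and `indications` are collapsed (they are sets).
#'
#' @param reports tibble with columns `report_id`, `sex`, `age_years`,
#'   `region`, `serious`, `notifier`, `report_type`, `year`. Unknown
#'   categorical values are the literal `"unknown"`; unknown age/year are `NA`.
#' @param drugs tibble with columns `report_id`, `drug`, `role`
#'   (`suspected`, `interacting` or `concomitant`). Every report needs at
#'   least one drug.
#' @param reactions tibble with columns `report_id`, `pt` (MedDRA preferred
#'   term). Every report needs at least one reaction.
#' @param indications optional tibble with columns `report_id`, `indication`.
#' @return an `icsr_set`.
#' @export
icsr_set <- function(reports, drugs, reactions, indications = NULL) {
  reports <- tibble::as_tibble(reports)
  drugs <- dplyr::distinct(tibble::as_tibble(drugs))
  reactions <- dplyr::distinct(tibble::as_tibble(reactions))
  if (is.null(indications)) {
    indications <- tibble::tibble(report_id = character(), indication = character())
  }
  indications <- dplyr::distinct(tibble::as_tibble(indications))

  need <- c("report_id", "sex", "age_years", "region", "serious", "notifier",
            "report_type", "year")
  missing_cols <- setdiff(need, names(reports))
  if (length(missing_cols)) {
    pv_abort(paste0("reports is missing column(s): ",
                    paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(reports$report_id)) {
    pv_abort("report_id must be unique within a dataset")
  }
  check_vocab(reports$sex, sex_levels, "sex")
  check_vocab(reports$region, region_levels, "region")
  check_vocab(reports$serious, serious_levels, "serious")
  check_vocab(reports$notifier, notifier_levels, "notifier")
  check_vocab(reports$report_type, report_type_levels, "report_type")
  if (any(reports$age_years < 0, na.rm = TRUE)) {
    pv_abort("age_years must be nonnegative")
  }
  check_vocab(drugs$role, drug_roles, "role")
  if (nrow(reports)) {
    for (nm in c("drugs", "reactions")) {
      tab <- if (nm == "drugs") drugs else reactions
      orphans <- setdiff(reports$report_id, tab$report_id)
      if (length(orphans)) {
        pv_abort(paste0("every report needs at least one entry in ", nm,
                        "; missing for: ", paste(head(orphans, 5), collapse = ", ")))
      }
    }
  }
  for (nm in c("drugs", "reactions", "indications")) {
    tab <- switch(nm, drugs = drugs, reactions = reactions, indications = indications)
    stray <- setdiff(tab$report_id, reports$report_id)
    if (length(stray)) {
      pv_abort(paste0(nm, " references unknown report_id: ",
                      paste(head(stray, 5), collapse = ", ")))
    }
  }

  structure(
    list(reports = reports, drugs = drugs, reactions = reactions,
         indications = indications),
    class = "icsr_set"
  )
}

check_vocab <- function(x, levels, field) {
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad)) {
    pv_abort(paste0("invalid ", field, " value(s): ",
                    paste(head(bad, 5), collapse = ", "),
                    " (allowed: ", paste(levels, collapse = ", "), ")"))
  }
}

#' @export
print.icsr_set <- function(x, ...) {
  cat("<icsr_set> ", nrow(x$reports), " reports, ",
      dplyr::n_distinct(x$drugs$drug), " drugs, ",
      dplyr::n_distinct(x$reactions$pt), " preferred terms\n", sep = "")
  invisible(x)
}

#' Number of reports in a dataset
#' @param x an `icsr_set`.
#' @return integer count of distinct reports.
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "icsr_set"))
  nrow(x$reports)
}

# Restrict a dataset to a set of report ids, preserving order.
subset_reports <- function(x, ids) {
  keep <- x$reports$report_id %in% ids
  structure(
    list(
      reports = x$reports[keep, ],
      drugs = dplyr::filter(x$drugs, .data$report_id %in% ids),
      reactions = dplyr::filter(x$reactions, .data$report_id %in% ids),
      indications = dplyr::filter(x$indications, .data$report_id %in% ids)
    ),
    class = "icsr_set"
  )
}

#' Write an ICSR dataset as delimited text
#'
#' One row per report-drug-PT triple (the cartesian product of a report's
#' drugs and reactions), tab-separated, UTF-8, with report-level fields
#' repeated on every row. Unknown values are written as empty strings; a
#' report's indications are joined with `";"` into the `indication` column.
#'
#' @param x an `icsr_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(x, path) {
  stopifnot(inherits(x, "icsr_set"))
  ind <- x$indications %>%
    group_by(.data$report_id) %>%
    summarise(indication = paste(sort(.data$indication), collapse = ";"))
  long <- x$reports %>%
    inner_join(x$drugs, by = "report_id") %>%
    inner_join(x$reactions, by = "report_id", relationship = "many-to-many") %>%
    left_join(ind, by = "report_id") %>%
    arrange(.data$report_id, .data$drug, .data$role, .data$pt) %>%
    mutate(
      sex = ifelse(.data$sex == "unknown", "", .data$sex),
      region = ifelse(.data$region == "unknown", "", .data$region),
      serious = ifelse(.data$serious == "unknown", "", .data$serious),
      notifier = ifelse(.data$notifier == "unknown", "", .data$notifier),
      report_type = ifelse(.data$report_type == "unknown", "", .data$report_type),
      age_years = ifelse(is.na(.data$age_years), "", as.character(.data$age_years)),
      year = ifelse(is.na(.data$year), "", as.character(.data$year)),
      indication = ifelse(is.na(.data$indication), "", .data$indication)
    ) %>%
    select(dplyr::all_of(icsr_columns))
  readr::write_tsv(long, path, na = "")
  invisible(path)
}

#' Read an ICSR dataset from delimited text
#'
#' Reads the long format produced by [write_reports()]. Rows sharing a
#' `report_id` are merged into one report; duplicate (report, drug, PT) rows
#' collapse silently. Report-level fields must agree across a report's rows.
#'
#' @param path input file path.
#' @return an `icsr_set`.
#' @export
read_reports <- function(path) {
  if (!file.exists(path)) pv_abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  unknown_cols <- setdiff(names(raw), icsr_columns)
  if (length(unknown_cols)) {
    pv_abort(paste0("line 1: unknown column(s): ",
                    paste(unknown_cols, collapse = ", ")))
  }
  missing_cols <- setdiff(icsr_columns, names(raw))
  if (length(missing_cols)) {
    pv_abort(paste0("line 1: missing column(s): ",
                    paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) pv_abort("empty file: no data rows after the header")

  parse_int <- function(x, field) {
    x[x == ""] <- NA_character_
    out <- suppressWarnings(as.integer(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      pv_abort(paste0("line ", bad[1] + 1L, ": malformed ", field, ": '",
                      x[bad[1]], "'"))
    }
    out
  }
  blank_to_unknown <- function(x) ifelse(x == "", "unknown", x)

  raw <- raw %>%
    mutate(
      sex = blank_to_unknown(.data$sex),
      region = blank_to_unknown(.data$region),
      serious = blank_to_unknown(.data$serious),
      notifier = blank_to_unknown(.data$notifier),
      report_type = blank_to_unknown(.data$report_type),
      age_years = parse_int(.data$age_years, "age"),
      year = parse_int(.data$year, "year")
    )

  reports <- raw %>%
    distinct(.data$report_id, .data$sex, .data$age_years, .data$region,
             .data$serious, .data$notifier, .data$report_type, .data$year)
  dup <- reports$report_id[duplicated(reports$report_id)]
  if (length(dup)) {
    pv_abort(paste0("inconsistent report-level fields for report_id: ",
                    paste(unique(dup), collapse = ", ")))
  }
  drugs <- distinct(raw, .data$report_id, .data$drug, .data$role)
  reactions <- distinct(raw, .data$report_id, .data$pt)
  indications <- raw %>%
    distinct(.data$report_id, .data$indication) %>%
    filter(.data$indication != "") %>%
    tidyr::separate_longer_delim("indication", delim = ";") %>%
    mutate(indication = trimws(.data$indication)) %>%
    filter(.data$indication != "") %>%
    distinct()
  icsr_set(reports, drugs, reactions, indications)
}

#' Age-band labels
#'
#' The six bands used for stratified analysis, in display order.
#' @return character vector of band labels.
#' @export
age_band_levels <- function() {
  c("<18", "18–44", "45–64", "65–74", "≥75", "unknown")
}

#' Bin ages into bands
#'
#' Maps integer ages in years onto the bands `<18`, `18-44`, `45-64`,
#' `65-74`, `>=75`; `NA` maps to `"unknown"`. Boundaries are closed as
#' printed (18-44 includes both 18 and 44).
#'
#' @param age_years numeric vector of nonnegative ages, `NA` for unknown.
#' @return character vector of band labels.
#' @export
age_band <- function(age_years) {
  if (any(age_years < 0, na.rm = TRUE)) pv_abort("age_years must be nonnegative")
  lv <- age_band_levels()
  out <- rep(lv[6], length(age_years))
  known <- !is.na(age_years)
  a <- age_years[known]
  out[known] <- dplyr::case_when(
    a < 18 ~ lv[1],
    a <= 44 ~ lv[2],
    a <= 64 ~ lv[3],
    a <= 74 ~ lv[4],
    TRUE ~ lv[5]
  )
  out
}

#' Filter reports by demographic or drug-role predicates
#'
#' Keeps reports matching every supplied predicate, preserving order.
#' Allowed predicate names: `sex`, `age_band`, `role`, `report_type`.
#' A `role` predicate restricts each report's drug links to that role and
#' drops reports left with no drug of that role.
#'
#' @param x an `icsr_set`.
#' @param ... named predicates, each a character vector of accepted levels.
#' @return a filtered `icsr_set`.
#' @export
filter_reports <- function(x, ...) {
  stopifnot(inherits(x, "icsr_set"))
  preds <- list(...)
  allowed <- c("sex", "age_band", "role", "report_type")
  bad <- setdiff(names(preds), allowed)
  if (length(bad) || (length(preds) && is.null(names(preds)))) {
    pv_abort(paste0("unknown predicate key(s): ",
                    paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
                    " (allowed: ", paste(allowed, collapse = ", "), ")"))
  }
  keep <- x$reports$report_id
  if (!is.null(preds$sex)) {
    check_vocab(preds$sex, sex_levels, "sex")
    keep <- intersect(keep, x$reports$report_id[x$reports$sex %in% preds$sex])
  }
  if (!is.null(preds$age_band)) {
    check_vocab(preds$age_band, age_band_levels(), "age_band")
    bands <- age_band(x$reports$age_years)
    keep <- intersect(keep, x$reports$report_id[bands %in% preds$age_band])
  }
  if (!is.null(preds$report_type)) {
    check_vocab(preds$report_type, report_type_levels, "report_type")
    keep <- intersect(keep,
                      x$reports$report_id[x$reports$report_type %in% preds$report_type])
  }
  out <- subset_reports(x, keep)
  if (!is.null(preds$role)) {
    check_vocab(preds$role, drug_roles, "role")
    out$drugs <- filter(out$drugs, .data$role %in% preds$role)
    out <- subset_reports(out, unique(out$drugs$report_id))
  }
  out
}
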