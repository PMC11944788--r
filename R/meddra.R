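# Mock MedDRA-style hierarchy: PT -> HLT -> HLGT -> SOC with a primary-SOC
# designation per preferred term. A PT may appear under several SOCs
# (multi-axiality); classification and rollups always follow the primary path
# so each PT is counted once.

#' Build a MedDRA-style dictionary
#'
#' @param entries tibble with columns `pt`, `hlt`, `hlgt`, `soc`,
#'   `primary_flag` (`"yes"`/`"no"` or logical). Every PT must have exactly
#'   one primary entry.
#' @param version free-text version label.
#' @return a `meddra_dictionary`.
#' @export
meddra_dictionary <- function(entries, version = "mock") {
  entries <- dplyr::distinct(tibble::as_tibble(entries))
  need <- c("pt", "hlt", "hlgt", "soc", "primary_flag")
  missing_cols <- setdiff(need, names(entries))
  if (length(missing_cols)) {
    pv_abort(paste0("dictionary is missing column(s): ",
                    paste(missing_cols, collapse = ", ")))
  }
  if (is.character(entries$primary_flag)) {
    bad <- setdiff(unique(entries$primary_flag), c("yes", "no"))
    if (length(bad)) {
      pv_abort(paste0("primary_flag must be yes/no, got: ",
                      paste(bad, collapse = ", ")))
    }
    entries$primary_flag <- entries$primary_flag == "yes"
  }
  entries$pt_key <- pt_key(entries$pt)
  n_primary <- entries %>%
    group_by(.data$pt_key) %>%
    summarise(pt = .data$pt[1], n = sum(.data$primary_flag))
  offenders <- filter(n_primary, .data$n != 1L)
  if (nrow(offenders)) {
    pv_abort(paste0(
      "every PT needs exactly one primary SOC; offenders: ",
      paste(sprintf("%s (%d primary rows)", offenders$pt, offenders$n),
            collapse = ", ")
    ))
  }
  structure(list(entries = entries, version = version),
            class = "meddra_dictionary")
}

pt_key <- function(pt) tolower(trimws(pt))

#' @export
print.meddra_dictionary <- function(x, ...) {
  cat("<meddra_dictionary> version ", x$version, ": ",
      dplyr::n_distinct(x$entries$pt_key), " PTs, ",
      dplyr::n_distinct(x$entries$soc), " SOCs\n", sep = "")
  invisible(x)
}

#' Load a dictionary from delimited text
#'
#' Tab-separated with header `pt, hlt, hlgt, soc, primary_flag`. PT lookup
#' downstream is case-insensitive and whitespace-trimmed.
#'
#' @param path file path.
#' @param version version label; defaults to the file name.
#' @return a `meddra_dictionary`.
#' @export
load_dictionary <- function(path, version = NULL) {
  if (!file.exists(path)) pv_abort(paste0("file not found: ", path))
  entries <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                             na = character(), progress = FALSE)
  meddra_dictionary(entries, version = version %||% basename(path))
}

#' Bundled mock dictionary
#'
#' A small synthetic dictionary shipped with the package covering the
#' neurological preferred terms analysed in the worked examples plus
#' non-neurological decoys. Mock content, not licensed MedDRA.
#'
#' @return a `meddra_dictionary`.
#' @export
example_dictionary <- function() {
  load_dictionary(system.file("extdata", "meddra_mock.tsv", package = "pvsignal"),
                  version = "mock-26.1-synthetic")
}

# Primary hierarchy path for each requested PT (one row per input element;
# NA path for PTs absent from the dictionary).
primary_path <- function(dict, pts) {
  stopifnot(inherits(dict, "meddra_dictionary"))
  prim <- dict$entries %>%
    filter(.data$primary_flag) %>%
    select("pt_key", "hlt", "hlgt", "soc")
  tibble::tibble(pt = pts, pt_key = pt_key(pts)) %>%
    left_join(prim, by = "pt_key") %>%
    select(-"pt_key")
}

#' Is a preferred term neurological?
#'
#' TRUE iff the PT's primary SOC is the nervous-system SOC.
#'
#' @param pt character vector of preferred terms.
#' @param dict a `meddra_dictionary`.
#' @param on_missing `"error"` (default) to fail on PTs absent from the
#'   dictionary, `"false"` to classify them as non-neurological.
#' @return logical vector.
#' @export
is_neurological <- function(pt, dict, on_missing = c("error", "false")) {
  on_missing <- match.arg(on_missing)
  path <- primary_path(dict, pt)
  if (anyNA(path$soc)) {
    if (on_missing == "error") {
      pv_abort(paste0("PT(s) not in dictionary: ",
                      paste(unique(pt[is.na(path$soc)]), collapse = ", ")))
    }
    path$soc[is.na(path$soc)] <- ""
  }
  path$soc == nervous_system_soc
}

#' Roll signals up the hierarchy
#'
#' Groups per-PT signal rows by their primary path at the requested level and
#' totals signals and reports. Totals are conserved at every level.
#'
#' @param rows tibble with columns `pt` and `n_reports` (one row per signal
#'   PT; a `drug` column, if present, keeps distinct drugs' signals distinct).
#' @param dict a `meddra_dictionary`.
#' @param level `"soc"`, `"hlgt"` or `"hlt"`.
#' @return tibble of the grouping terms plus `n_signals` and `n_reports`,
#'   ordered by descending `n_signals` then label.
#' @export
rollup <- function(rows, dict, level = c("soc", "hlgt", "hlt")) {
  level <- match.arg(level)
  rows <- tibble::as_tibble(rows)
  if (!all(c("pt", "n_reports") %in% names(rows))) {
    pv_abort("rows must have columns pt and n_reports")
  }
  keys <- switch(level,
    soc = "soc",
    hlgt = c("soc", "hlgt"),
    hlt = c("soc", "hlgt", "hlt")
  )
  path <- primary_path(dict, rows$pt)
  if (anyNA(path$soc)) {
    pv_abort(paste0("PT(s) not in dictionary: ",
                    paste(unique(rows$pt[is.na(path$soc)]), collapse = ", ")))
  }
  joined <- dplyr::bind_cols(rows[setdiff(names(rows), keys)],
                             path[keys])
  label <- keys[length(keys)]
  joined %>%
    group_by(across(dplyr::all_of(keys))) %>%
    summarise(n_signals = dplyr::n(), n_reports = sum(.data$n_reports),
              .groups = "drop") %>%
    arrange(dplyr::desc(.data$n_signals), .data[[label]])
}
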