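# Synthetic ICSR generator. Emulates the structure of a large spontaneous
# reporting database - many drugs crossed with many preferred terms,
# report-level multiplicity of both, demographic mixtures with first-class
# "unknown" categories - with planted drug-event associations of known
# reporting-rate ratio, so every downstream stage can be tested against
# ground truth.
#
# Generative model, per report:
#   * demographics drawn independently from the configured categorical
#     distributions; age drawn as an integer uniformly within its band;
#   * each drug present independently with its marginal probability;
#   * each PT present independently with probability
#     min(1, background * prod(rho over present associated drugs));
#   * reports drawing zero drugs or zero PTs are re-drawn (every ICSR names
#     at least one drug and one reaction);
#   * the lowest-indexed drug on a report is "suspected"; other drug links
#     draw a role from `role_probs`.

#' Configuration for the synthetic generator
#'
#' @param n_reports number of reports to generate.
#' @param drugs named numeric vector: per-drug marginal probability that a
#'   report mentions the drug.
#' @param events named numeric vector: per-PT background probability that a
#'   report lists the PT.
#' @param associations optional tibble with columns `drug`, `pt`, `rho`
#'   (reporting-rate ratio >= 0 multiplying the PT's background probability
#'   in reports mentioning the drug). Pairs not listed have rho = 1 (null).
#' @param demographics named list of categorical distributions (each a named
#'   numeric vector summing to 1) for `sex`, `age_band`, `region`, `serious`,
#'   `notifier`, `report_type`, `year`. Defaults: [default_demographics()].
#' @param max_pts_per_report cap on reactions per report; reports drawing
#'   more keep a random subset of this size.
#' @param role_probs distribution over drug roles for non-first drug links.
#' @param seed RNG seed; identical seeds give identical datasets.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_reports, drugs, events, associations = NULL,
                         demographics = default_demographics(),
                         max_pts_per_report = 10L,
                         role_probs = c(suspected = 0.70, interacting = 0.05,
                                        concomitant = 0.25),
                         seed = 1L) {
  if (!is.numeric(n_reports) || length(n_reports) != 1 || n_reports < 1) {
    pv_abort("n_reports must be a positive integer")
  }
  check_probs <- function(p, field, named_over = NULL) {
    if (length(p) == 0) pv_abort(paste0(field, " must be nonempty"))
    if (is.null(names(p)) || any(names(p) == "")) {
      pv_abort(paste0(field, " must be a fully named numeric vector"))
    }
    if (anyDuplicated(names(p))) pv_abort(paste0(field, " has duplicate names"))
    if (any(p < 0 | p > 1) || anyNA(p)) {
      pv_abort(paste0(field, ": probabilities must be in [0, 1]"))
    }
    if (!is.null(named_over)) {
      bad <- setdiff(names(p), named_over)
      if (length(bad)) {
        pv_abort(paste0(field, ": unknown level(s) ", paste(bad, collapse = ", ")))
      }
      if (abs(sum(p) - 1) > 1e-9) {
        pv_abort(paste0(field, " must sum to 1 (got ", format(sum(p)), ")"))
      }
    }
    invisible(p)
  }
  check_probs(drugs, "drugs")
  check_probs(events, "events")
  demo_levels <- list(
    sex = sex_levels, age_band = age_band_levels(), region = region_levels,
    serious = serious_levels, notifier = notifier_levels,
    report_type = report_type_levels, year = NULL
  )
  for (ax in names(demo_levels)) {
    if (is.null(demographics[[ax]])) {
      pv_abort(paste0("demographics is missing the '", ax, "' distribution"))
    }
    check_probs(demographics[[ax]], paste0("demographics$", ax),
                named_over = demo_levels[[ax]] %||% names(demographics[[ax]]))
  }
  if (abs(sum(demographics$year) - 1) > 1e-9) {
    pv_abort("demographics$year must sum to 1")
  }
  if (!is.null(associations)) {
    associations <- tibble::as_tibble(associations)
    need <- c("drug", "pt", "rho")
    if (!all(need %in% names(associations))) {
      pv_abort("associations needs columns drug, pt, rho")
    }
    if (any(associations$rho < 0)) pv_abort("associations: rho must be >= 0")
    bad_drug <- setdiff(associations$drug, names(drugs))
    bad_pt <- setdiff(associations$pt, names(events))
    if (length(bad_drug) || length(bad_pt)) {
      pv_abort(paste0("associations reference unknown drug/pt: ",
                      paste(c(bad_drug, bad_pt), collapse = ", ")))
    }
  }
  check_probs(role_probs, "role_probs", named_over = drug_roles)
  if (max_pts_per_report < 1) pv_abort("max_pts_per_report must be positive")
  structure(
    list(n_reports = as.integer(n_reports), drugs = drugs, events = events,
         associations = associations, demographics = demographics,
         max_pts_per_report = as.integer(max_pts_per_report),
         role_probs = role_probs, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Default demographic mixture
#'
#' Categorical distributions modelled on the demographic profile of adverse
#' event reporting for a widely reported oral immunomodulator: predominantly
#' female, middle-aged, from the Americas, spontaneously reported by
#' consumers, with sizeable "unknown" fractions for age and sex.
#'
#' @return named list of named probability vectors.
#' @export
default_demographics <- function() {
  norm <- function(x) x / sum(x)
  list(
    sex = norm(c(male = 19933, female = 82018, unknown = 3847)),
    age_band = norm(setNames(
      c(388, 10326, 43264, 21802, 10299, 19719), age_band_levels())),
    region = norm(c(Americas = 97351, Europe = 5700, Asia = 2155,
                    Oceania = 559, Africa = 33, unknown = 0)),
    serious = norm(c(yes = 33052, no = 72405, unknown = 341)),
    notifier = norm(c(
      "physician" = 24507, "pharmacist" = 3639,
      "other health professional" = 22534,
      "consumer/non-health professional" = 53971,
      "lawyer" = 66, "unknown" = 1081)),
    report_type = norm(c(spontaneous = 101750, from_study = 3650,
                         unknown = 398)),
    year = norm(setNames(
      c(2323, 5093, 5769, 11717, 20083, 25297, 17261, 17293, 962),
      c("2012", "2015", "2016", "2017", "2018", "2019", "2020", "2021", "2022")))
  )
}

# Uniform integer age within a band label; NA for "unknown".
age_from_band <- function(bands) {
  n <- length(bands)
  lv <- age_band_levels()
  lo <- c(0L, 18L, 45L, 65L, 75L)[match(bands, lv[1:5])]
  hi <- c(17L, 44L, 64L, 74L, 90L)[match(bands, lv[1:5])]
  out <- rep(NA_integer_, n)
  known <- !is.na(lo)
  out[known] <- lo[known] +
    as.integer(floor(runif(sum(known)) * (hi[known] - lo[known] + 1L)))
  out
}

#' Generate a synthetic ICSR dataset
#'
#' @param config a [synth_config()].
#' @return an `icsr_set` with exactly `config$n_reports` reports, each
#'   listing at least one drug and one reaction.
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(config$seed, generate_reports_impl(config))
}

generate_reports_impl <- function(config) {
  n <- config$n_reports
  drug_names <- names(config$drugs)
  pt_names <- names(config$events)
  J <- length(drug_names)
  K <- length(pt_names)

  draw_cat <- function(dist, n) sample(names(dist), n, replace = TRUE, prob = dist)
  demo <- config$demographics
  reports <- tibble::tibble(
    report_id = sprintf("R%07d", seq_len(n)),
    sex = draw_cat(demo$sex, n),
    age_years = age_from_band(draw_cat(demo$age_band, n)),
    region = draw_cat(demo$region, n),
    serious = draw_cat(demo$serious, n),
    notifier = draw_cat(demo$notifier, n),
    report_type = draw_cat(demo$report_type, n),
    year = suppressWarnings(as.integer(draw_cat(demo$year, n)))
  )

  # Drug presence: n x J Bernoulli; re-draw all-zero rows.
  draw_drugs <- function(m) {
    matrix(runif(m * J) < rep(config$drugs, each = m), nrow = m)
  }
  drug_mat <- draw_drugs(n)
  repeat {
    empty <- which(rowSums(drug_mat) == 0L)
    if (!length(empty)) break
    drug_mat[empty, ] <- draw_drugs(length(empty))
  }

  # PT presence given drugs: background prob scaled by planted rate ratios.
  pt_prob_rows <- function(rows) {
    p <- matrix(rep(config$events, each = length(rows)), nrow = length(rows))
    if (!is.null(config$associations)) {
      assoc <- config$associations
      for (i in seq_len(nrow(assoc))) {
        j <- match(assoc$drug[i], drug_names)
        k <- match(assoc$pt[i], pt_names)
        has_drug <- drug_mat[rows, j]
        p[has_drug, k] <- pmin(1, p[has_drug, k] * assoc$rho[i])
      }
    }
    p
  }
  draw_pts <- function(rows) {
    p <- pt_prob_rows(rows)
    matrix(runif(length(rows) * K) < p, nrow = length(rows))
  }
  pt_mat <- draw_pts(seq_len(n))
  repeat {
    empty <- which(rowSums(pt_mat) == 0L)
    if (!length(empty)) break
    pt_mat[empty, ] <- draw_pts(empty)
  }

  # Cap reactions per report: keep a random subset where the draw overflows.
  overflow <- which(rowSums(pt_mat) > config$max_pts_per_report)
  for (i in overflow) {
    present <- which(pt_mat[i, ])
    keep <- sample(present, config$max_pts_per_report)
    pt_mat[i, ] <- FALSE
    pt_mat[i, keep] <- TRUE
  }

  drug_idx <- which(drug_mat, arr.ind = TRUE)
  drug_links <- tibble::tibble(
    report_id = reports$report_id[drug_idx[, 1]],
    drug = drug_names[drug_idx[, 2]],
    col = drug_idx[, 2]
  ) %>% arrange(.data$report_id, .data$col)
  first <- !duplicated(drug_links$report_id)
  roles <- draw_cat(config$role_probs, nrow(drug_links))
  roles[first] <- "suspected"
  drug_links <- tibble::tibble(report_id = drug_links$report_id,
                               drug = drug_links$drug, role = roles)

  pt_idx <- which(pt_mat, arr.ind = TRUE)
  reactions <- tibble::tibble(
    report_id = reports$report_id[pt_idx[, 1]],
    pt = pt_names[pt_idx[, 2]]
  ) %>% arrange(.data$report_id, .data$pt)

  icsr_set(reports, drug_links, reactions)
}

#' Empirical reporting-rate ratio for one pair
#'
#' The rate of `pt` among reports mentioning `drug` divided by its rate among
#' reports not mentioning `drug` - the ground-truth check for a planted
#' association (approximately rho when the drug is rare).
#'
#' @param x an `icsr_set`.
#' @param drug,pt the pair to evaluate.
#' @return nonnegative number.
#' @export
empirical_rate_ratio <- function(x, drug, pt) {
  stopifnot(inherits(x, "icsr_set"))
  if (nrow(x$reports) == 0) pv_abort("empty dataset")
  with_drug <- unique(x$drugs$report_id[x$drugs$drug == drug])
  without <- setdiff(x$reports$report_id, with_drug)
  if (length(without) == 0) {
    pv_abort(paste0("division impossible: no report lacks drug ", drug))
  }
  with_pt <- unique(x$reactions$report_id[x$reactions$pt == pt])
  r1 <- mean(with_drug %in% with_pt)
  r0 <- mean(without %in% with_pt)
  if (r0 == 0) {
    pv_abort(paste0("division impossible: ", pt,
                    " never reported without ", drug))
  }
  r1 / r0
}

#' Read a generator configuration from YAML
#'
#' Key names match [synth_config()]'s arguments; `drugs` and `events` are
#' maps from name to probability, `associations` a list of
#' `{drug, pt, rho}` maps.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's.
#' @return a `synth_config`.
#' @export
read_synth_config <- function(path, seed = NULL) {
  if (!file.exists(path)) pv_abort(paste0("file not found: ", path))
  y <- yaml::read_yaml(path)
  as_named <- function(x) unlist(x)
  assoc <- NULL
  if (!is.null(y$associations)) {
    assoc <- dplyr::bind_rows(lapply(y$associations, tibble::as_tibble))
    assoc$rho <- as.numeric(assoc$rho)
  }
  demographics <- if (is.null(y$demographics)) default_demographics() else
    lapply(y$demographics, as_named)
  synth_config(
    n_reports = y$n_reports,
    drugs = as_named(y$drugs),
    events = as_named(y$events),
    associations = assoc,
    demographics = demographics,
    max_pts_per_report = y$max_pts_per_report %||% 10L,
    seed = seed %||% y$seed %||% 1L
  )
}
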