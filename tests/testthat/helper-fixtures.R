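# Fixture builders and independent oracles shared across the suite.

# Build a small icsr_set from a compact spec: a list of lists with fields
# id, drugs (character), pts (character), and optional demographics.
tiny_icsr <- function(specs) {
  defaults <- list(sex = "female", age = 50L, region = "Americas",
                   serious = "no", notifier = "physician",
                   report_type = "spontaneous", year = 2020L)
  reports <- dplyr::bind_rows(lapply(specs, function(s) {
    tibble::tibble(
      report_id = s$id,
      sex = s$sex %||% defaults$sex,
      age_years = if (is.null(s$age)) defaults$age else
        (if (is.na(s$age)) NA_integer_ else as.integer(s$age)),
      region = s$region %||% defaults$region,
      serious = s$serious %||% defaults$serious,
      notifier = s$notifier %||% defaults$notifier,
      report_type = s$report_type %||% defaults$report_type,
      year = as.integer(s$year %||% defaults$year)
    )
  }))
  drugs <- dplyr::bind_rows(lapply(specs, function(s) {
    roles <- s$roles %||% rep("suspected", length(s$drugs))
    tibble::tibble(report_id = s$id, drug = s$drugs, role = roles)
  }))
  reactions <- dplyr::bind_rows(lapply(specs, function(s) {
    tibble::tibble(report_id = s$id, pt = s$pts)
  }))
  indications <- dplyr::bind_rows(lapply(specs, function(s) {
    if (is.null(s$indications)) return(NULL)
    tibble::tibble(report_id = s$id, indication = s$indications)
  }))
  if (nrow(indications) == 0) indications <- NULL
  icsr_set(reports, drugs, reactions, indications)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force 2x2 oracle: explicit double loop over reports x pairs,
# independent of the join-based implementation.
brute_force_tables <- function(x, drugs = NULL, pts = NULL) {
  drug_sets <- lapply(split(x$drugs$drug, x$drugs$report_id), unique)
  pt_sets <- lapply(split(x$reactions$pt, x$reactions$report_id), unique)
  ids <- x$reports$report_id
  all_drugs <- sort(unique(unlist(drug_sets)))
  all_pts <- sort(unique(unlist(pt_sets)))
  if (is.null(drugs)) drugs <- all_drugs
  if (is.null(pts)) pts <- all_pts
  out <- list()
  for (d in drugs) {
    for (p in pts) {
      A <- B <- C <- D <- 0
      for (id in ids) {
        has_d <- d %in% drug_sets[[id]]
        has_p <- p %in% pt_sets[[id]]
        if (has_d && has_p) A <- A + 1
        else if (has_d) B <- B + 1
        else if (has_p) C <- C + 1
        else D <- D + 1
      }
      out[[length(out) + 1]] <- tibble::tibble(
        drug = d, pt = p, A = A, B = B, C = C, D = D,
        N = as.numeric(length(ids)))
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), drug, pt)
}

# A medium synthetic dataset for oracle comparisons.
oracle_dataset <- function(n = 200, seed = 101) {
  cfg <- synth_config(
    n_reports = n,
    drugs = c(alpha = 0.35, beta = 0.25, gamma = 0.15, delta = 0.4),
    events = c(P1 = 0.2, P2 = 0.15, P3 = 0.1, P4 = 0.25, P5 = 0.05),
    associations = data.frame(drug = "alpha", pt = "P3", rho = 4),
    seed = seed
  )
  generate_reports(cfg)
}

# The published neurological signal rows for the most-reported drug in the
# worked example (PT and report count), used as rollup inputs.
tofa_signal_rows <- function() {
  tibble::tribble(
    ~pt, ~n_reports,
    "Memory impairment", 1275,
    "Dementia", 159,
    "Dementia Alzheimer's type", 50,
    "Dysstasia", 232,
    "Dysgraphia", 80,
    "Cerebral disorder", 40,
    "Post-herpetic neuralgia", 35,
    "Dyslexia", 18,
    "Tinel's sign", 3,
    "Movement disorder", 315,
    "Fine motor skill dysfunction", 28,
    "Bradykinesia", 27,
    "Essential tremor", 8,
    "Carpal tunnel syndrome", 179,
    "Nerve compression", 134,
    "Sciatic nerve neuropathy", 10,
    "Sciatica", 172,
    "Spinal cord compression", 18,
    "Spinal cord disorder", 9,
    "Radicular pain", 9,
    "Sinus headache", 71,
    "Cold-stimulus headache", 6,
    "Intracranial aneurysm", 21,
    "Amyotrophic lateral sclerosis", 12
  )
}

# Delta-method standard error of log of a ratio of two binomial proportions.
log_ratio_se <- function(p1, n1, p0, n0) {
  sqrt((1 - p1) / (n1 * p1) + (1 - p0) / (n0 * p0))
}

# Background drugs/events so that conditioning on >=1 drug and >=1 reaction
# almost never triggers a re-draw.
padded_config <- function(n, drugs, events, associations = NULL, seed = 1) {
  bg_drugs <- setNames(rep(0.4, 3), paste0("bgdrug", 1:3))
  bg_events <- setNames(rep(0.12, 20), sprintf("bgpt%02d", 1:20))
  synth_config(n, c(drugs, bg_drugs), c(events, bg_events),
               associations = associations, seed = seed)
}
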