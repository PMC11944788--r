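# Combine two generated datasets into one (re-keyed report ids); used to
# plant stratum-specific effects.
bind_icsr <- function(a, b) {
  rekey <- function(x, prefix) {
    for (nm in c("reports", "drugs", "reactions", "indications")) {
      x[[nm]]$report_id <- paste0(prefix, x[[nm]]$report_id)
    }
    x
  }
  a <- rekey(a, "A"); b <- rekey(b, "B")
  icsr_set(dplyr::bind_rows(a$reports, b$reports),
           dplyr::bind_rows(a$drugs, b$drugs),
           dplyr::bind_rows(a$reactions, b$reactions),
           dplyr::bind_rows(a$indications, b$indications))
}

demo_with_ages <- function(bands_probs) {
  d <- default_demographics()
  d$age_band <- bands_probs
  d
}

test_that("an all-female dataset collapses the sex strata", {
  x <- tiny_icsr(lapply(1:20, function(i) {
    list(id = paste0("R", i), drugs = if (i <= 10) "drugx" else "other",
         pts = if (i %% 2 == 0) "pt1" else "pt2", sex = "female")
  }))
  res <- stratified_dispro(x, "drugx", "pt1", axes = "sex")
  all_row <- dplyr::filter(res, stratum == "all")
  female <- dplyr::filter(res, stratum == "female")
  expect_equal(female[c("A", "B", "C", "D", "prr", "ror", "ic")],
               all_row[c("A", "B", "C", "D", "prr", "ror", "ic")])
  male <- dplyr::filter(res, stratum == "male")
  expect_equal(male$n, 0)
  expect_equal(male$reason, "empty_stratum")
  expect_false(male$signal)
})

test_that("stratum tables match brute-force per-stratum counting", {
  x <- oracle_dataset(n = 300, seed = 404)
  res <- stratified_dispro(x, "alpha", "P3")
  for (band in setdiff(age_band_levels(), "unknown")) {
    sub <- x
    keep <- x$reports$report_id[age_band(x$reports$age_years) == band]
    sub$reports <- dplyr::filter(sub$reports, report_id %in% keep)
    sub$drugs <- dplyr::filter(sub$drugs, report_id %in% keep)
    sub$reactions <- dplyr::filter(sub$reactions, report_id %in% keep)
    want <- brute_force_tables(sub, drugs = "alpha", pts = "P3")
    got <- dplyr::filter(res, axis == "age", stratum == band)
    expect_equal(got[c("A", "B", "C", "D")], want[c("A", "B", "C", "D")],
                 ignore_attr = TRUE)
    expect_equal(got$N, nrow(sub$reports))
  }
})

test_that("a stratum-specific planted effect is flagged only in its stratum", {
  old <- padded_config(10000, drugs = c(drugx = 0.08), events = c(pty = 0.02),
                       associations = data.frame(drug = "drugx", pt = "pty",
                                                 rho = 5),
                       seed = 31)
  old$demographics <- demo_with_ages(setNames(c(0, 0, 0, 0, 1, 0),
                                              age_band_levels()))
  young <- padded_config(10000, drugs = c(drugx = 0.08), events = c(pty = 0.02),
                         seed = 32)
  young$demographics <- demo_with_ages(setNames(c(0, 1, 0, 0, 0, 0),
                                                age_band_levels()))
  x <- bind_icsr(generate_reports(old), generate_reports(young))
  res <- stratified_dispro(x, "drugx", "pty", axes = "age")
  elderly <- dplyr::filter(res, stratum == "≥75")
  expect_gte(elderly$A, 30)
  expect_true(elderly$signal)
  expect_false(dplyr::filter(res, stratum == "18–44")$signal)
})

test_that("stratum pair counts partition the overall count", {
  for (seed in c(1, 2, 3)) {
    x <- oracle_dataset(n = 250, seed = seed)
    res <- stratified_dispro(x, "alpha", "P1")
    chk <- stratum_consistency_check(res)
    expect_true(all(chk$consistent))
    # known ages in oracle_dataset may include unknowns from the default mix
    unknown_ids <- x$reports$report_id[is.na(x$reports$age_years)]
    pair_ids <- intersect(
      x$drugs$report_id[x$drugs$drug == "alpha"],
      x$reactions$report_id[x$reactions$pt == "P1"]
    )
    age_row <- dplyr::filter(chk, axis == "age")
    expect_equal(age_row$unknown_A, length(intersect(pair_ids, unknown_ids)))
    expect_equal(age_row$strata_A + age_row$unknown_A, age_row$overall_A)
  }
})

test_that("consistency is exact when no stratum value is unknown", {
  x <- tiny_icsr(lapply(1:30, function(i) {
    list(id = paste0("R", i), drugs = if (i %% 3 == 0) "drugx" else "other",
         pts = "pt1", age = c(20, 50, 80)[1 + (i %% 3)],
         sex = c("male", "female")[1 + (i %% 2)])
  }))
  res <- stratified_dispro(x, "drugx", "pt1")
  chk <- stratum_consistency_check(res)
  expect_true(all(chk$unknown_A == 0))
  expect_true(all(chk$strata_A == chk$overall_A))
})

test_that("an empty result set yields an empty consistency report", {
  empty <- stratum_consistency_check(tibble::tibble())
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("axis", "strata_A", "overall_A", "unknown_A",
                        "consistent"))
})

test_that("unknown stratum axes and absent pairs are rejected", {
  x <- oracle_dataset(50, seed = 9)
  expect_error(stratified_dispro(x, "alpha", "P1", axes = "region"),
               "unknown axis")
  expect_error(stratified_dispro(x, "nodrug", "P1"), "drug not in data")
})
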