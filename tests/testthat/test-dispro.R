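tbl <- function(A, B, C, D) tibble::tibble(A = A, B = B, C = C, D = D,
                                           N = A + B + C + D)

# random strictly-positive tables for property checks
random_tables <- function(n, seed) {
  set.seed(seed)
  tbl(sample(1:500, n, TRUE), sample(1:5000, n, TRUE),
      sample(1:5000, n, TRUE), sample(1:50000, n, TRUE))
}

test_that("equal reporting proportions give PRR and ROR of 1", {
  expect_equal(prr(tbl(10, 990, 100, 9900))$prr, 1)
  r <- ror(tbl(5, 5, 5, 5))
  expect_equal(r$ror, 1)
  expect_false(r$ror_corrected)
})

test_that("the degenerate all-cells-tied table yields a collapsed interval", {
  p <- prr(tbl(1, 0, 1, 0))
  expect_equal(p$prr, 1)
  expect_equal(p$prr_low, 1)
  expect_equal(p$prr_high, 1)
})

test_that("undefined and zero cells are flagged, not dropped", {
  p <- prr(tbl(5, 5, 0, 10))
  expect_false(p$prr_defined)
  expect_true(is.na(p$prr))
  p0 <- prr(tbl(0, 10, 5, 5))
  expect_equal(p0$prr, 0)
  expect_true(is.na(p0$prr_low))
  r <- ror(tbl(3, 0, 2, 10))
  expect_true(r$ror_corrected)
  expect_equal(r$ror, (3.5 * 10.5) / (0.5 * 2.5))
})

test_that("ROR equals PRR times the odds correction factor", {
  t <- random_tables(200, seed = 31)
  lhs <- ror(t)$ror
  rhs <- prr(t)$prr * (1 - t$C / (t$C + t$D)) / (1 - t$A / (t$A + t$B))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("shrinkage pulls the IC toward zero without changing its side", {
  t <- random_tables(200, seed = 32)
  res <- ic(t)
  plain <- log2(t$A / res$E)
  same_side <- (t$A / res$E > 1) == ((t$A + 0.5) / (res$E + 0.5) > 1)
  expect_true(all(abs(res$ic[same_side]) <= abs(plain[same_side])))
  expect_true(all(sign(res$ic[same_side]) == sign(plain[same_side]) |
                    plain[same_side] == 0))
  # the observed-equals-expected point sits at zero
  expect_equal(ic(tbl(10, 90, 10, 90))$ic, 0)
})

test_that("PRR, ROR and IC increase strictly with A at fixed B, C, D", {
  A <- 1:60
  t <- tbl(A, 400, 700, 90000)
  expect_true(all(diff(prr(t)$prr) > 0))
  expect_true(all(diff(ror(t)$ror) > 0))
  expect_true(all(diff(ic(t)$ic) > 0))
})

test_that("Monte-Carlo and closed-form IC intervals agree for common pairs", {
  t <- tbl(c(50, 120, 400, 1275), c(500, 1000, 5000, 104523),
           c(600, 2000, 9000, 105520), c(60000, 150000, 400000, 29839841))
  a <- ic(t, method = "approx")
  m <- ic(t, method = "mc", nsim = 200000, seed = 99)
  expect_equal(a$ic, m$ic)
  expect_lt(max(abs(a$ic_low - m$ic_low)), 0.05)
  expect_lt(max(abs(a$ic_high - m$ic_high)), 0.05)
  # seeded: repeatable, and the caller's RNG is untouched
  set.seed(1); before <- .Random.seed
  m2 <- ic(t, method = "mc", nsim = 200000, seed = 99)
  expect_identical(m$ic_low, m2$ic_low)
  expect_identical(before, .Random.seed)
})

test_that("the joint rule requires every criterion simultaneously", {
  res <- tibble::tibble(
    n = c(48, 1275, 2, 100, 100, 100),
    prr = c(1.13, 3.42, 50, 1.9, 2.5, 2.5),
    ror = c(1.13, 3.44, 50, 2.5, 1.9, 2.5),
    ic_low = c(-0.27, 1.68, 3, 0.5, 0.5, -0.01)
  )
  expect_equal(classify_signal(res),
               c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # thresholds are overridable
  loose <- signal_thresholds(min_count = 1, min_prr = 1, min_ror = 1,
                             min_ic_low = -1)
  expect_true(all(classify_signal(res, loose)))
  # undefined components are never signals
  res$prr[2] <- NA
  expect_false(classify_signal(res)[2])
})

test_that("a full run flags the planted pair and survives degenerate input", {
  cfg <- padded_config(
    5000, drugs = c(drugx = 0.1), events = c(pty = 0.02),
    associations = data.frame(drug = "drugx", pt = "pty", rho = 10),
    seed = 21
  )
  x <- generate_reports(cfg)
  res <- run_dispro(x)
  hit <- dplyr::filter(res, drug == "drugx", pt == "pty")
  expect_true(hit$signal)
  expect_gt(hit$prr, 2)

  # single-drug single-PT dataset: C = 0 everywhere, flagged not crashed
  degen <- generate_reports(synth_config(20, c(only = 1), c(p = 1), seed = 2))
  dres <- run_dispro(degen)
  expect_false(any(dres$signal))
  expect_equal(dres$reason, "undefined_statistic")
})

test_that("the SOC filter restricts results to the nervous-system hierarchy", {
  d <- example_dictionary()
  x <- tiny_icsr(list(
    list(id = "R1", drugs = "drugx", pts = c("Memory impairment", "Nausea")),
    list(id = "R2", drugs = "drugx", pts = "Sciatica"),
    list(id = "R3", drugs = "other", pts = c("Memory impairment", "Rash")),
    list(id = "R4", drugs = "other", pts = "Nausea"),
    list(id = "R5", drugs = "other", pts = "Sciatica")
  ))
  res <- run_dispro(x, dict = d, drugs = "drugx",
                    soc_filter = nervous_system_soc)
  expect_setequal(res$pt, c("Memory impairment", "Sciatica"))
  expect_error(run_dispro(x, soc_filter = nervous_system_soc), "dictionary")
})

test_that("role restriction changes the analysed marginals", {
  x <- tiny_icsr(list(
    list(id = "R1", drugs = "drugx", pts = "P1", roles = "concomitant"),
    list(id = "R2", drugs = "drugx", pts = "P2", roles = "suspected"),
    list(id = "R3", drugs = "other", pts = "P1"),
    list(id = "R4", drugs = "other", pts = "P2")
  ))
  all_roles <- run_dispro(x, drugs = "drugx")
  suspected <- run_dispro(x, drugs = "drugx", role = "suspected")
  expect_setequal(all_roles$pt, c("P1", "P2"))
  expect_equal(suspected$pt, "P2")
})
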