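test_that("match_steps reproduces worked matching examples", {
  m <- match_steps(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(m$TP, m$FP, m$FN), c(3, 0, 0))
  expect_equal(m$f1, 1.0)

  # expected counts confirmed by the exhaustive matching oracle
  det <- c(1.1, 2.5, 2.9, 5.0)
  ref <- c(1.0, 2.0, 3.0)
  expect_equal(oracle_max_matching(det, ref, 0.3), 2L)
  m2 <- match_steps(det, ref, 0.3)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(2, 2, 1))
  expect_equal(m2$precision, 0.5)
  expect_equal(m2$recall, 2 / 3)
  expect_equal(m2$f1, 4 / 7)
  expect_true(all(abs(m2$pairs[, 1] - m2$pairs[, 2]) <= 0.3))

  m3 <- match_steps(numeric(0), c(1, 2))
  expect_equal(c(m3$TP, m3$FP, m3$FN), c(0, 0, 2))
  expect_equal(c(m3$precision, m3$recall, m3$f1), c(0, 0, 0))

  expect_error(match_steps(c(2, 1), c(1, 2)), "sorted")
  expect_error(match_steps(1, 1, tolerance_s = 0), "positive")
})

test_that("matching is symmetric and monotone in the tolerance", {
  set.seed(21)
  for (i in 1:50) {
    det <- sort(runif(sample(0:8, 1), 0, 10))
    ref <- sort(runif(sample(0:8, 1), 0, 10))
    tol <- runif(1, 0.05, 1)
    a <- match_steps(det, ref, tol)
    b <- match_steps(ref, det, tol)
    expect_equal(a$TP, b$TP)
    expect_equal(a$FP, b$FN)
    expect_equal(a$precision, b$recall)
    expect_equal(a$f1, b$f1)
    wider <- match_steps(det, ref, tol * 2)
    expect_gte(wider$TP, a$TP)
    # metric range invariants
    expect_true(all(c(a$precision, a$recall, a$f1) >= 0))
    expect_true(all(c(a$precision, a$recall, a$f1) <= 1))
    expect_lte(a$f1, min(2 * a$precision, 2 * a$recall) + 1e-12)
  }
})

test_that("prf applies the formulas with the 0/0 convention", {
  expect_equal(unname(prf(3, 0, 0)), c(1, 1, 1))
  expect_equal(prf(2, 2, 1), c(precision = 0.5, recall = 2 / 3,
                               f1 = 2 * 0.5 * (2 / 3) / (0.5 + 2 / 3)),
               tolerance = 1e-12)
  expect_equal(unname(prf(0, 0, 0)), c(0, 0, 0))
  expect_error(prf(-1, 0, 0), "nonnegative")
})

test_that("plausibility screen counts the in-range fraction", {
  s <- plausibility_screen(c(10, 10, 10))
  expect_equal(s$pct_plausible, 100)
  expect_equal(s$median, 10)

  expect_equal(plausibility_screen(c(2, 10, 300, 15))$pct_plausible, 50)
  # bounds are inclusive
  expect_equal(plausibility_screen(rep(20, 5))$pct_plausible, 100)
  expect_equal(plausibility_screen(rep(4, 5))$pct_plausible, 100)

  set.seed(31)
  for (i in 1:20) {
    counts <- sample(0:300, sample(1:40, 1), replace = TRUE)
    s <- plausibility_screen(counts)
    expect_lte(s$p10, s$median)
    expect_lte(s$median, s$p90)
    expect_lte(s$p90, s$p99)
    expect_gte(s$pct_plausible, 0)
    expect_lte(s$pct_plausible, 100)
    # nearest-rank percentiles of integer counts are themselves integers
    expect_true(all(c(s$median, s$p10, s$p90, s$p99) %in% counts))
  }
  expect_error(plausibility_screen(numeric(0)), "non-empty")
})

test_that("bilateral consistency summarizes paired count differences", {
  expect_equal(unname(bilateral_consistency(c(5, 9), c(5, 9))), c(0, 0))
  bc <- bilateral_consistency(c(10, 12), c(8, 12))
  expect_equal(bc[["mean_abs_diff"]], 1.0)
  expect_equal(bc[["sd_abs_diff"]], sd(c(2, 0)))
  expect_warning(one <- bilateral_consistency(10, 12), "single")
  expect_equal(unname(one), c(2, 0))
  expect_error(bilateral_consistency(1:3, 1:2), "same length")
})

test_that("the plausibility report renders CSV and aligned text", {
  sums <- list(peak = plausibility_screen(c(8, 12, 30)),
               spectral = plausibility_screen(c(2, 50, 60)))
  csv <- tempfile(fileext = ".csv")
  txt <- tempfile(fileext = ".txt")
  df <- write_plausibility_report(sums, csv_path = csv, txt_path = txt)
  expect_equal(df$algorithm, c("peak", "spectral"))
  back <- read.csv(csv)
  expect_equal(back$pct_plausible, df$pct_plausible)
  lines <- readLines(txt)
  expect_match(lines[1], "Plausible")
  expect_length(lines, 3)
})
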