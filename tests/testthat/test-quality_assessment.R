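test_that("diagnostic decision: maximum, just-above-threshold, and boundary cases", {
  top <- diagnostic_decision(make_ratings(item_score = 4L, overall_score = 4L), "s1")
  expect_equal(top$mean_item_sum, 20)
  expect_true(top$diagnostic)

  just <- diagnostic_decision(make_ratings(item_score = 3L, overall_score = 3L), "s1")
  expect_equal(just$mean_item_sum, 15)
  expect_true(just$diagnostic)

  # mean item sum exactly 14 is NOT diagnostic (strict inequality):
  # every reader scores noise 2 and the other four items 3 -> sum 14
  boundary <- data.table::copy(make_ratings(item_score = 3L, overall_score = 3L))
  boundary$score[boundary$item == "noise"] <- 2L
  dec <- diagnostic_decision(rating_table(boundary), "s1")
  expect_equal(dec$mean_item_sum, 14)
  expect_false(dec$diagnostic)

  # good items but one reader's overall below 3 vetoes the scan
  veto <- make_ratings(item_score = 4L)
  veto$score[veto$item == "overall" & veto$reader_id == "B"] <- 2L
  dec2 <- diagnostic_decision(rating_table(veto), "s1")
  expect_equal(dec2$mean_item_sum, 20)
  expect_false(dec2$diagnostic)
})

test_that("diagnostic decision reports missing cells and is monotone in scores", {
  r <- make_ratings()
  incomplete <- r[!(r$reader_id == "B" & r$item == "noise"), ]
  expect_error(diagnostic_decision(rating_table(incomplete), "s1"), "B/noise")
  expect_error(diagnostic_decision(r, "nope"), "not present")

  # raising any single score never flips diagnostic -> non-diagnostic
  set.seed(21)
  for (rep in 1:20) {
    base <- make_ratings(item_score = 1L)
    base$score <- sample(1:4, nrow(base), replace = TRUE)
    before <- diagnostic_decision(rating_table(base), "s1")$diagnostic
    i <- sample(which(base$score < 4L), 1)
    bumped <- data.table::copy(base)
    bumped$score[i] <- bumped$score[i] + 1L
    after <- diagnostic_decision(rating_table(bumped), "s1")$diagnostic
    expect_false(before && !after)
  }
})

test_that("icc_3k: perfect consistency, ANOVA oracle, independence, offsets", {
  # identical columns -> MSE 0 -> ICC exactly 1
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc_3k(m)$value, 1)
  # reader-specific constant offsets leave the consistency ICC unchanged
  expect_equal(icc_3k(m + rep(c(0, 5, -2), each = 4))$value, 1)

  # 4 x 2 worked matrix against the independent two-way ANOVA oracle
  w <- cbind(c(2, 4, 3, 1), c(3, 4, 4, 2))
  expect_equal(icc_3k(w)$value, icc_oracle(w), tolerance = 1e-12)

  set.seed(31)
  for (i in 1:20) {
    m <- matrix(rnorm(30), 10, 3)
    expect_equal(icc_3k(m)$value, icc_oracle(m), tolerance = 1e-10)
    off <- m + rep(rnorm(3), each = 10)
    expect_equal(icc_3k(off)$value, icc_3k(m)$value, tolerance = 1e-9)
    expect_lte(icc_3k(m)$value, 1)
  }

  # independent uniform scores: ICC near 0
  set.seed(32)
  u <- matrix(sample(1:4, 600, replace = TRUE), 200, 3)
  expect_lt(abs(icc_3k(u)$value), 0.15)

  expect_error(icc_3k(matrix(1:4, 2, 2) * NA), "complete")
  expect_error(icc_3k(matrix(c(1, 1, 2, 2), 2, 2)), "MSR = 0")
  expect_error(icc_3k(matrix(1:3, 3, 1)), "at least 2")
})

test_that("icc_3k labels follow the interpretation bands and CI brackets the value", {
  set.seed(33)
  truth <- rnorm(50, sd = 2)
  noisy <- sapply(1:3, function(i) truth + rnorm(50, sd = 0.3))
  res <- icc_3k(noisy)
  expect_equal(res$label, "excellent")
  expect_gt(res$value, 0.9)
  expect_true(res$conf_int[1] < res$value && res$value < res$conf_int[2])

  lowish <- sapply(1:3, function(i) truth + rnorm(50, sd = 4))
  expect_true(icc_3k(lowish)$label %in% c("poor", "moderate"))
})

test_that("score_matrix pivots items and the five-item sum", {
  r <- make_ratings(scan_ids = c("s1", "s2"))
  m <- score_matrix(r, "sum")
  expect_equal(dim(m), c(2L, 3L))
  expect_true(all(m == 15))
  expect_true(all(score_matrix(r, "overall") == 3))
})

test_that("fit_dose_response: exact polynomial recovery and nested-model comparison", {
  x <- seq(0.05, 1.5, length.out = 13)
  y <- 2 + 3 * x - 4 * x^2 + 1.5 * x^3
  fit <- fit_dose_response(x, y, degree = 3)
  expect_equal(fit$coefficients, c(2, 3, -4, 1.5), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  const <- fit_dose_response(x, rep(5, 13), degree = 2)
  expect_equal(const$coefficients[2:3], c(0, 0), tolerance = 1e-8)

  set.seed(41)
  y2 <- 100 * x^(1 / 3) + rnorm(13, sd = 2)  # saturating curve
  cubic <- fit_dose_response(x, y2, degree = 3)
  linear <- lm(y2 ~ x)
  expect_lt(sum(residuals(cubic$model)^2), sum(residuals(linear)^2))

  band <- dose_response_band(cubic, x)
  expect_true(all(band$lwr <= band$fit & band$fit <= band$upr))
  expect_error(fit_dose_response(c(1, 1, 1, 1, 1), 1:5, degree = 2),
               "rank-deficient")
  expect_error(fit_dose_response(1:4, 1:4, degree = 3), "degree \\+ 2")
})

test_that("threshold_analysis picks the minimum-dose diagnostic scan, order-invariant", {
  mk <- function(kvp, ma, ctdi, ed, steep, diag) list(
    record = scan_record(kvp, ma, 0.28, ctdi_vol = ctdi, scan_length = 36),
    sharpness = steep, decision = diag, effective_dose = ed)
  scans <- list(mk(140, 50, 1.59, 1.48, 5324, TRUE),
                mk(100, 10, 0.14, 0.13, 713, TRUE),
                mk(80, 10, 0.07, 0.07, 475, FALSE),
                mk(100, 20, 0.27, 0.25, 938, TRUE))
  res <- threshold_analysis(scans)
  expect_true(res$found)
  expect_equal(res$record$kvp, 100)
  expect_equal(res$record$ma, 10)
  expect_equal(res$sharpness_cutoff, 713)

  set.seed(51)
  res2 <- threshold_analysis(sample(scans))
  expect_equal(res2$sharpness_cutoff, res$sharpness_cutoff)

  # single diagnostic scan; all-diagnostic argmin; none-diagnostic signal
  expect_equal(threshold_analysis(scans[2])$sharpness_cutoff, 713)
  all_diag <- lapply(scans, function(s) { s$decision <- TRUE; s })
  expect_equal(threshold_analysis(all_diag)$record$ma, 10)  # ED 0.07 scan
  none <- lapply(scans, function(s) { s$decision <- FALSE; s })
  expect_false(threshold_analysis(none)$found)
  expect_true(is.na(threshold_analysis(none)$sharpness_cutoff))

  # tie on ED broken by CTDIvol then mAs
  tie <- list(mk(100, 20, 0.27, 0.10, 900, TRUE),
              mk(100, 10, 0.14, 0.10, 700, TRUE))
  expect_equal(threshold_analysis(tie)$record$ma, 10)
})

test_that("rating tables validate scores and read from CSV", {
  bad <- expand.grid(scan_id = "s", reader_id = "A",
                     item = c("overall", rating_items()))
  bad$score <- 5L
  expect_error(rating_table(bad), "1..4")
  bad$score <- 3L
  bad$item <- as.character(bad$item)
  bad$item[2] <- "sparkle"
  expect_error(rating_table(bad), "unknown rating item")

  r <- make_ratings(scan_ids = c("a", "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(r, path)
  back <- read_rating_table(path)
  expect_equal(nrow(back), nrow(r))
  expect_true(diagnostic_decision(back, "a")$diagnostic)
})
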