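mk_fixes <- function(minute, x = 0, y = 0, focal = TRUE) {
  n <- length(minute)
  data.frame(timestamp = as.POSIXct("2011-01-10", tz = "UTC") + minute * 60,
             date = as.Date("2011-01-10"), minute = minute,
             x = rep_len(x, n), y = rep_len(y, n),
             has_focal_behaviour = rep_len(focal, n),
             stringsAsFactors = FALSE)
}

test_that("subsampling picks fixes 15 min apart when all are eligible", {
  fx <- mk_fixes(0:60)
  sub <- subsample_fixes(fx)
  expect_equal(sub$minute, c(0, 15, 30, 45, 60))
  expect_equal(track_segments(sub)$dt, rep(15, 4))
})

test_that("subsampling respects the +/- 5 min window, skips documented gaps", {
  # partial eligibility hole: pick the eligible fix nearest to target 15
  fx <- mk_fixes(0:40, focal = TRUE)
  fx$has_focal_behaviour[fx$minute %in% 13:18] <- FALSE
  sub <- subsample_fixes(fx)
  expect_equal(sub$minute[1:2], c(0, 12))      # 12 is nearest to target 15
  # hole covering the whole window [10, 20]: the window is skipped
  fxh <- mk_fixes(0:40)
  fxh$has_focal_behaviour[fxh$minute %in% 10:20] <- FALSE
  subh <- subsample_fixes(fxh)
  expect_equal(subh$minute[1:2], c(0, 21))
  expect_true(subh$new_leg[2])
  # no eligible fix at all in the window -> skip, new leg starts
  fx2 <- mk_fixes(c(0:5, 25:40))
  sub2 <- subsample_fixes(fx2)
  expect_true(any(sub2$new_leg[-1]))
  seg2 <- track_segments(sub2)
  expect_true(all(seg2$dt >= 10 & seg2$dt <= 20))
})

test_that("consecutive selected gaps lie in [10, 20] minutes on random tracks", {
  set.seed(31)
  for (i in 1:50) {
    fx <- mk_fixes(0:300)
    fx$has_focal_behaviour <- runif(301) < 0.5
    sub <- subsample_fixes(fx)
    if (nrow(sub) < 2) next
    gaps <- diff(sub$minute)
    ok <- (gaps >= 10 & gaps <= 20) | sub$new_leg[-1]
    expect_true(all(ok))
    expect_true(all(sub$has_focal_behaviour))
  }
})

test_that("hourly distance is four times the mean quarter-hour displacement", {
  expect_equal(hourly_distance(rep(100, 4)), 400)
  expect_equal(hourly_distance(rep(0, 6)), 0)
  expect_equal(hourly_distance(c(50, 150)), 400)   # 4 * 200 / 2
  expect_true(is.na(hourly_distance(numeric(0))))
  # homogeneity
  set.seed(2)
  d <- runif(10, 0, 300)
  expect_equal(hourly_distance(3.7 * d), 3.7 * hourly_distance(d))
})

test_that("height categories map to 5-m band centres", {
  expect_equal(height_from_category(2), 7.5)
  expect_equal(height_from_category(3), 12.5)
  expect_equal(height_from_category(0), 0)
  expect_equal(height_from_category(c(1, 4, 5, 6)), c(3, 17.5, 22.5, 27.5))
  expect_error(height_from_category(7), "0-6")
  expect_equal(height_from_category(6, cat6_height = 30), 30)
})

test_that("vertical rate sums absolute height changes over coded hours", {
  expect_equal(vertical_rate(scan_day(120, height = 3L)), 0)
  alt <- scan_day(61, height = rep(c(2L, 3L), length.out = 61))
  expect_equal(vertical_rate(alt, "hour"), 60 * 5 / (61 / 60))
  seq4 <- scan_day(4, height = c(0L, 2L, 2L, 4L))
  # |7.5| + |0| + |10| = 17.5 m over 4 coded minutes
  expect_equal(vertical_rate(seq4, "hour") * (4 / 60), 17.5)
  expect_equal(vertical_rate(seq4, "minute"), 17.5 / 3)
  # ascent-only mode and gap exclusion
  expect_equal(vertical_rate(seq4, "minute", ascent_only = TRUE), 17.5 / 3)
  down <- scan_day(3, height = c(4L, 2L, 2L))
  expect_equal(vertical_rate(down, "minute", ascent_only = TRUE), 0)
  gappy <- scan_day(4, minute = c(480L, 481L, 490L, 491L),
                    height = c(2L, 3L, 0L, 6L))
  expect_equal(vertical_rate(gappy, "minute"), (5 + 27.5) / 2)
})

test_that("subsampling a straight constant-speed track changes the rate by < 1 %", {
  fx <- mk_fixes(0:360, x = 2.5 * (0:360), y = 0)
  minute_rate <- 60 * 2.5                       # 150 m/h ground truth
  sub_rate <- hourly_distance(track_segments(subsample_fixes(fx)))
  expect_lt(abs(sub_rate - minute_rate) / minute_rate, 0.01)
})

test_that("expected spurious path follows the 600-to-40 m/h error-reduction arithmetic", {
  expect_equal(expected_error_path(1, 10), 600)
  expect_equal(expected_error_path(15, 10), 40)
  expect_equal(expected_error_path(7, 0), 0)
  set.seed(99)
  mc <- expected_error_path(15, 10, method = "monte_carlo", steps = 1e5)
  expect_lt(abs(mc - 40) / 40, 0.02)
  expect_equal(expected_error_path(3, 0, method = "monte_carlo"), 0)
})

test_that("daily travel converts to the published hourly rate", {
  expect_equal(round(hourly_rate_from_daily(1.40, 12)), 117)
  expect_equal(round(hourly_rate_from_daily(1.96, 12)), 163)
})
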