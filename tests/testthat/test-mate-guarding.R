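mk_follow <- function(pattern, female = "F01") {
  # pattern: character vector of "q" (qualifying), "x" (present, not
  # following), "f" (following but > 10 m), "." (minute missing)
  n <- length(pattern)
  sc <- scan_day(n)
  sc$following_female[pattern %in% c("q", "f")] <- female
  sc$female_distance_le_10m[pattern == "q"] <- TRUE
  sc$female_distance_le_10m[pattern == "f"] <- FALSE
  sc[pattern != ".", , drop = FALSE]
}

test_that("episode opening, boundary and grace rules follow the >5 min / <=10 m / 2-min definition", {
  # 10 consecutive qualifying minutes -> one 10-min episode
  ep <- segment_episodes(mk_follow(rep("q", 10)))
  expect_equal(nrow(ep), 1)
  expect_equal(ep$duration_min, 10)
  # exactly 5 qualifying minutes -> no episode ("more than five")
  expect_equal(nrow(segment_episodes(mk_follow(c(rep("q", 5), rep("x", 5))))),
               0)
  # 8 qualifying + 2 beyond 10 m + 8 qualifying -> one 18-min episode
  ep <- segment_episodes(mk_follow(c(rep("q", 8), "f", "f", rep("q", 8))))
  expect_equal(ep$duration_min, 18)
  # 3 intervening minutes close the episode: two episodes of 8 and 8
  ep <- segment_episodes(mk_follow(c(rep("q", 8), "f", "f", "f",
                                     rep("q", 8))))
  expect_equal(ep$duration_min, c(8, 8))
  # trailing grace is back-dated to the last qualifying minute
  ep <- segment_episodes(mk_follow(c(rep("q", 7), "f", "x")))
  expect_equal(ep$duration_min, 7)
})

test_that("worked scenario days segment as documented", {
  for (s in c("boundary_5min", "grace_window", "female_switch", "gap")) {
    wd <- emit_worked_day(s)
    ep <- segment_episodes(wd$scans)
    expect_equal(ep, wd$expected_episodes, info = s)
  }
})

test_that("segmentation requires sorted single male-days", {
  sc <- mk_follow(rep("q", 10))
  expect_error(segment_episodes(sc[c(2, 1, 3:10), ]), "sorted")
})

test_that("segmenter matches the brute-force reference scanner on random days", {
  set.seed(101)
  for (i in 1:500) {
    sc <- rand_scan_day()
    got <- segment_episodes(sc)
    ref <- ref_segment(sc)
    expect_identical(got, ref,
                     info = sprintf("random day %d", i))
  }
})

test_that("segmentation is idempotent and ignores trailing non-qualifying minutes", {
  set.seed(7)
  sc <- rand_scan_day()
  ep1 <- segment_episodes(sc)
  tail_sc <- scan_day(30, minute = max(sc$minute) + 1:30)
  tail_sc$date <- sc$date[1]
  ep2 <- segment_episodes(rbind(sc, tail_sc))
  expect_equal(ep1, ep2)
  # episodes never overlap and fit within observation
  if (nrow(ep1) > 1) {
    expect_true(all(ep1$start_minute[-1] > ep1$end_minute[-nrow(ep1)]))
  }
  expect_true(sum(ep1$duration_min) <= diff(range(sc$minute)) + 1)
})

test_that("daily summary applies the strict >50 % extensive rule", {
  sc <- mk_follow(c(rep("q", 60), rep("x", 60)))
  ep <- segment_episodes(sc)
  s <- daily_mg_summary(ep, sc)
  expect_equal(s$observed_min, 120)
  expect_equal(s$mg_min, 60)
  expect_equal(s$mg_fraction, 0.5)
  expect_false(s$extensive)           # exactly half is not extensive

  sc61 <- mk_follow(c(rep("q", 61), rep("x", 59)))
  s61 <- daily_mg_summary(segment_episodes(sc61), sc61)
  expect_equal(s61$mg_fraction, 61 / 120)
  expect_true(s61$extensive)
})

test_that("out-of-sight minutes follow the observation-time convention flag", {
  sc <- mk_follow(c(rep("q", 30), rep("x", 20)))
  sc$activity[41:50] <- "out_of_sight"
  ep <- segment_episodes(sc)
  excl <- daily_mg_summary(ep, sc)
  incl <- daily_mg_summary(ep, sc, include_out_of_sight = TRUE)
  expect_equal(excl$observed_min, 40)
  expect_equal(incl$observed_min, 50)
  expect_equal(excl$mg_min, incl$mg_min)
})

test_that("MG periods are maximal runs of extensive observed days", {
  d <- as.Date("2011-01-01") + c(0, 1, 2, 3, 4)
  summ <- data.frame(male_id = "m01", date = d,
                     observed_min = 400, mg_min = c(300, 300, 300, 10, 300),
                     mg_fraction = c(.75, .75, .75, .025, .75),
                     extensive = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  per <- mg_periods(summ)
  expect_equal(per$length_days, c(3, 1))
  expect_equal(per$start_date, d[c(1, 5)])

  # an unobserved calendar day between extensive days does not break a period
  summ2 <- summ[c(1, 2, 5), ]
  summ2$extensive <- TRUE
  per2 <- mg_periods(summ2)
  expect_equal(per2$length_days, 3)

  # no extensive days -> no periods
  summ$extensive <- FALSE
  expect_equal(nrow(mg_periods(summ)), 0)
})

test_that("per-male mean period lengths average to the published 4.0 days", {
  s <- focal_male_summary()
  expect_equal(mean(s$mean_mg_period_days), 4.0)
  expect_equal(mean(s$overall_mg_pct), 29.8, tolerance = 1e-10)
})
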