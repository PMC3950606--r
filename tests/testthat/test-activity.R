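test_that("activity budget resolves concurrent states by feeding precedence", {
  sc <- scan_day(60)
  b <- activity_budget(sc)
  expect_equal(unname(b["resting"]), 1)

  # 30 minutes groomed-while-feeding (food item recorded) + 30 resting
  sc2 <- scan_day(60, activity = c(rep("grooming", 30), rep("resting", 30)),
                  food = c(rep("fruit", 30), rep(NA, 30)))
  b2 <- activity_budget(sc2)
  expect_equal(unname(b2["feeding"]), 0.5)
  expect_equal(sum(b2), 1)
})

test_that("budget proportions match an independent tally on random days", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(60:200, 1)
    acts <- sample(c("resting", "feeding", "travelling", "grooming",
                     "vigilant", "out_of_sight"), n, replace = TRUE)
    sc <- scan_day(n, activity = acts)
    sc$food_item[sc$activity == "feeding"] <- "leaf"
    b <- activity_budget(sc)
    coded <- acts[acts != "out_of_sight"]
    for (a in unique(coded)) {
      expect_equal(unname(b[a]), sum(coded == a) / length(coded))
    }
    expect_equal(sum(b), 1)
  }
})

test_that("diet composition is computed over feeding scans", {
  sc <- scan_day(20, activity = "feeding",
                 food = c(rep("fruit", 10), rep("leaf", 10)))
  d <- diet_composition(sc)
  expect_equal(unname(d["fruit"]), 0.5)
  sc$food_item <- "fruit"
  expect_equal(unname(diet_composition(sc)["fruit"]), 1)
  expect_null(diet_composition(scan_day(10)))
})

test_that("restlessness counts locomotion/position changes over adjacent pairs", {
  expect_equal(as.numeric(restlessness(scan_day(60))), 0)
  alt <- scan_day(60, locomotion = rep(c("sitting", "walking"), 30))
  expect_equal(as.numeric(restlessness(alt)), 1)
  seq5 <- scan_day(5, locomotion = c("sitting", "sitting", "walking",
                                     "walking", "running"))
  expect_equal(as.numeric(restlessness(seq5)), 0.5)   # 2 changes / 4 pairs
})

test_that("restlessness excludes pairs across gaps and is relabel-invariant", {
  sc <- scan_day(10, locomotion = c(rep("sitting", 5), rep("walking", 5)))
  gap <- sc[-6, ]   # the single sitting->walking change now spans the gap
  expect_equal(as.numeric(restlessness(gap)), 0)
  expect_equal(attr(restlessness(gap), "n_pairs"), 7)

  relab <- sc
  relab$locomotion_position <- ifelse(sc$locomotion_position == "sitting",
                                      "lying", "standing")
  expect_equal(as.numeric(restlessness(sc)),
               as.numeric(restlessness(relab)))
  expect_null(restlessness(scan_day(1)))
})

test_that("the one-hour day filter removes short male-days", {
  long_day <- scan_day(60)
  short_day <- scan_day(59)
  short_day$date <- as.Date("2011-01-11")
  da <- daily_activity(rbind(long_day, short_day))
  expect_equal(nrow(da), 1)
  expect_equal(da$n_coded, 60)

  # out-of-sight minutes do not count as coded focal time
  oos_day <- scan_day(70, activity = c(rep("resting", 59),
                                       rep("out_of_sight", 11)))
  expect_equal(nrow(daily_activity(oos_day)), 0)
})

test_that("generator-known activity multinomials are recovered from scans", {
  st <- generate_study(study_config(n_days = 20L, seed = 9))
  da <- daily_activity(st$scans)
  tr <- merge(da, st$truth$daily, by = c("male_id", "date"))
  tr <- merge(tr, st$truth$responses[, c("male_id", "date", "p_feed",
                                         "p_fruit")],
              by = c("male_id", "date"))
  expect_gt(nrow(tr), 10)
  # feeding scans are a deterministic count of the day's target proportion
  expect_equal(tr$pct_feeding, tr$n_feed_true / tr$observed_min,
               tolerance = 1e-10)
  expect_true(all(abs(tr$pct_feeding - tr$p_feed) < 0.01))
  with_feed <- tr[tr$n_feed_true > 20, ]
  expect_true(all(abs(with_feed$pct_fruit_in_diet - with_feed$p_fruit) <
                    0.05))
})
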