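mk_survey <- function(scores, territory = "G1",
                      date = as.Date("2011-01-31")) {
  data.frame(territory_id = territory,
             tree_id = sprintf("t%03d", seq_along(scores)),
             survey_date = date, fruit_score = as.integer(scores),
             stringsAsFactors = FALSE)
}

test_that("fruit index is the percentage of trees with any fruit", {
  fi <- fruit_index(mk_survey(c(rep(0, 90), rep(2, 30))))
  expect_equal(fi$pct_trees_fruiting, 25)
  expect_equal(fi$n_trees, 120)
  expect_equal(fruit_index(mk_survey(rep(0, 120)))$pct_trees_fruiting, 0)
  dup <- mk_survey(c(1, 2)); dup$tree_id <- "t1"
  expect_error(fruit_index(dup), "duplicate")
})

test_that("index recovers the per-tree fruiting probability within binomial error", {
  set.seed(14)
  p <- 0.3
  hits <- 0
  for (i in 1:50) {
    scores <- ifelse(runif(120) < p, sample(1:5, 120, replace = TRUE), 0)
    fi <- fruit_index(mk_survey(scores))
    half_width <- 100 * 3 * sqrt(p * (1 - p) / 120)
    if (abs(fi$pct_trees_fruiting - 100 * p) < half_width) hits <- hits + 1
  }
  expect_gte(hits, 48)   # ~3-sigma binomial band
})

test_that("days map to the covering month-end survey window (16th to 15th)", {
  idx <- rbind(fruit_index(mk_survey(rep(1, 10),
                                     date = as.Date("2011-01-31"))),
               fruit_index(mk_survey(rep(0:1, 5),
                                     date = as.Date("2011-02-28"))))
  expect_equal(assign_index(as.Date("2011-01-20"), idx), 100)
  expect_equal(assign_index(as.Date("2011-02-10"), idx), 100)
  expect_equal(assign_index(as.Date("2011-02-16"), idx), 50)
  expect_equal(assign_index(as.Date("2011-03-15"), idx), 50)
  # every covered day maps to exactly one survey; uncovered days warn
  expect_warning(out <- assign_index(as.Date("2010-12-20"), idx),
                 "2010-12")
  expect_true(is.na(out))
})

test_that("percent-fruiting and mean log score are positively rank-correlated", {
  st <- generate_study(study_config(n_days = 150L, seed = 4))
  fi <- fruit_index_table(st$phenology)
  rho <- stats::cor(fi$pct_trees_fruiting, fi$mean_log_score,
                    method = "spearman")
  expect_gt(rho, 0)
})
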