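linear_wins <- function(n) {
  m <- matrix(0L, n, n, dimnames = list(paste0("i", 1:n), paste0("i", 1:n)))
  m[upper.tri(m)] <- 3L       # everyone beats everyone ranked below
  m
}

test_that("a perfectly linear matrix yields its order with I = SI = 0", {
  w <- linear_wins(4)
  r <- isi_rank(w, direction = "dominance")
  expect_equal(r$order, paste0("i", 1:4))
  expect_equal(c(r$I, r$SI), c(0, 0))
  # reversing a perfectly linear order gives I = n(n-1)/2
  rev_score <- isi_score(4:1, w)
  expect_equal(unname(rev_score["I"]), 6)
  # bared-teeth convention: the subordinate is the display giver
  bt <- t(w)
  expect_equal(isi_rank(bt, direction = "submission")$order,
               paste0("i", 1:4))
})

test_that("a single adjacent reversal costs I = 1, SI = 1", {
  w <- linear_wins(4)
  w["i3", "i2"] <- 5L         # i3 dominates i2
  w["i2", "i3"] <- 0L
  r <- isi_rank(w, direction = "dominance")
  expect_equal(c(r$I, r$SI), c(0, 0))   # swap fixes it entirely
  # force a true inconsistency: i4 beats i1 but loses to everyone else
  w2 <- linear_wins(4)
  w2["i4", "i1"] <- 5L
  w2["i1", "i4"] <- 0L
  r2 <- isi_rank(w2, direction = "dominance")
  expect_equal(unname(exhaustive_isi(w2)), unname(c(r2$I, r2$SI)))
})

test_that("heuristic attains the exhaustive (I, SI) optimum on random matrices", {
  set.seed(61)
  for (i in 1:30) {
    w <- rand_wins_matrix(6)
    r <- isi_rank(w, direction = "dominance", seed = i)
    expect_equal(unname(c(r$I, r$SI)), unname(exhaustive_isi(w)),
                 info = sprintf("matrix %d", i))
    id_score <- isi_score(seq_len(6), w)
    expect_true(r$I < id_score["I"] ||
                  (r$I == id_score["I"] && r$SI <= id_score["SI"]))
  }
})

test_that("rank classes split alpha/beta from the rest, label-invariantly", {
  r <- isi_rank(linear_wins(4), direction = "dominance")
  rc <- rank_class(r)
  expect_equal(unname(rc), c("high", "high", "low", "low"))
  expect_equal(names(rc), r$order)
  expect_equal(unname(rank_class(c("b", "a"))), c("high", "high"))
  relab <- linear_wins(4)
  dimnames(relab) <- list(letters[4:1], letters[4:1])
  rc2 <- rank_class(isi_rank(relab, direction = "dominance"))
  expect_equal(unname(rc2), c("high", "high", "low", "low"))
  expect_error(isi_rank(matrix(0, 1, 1)), "at least 2")
})
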