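# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package code paths they check.

# Brute-force episode scanner: per female, enumerate qualifying runs with
# rle(), merge runs separated by <= grace non-qualifying calendar minutes
# into chains, and emit one episode per chain that contains a run of length
# >= min_run (starting at the first such run, ending at the chain's last
# qualifying minute).
ref_segment <- function(scans, min_run = 6L, grace = 2L) {
  out <- list()
  females <- unique(stats::na.omit(scans$following_female))
  for (f in females) {
    qual <- rep(FALSE, 1440L)
    ok <- !is.na(scans$following_female) & scans$following_female == f &
      !is.na(scans$female_distance_le_10m) & scans$female_distance_le_10m
    qual[scans$minute[ok] + 1L] <- TRUE
    r <- rle(qual)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    if (!nrow(runs)) next
    gap_prev <- c(Inf, runs$start[-1] - runs$end[-nrow(runs)] - 1L)
    chain <- cumsum(gap_prev > grace)
    for (ch in unique(chain)) {
      cr <- runs[chain == ch, , drop = FALSE]
      long <- which(cr$end - cr$start + 1L >= min_run)
      if (!length(long)) next
      s <- cr$start[long[1]]
      e <- cr$end[nrow(cr)]
      if (e < s) next
      out[[length(out) + 1L]] <- data.frame(
        male_id = scans$male_id[1], date = scans$date[1], female_id = f,
        start_minute = s - 1L, end_minute = e - 1L,
        duration_min = e - s + 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(male_id = character(), date = as.Date(character()),
                      female_id = character(), start_minute = integer(),
                      end_minute = integer(), duration_min = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start_minute), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# random scan day rich in segmentation edge cases: clustered following via a
# Markov chain, two females, missing minutes and missing distance flags
rand_scan_day <- function(n_min = 120L, start = 420L) {
  minutes <- start + 0:(n_min - 1L)
  keep <- runif(n_min) > 0.08
  follow <- rep(NA_character_, n_min)
  state <- 0L   # 0 none, 1 F01, 2 F02
  for (t in seq_len(n_min)) {
    state <- if (state == 0L) {
      sample(0:2, 1, prob = c(0.85, 0.1, 0.05))
    } else {
      sample(c(0L, state, setdiff(1:2, state)), 1,
             prob = c(0.18, 0.77, 0.05))
    }
    if (state > 0L) follow[t] <- sprintf("F%02d", state)
  }
  dist <- ifelse(is.na(follow), NA,
                 sample(c(TRUE, FALSE, NA), n_min, replace = TRUE,
                        prob = c(0.75, 0.15, 0.1)))
  data.frame(
    male_id = "m01", date = as.Date("2011-01-20"), minute = minutes,
    activity = "resting", locomotion_position = "sitting",
    height_category = 2L, food_item = NA_character_,
    following_female = follow, female_distance_le_10m = dist,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

# small scan-day builder for hand-constructed cases
scan_day <- function(n, minute = 480L + 0:(n - 1L), activity = "resting",
                     locomotion = "sitting", height = 2L,
                     food = NA_character_, follow = NA_character_,
                     dist = NA) {
  data.frame(male_id = "m01", date = as.Date("2011-01-10"), minute = minute,
             activity = rep_len(activity, n),
             locomotion_position = rep_len(locomotion, n),
             height_category = rep_len(height, n),
             food_item = rep_len(food, n),
             following_female = rep_len(follow, n),
             female_distance_le_10m = rep_len(dist, n),
             stringsAsFactors = FALSE)
}

# all permutations of 1..n (for exhaustive I&SI search)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# exhaustive I&SI optimum over all orders
exhaustive_isi <- function(wins) {
  best <- c(I = Inf, SI = Inf)
  for (p in all_perms(nrow(wins))) {
    s <- mguard::isi_score(p, wins)
    if (s[1] < best[1] || (s[1] == best[1] && s[2] < best[2])) best <- s
  }
  best
}

rand_wins_matrix <- function(n = 6L, p_interact = 0.7) {
  m <- matrix(0L, n, n, dimnames = list(paste0("i", 1:n), paste0("i", 1:n)))
  for (a in 1:(n - 1L)) {
    for (b in (a + 1L):n) {
      if (runif(1) < p_interact) {
        tot <- sample(1:8, 1)
        w <- rbinom(1, tot, 0.75)
        m[a, b] <- w
        m[b, a] <- tot - w
      }
    }
  }
  m
}
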