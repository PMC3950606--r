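#' Segment one male-day of scans into mate-guarding episodes
#'
#' A male is mate-guarding a female when he follows her for more than five
#' consecutive minutes while staying within 10 m of her. Episode rules, on
#' the one-minute scan grid:
#' \itemize{
#'   \item a minute \emph{qualifies} for female F when the scan records
#'     \code{following_female == F} and \code{female_distance_le_10m} is
#'     \code{TRUE};
#'   \item an episode opens at the first minute of a run of at least
#'     \code{min_run} (default 6, i.e. strictly more than five) consecutive
#'     calendar minutes qualifying for the same female;
#'   \item within an open episode up to \code{grace} (default 2) consecutive
#'     non-qualifying minutes -- the female beyond 10 m, following not
#'     recorded, or the minute unobserved -- do not close it; one more closes
#'     it, back-dated to the last qualifying minute;
#'   \item a switch to another female closes the current episode by the same
#'     grace rule, and a new episode opens once the new female satisfies the
#'     opening run on her own.
#' }
#' Episode duration counts all minutes from start to (back-dated) end,
#' including bridged grace minutes. Episodes never overlap and never span
#' midnight (input is a single day).
#'
#' @param scans one male-day of scan records (see [read_scans()]), sorted by
#'   minute.
#' @param min_run minimum opening run length in minutes.
#' @param grace maximum number of consecutive non-qualifying minutes bridged
#'   inside an open episode.
#' @return data.frame with columns \code{male_id}, \code{date},
#'   \code{female_id}, \code{start_minute}, \code{end_minute},
#'   \code{duration_min}; zero rows if no episode.
#' @export
segment_episodes <- function(scans, min_run = 6L, grace = 2L) {
  if (!nrow(scans)) return(.empty_episodes())
  if (length(unique(scans$male_id)) != 1L ||
      length(unique(scans$date)) != 1L) {
    stop("segment_episodes expects a single male-day", call. = FALSE)
  }
  if (is.unsorted(scans$minute, strictly = TRUE)) {
    stop("scans must be sorted by strictly increasing minute", call. = FALSE)
  }

  # qualifying female per calendar minute (NA = non-qualifying / unobserved)
  qual <- rep(NA_character_, 1440L)
  ok <- !is.na(scans$following_female) &
    !is.na(scans$female_distance_le_10m) & scans$female_distance_le_10m
  qual[scans$minute[ok] + 1L] <- scans$following_female[ok]

  lo <- min(scans$minute) + 1L
  hi <- max(scans$minute) + 1L
  eps <- list()
  t <- lo
  open_f <- NA_character_; ep_start <- NA_integer_; ep_last <- NA_integer_
  run_f <- NA_character_; run_start <- NA_integer_
  n_bad <- 0L

  while (t <= hi + 1L) {                      # hi+1 acts as day-end sentinel
    q <- if (t <= hi) qual[t] else NA_character_
    if (!is.na(open_f)) {
      if (!is.na(q) && q == open_f) {
        ep_last <- t; n_bad <- 0L
      } else {
        n_bad <- n_bad + 1L
        if (n_bad > grace || t > hi) {
          eps[[length(eps) + 1L]] <- list(open_f, ep_start, ep_last)
          open_f <- NA_character_
          t <- ep_last                        # replay grace region
        }
      }
    } else {
      if (!is.na(q)) {
        if (is.na(run_f) || q != run_f || t - 1L != run_last) {
          run_f <- q; run_start <- t
        }
        run_last <- t
        if (t - run_start + 1L >= min_run) {
          open_f <- run_f; ep_start <- run_start; ep_last <- t; n_bad <- 0L
          run_f <- NA_character_
        }
      } else {
        run_f <- NA_character_
      }
    }
    t <- t + 1L
  }

  if (!length(eps)) return(.empty_episodes(scans))
  out <- data.frame(
    male_id = scans$male_id[1],
    date = scans$date[1],
    female_id = vapply(eps, function(e) e[[1]], character(1)),
    start_minute = as.integer(vapply(eps, function(e) e[[2]], numeric(1))) - 1L,
    end_minute = as.integer(vapply(eps, function(e) e[[3]], numeric(1))) - 1L,
    stringsAsFactors = FALSE
  )
  out$duration_min <- out$end_minute - out$start_minute + 1L
  out
}

.empty_episodes <- function(scans = NULL) {
  data.frame(male_id = character(), date = as.Date(character()),
             female_id = character(), start_minute = integer(),
             end_minute = integer(), duration_min = integer(),
             stringsAsFactors = FALSE)
}

#' Daily mate-guarding summary for one male-day
#'
#' Observation time is the number of scanned minutes; by default
#' \code{out_of_sight} minutes do not count as observation time (set
#' \code{include_out_of_sight = TRUE} for the alternative convention).
#' Mate-guarding minutes are the observed minutes covered by an episode, so
#' \code{mg_min <= observed_min} always holds. A day is an \emph{extensive}
#' mate-guarding day when the MG fraction strictly exceeds
#' \code{extensive_threshold} of observation time.
#'
#' @param episodes output of [segment_episodes()] for the same scans.
#' @param scans the male-day scan records.
#' @param include_out_of_sight count \code{out_of_sight} minutes as observed?
#' @param extensive_threshold MG fraction above which a day is extensive.
#' @return one-row data.frame: \code{male_id}, \code{date},
#'   \code{observed_min}, \code{mg_min}, \code{mg_fraction},
#'   \code{extensive}.
#' @export
daily_mg_summary <- function(episodes, scans, include_out_of_sight = FALSE,
                             extensive_threshold = 0.5) {
  obs <- scans$minute[include_out_of_sight |
                        scans$activity != "out_of_sight"]
  covered <- rep(FALSE, 1440L)
  if (nrow(episodes)) {
    for (i in seq_len(nrow(episodes))) {
      covered[(episodes$start_minute[i]:episodes$end_minute[i]) + 1L] <- TRUE
    }
  }
  mg_min <- sum(covered[obs + 1L])
  observed_min <- length(obs)
  frac <- if (observed_min > 0L) mg_min / observed_min else NA_real_
  data.frame(male_id = scans$male_id[1], date = scans$date[1],
             observed_min = observed_min, mg_min = mg_min,
             mg_fraction = frac,
             extensive = !is.na(frac) & frac > extensive_threshold,
             stringsAsFactors = FALSE)
}

#' Mate-guarding periods from per-male day summaries
#'
#' A mate-guarding period is a maximal run of consecutive extensive MG days.
#' Consecutive is taken over \emph{observed} days: an unobserved calendar day
#' between two extensive days does not break a period (groups were not
#' followed daily throughout), but only observed extensive days count toward
#' the period length. An observed non-extensive day always breaks a period.
#'
#' @param day_summaries per-male rows from [daily_mg_summary()], any order.
#' @return data.frame with \code{male_id}, \code{start_date},
#'   \code{end_date}, \code{length_days}, \code{female_ids}
#'   (comma-separated guarded females when episode data are attached via the
#'   optional \code{episodes} argument).
#' @param episodes optional episode table used to annotate guarded females.
#' @export
mg_periods <- function(day_summaries, episodes = NULL) {
  out <- list()
  for (m in unique(day_summaries$male_id)) {
    d <- day_summaries[day_summaries$male_id == m, , drop = FALSE]
    d <- d[order(d$date), , drop = FALSE]
    r <- rle(d$extensive)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      fem <- ""
      if (!is.null(episodes)) {
        e <- episodes[episodes$male_id == m &
                        episodes$date %in% d$date[idx], , drop = FALSE]
        fem <- paste(sort(unique(e$female_id)), collapse = ",")
      }
      out[[length(out) + 1L]] <- data.frame(
        male_id = m, start_date = d$date[idx[1]],
        end_date = d$date[idx[length(idx)]],
        length_days = length(idx), female_ids = fem,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(male_id = character(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      length_days = integer(), female_ids = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
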