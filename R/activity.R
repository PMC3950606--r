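#' Daily activity budget from one male-day of scans
#'
#' Proportion of coded focal minutes in each exclusive activity state.
#' Because grooming, self-grooming and travelling can co-occur with feeding
#' in the field protocol, concurrent states are resolved by the feeding
#' precedence rule: any minute recording food handling/consumption counts as
#' feeding. \code{out_of_sight} minutes are not coded minutes and enter no
#' denominator.
#'
#' @param scans one male-day of scan records.
#' @return named numeric vector of proportions over coded minutes (one entry
#'   per activity state observed, summing to 1), with attribute
#'   \code{n_coded}; a day with zero coded minutes returns \code{NULL}.
#' @export
activity_budget <- function(scans) {
  act <- .resolved_activity(scans)
  act <- act[!is.na(act)]
  if (!length(act)) return(NULL)
  p <- table(act) / length(act)
  out <- as.numeric(p)
  names(out) <- names(p)
  attr(out, "n_coded") <- length(act)
  out
}

# feeding precedence: a feeding scan is feeding whatever else co-occurs;
# out_of_sight minutes are uncoded (NA)
.resolved_activity <- function(scans) {
  act <- scans$activity
  act[act == "out_of_sight"] <- NA_character_
  act[!is.na(scans$food_item) | (!is.na(act) & act == "feeding")] <- "feeding"
  act
}

#' Diet composition over feeding scans
#'
#' @param scans one male-day of scan records.
#' @return named numeric vector of food-item proportions over feeding scans
#'   with a recorded item (sums to 1), or \code{NULL} if the day has no
#'   feeding scan.
#' @export
diet_composition <- function(scans) {
  items <- scans$food_item[!is.na(scans$food_item)]
  if (!length(items)) return(NULL)
  p <- table(items) / length(items)
  out <- as.numeric(p)
  names(out) <- names(p)
  out
}

#' Restlessness score for one male-day
#'
#' Restlessness is the rate of change in locomotion/position: for every
#' coded minute whose predecessor minute is also coded (calendar-adjacent,
#' both with a locomotion/position record), emit 1 if the state differs from
#' the minute before and 0 otherwise; the score is the mean of these binary
#' values. Pairs spanning observation gaps or out-of-sight minutes
#' contribute nothing. 0 means complete absence of restlessness, 1 maximal
#' restlessness.
#'
#' @param scans one male-day of scan records.
#' @return score in \[0, 1\] with attribute \code{n_pairs}, or \code{NULL}
#'   when no adjacent coded pair exists.
#' @export
restlessness <- function(scans) {
  ok <- !is.na(scans$locomotion_position) &
    (is.na(scans$activity) | scans$activity != "out_of_sight")
  minute <- scans$minute[ok]
  state <- scans$locomotion_position[ok]
  if (length(minute) < 2L) return(NULL)
  adj <- which(diff(minute) == 1L)
  if (!length(adj)) return(NULL)
  changes <- state[adj + 1L] != state[adj]
  out <- mean(changes)
  attr(out, "n_pairs") <- length(adj)
  out
}

#' Assemble per-male-day activity metrics
#'
#' Applies [activity_budget()], [diet_composition()] and [restlessness()] to
#' every male-day in a scan table and applies the minimum-observation day
#' filter: male-days with fewer than \code{min_coded_min} coded focal
#' minutes (default 60, i.e. at least one hour of focal data) are excluded
#' from the output.
#'
#' @param scans scan records for any number of male-days.
#' @param min_coded_min day filter threshold in coded minutes.
#' @return data.frame with one row per retained male-day: \code{male_id},
#'   \code{date}, \code{n_coded}, \code{pct_feeding}, \code{pct_resting},
#'   \code{pct_travelling}, \code{pct_fruit_in_diet} (NA when the day has no
#'   feeding scan) and \code{restlessness}.
#' @export
daily_activity <- function(scans, min_coded_min = 60L) {
  key <- interaction(scans$male_id, scans$date, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(scans)), key), function(idx) {
    day <- scans[idx, , drop = FALSE]
    budget <- activity_budget(day)
    if (is.null(budget) || attr(budget, "n_coded") < min_coded_min) {
      return(NULL)
    }
    diet <- diet_composition(day)
    rl <- restlessness(day)
    pct <- function(tab, nm) if (nm %in% names(tab)) unname(tab[nm]) else 0
    data.frame(
      male_id = day$male_id[1], date = day$date[1],
      n_coded = attr(budget, "n_coded"),
      pct_feeding = pct(budget, "feeding"),
      pct_resting = pct(budget, "resting"),
      pct_travelling = pct(budget, "travelling"),
      pct_fruit_in_diet = if (is.null(diet)) NA_real_ else
        pct(diet, "fruit"),
      restlessness = if (is.null(rl)) NA_real_ else as.numeric(rl),
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(male_id = character(), date = as.Date(character()),
                      n_coded = integer(), pct_feeding = numeric(),
                      pct_resting = numeric(), pct_travelling = numeric(),
                      pct_fruit_in_diet = numeric(),
                      restlessness = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$male_id, out$date), , drop = FALSE]
}
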