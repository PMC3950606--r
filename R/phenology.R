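#' Monthly fruit-availability index for one territory survey
#'
#' Fruit abundance per surveyed tree is scored on the ordinal log scale
#' (0 absence, 1 = 1--10 items, 2 = 11--100, 3 = 101--1,000,
#' 4 = 1,001--10,000, 5 = >10,000). The territory-level index is the
#' percentage of surveyed trees carrying any fruit (score >= 1); the mean
#' log score is reported alongside since the two track each other closely.
#'
#' @param records phenology rows for a single territory and survey date.
#' @return one-row data.frame: \code{territory_id}, \code{survey_date},
#'   \code{n_trees}, \code{pct_trees_fruiting} (0--100),
#'   \code{mean_log_score}.
#' @export
fruit_index <- function(records) {
  if (length(unique(records$territory_id)) != 1L ||
      length(unique(records$survey_date)) != 1L) {
    stop("fruit_index expects a single territory and survey date",
         call. = FALSE)
  }
  if (anyDuplicated(records$tree_id)) {
    stop("duplicate tree in survey", call. = FALSE)
  }
  data.frame(territory_id = records$territory_id[1],
             survey_date = records$survey_date[1],
             n_trees = nrow(records),
             pct_trees_fruiting = 100 * mean(records$fruit_score >= 1L),
             mean_log_score = mean(records$fruit_score),
             stringsAsFactors = FALSE)
}

#' Fruit indices for all territory-surveys in a phenology table
#'
#' @param phenology table from [read_phenology()].
#' @return data.frame of [fruit_index()] rows, one per territory-survey.
#' @export
fruit_index_table <- function(phenology) {
  key <- interaction(phenology$territory_id, phenology$survey_date,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(phenology, key), fruit_index))
  rownames(out) <- NULL
  out[order(out$territory_id, out$survey_date), , drop = FALSE]
}

#' Assign the monthly fruit index to an observation day
#'
#' Surveys run in the last three days of each month and are dated to the
#' month end. The survey of month m covers observation days from the 16th
#' of m through the 15th of m+1 (the month-end record is the closest survey
#' for exactly those days): an observation on 20 January or 10 February uses
#' the 31 January survey.
#'
#' @param date a vector of observation dates.
#' @param indices [fruit_index_table()] rows for a single territory.
#' @return numeric vector of \code{pct_trees_fruiting}; days whose covering
#'   survey is absent get \code{NA} with a warning naming the month.
#' @export
assign_index <- function(date, indices) {
  if (length(unique(indices$territory_id)) > 1L) {
    stop("assign_index expects indices for a single territory",
         call. = FALSE)
  }
  dom <- as.integer(format(date, "%d"))
  base <- as.Date(ifelse(dom >= 16L, as.numeric(date),
                         as.numeric(date - dom)),       # last day of prev month
                  origin = "1970-01-01")
  covering <- .month_end(base)
  pos <- match(covering, indices$survey_date)
  if (anyNA(pos)) {
    warning("no survey covering ",
            paste(unique(format(covering[is.na(pos)], "%Y-%m")),
                  collapse = ", "), call. = FALSE)
  }
  indices$pct_trees_fruiting[pos]
}
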