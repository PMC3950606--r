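#' Read minute-resolution focal scan records
#'
#' Reads a focal-scan CSV in the fixed package dialect: one row per one-minute
#' scan, columns \code{male_id}, \code{timestamp} (ISO-8601,
#' \code{YYYY-MM-DDTHH:MM:SS}), \code{activity}, \code{locomotion_position},
#' \code{height_category} (0--6 or blank), \code{food_item},
#' \code{following_female}, \code{female_distance_le_10m}
#' (\code{true}/\code{false}/blank). Blank cells are missing values; missing
#' minutes are represented by the absence of a row, never by sentinel rows.
#'
#' Rows violating per-row invariants (unknown enum token, a food item on a
#' non-feeding scan, a distance flag without a followed female) are rejected
#' and reported with their file line numbers in the \code{"rejects"}
#' attribute, so that rows in = rows kept + rows rejected. Non-monotone
#' timestamps within a male-day are a hard validation error.
#'
#' @param path path to a scan CSV file.
#' @return a \code{data.frame} of validated scans with columns
#'   \code{male_id}, \code{date}, \code{minute} (minute of day, 0--1439),
#'   \code{activity}, \code{locomotion_position}, \code{height_category},
#'   \code{food_item}, \code{following_female}, \code{female_distance_le_10m},
#'   plus an attribute \code{rejects} (data.frame of \code{line},
#'   \code{reason}).
#' @seealso [write_scans()], [validate_scans()]
#' @export
read_scans <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  .check_columns(raw, c("male_id", "timestamp", "activity",
                        "locomotion_position", "height_category", "food_item",
                        "following_female", "female_distance_le_10m"),
                 "scan file")
  ts <- .parse_timestamp(raw$timestamp)
  hc <- .blank_to_na(raw$height_category)
  scans <- data.frame(
    male_id = raw$male_id,
    date = ts$date,
    minute = ts$minute,
    activity = .blank_to_na(raw$activity),
    locomotion_position = .blank_to_na(raw$locomotion_position),
    height_category = suppressWarnings(as.integer(hc)),
    food_item = .blank_to_na(raw$food_item),
    following_female = .blank_to_na(raw$following_female),
    female_distance_le_10m = .parse_logical(raw$female_distance_le_10m),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(hc) & is.na(scans$height_category))) {
    stop("scan file: non-integer height_category", call. = FALSE)
  }
  validate_scans(scans, line_offset = 1L)
}

#' Validate scan records against the scan-table invariants
#'
#' Checks enum membership and the per-row consistency rules (food item only on
#' feeding scans; a female distance flag only when a followed female is
#' recorded), drops and reports offending rows, and errors if timestamps are
#' not strictly increasing within a male-day.
#'
#' @param scans a scan data.frame as returned by [read_scans()].
#' @param line_offset added to row indices when reporting rejects (use 1 for a
#'   CSV with a header line).
#' @return the validated scans, with a \code{rejects} attribute.
#' @export
validate_scans <- function(scans, line_offset = 0L) {
  n <- nrow(scans)
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why

  flag(is.na(scans$activity) | !(scans$activity %in% .mg_activities),
       "unknown or missing activity")
  flag(!is.na(scans$locomotion_position) &
         !(scans$locomotion_position %in% .mg_locomotion),
       "unknown locomotion/position")
  flag(!is.na(scans$height_category) &
         (scans$height_category < 0L | scans$height_category > 6L),
       "height_category outside 0-6")
  flag(!is.na(scans$food_item) & !(scans$food_item %in% .mg_food_items),
       "unknown food item")
  flag(!is.na(scans$food_item) &
         (is.na(scans$activity) | scans$activity != "feeding"),
       "food_item recorded on a non-feeding scan")
  flag(!is.na(scans$female_distance_le_10m) & is.na(scans$following_female),
       "distance flag without a followed female")

  keep <- is.na(reason)
  rejects <- data.frame(line = which(!keep) + line_offset,
                        reason = reason[!keep], stringsAsFactors = FALSE)
  out <- scans[keep, , drop = FALSE]
  rownames(out) <- NULL

  key <- paste(out$male_id, out$date)
  for (k in unique(key)) {
    m <- out$minute[key == k]
    if (any(diff(m) <= 0L)) {
      stop("non-monotone timestamps within male-day ", k, call. = FALSE)
    }
  }
  attr(out, "rejects") <- rejects
  out
}

#' Write scan records in the package CSV dialect
#'
#' Inverse of [read_scans()]; `write_scans` then `read_scans` round-trips
#' valid records exactly.
#'
#' @param scans a scan data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scans <- function(scans, path) {
  out <- data.frame(
    male_id = scans$male_id,
    timestamp = .format_timestamp(scans$date, scans$minute),
    activity = ifelse(is.na(scans$activity), "", scans$activity),
    locomotion_position = ifelse(is.na(scans$locomotion_position), "",
                                 scans$locomotion_position),
    height_category = ifelse(is.na(scans$height_category), "",
                             as.character(scans$height_category)),
    food_item = ifelse(is.na(scans$food_item), "", scans$food_item),
    following_female = ifelse(is.na(scans$following_female), "",
                              scans$following_female),
    female_distance_le_10m = .format_logical(scans$female_distance_le_10m),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
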