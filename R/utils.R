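# internal helpers shared across modules

.mg_activities <- c("resting", "vigilant", "feeding", "drinking", "travelling",
                    "aggressing", "affiliating", "grooming", "self_grooming",
                    "out_of_sight")
.mg_locomotion <- c("lying", "sitting", "standing", "walking", "running",
                    "jumping", "climbing")
.mg_food_items <- c("fruit", "leaf", "flower", "arthropod", "bark", "mushroom",
                    "other")

# ISO-8601 "YYYY-MM-DDTHH:MM:SS" <-> (Date, minute-of-day); all times are
# local study time, no zone arithmetic.
.parse_timestamp <- function(x) {
  tt <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- is.na(tt) & !is.na(x) & nzchar(x)
  if (any(bad)) {
    stop("unparseable ISO-8601 timestamp(s), e.g. '", x[which(bad)[1]], "'")
  }
  list(date = as.Date(tt, tz = "UTC"),
       minute = as.integer(format(tt, "%H", tz = "UTC")) * 60L +
         as.integer(format(tt, "%M", tz = "UTC")))
}

.format_timestamp <- function(date, minute) {
  sprintf("%sT%02d:%02d:00", format(date), minute %/% 60L, minute %% 60L)
}

.blank_to_na <- function(x) {
  x <- as.character(x)
  x[!nzchar(trimws(ifelse(is.na(x), "", x)))] <- NA_character_
  x
}

.parse_logical <- function(x) {
  x <- tolower(.blank_to_na(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) stop("unparseable logical value '", x[which(bad)[1]], "'")
  out
}

.format_logical <- function(x) ifelse(is.na(x), "", ifelse(x, "true", "false"))

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

# last calendar day of the month containing `date` (vectorized)
.month_end <- function(date) {
  first <- as.Date(format(date, "%Y-%m-01"))
  as.Date(vapply(first, function(f)
    as.numeric(seq(f, by = "1 month", length.out = 2L)[2L] - 1L),
    numeric(1)), origin = "1970-01-01")
}

.stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop(name, " must be a finite number", if (min > -Inf)
      paste0(" >= ", min), call. = FALSE)
  }
}
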