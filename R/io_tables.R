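# readers/writers for the remaining tabular inputs: phenology surveys,
# daily rainfall, urine assays and the bared-teeth interaction matrix

#' Read a monthly fruit-phenology survey
#'
#' Columns: \code{territory_id}, \code{tree_id}, \code{survey_date}
#' (\code{YYYY-MM-DD}), \code{fruit_score} (ordinal 0--5 on the standard
#' log-abundance scale: 0 absence, 1 = 1--10 items, ... 5 = >10,000).
#'
#' @param path CSV path.
#' @return validated data.frame; duplicate tree records within a survey or
#'   out-of-range scores are errors.
#' @export
read_phenology <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("territory_id", "tree_id", "survey_date",
                       "fruit_score"), "phenology file")
  df$survey_date <- as.Date(df$survey_date)
  df$fruit_score <- as.integer(df$fruit_score)
  if (any(is.na(df$fruit_score) | df$fruit_score < 0L | df$fruit_score > 5L)) {
    stop("phenology: fruit_score outside 0-5", call. = FALSE)
  }
  key <- paste(df$territory_id, df$survey_date, df$tree_id)
  if (anyDuplicated(key)) {
    stop("phenology: duplicate tree record within a survey", call. = FALSE)
  }
  df
}

#' @rdname read_phenology
#' @param phenology a phenology data.frame.
#' @export
write_phenology <- function(phenology, path) {
  out <- phenology[, c("territory_id", "tree_id", "survey_date",
                       "fruit_score")]
  out$survey_date <- format(out$survey_date)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read daily rainfall
#'
#' Columns: \code{date} (\code{YYYY-MM-DD}), \code{rainfall_mm} (>= 0).
#' @param path CSV path.
#' @export
read_rainfall <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("date", "rainfall_mm"), "rainfall file")
  df$date <- as.Date(df$date)
  df$rainfall_mm <- as.numeric(df$rainfall_mm)
  if (any(!is.finite(df$rainfall_mm) | df$rainfall_mm < 0)) {
    stop("rainfall: negative or non-finite values", call. = FALSE)
  }
  df
}

#' @rdname read_rainfall
#' @param rainfall a rainfall data.frame.
#' @export
write_rainfall <- function(rainfall, path) {
  out <- rainfall[, c("date", "rainfall_mm")]
  out$date <- format(out$date)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a urine assay table
#'
#' Columns: \code{male_id}, \code{collection_datetime} (ISO-8601),
#' \code{cpeptide_ng_per_ml}, \code{creatinine_mg_per_ml},
#' \code{storage_months} (months frozen before lyophilisation),
#' \code{original_volume_ml}, \code{reconstitution_volume_ml}.
#'
#' @param path CSV path.
#' @export
read_urine <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("male_id", "collection_datetime",
                       "cpeptide_ng_per_ml", "creatinine_mg_per_ml",
                       "storage_months", "original_volume_ml",
                       "reconstitution_volume_ml"), "urine file")
  ts <- .parse_timestamp(df$collection_datetime)
  df$collection_date <- ts$date
  df$collection_minute <- ts$minute
  num <- c("cpeptide_ng_per_ml", "creatinine_mg_per_ml", "storage_months",
           "original_volume_ml", "reconstitution_volume_ml")
  for (col in num) df[[col]] <- as.numeric(df[[col]])
  if (any(df$cpeptide_ng_per_ml < 0 | df$creatinine_mg_per_ml < 0,
          na.rm = TRUE)) {
    stop("urine: negative concentrations", call. = FALSE)
  }
  if (any(!is.finite(df$storage_months) | df$storage_months < 0)) {
    stop("urine: storage_months must be finite and non-negative",
         call. = FALSE)
  }
  df
}

#' @rdname read_urine
#' @param urine a urine data.frame.
#' @export
write_urine <- function(urine, path) {
  out <- urine[, c("male_id", "collection_datetime", "cpeptide_ng_per_ml",
                   "creatinine_mg_per_ml", "storage_months",
                   "original_volume_ml", "reconstitution_volume_ml")]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a directed bared-teeth interaction matrix
#'
#' Square CSV with individual identifiers as first column and header;
#' \code{counts[i, j]} is the number of bared-teeth displays \emph{given} by
#' row individual \code{i} to column individual \code{j} (the bared-teeth
#' face is a submissive signal, so the giver is the subordinate).
#'
#' @param path CSV path.
#' @return an integer matrix with identical row/column names, zero diagonal.
#' @export
read_interaction_matrix <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("interaction matrix must be square with matching row/column ids",
         call. = FALSE)
  }
  if (any(is.na(m)) || any(m < 0L)) {
    stop("interaction matrix must be non-negative integers", call. = FALSE)
  }
  if (any(diag(m) != 0L)) {
    stop("interaction matrix must have a zero diagonal", call. = FALSE)
  }
  m
}

#' @rdname read_interaction_matrix
#' @param counts square integer matrix with dimnames.
#' @export
write_interaction_matrix <- function(counts, path) {
  out <- data.frame(id = rownames(counts), counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
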