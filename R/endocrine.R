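#' Creatinine-indexed urinary C-peptide
#'
#' Urinary C-peptide (UCP) concentrations are corrected for urine dilution
#' by dividing by creatinine concentration, giving ng C-peptide per mg
#' creatinine. The index is invariant to reconstitution or dilution applied
#' equally to both analytes, so lyophilised samples reconstituted in a
#' different volume than the original urine are directly comparable.
#' Samples whose creatinine falls below the creatinine assay sensitivity
#' (0.1 mg/ml) are excluded with a QC flag rather than indexed.
#'
#' @param samples urine table from [read_urine()].
#' @param creatinine_sensitivity assay sensitivity in mg/ml; samples below
#'   it are excluded.
#' @return the input with columns \code{ucp_ng_per_mg_creatinine} (NA for
#'   excluded samples) and \code{qc_flag} (\code{""} or
#'   \code{"creatinine_below_sensitivity"}).
#' @export
ucp_index <- function(samples, creatinine_sensitivity = 0.1) {
  low <- samples$creatinine_mg_per_ml < creatinine_sensitivity
  samples$ucp_ng_per_mg_creatinine <- ifelse(
    low, NA_real_,
    samples$cpeptide_ng_per_ml / samples$creatinine_mg_per_ml)
  samples$qc_flag <- ifelse(low, "creatinine_below_sensitivity", "")
  samples
}

#' Exclude urine samples stored frozen too long before lyophilisation
#'
#' C-peptide degrades in samples stored frozen for more than 8 months prior
#' to lyophilisation; such samples are dropped. Storage of exactly the
#' threshold is retained (the rule is strictly "longer than").
#'
#' @param samples urine table from [read_urine()].
#' @param max_storage_months exclusion threshold in months.
#' @return retained rows, with attributes \code{n_in} and \code{n_excluded}.
#' @export
filter_storage <- function(samples, max_storage_months = 8) {
  keep <- samples$storage_months <= max_storage_months
  out <- samples[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_in") <- nrow(samples)
  attr(out, "n_excluded") <- sum(!keep)
  out
}
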