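#' Z-standardize a numeric column
#'
#' Continuous fixed effects entering the mixed models are standardised to a
#' mean of 0 and (sample) standard deviation of 1, so estimates are
#' comparable across predictors.
#'
#' @param x numeric vector with positive variance.
#' @param name column name used in the zero-variance error message.
#' @return standardized vector.
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize zero-variance column '", name, "'",
         call. = FALSE)
  }
  (x - mean(x, na.rm = TRUE)) / s
}

#' Gaussian-kernel temporal autocorrelation covariate
#'
#' Day-to-day dependence in a male's residuals unexplained by the fixed
#' effects is absorbed by an autocorrelation covariate: for each row, the
#' weighted mean of all \emph{other} rows of the same male's residuals, with
#' Gaussian weights \eqn{\exp(-\Delta d^2 / (2\sigma^2))} in days. Rows with
#' no same-male neighbour get 0. The residuals come from the model fitted
#' without the autocorrelation term (here: the null model, see
#' [fit_model()]); the kernel width \eqn{\sigma} is chosen from a fixed grid
#' to maximise the full-model likelihood.
#'
#' @param date vector of dates (or numeric days).
#' @param male_id grouping vector.
#' @param residuals residuals from the fit without the AC term.
#' @param sigma kernel width in days.
#' @return numeric AC covariate, one value per row.
#' @export
build_ac_term <- function(date, male_id, residuals, sigma) {
  d <- as.numeric(date)
  out <- numeric(length(d))
  for (m in unique(male_id)) {
    idx <- which(male_id == m)
    if (length(idx) == 1L) next
    dd <- outer(d[idx], d[idx], "-")
    w <- exp(-dd^2 / (2 * sigma^2))
    diag(w) <- 0
    tot <- rowSums(w)
    val <- as.vector(w %*% residuals[idx])
    out[idx] <- ifelse(tot > 0, val / tot, 0)
  }
  out
}

#' Variance inflation factors for a fixed-effect specification
#'
#' Collinearity diagnostic applied to a standard linear model excluding the
#' random effects: each predictor column of the design matrix is regressed
#' on all the others and \eqn{VIF = 1/(1 - R^2)}. Values below 5 indicate
#' that covariation among the predictors is not strong enough to threaten
#' the model.
#'
#' @param table model data.
#' @param predictors character vector of predictor column names.
#' @param threshold flagging threshold.
#' @return data.frame with \code{predictor}, \code{vif} (Inf under perfect
#'   collinearity) and \code{flagged}.
#' @export
vif_table <- function(table, predictors, threshold = 5) {
  if (length(predictors) < 2L) {
    stop("VIF needs at least 2 predictors", call. = FALSE)
  }
  mm <- stats::model.matrix(
    as.formula(paste("~", paste(predictors, collapse = " + "))), table)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  vifs <- vapply(seq_len(ncol(mm)), function(j) {
    fit <- lm.fit(cbind(1, mm[, -j, drop = FALSE]), mm[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((mm[, j] - mean(mm[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = colnames(mm), vif = vifs,
             flagged = !is.finite(vifs) | vifs >= threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Likelihood ratio test between nested mixed-model fits
#'
#' @param full,null \code{merMod} fits of the same data by maximum
#'   likelihood, \code{null} nested in \code{full}.
#' @return list with \code{chisq} (clipped at 0), \code{df} (parameter
#'   difference) and \code{p}.
#' @export
lrt <- function(full, null) {
  if (lme4::isREML(full) || lme4::isREML(null)) {
    stop("LRT requires maximum-likelihood fits", call. = FALSE)
  }
  if (stats::nobs(full) != stats::nobs(null)) {
    stop("full and null models fit different data", call. = FALSE)
  }
  tf <- attr(stats::terms(stats::formula(full, fixed.only = TRUE)),
             "term.labels")
  tn <- attr(stats::terms(stats::formula(null, fixed.only = TRUE)),
             "term.labels")
  if (!all(tn %in% tf)) {
    stop("null model is not nested in the full model", call. = FALSE)
  }
  llf <- logLik(full); lln <- logLik(null)
  df <- attr(llf, "df") - attr(lln, "df")
  if (df < 0) stop("null model has more parameters than the full model",
                   call. = FALSE)
  chisq <- max(0, 2 * (as.numeric(llf) - as.numeric(lln)))
  p <- if (df == 0) {
    if (chisq < 1e-8) 1 else NA_real_
  } else {
    pchisq(chisq, df, lower.tail = FALSE)
  }
  list(chisq = chisq, df = df, p = p)
}

.fixed_formula <- function(response, terms, random) {
  paste(response, "~",
        paste(c(terms, sprintf("(1 | %s)", random)), collapse = " + "))
}

.lmer_quiet <- function(formula, data) {
  fit <- withCallingHandlers(
    lme4::lmer(as.formula(formula), data = data, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore")),
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage"))
  fit
}

.fit_flags <- function(fit) {
  list(singular = lme4::isSingular(fit, tol = 1e-4),
       converged = length(fit@optinfo$conv$lme4$messages) == 0L)
}

#' Fit one mate-guarding mixed model with AC term and full-vs-null LRT
#'
#' Fits a Gaussian linear mixed model by maximum likelihood with random
#' intercepts for group and for male (nested in group via globally unique
#' male ids), following the study design:
#' \enumerate{
#'   \item continuous predictors (and the test predictor, if continuous)
#'     are z-standardized over the model table;
#'   \item a null model without the test predictor and without the AC term
#'     is fitted; its residuals feed [build_ac_term()];
#'   \item the kernel width \eqn{\sigma} is selected from \code{ac_grid} by
#'     maximising the full-model log-likelihood (or fixed, or the AC term
#'     omitted entirely);
#'   \item the same AC covariate enters full and null models, so the
#'     full-vs-null [lrt()] tests exactly the test predictor;
#'   \item VIFs are computed on a fixed-effects-only linear model.
#' }
#' The test-by-fruit interaction can be included permanently, dropped (the
#' default reporting path: in the study it was never significant), or
#' tested and kept only when its own LRT p-value is below 0.05.
#'
#' @param table model data, one row per male-day (or per urine sample).
#' @param response response column name.
#' @param test name of the test predictor (dropped in the null model).
#' @param controls character vector of control fixed effects.
#' @param random character vector of random-intercept grouping columns.
#' @param date_col,male_col columns used by the AC term.
#' @param ac \code{"grid"} (select sigma from \code{ac_grid}),
#'   \code{"none"}, or a single numeric sigma in days.
#' @param ac_grid candidate kernel widths in days.
#' @param interaction \code{"none"}, \code{"always"} or \code{"test"}; the
#'   interaction is \code{test:controls[1]} (mate-guarding by fruit
#'   availability).
#' @param min_groups below this number of levels in any random grouping a
#'   small-cluster warning (class \code{"mg_small_cluster_warning"}) is
#'   emitted: variance components estimated from 3 groups are honest but
#'   poorly identified.
#' @return an object of class \code{"mg_fit"}: list with \code{coefficients}
#'   (data.frame estimate/SE/t per fixed effect), \code{lrt},
#'   \code{ac_sigma}, \code{vif}, \code{ranef_sd}, \code{logLik}, \code{n},
#'   \code{formula_full}, \code{formula_null}, \code{flags} and the
#'   underlying \code{fit_full}/\code{fit_null} merMod objects.
#' @export
fit_model <- function(table, response, test, controls,
                      random = c("group_id", "male_id"),
                      date_col = "date", male_col = "male_id",
                      ac = "grid", ac_grid = c(0.5, 1, 2, 4, 8, 16),
                      ac_resid = c("null", "full"),
                      interaction = c("none", "always", "test"),
                      min_groups = 5L) {
  ac_resid <- match.arg(ac_resid)
  interaction <- match.arg(interaction)
  used <- unique(c(response, test, controls, random, date_col, male_col))
  .check_columns(table, used, "model table")
  df <- table[complete.cases(table[, used]), used, drop = FALSE]
  if (!nrow(df)) stop("no complete rows in model table", call. = FALSE)

  for (col in c(test, controls)) {
    if (is.numeric(df[[col]])) df[[col]] <- standardize(df[[col]], col)
  }
  for (g in random) {
    if (length(unique(df[[g]])) < min_groups) {
      warning(warningCondition(sprintf(
        "random effect '%s' has only %d levels; variance components are poorly identified",
        g, length(unique(df[[g]]))),
        class = "mg_small_cluster_warning"))
    }
  }

  int_term <- if (interaction != "none") {
    paste0(test, ":", controls[1])
  } else NULL
  full_terms <- c(test, controls, int_term)

  # AC covariate from the null fit without the AC term
  use_ac <- !identical(ac, "none")
  if (use_ac) {
    base_terms <- if (identical(ac_resid, "full")) full_terms else controls
    null0 <- .lmer_quiet(.fixed_formula(response, base_terms, random), df)
    r0 <- resid(null0)
    sigmas <- if (is.numeric(ac)) ac else ac_grid
    best <- NULL
    for (s in sigmas) {
      df$ac_term <- build_ac_term(df[[date_col]], df[[male_col]], r0, s)
      cand <- .lmer_quiet(
        .fixed_formula(response, c(full_terms, "ac_term"), random), df)
      if (is.null(best) || logLik(cand) > best$ll) {
        best <- list(sigma = s, ll = as.numeric(logLik(cand)),
                     ac = df$ac_term, fit = cand)
      }
    }
    df$ac_term <- best$ac
    fit_full <- best$fit
    ac_sigma <- best$sigma
    fixed_full <- c(full_terms, "ac_term")
  } else {
    fit_full <- .lmer_quiet(.fixed_formula(response, full_terms, random), df)
    ac_sigma <- NA_real_
    fixed_full <- full_terms
  }

  if (interaction == "test") {
    no_int <- setdiff(fixed_full, int_term)
    fit_noint <- .lmer_quiet(.fixed_formula(response, no_int, random), df)
    if (lrt(fit_full, fit_noint)$p > 0.05) {
      fit_full <- fit_noint
      fixed_full <- no_int
      int_term <- NULL
    }
  }

  fixed_null <- setdiff(fixed_full, c(test, int_term))
  fit_null <- .lmer_quiet(.fixed_formula(response, fixed_null, random), df)

  ct <- as.data.frame(coef(summary(fit_full)))
  names(ct) <- c("estimate", "se", "t")[seq_len(ncol(ct))]
  ct <- data.frame(term = rownames(ct), ct, row.names = NULL,
                   stringsAsFactors = FALSE)

  vc <- as.data.frame(lme4::VarCorr(fit_full))
  structure(list(
    response = response, test = test,
    coefficients = ct,
    lrt = lrt(fit_full, fit_null),
    ac_sigma = ac_sigma,
    vif = vif_table(df, setdiff(fixed_full, int_term)),
    ranef_sd = setNames(vc$sdcor, vc$grp),
    logLik = as.numeric(logLik(fit_full)),
    n = nrow(df),
    n_males = length(unique(df[[male_col]])),
    formula_full = .fixed_formula(response, fixed_full, random),
    formula_null = .fixed_formula(response, fixed_null, random),
    flags = .fit_flags(fit_full),
    fit_full = fit_full, fit_null = fit_null),
    class = "mg_fit")
}

#' @export
#' @method print mg_fit
print.mg_fit <- function(x, ...) {
  cat("Mixed model:", x$formula_full, "\n")
  cat(sprintf("n = %d rows, %d males; ML logLik = %.2f%s\n", x$n, x$n_males,
              x$logLik,
              if (!is.na(x$ac_sigma))
                sprintf("; AC kernel sigma = %g days", x$ac_sigma) else ""))
  cat(sprintf("Full vs null LRT: chisq = %.2f, df = %d, p = %.4g\n",
              x$lrt$chisq, x$lrt$df, x$lrt$p))
  print(x$coefficients, digits = 3)
  if (any(x$vif$flagged)) {
    cat("WARNING: VIF >= 5 for:",
        paste(x$vif$predictor[x$vif$flagged], collapse = ", "), "\n")
  }
  if (!x$flags$converged) cat("WARNING: optimizer convergence flagged\n")
  invisible(x)
}

#' The predefined study model specifications
#'
#' Five behavioural daily-response models (percentage of time feeding,
#' percentage of fruit in the diet, height climbed per hour, distance
#' travelled per hour, restlessness), each with mate-guarding time as test
#' predictor, fruit availability and rainfall as controls and the temporal
#' AC term; and two urinary C-peptide models (the MG model with height
#' climbed, feeding time, fruit availability, collection time and storage
#' length as controls; the rank model with the high/low rank class as the
#' test predictor).
#'
#' @return named list of specs: \code{response}, \code{test},
#'   \code{controls}, \code{ac}, \code{table} (\code{"behaviour"},
#'   \code{"ucp_mg"} or \code{"ucp_rank"}).
#' @export
mg_model_specs <- function() {
  beh <- function(resp) list(response = resp, test = "mg_pct",
                             controls = c("fruit_index", "rainfall_mm"),
                             ac = "grid", table = "behaviour")
  list(
    pct_feeding = beh("pct_feeding"),
    pct_fruit_in_diet = beh("pct_fruit_in_diet"),
    hourly_vertical_m = beh("hourly_vertical_m"),
    hourly_distance_m = beh("hourly_distance_m"),
    restlessness = beh("restlessness"),
    ucp_mg = list(response = "ucp", test = "mg_pct",
                  controls = c("hourly_vertical_m", "pct_feeding",
                               "fruit_index", "collection_time",
                               "storage_months"),
                  ac = "none", table = "ucp_mg"),
    ucp_rank = list(response = "ucp", test = "rank_class",
                    controls = c("fruit_index", "collection_time",
                                 "storage_months"),
                    ac = "none", table = "ucp_rank"))
}

#' Assemble the per-male-day behavioural model table
#'
#' Joins the daily mate-guarding summaries, activity metrics, movement
#' metrics, assigned fruit index and rainfall into one row per male-day.
#' Only male-days retained by the activity day filter (>= 1 h of coded focal
#' data) appear.
#'
#' @param mg_days rows from [daily_mg_summary()].
#' @param activity output of [daily_activity()].
#' @param movement output of [daily_movement()].
#' @param fruit output of [fruit_index_table()] (all territories).
#' @param rainfall rainfall table.
#' @param group_of_male named vector mapping male id to group/territory id.
#' @return data.frame with columns used by [mg_model_specs()]'s behaviour
#'   specs (\code{mg_pct} is the percentage 0--100 of observation time spent
#'   mate-guarding).
#' @export
build_model_table <- function(mg_days, activity, movement, fruit, rainfall,
                              group_of_male) {
  tab <- merge(activity, mg_days[, c("male_id", "date", "observed_min",
                                     "mg_min", "mg_fraction", "extensive")],
               by = c("male_id", "date"))
  tab <- merge(tab, movement, by = c("male_id", "date"), all.x = TRUE)
  tab$group_id <- unname(group_of_male[tab$male_id])
  tab$mg_pct <- 100 * tab$mg_fraction
  tab$rainfall_mm <- rainfall$rainfall_mm[match(tab$date, rainfall$date)]
  tab$fruit_index <- NA_real_
  for (g in unique(tab$group_id)) {
    idx <- tab$group_id == g
    tab$fruit_index[idx] <- assign_index(
      tab$date[idx], fruit[fruit$territory_id == g, , drop = FALSE])
  }
  tab[order(tab$male_id, tab$date), , drop = FALSE]
}

#' Assemble the urinary C-peptide model tables
#'
#' Applies the storage filter and creatinine QC, then builds the two sample
#' level tables: the MG model table (samples from focal males joined to that
#' male-day's behavioural metrics) and the rank model table (all samples,
#' with the high/low rank class).
#'
#' @param urine urine table from [read_urine()].
#' @param behaviour behavioural model table from [build_model_table()].
#' @param rank_class_map named vector mapping male id to
#'   \code{"high"}/\code{"low"} (see [rank_class()]).
#' @param group_of_male named vector mapping male id to group id.
#' @param fruit fruit index table, for samples lacking a behaviour row.
#' @param max_storage_months,creatinine_sensitivity filter settings.
#' @return list with data.frames \code{ucp_mg} and \code{ucp_rank};
#'   \code{collection_time} is the hour of day, \code{ucp} is ng C-peptide
#'   per mg creatinine.
#' @export
build_ucp_table <- function(urine, behaviour, rank_class_map, group_of_male,
                            fruit, max_storage_months = 8,
                            creatinine_sensitivity = 0.1) {
  s <- filter_storage(urine, max_storage_months)
  s <- ucp_index(s, creatinine_sensitivity)
  s <- s[s$qc_flag == "", , drop = FALSE]
  s$ucp <- s$ucp_ng_per_mg_creatinine
  s$collection_time <- s$collection_minute / 60
  s$date <- s$collection_date
  s$group_id <- unname(group_of_male[s$male_id])
  s$fruit_index <- NA_real_
  for (g in unique(s$group_id)) {
    idx <- s$group_id == g
    s$fruit_index[idx] <- assign_index(
      s$date[idx], fruit[fruit$territory_id == g, , drop = FALSE])
  }

  beh_cols <- c("male_id", "date", "mg_pct", "hourly_vertical_m",
                "pct_feeding")
  ucp_mg <- merge(
    s[, c("male_id", "date", "ucp", "collection_time", "storage_months",
          "fruit_index", "group_id")],
    behaviour[, beh_cols], by = c("male_id", "date"))

  s$rank_class <- unname(rank_class_map[s$male_id])
  ucp_rank <- s[!is.na(s$rank_class),
                c("male_id", "date", "ucp", "rank_class", "collection_time",
                  "storage_months", "fruit_index", "group_id")]
  rownames(ucp_rank) <- NULL
  list(ucp_mg = ucp_mg, ucp_rank = ucp_rank)
}
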