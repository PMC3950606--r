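#' Subsample minute-resolution GPS fixes at 15 +/- 5 minutes
#'
#' Reduces per-fix positional error in path-length estimates by keeping
#' roughly one fix per quarter hour. Selection is greedy-forward and
#' deterministic: starting from the first eligible fix, the next fix chosen
#' is the eligible fix nearest to (previous + \code{interval}) minutes
#' within +/- \code{tolerance}, ties broken toward the earlier fix. Only
#' fixes with \code{has_focal_behaviour = TRUE} are eligible -- positions
#' are trusted only when the observer had the animal in view at that exact
#' minute. If no eligible fix falls in a window, the selection restarts at
#' the first eligible fix after the window (a documented skip: the gap
#' across a skip is not a valid travel segment).
#'
#' @param fixes fix table from [read_gps()] (needs \code{minute}, \code{x},
#'   \code{y}, \code{has_focal_behaviour}).
#' @param interval target spacing in minutes.
#' @param tolerance half-width of the selection window in minutes.
#' @return the selected fixes, with a logical column \code{new_leg} marking
#'   fixes that start a new chain after a skip.
#' @export
subsample_fixes <- function(fixes, interval = 15, tolerance = 5) {
  el <- fixes[fixes$has_focal_behaviour, , drop = FALSE]
  if (!nrow(el)) {
    el$new_leg <- logical(0)
    return(el)
  }
  sel <- integer(0)
  new_leg <- logical(0)
  i <- 1L
  sel <- c(sel, i); new_leg <- c(new_leg, TRUE)
  repeat {
    target <- el$minute[i] + interval
    win <- which(el$minute >= target - tolerance &
                   el$minute <= target + tolerance & el$minute > el$minute[i])
    if (length(win)) {
      d <- abs(el$minute[win] - target)
      j <- win[which.min(d)]          # which.min returns the earliest tie
      sel <- c(sel, j); new_leg <- c(new_leg, FALSE)
      i <- j
    } else {
      nxt <- which(el$minute > target + tolerance)
      if (!length(nxt)) break
      i <- nxt[1L]
      sel <- c(sel, i); new_leg <- c(new_leg, TRUE)
    }
  }
  out <- el[sel, , drop = FALSE]
  out$new_leg <- new_leg
  rownames(out) <- NULL
  out
}

#' Build travel segments from subsampled fixes
#'
#' Consecutive selected fixes within a chain (no skip in between) form the
#' displacement segments whose planar lengths D_i feed the hourly travel
#' rate. Segments have \code{dt} within \code{interval +/- tolerance} by
#' construction.
#'
#' @param sub output of [subsample_fixes()].
#' @return data.frame with \code{D_i} (metres) and \code{dt} (minutes).
#' @export
track_segments <- function(sub) {
  n <- nrow(sub)
  if (n < 2L) return(data.frame(D_i = numeric(0), dt = numeric(0)))
  keep <- !sub$new_leg[-1L]
  data.frame(
    D_i = sqrt(diff(sub$x)^2 + diff(sub$y)^2)[keep],
    dt = diff(sub$minute)[keep])
}

#' Average hourly travelling distance from 15-minute segments
#'
#' The daily horizontal travel rate is \eqn{\sum_i 4 D_i / n}: the mean
#' quarter-hour displacement times four.
#'
#' @param D_i numeric vector of segment lengths in metres (or a segment
#'   data.frame from [track_segments()]).
#' @return metres per hour, or \code{NA} when no segment is available.
#' @export
hourly_distance <- function(D_i) {
  if (is.data.frame(D_i)) D_i <- D_i$D_i
  if (!length(D_i)) return(NA_real_)
  if (any(D_i < 0)) stop("negative displacement", call. = FALSE)
  4 * sum(D_i) / length(D_i)
}

#' Height in metres from a canopy-height category
#'
#' Categories code 5-m canopy bands (0 = animal on the ground, 1 = 1--5 m,
#' 2 = 5--10 m, ... 6 = >25 m); the band centre is used as the height
#' estimate, e.g. 7.5 m for category 2 and 12.5 m for category 3. The open
#' top category 6 is assigned 27.5 m, continuing the 5-m band width (see the
#' methods vignette for the sensitivity flag).
#'
#' @param cat integer vector of categories 0--6 (NA passed through).
#' @param cat6_height height assigned to the open category 6.
#' @return heights in metres.
#' @export
height_from_category <- function(cat, cat6_height = 27.5) {
  mid <- c(0, 3, 7.5, 12.5, 17.5, 22.5, cat6_height)
  bad <- !is.na(cat) & (cat < 0L | cat > 6L | cat != floor(cat))
  if (any(bad)) stop("height category outside 0-6", call. = FALSE)
  mid[as.integer(cat) + 1L]
}

#' Vertical travel rate from minute-scan height categories
#'
#' Converts each coded minute's height category to metres with
#' [height_from_category()] and sums absolute height differences between
#' calendar-adjacent coded minutes (total vertical path, ascent plus
#' descent; set \code{ascent_only = TRUE} for climbed-only). Pairs spanning
#' observation gaps are excluded.
#'
#' @param scans one male-day of scan records.
#' @param per \code{"hour"}: total vertical metres divided by coded
#'   observation hours (minutes with a height category / 60);
#'   \code{"minute"}: mean absolute height change per adjacent pair.
#' @param ascent_only count upward movement only.
#' @param cat6_height passed to [height_from_category()].
#' @return rate in metres (per hour or per minute), or \code{NA} when no
#'   adjacent coded pair exists.
#' @export
vertical_rate <- function(scans, per = c("hour", "minute"),
                          ascent_only = FALSE, cat6_height = 27.5) {
  per <- match.arg(per)
  ok <- !is.na(scans$height_category)
  minute <- scans$minute[ok]
  h <- height_from_category(scans$height_category[ok], cat6_height)
  if (length(minute) < 2L) return(NA_real_)
  adj <- which(diff(minute) == 1L)
  if (!length(adj)) return(NA_real_)
  dh <- h[adj + 1L] - h[adj]
  total <- if (ascent_only) sum(pmax(dh, 0)) else sum(abs(dh))
  switch(per,
         hour = total / (length(minute) / 60),
         minute = total / length(adj))
}

#' Daily movement metrics for every male-day
#'
#' Joins GPS-based horizontal travel and scan-based vertical travel per
#' male-day. GPS fixes are matched to scan days by calendar date (the fix
#' table carries no male id; supply per-male fixes via \code{gps_by_male}, a
#' named list of fix tables).
#'
#' @param scans scan records.
#' @param gps_by_male named list (by male id) of fix tables.
#' @param interval,tolerance subsampling parameters.
#' @return data.frame: \code{male_id}, \code{date}, \code{hourly_distance_m},
#'   \code{n_segments}, \code{hourly_vertical_m}, \code{vertical_m_per_min}.
#' @export
daily_movement <- function(scans, gps_by_male, interval = 15, tolerance = 5) {
  key <- interaction(scans$male_id, scans$date, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(scans)), key), function(idx) {
    day <- scans[idx, , drop = FALSE]
    m <- day$male_id[1]
    hd <- NA_real_; nseg <- 0L
    if (m %in% names(gps_by_male)) {
      g <- gps_by_male[[m]]
      g <- g[g$date == day$date[1], , drop = FALSE]
      if (nrow(g) >= 2L) {
        seg <- track_segments(subsample_fixes(g, interval, tolerance))
        nseg <- nrow(seg)
        if (nseg > 0L) hd <- hourly_distance(seg)
      }
    }
    data.frame(male_id = m, date = day$date[1],
               hourly_distance_m = hd, n_segments = nseg,
               hourly_vertical_m = vertical_rate(day, "hour"),
               vertical_m_per_min = vertical_rate(day, "minute"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$male_id, out$date), , drop = FALSE]
}

#' Expected spurious path length per hour from GPS fix error
#'
#' A stationary animal recorded with positional error still accumulates
#' apparent path length: with fixes every \code{interval} minutes and a mean
#' spurious displacement of \code{per_step_error} metres between consecutive
#' fixes, the expected apparent travel is \code{(60/interval) *
#' per_step_error} metres per hour -- e.g. 600 m/h at 1-min fixes with 10 m
#' error, dropping to 40 m/h at 15-min fixes. The Monte-Carlo mode draws
#' isotropic bivariate-normal fix errors calibrated so that the mean
#' consecutive-fix displacement equals \code{per_step_error} and reports the
#' realised apparent rate.
#'
#' @param interval_min fix interval in minutes (>= 1).
#' @param per_step_error_m mean spurious displacement between consecutive
#'   fixes, metres.
#' @param method \code{"analytic"} or \code{"monte_carlo"}.
#' @param steps number of simulated fixes for the Monte-Carlo mode.
#' @return metres of apparent travel per hour.
#' @export
expected_error_path <- function(interval_min, per_step_error_m,
                                method = c("analytic", "monte_carlo"),
                                steps = 1e5) {
  method <- match.arg(method)
  .stopifnot_scalar_number(interval_min, "interval_min", min = 1)
  .stopifnot_scalar_number(per_step_error_m, "per_step_error_m", min = 0)
  if (method == "analytic") {
    return(60 / interval_min * per_step_error_m)
  }
  if (per_step_error_m == 0) return(0)
  # error ~ N(0, s^2 I2); |e2 - e1| is Rayleigh(s*sqrt(2)), mean s*sqrt(pi)
  s <- per_step_error_m / sqrt(pi)
  ex <- rnorm(steps, sd = s); ey <- rnorm(steps, sd = s)
  disp <- sqrt(diff(ex)^2 + diff(ey)^2)
  sum(disp) / ((steps - 1) * interval_min / 60)
}

#' Convert a daily travel distance to an hourly rate
#'
#' @param km_per_day kilometres travelled per day.
#' @param active_hours length of the active day in hours (12 for a
#'   dawn-to-dusk equatorial forest day).
#' @return metres per hour.
#' @export
hourly_rate_from_daily <- function(km_per_day, active_hours = 12) {
  1000 * km_per_day / active_hours
}
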