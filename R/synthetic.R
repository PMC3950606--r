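# Synthetic study generator: emits a complete raw-data bundle (scans, GPS,
# phenology, rainfall, urine, interaction matrices) with known ground truth,
# structured like the field study it emulates: 3 wild groups, the alpha and
# beta male of each group as focal males, ~580 male-days over a mating
# period, urine from focal plus two low-ranking control males per group.

#' Configuration for the synthetic study generator
#'
#' Defaults mirror the study footprint: 3 groups with 2 focal (alpha, beta)
#' and 2 control males each, a 220-day mating period followed on an
#' alternate-day schedule giving roughly 580 usable male-days, per-male
#' mate-guarding prevalences spanning overall MG times of roughly 8--54 %,
#' 10 m GPS fix error, and mate-guarding effect sizes on the standardized
#' response scale equal to the fitted study estimates (feeding -2.16, fruit
#' in diet -2.97, vertical locomotion -1.76) with a null effect on urinary
#' C-peptide. See the methods vignette for the rationale behind every
#' default.
#'
#' @param n_groups,focal_per_group,controls_per_group study structure.
#' @param start_date first study day.
#' @param n_days length of the study period in days.
#' @param follow_schedule \code{"alternate"} (every other day per male) or
#'   \code{"daily"}.
#' @param p_follow probability a scheduled follow yields a usable day.
#' @param day_len_range range (minutes) of coded focal minutes per day.
#' @param day_start_minute first scan minute of the day (06:00).
#' @param mg_prevalence_range per-male range of the stationary probability
#'   of an extensive MG day; males are spread evenly across it.
#' @param mg_stay day-to-day persistence of MG periods (P(extensive
#'   tomorrow | extensive today)), giving mean period lengths of a few
#'   days.
#' @param mg_frac_range MG fraction of observation time on extensive days.
#' @param episode_len_mean mean MG episode length in minutes.
#' @param beta_mg_feeding,beta_mg_fruitdiet,beta_mg_vertical,beta_mg_ucp
#'   mate-guarding effects on the standardized response scale.
#' @param beta_fruit_feeding,beta_fruit_fruitdiet,beta_fruit_vertical fruit
#'   availability effects (standardized scale).
#' @param rho AR(1) correlation of day-to-day response residuals per male.
#' @param sd_male,sd_group random-intercept SDs (standardized scale).
#' @param gps_error_m isotropic per-fix GPS error (RMS radius, metres).
#' @param p_gps probability a followed day has a GPS tracklog.
#' @param p_oos,p_gap per-minute probabilities of out-of-sight coding and of
#'   a missing row (applied outside MG episodes).
#' @param trees_per_territory,fruit_p0,fruit_amp,fruit_phase phenology:
#'   surveyed trees per territory and the seasonal fruiting probability
#'   \code{p0 + amp * sin(2*pi*(month - phase)/12)}.
#' @param ucp_mean_ng_mg,ucp_sdlog urinary C-peptide lognormal scale.
#' @param seed RNG seed; the whole bundle is deterministic under it.
#' @return a \code{"study_config"} list.
#' @export
study_config <- function(n_groups = 3L, focal_per_group = 2L,
                         controls_per_group = 2L,
                         start_date = as.Date("2010-12-01"),
                         n_days = 220L,
                         follow_schedule = c("alternate", "daily"),
                         p_follow = 0.9,
                         day_len_range = c(360L, 660L),
                         day_start_minute = 360L,
                         mg_prevalence_range = c(0.08, 0.62),
                         mg_stay = 0.85,
                         mg_frac_range = c(0.55, 0.95),
                         episode_len_mean = 45,
                         beta_mg_feeding = -2.16,
                         beta_mg_fruitdiet = -2.97,
                         beta_mg_vertical = -1.76,
                         beta_mg_ucp = 0,
                         beta_fruit_feeding = -1.21,
                         beta_fruit_fruitdiet = 7.08,
                         beta_fruit_vertical = -1.87,
                         rho = 0.4,
                         sd_male = 0.5, sd_group = 0.3,
                         gps_error_m = 10, p_gps = 0.8,
                         p_oos = 0.04, p_gap = 0.03,
                         trees_per_territory = 120L,
                         fruit_p0 = 0.25, fruit_amp = 0.12,
                         fruit_phase = 3,
                         ucp_mean_ng_mg = 3, ucp_sdlog = 0.5,
                         seed = 1L) {
  cfg <- as.list(environment())
  cfg$follow_schedule <- match.arg(follow_schedule)
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$rho >= 0 && cfg$rho < 1, "rho must be in [0, 1)")
  chk(all(c(cfg$p_follow, cfg$p_gps, cfg$p_oos, cfg$p_gap, cfg$mg_stay,
            cfg$fruit_p0) >= 0 &
            c(cfg$p_follow, cfg$p_gps, cfg$p_oos, cfg$p_gap, cfg$mg_stay,
              cfg$fruit_p0) <= 1),
      "probabilities must be in [0, 1]")
  chk(all(c(cfg$sd_male, cfg$sd_group, cfg$ucp_sdlog) > 0) ||
        all(c(cfg$sd_male, cfg$sd_group, cfg$ucp_sdlog) >= 0),
      "SDs must be non-negative")
  chk(cfg$n_groups >= 1 && cfg$focal_per_group >= 1,
      "need at least one group and one focal male")
  chk(diff(range(cfg$mg_frac_range)) >= 0 && min(cfg$mg_frac_range) > 0.5,
      "mg_frac_range must lie above the 0.5 extensive threshold")
  if (length(problems)) {
    stop("invalid study config:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  structure(cfg, class = "study_config")
}

.with_seed <- function(seed, expr) {
  force(seed)   # must evaluate before the RNG state snapshot below
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# AR(1) series with marginal SD 1, correlation rho^(day gap) between
# consecutive observations (date-faithful: a two-day gap decorrelates more
# than a one-day gap)
.ar1 <- function(days, rho) {
  n <- length(days)
  if (n == 0L) return(numeric(0))
  e <- rnorm(n)
  x <- numeric(n)
  x[1] <- e[1]
  if (n > 1L) {
    r_step <- rho^diff(days)
    for (t in 2:n) {
      x[t] <- r_step[t - 1] * x[t - 1] + sqrt(1 - r_step[t - 1]^2) * e[t]
    }
  }
  x
}

.zstd <- function(x) {
  s <- sd(x)
  if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

#' Generate a complete synthetic study with known ground truth
#'
#' Produces the full raw-data bundle the pipeline consumes -- focal scans,
#' per-male GPS tracks, monthly phenology, daily rainfall, urine assays and
#' per-group bared-teeth matrices -- together with a \code{truth} list
#' recording, per male-day, the planted mate-guarding minutes, feeding and
#' fruit-feeding scan counts, vertical path and true GPS path length, plus
#' the effect-size vector used. Mate-guarding days follow a per-male
#' two-state Markov chain (periods of consecutive extensive days); scans
#' encode MG as episodes of qualifying following/distance minutes separated
#' by at least 3 non-qualifying minutes, so ground-truth MG minutes equal
#' segmentation output exactly on error-free scans. Behavioural responses
#' are generated on the standardized scale with additive AR(1) day effects
#' and mapped onto scan counts, height-category chains and GPS paths.
#'
#' @param config a [study_config()].
#' @return list with elements \code{scans}, \code{gps} (named list of fix
#'   tables), \code{phenology}, \code{rainfall}, \code{urine},
#'   \code{interactions} (named list of matrices), \code{males} (roster
#'   with group, role and planted rank) and \code{truth}.
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  .with_seed(config$seed, .generate_study_impl(config))
}

.generate_study_impl <- function(cfg) {
  groups <- paste0("G", seq_len(cfg$n_groups))
  males <- do.call(rbind, lapply(groups, function(g) {
    n <- cfg$focal_per_group + cfg$controls_per_group
    data.frame(male_id = sprintf("%s_m%d", g, seq_len(n)),
               group_id = g,
               role = c(rep("focal", cfg$focal_per_group),
                        rep("control", n - cfg$focal_per_group)),
               true_rank = seq_len(n), stringsAsFactors = FALSE)
  }))
  focal <- males$male_id[males$role == "focal"]
  dates <- cfg$start_date + 0:(cfg$n_days - 1L)

  # --- phenology, fruit index, rainfall --------------------------------
  months <- unique(.month_end(dates))
  months <- sort(unique(c(.month_end(cfg$start_date - 20), months)))
  phen <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(months, function(me) {
      mnum <- as.integer(format(me, "%m"))
      p <- min(max(cfg$fruit_p0 +
                     cfg$fruit_amp * sin(2 * pi * (mnum - cfg$fruit_phase) / 12) +
                     rnorm(1, 0, 0.02), 0.02), 0.98)
      fruiting <- runif(cfg$trees_per_territory) < p
      score <- ifelse(fruiting,
                      sample(1:5, cfg$trees_per_territory, replace = TRUE,
                             prob = c(0.4, 0.3, 0.15, 0.1, 0.05)), 0L)
      data.frame(territory_id = g,
                 tree_id = sprintf("%s_t%03d", g,
                                   seq_len(cfg$trees_per_territory)),
                 survey_date = me, fruit_score = as.integer(score),
                 stringsAsFactors = FALSE)
    }))
  }))
  fruit <- fruit_index_table(phen)
  rainfall <- data.frame(
    date = dates,
    rainfall_mm = round(ifelse(runif(length(dates)) < 0.45,
                               rgamma(length(dates), 0.9, scale = 13), 0), 1))

  # --- which male-days are followed, and their MG status ----------------
  prev <- seq(cfg$mg_prevalence_range[1], cfg$mg_prevalence_range[2],
              length.out = length(focal))
  daily <- list()
  for (k in seq_along(focal)) {
    m <- focal[k]
    pi_k <- prev[k]
    enter <- pi_k * (1 - cfg$mg_stay) / (1 - pi_k)
    ext <- logical(cfg$n_days)
    state <- runif(1) < pi_k
    for (d in seq_len(cfg$n_days)) {
      ext[d] <- state
      state <- runif(1) < if (state) cfg$mg_stay else enter
    }
    sched <- if (cfg$follow_schedule == "alternate") {
      seq((k %% 2L) + 1L, cfg$n_days, by = 2L)
    } else seq_len(cfg$n_days)
    followed <- sched[runif(length(sched)) < cfg$p_follow]
    L <- sample(seq(cfg$day_len_range[1], cfg$day_len_range[2]),
                length(followed), replace = TRUE)
    f <- ifelse(ext[followed],
                runif(length(followed), cfg$mg_frac_range[1],
                      cfg$mg_frac_range[2]),
                ifelse(runif(length(followed)) < 0.4,
                       runif(length(followed), 0.02, 0.35), 0))
    daily[[m]] <- data.frame(
      male_id = m, group_id = males$group_id[males$male_id == m],
      date = dates[followed], day_index = followed, L = L, mg_frac = f,
      extensive_true = ext[followed], stringsAsFactors = FALSE)
  }
  daily <- do.call(rbind, daily)
  rownames(daily) <- NULL

  # --- standardized-scale responses with AR(1) day effects --------------
  daily$mg_pct_target <- 100 * daily$mg_frac
  daily$fruit_index <- NA_real_
  for (g in groups) {
    idx <- daily$group_id == g
    daily$fruit_index[idx] <-
      assign_index(daily$date[idx], fruit[fruit$territory_id == g, ])
  }
  daily$rainfall_mm <- rainfall$rainfall_mm[match(daily$date,
                                                  rainfall$date)]
  z_mg <- .zstd(daily$mg_pct_target)
  z_fr <- .zstd(daily$fruit_index)
  u_male <- setNames(rnorm(length(focal), 0, cfg$sd_male), focal)
  u_group <- setNames(rnorm(length(groups), 0, cfg$sd_group), groups)
  re <- u_male[daily$male_id] + u_group[daily$group_id]
  ar_by_male <- function() {
    out <- numeric(nrow(daily))
    for (m in unique(daily$male_id)) {
      idx <- which(daily$male_id == m)
      o <- order(daily$date[idx])
      out[idx[o]] <- .ar1(as.numeric(daily$date[idx][o]), cfg$rho)
    }
    out
  }
  daily$y_feed <- cfg$beta_mg_feeding * z_mg +
    cfg$beta_fruit_feeding * z_fr + re + ar_by_male()
  daily$y_fruitdiet <- cfg$beta_mg_fruitdiet * z_mg +
    cfg$beta_fruit_fruitdiet * z_fr + re + ar_by_male()
  daily$y_vert <- cfg$beta_mg_vertical * z_mg +
    cfg$beta_fruit_vertical * z_fr + re + ar_by_male()
  daily$y_dist <- re + ar_by_male()          # no planted MG effect
  daily$y_rest <- re + ar_by_male()          # no planted MG effect

  # natural-scale targets (response SDs chosen so values stay in range)
  sc <- function(y) y / max(1, abs(cfg$beta_mg_feeding),
                            abs(cfg$beta_mg_fruitdiet),
                            abs(cfg$beta_fruit_fruitdiet)) # keep in (0,1)
  daily$p_feed <- pmin(pmax(0.30 + 0.06 * sc(daily$y_feed) * 3, 0.05), 0.70)
  daily$p_fruit <- pmin(pmax(0.55 + 0.12 * sc(daily$y_fruitdiet) * 3, 0.05),
                        0.95)
  daily$vert_target <- pmin(pmax(260 + 35 * daily$y_vert / 2, 30), 600)
  daily$dist_target <- pmin(pmax(140 + 25 * daily$y_dist / 2, 40), 400)
  daily$p_move <- pmin(pmax(0.35 + 0.08 * daily$y_rest / 2, 0.05), 0.90)

  # --- per-day scan construction ---------------------------------------
  females <- sprintf("F%02d", 1:15)
  scan_rows <- vector("list", nrow(daily))
  gps_rows <- list()
  truth_rows <- vector("list", nrow(daily))
  for (i in seq_len(nrow(daily))) {
    d <- daily[i, ]
    day <- .generate_day(d, cfg, females)
    scan_rows[[i]] <- day$scans
    truth_rows[[i]] <- day$truth
    if (runif(1) < cfg$p_gps) {
      gps_rows[[length(gps_rows) + 1L]] <-
        cbind(male_id = d$male_id, day$gps, stringsAsFactors = FALSE)
    }
  }
  scans <- do.call(rbind, scan_rows)
  rownames(scans) <- NULL
  truth_daily <- do.call(rbind, truth_rows)
  gps_all <- do.call(rbind, gps_rows)
  gps <- lapply(split(gps_all[, -1], gps_all$male_id), function(g) {
    g[order(g$timestamp), , drop = FALSE]
  })

  # --- urine sampling ---------------------------------------------------
  lyo_date <- max(dates) + 75
  urine <- list()
  for (j in seq_len(nrow(males))) {
    m <- males$male_id[j]
    coll <- dates[seq(sample(1:7, 1), cfg$n_days, by = 7L)]
    if (males$role[j] == "focal") {
      mg_days <- daily$date[daily$male_id == m & daily$extensive_true]
      coll <- sort(unique(c(coll, mg_days[seq_len(length(mg_days)) %% 2L ==
                                            1L])))
    }
    sub <- daily[daily$male_id == m, , drop = FALSE]
    mgf <- sub$mg_frac[match(coll, sub$date)]
    mgf[is.na(mgf)] <- 0
    y_ucp <- cfg$beta_mg_ucp * .zstd(100 * mgf) * 0.25
    true_mean <- cfg$ucp_mean_ng_mg * exp(y_ucp + rnorm(1, 0, 0.15))
    ucp_val <- rlnorm(length(coll), log(true_mean) - cfg$ucp_sdlog^2 / 2,
                      cfg$ucp_sdlog)
    creat <- rlnorm(length(coll), log(1), 0.45)
    dilute <- runif(length(coll)) < 0.02
    creat[dilute] <- runif(sum(dilute), 0.01, 0.09)
    vol <- round(runif(length(coll), 0.2, 1.5), 1)
    urine[[m]] <- data.frame(
      male_id = m,
      collection_datetime = .format_timestamp(
        coll, 360L + sample(0:360, length(coll), replace = TRUE)),
      cpeptide_ng_per_ml = round(ucp_val * creat, 4),
      creatinine_mg_per_ml = round(creat, 4),
      storage_months = round(as.numeric(lyo_date - coll) / 30.44, 2),
      original_volume_ml = vol,
      reconstitution_volume_ml = ifelse(vol < 0.5, 0.3, 0.5),
      ucp_true_ng_mg = round(ucp_val, 4),
      stringsAsFactors = FALSE)
  }
  urine <- do.call(rbind, urine)
  rownames(urine) <- NULL

  # --- bared-teeth matrices from the planted hierarchy ------------------
  interactions <- lapply(setNames(groups, groups), function(g) {
    ids <- males$male_id[males$group_id == g]
    n <- length(ids)
    m <- matrix(0L, n, n, dimnames = list(ids, ids))
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        m[b, a] <- rpois(1, 4) + 1L       # subordinate signals to dominant
        if (runif(1) < 0.05) m[a, b] <- rpois(1, 1) + 1L
      }
    }
    m
  })

  list(scans = scans, gps = gps, phenology = phen, rainfall = rainfall,
       urine = urine[, setdiff(names(urine), "ucp_true_ng_mg")],
       interactions = interactions, males = males,
       truth = list(
         daily = truth_daily,
         responses = daily,
         urine_truth = urine[, c("male_id", "collection_datetime",
                                 "ucp_true_ng_mg")],
         beta = c(mg_feeding = cfg$beta_mg_feeding,
                  mg_fruitdiet = cfg$beta_mg_fruitdiet,
                  mg_vertical = cfg$beta_mg_vertical,
                  mg_ucp = cfg$beta_mg_ucp),
         config = cfg))
}

# one male-day: scans + error-free/SD-error GPS + truth bookkeeping
.generate_day <- function(d, cfg, females) {
  L <- d$L
  minutes <- cfg$day_start_minute + 0:(L - 1L)

  # MG episode layout: blocks of >= 6 qualifying minutes, gaps >= 3
  M <- round(d$mg_frac * L)
  if (M > 0 && M < 6L) M <- 6L
  blocks <- list()
  remaining <- M
  while (remaining >= 6L) {
    len <- min(remaining, max(6L, round(rgamma(1, 2, scale =
                                                 cfg$episode_len_mean / 2))))
    if (remaining - len < 6L) len <- remaining
    blocks[[length(blocks) + 1L]] <- len
    remaining <- remaining - len
  }
  nb <- length(blocks)
  mg_mask <- rep(FALSE, L)
  if (nb > 0L) {
    lens <- unlist(blocks)
    free <- L - sum(lens) - 3L * (nb - 1L)
    if (free < 0) {                      # day nearly saturated with MG
      lens <- rep(floor((L - 3L * (nb - 1L)) / nb), nb)
      free <- L - sum(lens) - 3L * (nb - 1L)
    }
    cuts <- sort(sample.int(free + nb, nb)) - seq_len(nb)
    pos <- 1L
    starts <- integer(nb)
    gap_before <- c(cuts[1], diff(cuts)) + c(0L, rep(3L, nb - 1L))
    for (b in seq_len(nb)) {
      pos <- pos + gap_before[b]
      starts[b] <- pos
      mg_mask[pos:(pos + lens[b] - 1L)] <- TRUE
      pos <- pos + lens[b]
    }
  }
  # guarded female: one per day (switches between days/periods)
  fem <- sample(females, 1L)

  # out-of-sight and missing minutes, only outside MG episodes
  non_mg <- which(!mg_mask)
  oos <- non_mg[runif(length(non_mg)) < cfg$p_oos]
  gap <- setdiff(non_mg[runif(length(non_mg)) < cfg$p_gap], oos)

  keep <- setdiff(seq_len(L), gap)
  n_keep <- length(keep)
  coded <- setdiff(keep, oos)

  # feeding scans and diet among coded minutes
  n_feed <- round(d$p_feed * length(coded))
  feed_idx <- if (n_feed > 0) sample(coded, n_feed) else integer(0)
  n_fruit <- round(d$p_fruit * n_feed)
  fruit_idx <- if (n_fruit > 0) sample(feed_idx, n_fruit) else integer(0)
  other_items <- sample(c("leaf", "flower", "arthropod", "other"),
                        max(0L, n_feed - n_fruit), replace = TRUE,
                        prob = c(0.55, 0.2, 0.15, 0.1))

  activity <- rep(NA_character_, L)
  activity[coded] <- sample(c("resting", "travelling", "vigilant",
                              "grooming", "self_grooming", "affiliating",
                              "aggressing", "drinking"),
                            length(coded), replace = TRUE,
                            prob = c(0.42, 0.2, 0.12, 0.1, 0.06, 0.05,
                                     0.02, 0.03))
  activity[feed_idx] <- "feeding"
  activity[oos] <- "out_of_sight"
  food <- rep(NA_character_, L)
  food[fruit_idx] <- "fruit"
  food[setdiff(feed_idx, fruit_idx)] <- other_items

  # locomotion chain: change with p_move, uniformly to a new state
  loco <- character(L)
  loco[1] <- sample(.mg_locomotion, 1L)
  ch <- runif(L) < d$p_move
  for (t in 2:L) {
    loco[t] <- if (ch[t]) sample(setdiff(.mg_locomotion, loco[t - 1]), 1L)
    else loco[t - 1]
  }
  loco[oos] <- NA_character_

  # height-category chain targeting the vertical rate (5 m per step)
  q <- min(max(d$vert_target / 300, 0.02), 0.95)
  hcat <- integer(L)
  hcat[1] <- sample(1:4, 1L)
  hch <- runif(L) < q
  dir <- sample(c(-1L, 1L), L, replace = TRUE)
  for (t in 2:L) {
    hcat[t] <- hcat[t - 1]
    if (hch[t]) {
      nxt <- hcat[t - 1] + dir[t]
      if (nxt < 0L || nxt > 6L) nxt <- hcat[t - 1] - dir[t]
      hcat[t] <- nxt
    }
  }
  hcat_full <- hcat
  hcat[oos] <- NA_integer_

  # decoy following runs (< 6 min, >= 3 min away from episodes)
  follow <- rep(NA_character_, L)
  dist_ok <- rep(NA, L)
  follow[mg_mask] <- fem
  dist_ok[mg_mask] <- TRUE
  if (runif(1) < 0.35) {
    near_mg <- which(mg_mask)
    cand <- setdiff(coded, unlist(lapply(near_mg, function(x)
      (x - 3L):(x + 3L))))
    if (length(cand) > 6L) {
      st <- sample(cand, 1L)
      run <- st:min(st + sample(2:5, 1L) - 1L, L)
      run <- run[!mg_mask[run] & run %in% coded]
      if (length(run) && all(diff(run) == 1L) &&
          !any((min(run) - 3L):(max(run) + 3L) %in% near_mg)) {
        follow[run] <- sample(setdiff(females, fem), 1L)
        dist_ok[run] <- runif(length(run)) < 0.7
      }
    }
  }

  scans <- data.frame(
    male_id = d$male_id, date = d$date, minute = minutes,
    activity = activity, locomotion_position = loco,
    height_category = hcat, food_item = food,
    following_female = follow, female_distance_le_10m = dist_ok,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(scans) <- NULL

  # GPS: persistent-heading walk at the per-minute speed matching the
  # target hourly rate, plus isotropic fix error
  v <- d$dist_target / 60 / 0.87        # tortuosity of the heading walk
  heading <- cumsum(rnorm(L, 0, 0.18))
  step <- pmax(rnorm(L, v, v * 0.25), 0)
  tx <- cumsum(step * cos(heading))
  ty <- cumsum(step * sin(heading))
  err_s <- cfg$gps_error_m / sqrt(2)    # RMS radius = gps_error_m
  gx <- tx + rnorm(L, 0, err_s)
  gy <- ty + rnorm(L, 0, err_s)
  ts <- as.POSIXct(paste(d$date), tz = "UTC") + minutes * 60
  gps <- data.frame(timestamp = ts, date = d$date, minute = minutes,
                    x = gx, y = gy,
                    has_focal_behaviour = seq_len(L) %in% coded,
                    stringsAsFactors = FALSE)

  h_m <- height_from_category(hcat_full)
  truth <- data.frame(
    male_id = d$male_id, date = d$date,
    observed_min = length(coded), scanned_min = n_keep,
    mg_min_true = sum(mg_mask), mg_frac_true = d$mg_frac,
    extensive_true = d$extensive_true,
    n_feed_true = n_feed, n_fruit_true = n_fruit,
    vertical_m_true = sum(abs(diff(h_m))),
    path_len_m_true = sum(step[-1]),
    stringsAsFactors = FALSE)

  list(scans = scans, gps = gps, truth = truth)
}

#' Write a synthetic study bundle to disk in the package CSV dialects
#'
#' @param study output of [generate_study()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_scans(study$scans, file.path(dir, "scans.csv"))
  write_phenology(study$phenology, file.path(dir, "phenology.csv"))
  write_rainfall(study$rainfall, file.path(dir, "rainfall.csv"))
  write_urine(study$urine, file.path(dir, "urine.csv"))
  for (m in names(study$gps)) {
    g <- study$gps[[m]]
    out <- data.frame(timestamp = format(g$timestamp, "%Y-%m-%dT%H:%M:%S",
                                         tz = "UTC"),
                      x = sprintf("%.3f", g$x), y = sprintf("%.3f", g$y),
                      has_focal_behaviour =
                        .format_logical(g$has_focal_behaviour))
    write.csv(out, file.path(dir, paste0("gps_", m, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  for (g in names(study$interactions)) {
    write_interaction_matrix(study$interactions[[g]],
                             file.path(dir, paste0("bared_teeth_", g,
                                                   ".csv")))
  }
  write.csv(study$males, file.path(dir, "males.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}

#' Simulate a behavioural model table at study scale
#'
#' Generates the assembled per-male-day model table directly (no scans),
#' with the response on the standardized scale:
#' \deqn{y = \beta_{MG} z(MG\%) + \beta_{fruit} z(fruit) + \beta_{rain}
#'   z(rain) + u_{male} + u_{group} + \epsilon,}
#' where \eqn{\epsilon} is AR(1) within male over days with marginal SD
#' \code{sd_resid}. Used for likelihood-ratio-test calibration and
#' effect-recovery simulations where the raw-data layer is irrelevant.
#'
#' @param n_males,n_groups,days_per_male study scale (defaults approximate
#'   the study: 6 focal males in 3 groups, ~580 male-days).
#' @param beta_mg,beta_fruit,beta_rain fixed effects (standardized scale).
#' @param rho AR(1) correlation; \code{sd_resid} its marginal SD.
#' @param sd_male,sd_group random-intercept SDs.
#' @param sd_resid residual marginal SD.
#' @param seed RNG seed (restored on exit).
#' @return data.frame with \code{male_id}, \code{group_id}, \code{date},
#'   \code{mg_pct}, \code{fruit_index}, \code{rainfall_mm} and \code{y}.
#' @export
simulate_model_table <- function(n_males = 6L, n_groups = 3L,
                                 days_per_male = 97L, beta_mg = 0,
                                 beta_fruit = -1.2, beta_rain = 0.2,
                                 rho = 0.4, sd_male = 0.5, sd_group = 0.3,
                                 sd_resid = 1, seed = 1L) {
  .with_seed(seed, {
    males <- sprintf("m%02d", seq_len(n_males))
    grp <- paste0("G", rep_len(seq_len(n_groups), n_males))
    rows <- lapply(seq_len(n_males), function(k) {
      day <- sort(sample.int(2L * days_per_male, days_per_male))
      # zero-inflated MG time, clustered into runs like real MG periods
      ext <- logical(days_per_male)
      state <- FALSE
      pi_k <- runif(1, 0.1, 0.5)
      enter <- pi_k * 0.25 / (1 - pi_k)
      for (d in seq_len(days_per_male)) {
        ext[d] <- state
        state <- runif(1) < if (state) 0.75 else enter
      }
      mg <- ifelse(ext, runif(days_per_male, 55, 95),
                   ifelse(runif(days_per_male) < 0.4,
                          runif(days_per_male, 2, 35), 0))
      data.frame(male_id = males[k], group_id = grp[k],
                 date = as.Date("2010-12-01") + day,
                 day = day, mg_pct = mg, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    month <- as.integer(format(tab$date, "%m"))
    fr_month <- 25 + 12 * sin(2 * pi * (seq_len(12) - 3) / 12)
    g_off <- setNames(rnorm(n_groups, 0, 2), unique(grp))
    tab$fruit_index <- fr_month[month] + g_off[tab$group_id]
    tab$rainfall_mm <- ifelse(runif(nrow(tab)) < 0.45,
                              rgamma(nrow(tab), 0.9, scale = 13), 0)
    u_m <- setNames(rnorm(n_males, 0, sd_male), males)
    u_g <- setNames(rnorm(n_groups, 0, sd_group), unique(grp))
    eps <- numeric(nrow(tab))
    for (m in males) {
      idx <- which(tab$male_id == m)
      o <- order(tab$day[idx])
      eps[idx[o]] <- .ar1(tab$day[idx][o], rho) * sd_resid
    }
    tab$y <- beta_mg * .zstd(tab$mg_pct) +
      beta_fruit * .zstd(tab$fruit_index) +
      beta_rain * .zstd(tab$rainfall_mm) +
      u_m[tab$male_id] + u_g[tab$group_id] + eps
    tab$day <- NULL
    rownames(tab) <- NULL
    tab
  })
}

#' Tiny hand-auditable worked scan days for segmentation edge cases
#'
#' Each scenario is a short (<= 120 minute) single male-day encoding one
#' segmentation rule, with the expected episode table attached:
#' \describe{
#'   \item{boundary_5min}{exactly 5 qualifying minutes -- no episode (the
#'     rule is strictly more than five).}
#'   \item{grace_window}{8 qualifying, 2 beyond 10 m, 8 qualifying -- one
#'     18-minute episode.}
#'   \item{female_switch}{10 minutes on one female then 10 on another --
#'     two episodes.}
#'   \item{gap}{6 qualifying, a 3-minute observation gap, 6 qualifying --
#'     two episodes.}
#' }
#'
#' @param scenario scenario name.
#' @return list with \code{scans} and \code{expected_episodes}.
#' @export
emit_worked_day <- function(scenario = c("boundary_5min", "grace_window",
                                         "female_switch", "gap")) {
  scenario <- match.arg(scenario)
  base <- function(n, start = 480L) data.frame(
    male_id = "m01", date = as.Date("2011-01-10"),
    minute = start + 0:(n - 1L), activity = "resting",
    locomotion_position = "sitting", height_category = 2L,
    food_item = NA_character_, following_female = NA_character_,
    female_distance_le_10m = NA, stringsAsFactors = FALSE)
  exp_ep <- function(f, s, e) data.frame(
    male_id = rep("m01", length(f)),
    date = rep(as.Date("2011-01-10"), length(f)), female_id = f,
    start_minute = 480L + s, end_minute = 480L + e,
    duration_min = e - s + 1L, stringsAsFactors = FALSE)

  if (scenario == "boundary_5min") {
    sc <- base(20L)
    sc$following_female[1:5] <- "F01"
    sc$female_distance_le_10m[1:5] <- TRUE
    exp <- exp_ep(character(0), integer(0), integer(0))
  } else if (scenario == "grace_window") {
    sc <- base(30L)
    sc$following_female[c(1:8, 11:18)] <- "F01"
    sc$female_distance_le_10m[c(1:8, 11:18)] <- TRUE
    sc$following_female[9:10] <- "F01"          # female moved beyond 10 m
    sc$female_distance_le_10m[9:10] <- FALSE
    exp <- exp_ep("F01", 0L, 17L)
  } else if (scenario == "female_switch") {
    sc <- base(30L)
    sc$following_female[1:10] <- "F01"
    sc$following_female[11:20] <- "F02"
    sc$female_distance_le_10m[1:20] <- TRUE
    exp <- rbind(exp_ep("F01", 0L, 9L), exp_ep("F02", 10L, 19L))
  } else {
    sc <- base(15L)
    sc$following_female <- "F01"
    sc$female_distance_le_10m <- TRUE
    sc <- sc[-(7:9), ]                          # 3-minute observation gap
    exp <- rbind(exp_ep("F01", 0L, 5L), exp_ep("F01", 9L, 14L))
  }
  list(scans = sc, expected_episodes = exp)
}
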