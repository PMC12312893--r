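#' Study window: closure period and its open-year twin
#'
#' The closure window is given for 2020; the matched 2019 window spans the
#' identical month-days, so the two periods are seasonally comparable. The
#' default (1 April - 28 May) is a 58-day closure, the mean closure duration
#' across parks in the study system.
#'
#' @param closure_start,closure_end `Date`s (or parseable strings) in 2020,
#'   `closure_start < closure_end`.
#' @param park_id Optional park label.
#' @return Object of class `study_window` with POSIXct bounds `start_2019`,
#'   `end_2019`, `start_2020`, `end_2020` (closed intervals, UTC; the end day
#'   runs to 23:59:59).
#' @export
study_window <- function(closure_start = "2020-04-01",
                         closure_end = "2020-05-28", park_id = "P1") {
  s <- as.Date(closure_start); e <- as.Date(closure_end)
  if (is.na(s) || is.na(e)) stop("invalid closure dates")
  if (format(s, "%Y") != "2020" || format(e, "%Y") != "2020")
    stop("closure dates must fall in 2020")
  if (s >= e) stop("closure_start must precede closure_end")
  md <- function(d) format(d, "%m-%d")
  day_start <- function(d) as.POSIXct(paste(d, "00:00:00"), tz = "UTC")
  day_end <- function(d) as.POSIXct(paste(d, "23:59:59"), tz = "UTC")
  structure(list(
    park_id = park_id,
    start_2020 = day_start(s), end_2020 = day_end(e),
    start_2019 = day_start(as.Date(paste0("2019-", md(s)))),
    end_2019 = day_end(as.Date(paste0("2019-", md(e))))),
    class = "study_window")
}

window_for_year <- function(window, year) {
  year <- as.character(year)
  if (!year %in% c("2019", "2020")) stop("year must be 2019 or 2020")
  list(start = window[[paste0("start_", year)]],
       end = window[[paste0("end_", year)]])
}

#' Inclusion thresholds for individual-year datasets
#'
#' @param min_fixes Minimum retained locations per individual-year
#'   (default 30; must be >= 2).
#' @param max_outside_fraction Maximum tolerated share of fixes outside the
#'   park boundary (default 0.5: more than half outside means exclusion).
#' @param min_mean_footprint Minimum mean footprint over the home range
#'   (default 0.001); excludes animals with essentially no footprint
#'   exposure, for which the footprint coefficient is unidentifiable.
#' @return An `inclusion_thresholds` list.
#' @export
inclusion_thresholds <- function(min_fixes = 30, max_outside_fraction = 0.5,
                                 min_mean_footprint = 0.001) {
  if (min_fixes < 2) stop("min_fixes must be >= 2")
  if (max_outside_fraction < 0 || max_outside_fraction > 1)
    stop("max_outside_fraction must be in [0, 1]")
  structure(list(min_fixes = min_fixes,
                 max_outside_fraction = max_outside_fraction,
                 min_mean_footprint = min_mean_footprint),
            class = "inclusion_thresholds")
}

check_sorted <- function(track) {
  for (id in unique(track$animal_id)) {
    tt <- track$timestamp[track$animal_id == id]
    if (is.unsorted(as.numeric(tt)))
      stop("track not time-sorted for individual ", id)
  }
  invisible(TRUE)
}

#' Screen GPS error fixes
#'
#' Removes, per individual: (i) fixes whose timestamp duplicates the previous
#' retained fix within `duplicate_tolerance_s`, and (ii) fixes implying a
#' straight-line speed above `max_speed_mps` from the previous *retained*
#' fix. Every removal is logged with a machine-readable reason.
#'
#' @param track Data frame with `animal_id`, `timestamp` (POSIXct), `x`, `y`;
#'   time-sorted within individual.
#' @param max_speed_mps Speed threshold (m/s), default 10.
#' @param duplicate_tolerance_s Two fixes closer in time than this are
#'   duplicates (default 0: exact duplicates only).
#' @return List with `track` (retained fixes) and `log` (data.frame
#'   `animal_id`, `timestamp`, `reason` in `{"duplicate", "speed"}`).
#' @export
filter_gps_errors <- function(track, max_speed_mps = 10,
                              duplicate_tolerance_s = 0) {
  check_sorted(track)
  keep <- rep(TRUE, nrow(track))
  reason <- rep(NA_character_, nrow(track))
  for (id in unique(track$animal_id)) {
    rows <- which(track$animal_id == id)
    last <- NA_integer_
    for (r in rows) {
      if (is.na(last)) { last <- r; next }
      dt <- as.numeric(track$timestamp[r]) - as.numeric(track$timestamp[last])
      if (dt <= duplicate_tolerance_s) {
        keep[r] <- FALSE; reason[r] <- "duplicate"; next
      }
      dd <- sqrt((track$x[r] - track$x[last])^2 +
                 (track$y[r] - track$y[last])^2)
      if (dd / dt > max_speed_mps) {
        keep[r] <- FALSE; reason[r] <- "speed"; next
      }
      last <- r
    }
  }
  list(track = track[keep, , drop = FALSE],
       log = data.frame(animal_id = track$animal_id[!keep],
                        timestamp = track$timestamp[!keep],
                        reason = reason[!keep]))
}

#' Harmonise fix intervals
#'
#' Tracks sampled faster than the target interval are thinned to it: for each
#' successive target time (starting at the first fix) the nearest fix within
#' `tolerance_h` is kept, ties going to the earlier fix, and the next target
#' is anchored at the kept fix. Tracks whose median interval already meets or
#' exceeds the target are returned unchanged, maintaining original fix
#' intervals for data with lower sampling rates. The operation is idempotent.
#'
#' @param track Time-sorted fix data.frame for one or more individuals.
#' @param target_interval_h Target fix interval in hours (default 4; a 24 h
#'   interval reproduces the coarse-resampling sensitivity configuration).
#' @param tolerance_h Matching tolerance in hours (default 0.5).
#' @return The resampled fix data.frame.
#' @export
resample_track <- function(track, target_interval_h = 4, tolerance_h = 0.5) {
  if (target_interval_h <= 0) stop("target_interval_h must be positive")
  check_sorted(track)
  if (nrow(track) == 0) return(track)
  target_s <- target_interval_h * 3600
  tol_s <- tolerance_h * 3600
  out <- lapply(split(track, track$animal_id), function(tr) {
    n <- nrow(tr)
    if (n < 3) return(tr)
    tt <- as.numeric(tr$timestamp)
    if (stats::median(diff(tt)) >= target_s) return(tr)
    keep <- 1L
    cur <- 1L
    repeat {
      goal <- tt[cur] + target_s
      cand <- which(tt >= goal - tol_s & tt <= goal + tol_s & tt > tt[cur])
      if (length(cand) == 0) {
        nxt <- which(tt > goal + tol_s)  # jump the gap to the next fix
        if (length(nxt) == 0) break
        cur <- nxt[1]
      } else {
        cur <- cand[which.min(abs(tt[cand] - goal))]  # tie -> earlier fix
      }
      keep <- c(keep, cur)
      if (cur == n) break
    }
    tr[keep, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Clip a track to a study window
#'
#' Keeps fixes inside the closed interval of the given year's window and
#' attaches the year label.
#'
#' @param track Fix data.frame.
#' @param window A [study_window()].
#' @param year 2019 or 2020.
#' @return Fix data.frame with a `year` column.
#' @export
clip_to_window <- function(track, window, year) {
  win <- window_for_year(window, year)
  keep <- track$timestamp >= win$start & track$timestamp <= win$end
  out <- track[keep, , drop = FALSE]
  out$year <- rep(as.character(year), nrow(out))
  rownames(out) <- NULL
  out
}

#' Apply individual-year inclusion filters
#'
#' Drops individual-year groups with too few fixes, with more than the
#' allowed share of fixes outside the park, or whose home range has less
#' than the minimum mean footprint. Every exclusion is reported once with
#' the rule that triggered it; kept plus dropped equals the input.
#'
#' @param groups Named list of individual-year fix data.frames (names
#'   `"<animal>_<year>"`).
#' @param park Park boundary ring matrix (or list of rings).
#' @param footprint Footprint [fp_raster()].
#' @param thresholds An [inclusion_thresholds()].
#' @param home_ranges Named list of [estimate_kud()] home ranges aligned with
#'   `groups` (only needed for groups that pass the first two rules).
#' @return List with `kept` (list of groups) and `report` (data.frame
#'   `group`, `rule`, `value`).
#' @export
apply_inclusion_filters <- function(groups, park, footprint, thresholds,
                                    home_ranges = list()) {
  if (is.null(park)) stop("park polygon is required")
  kept <- list()
  rep_rows <- list()
  excl <- function(g, rule, value)
    data.frame(group = g, rule = rule, value = value)
  for (g in names(groups)) {
    tr <- groups[[g]]
    if (nrow(tr) < thresholds$min_fixes) {
      rep_rows[[g]] <- excl(g, "insufficient_data", nrow(tr)); next
    }
    outside <- mean(!points_in_polygon(cbind(tr$x, tr$y), park))
    if (outside > thresholds$max_outside_fraction) {
      rep_rows[[g]] <- excl(g, "outside_park", outside); next
    }
    hr <- home_ranges[[g]]
    if (!is.null(hr)) {
      mf <- home_range_mean_footprint(hr, footprint)
      if (is.na(mf) || mf < thresholds$min_mean_footprint) {
        rep_rows[[g]] <- excl(g, "limited_footprint", mf); next
      }
    }
    kept[[g]] <- tr
  }
  list(kept = kept,
       report = if (length(rep_rows)) do.call(rbind, rep_rows)
                else data.frame(group = character(), rule = character(),
                                value = numeric()))
}

# Mean footprint over raster cells whose centres fall inside a home range.
home_range_mean_footprint <- function(home_range, footprint) {
  g <- footprint$grid
  ctr <- grid_centers(g)
  pts <- cbind(rep(ctr$x, each = g$nrow), rep(ctr$y, times = g$ncol))
  bb <- home_range_bbox(home_range)
  cand <- which(pts[, 1] >= bb[1] & pts[, 1] <= bb[2] &
                pts[, 2] >= bb[3] & pts[, 2] <= bb[4])
  if (length(cand) == 0) return(NA_real_)
  inside <- points_in_polygon(pts[cand, , drop = FALSE], home_range$rings)
  if (!any(inside)) return(NA_real_)
  mean(as.numeric(footprint$values)[cand[inside]])
}

#' Prepare raw telemetry into individual-year groups
#'
#' Convenience wrapper chaining the error filter, the interval resampler and
#' the window clip, then splitting into individual-year groups.
#'
#' @param fixes Raw fix data.frame (`animal_id`, `timestamp`, `x`, `y`).
#' @param window A [study_window()].
#' @param years Years to clip to (default both).
#' @param max_speed_mps,target_interval_h,tolerance_h Passed through.
#' @return List with `groups` (named list `"<animal>_<year>"`) and
#'   `error_log`.
#' @export
prep_tracks <- function(fixes, window, years = c("2019", "2020"),
                        max_speed_mps = 10, target_interval_h = 4,
                        tolerance_h = 0.5) {
  flt <- filter_gps_errors(fixes, max_speed_mps)
  res <- resample_track(flt$track, target_interval_h, tolerance_h)
  groups <- list()
  for (y in years) {
    cl <- clip_to_window(res, window, y)
    for (id in unique(cl$animal_id)) {
      gr <- cl[cl$animal_id == id, , drop = FALSE]
      if (nrow(gr)) groups[[paste(id, y, sep = "_")]] <- gr
    }
  }
  list(groups = groups, error_log = flt$log)
}
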