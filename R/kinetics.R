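# Synaptic residence-time and exchange-rate kinetics. Each trajectory is
# labelled frame-by-frame as synaptic (inside a delineated region) or
# extrasynaptic, brief excursions shorter than three frames (<= 100 ms at
# 50 ms frame interval by default) are merged away, and trajectories with at
# least four remaining transitions contribute to the population kinetics.

# Fill missing-frame runs: inherit when both neighbours agree, otherwise
# split at the midpoint (left state takes the first ceil(n/2) frames).
fill_missing_states <- function(states) {
  na <- is.na(states)
  if (!any(na)) return(states)
  r <- rle(na)
  pos <- cumsum(r$lengths) - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i0 <- pos[k]; i1 <- i0 + r$lengths[k] - 1L
    left <- if (i0 > 1) states[i0 - 1L] else NA
    right <- if (i1 < length(states)) states[i1 + 1L] else NA
    if (is.na(left)) left <- right
    if (is.na(right)) right <- left
    if (left == right) {
      states[i0:i1] <- left
    } else {
      nl <- ceiling(r$lengths[k] / 2)
      states[i0:(i0 + nl - 1L)] <- left
      if (nl < r$lengths[k]) states[(i0 + nl):i1] <- right
    }
  }
  states
}

# Merge runs shorter than min_frames into the adjoining state, shortest runs
# first (ties: earliest), iterating until none remain (or one run is left).
merge_short_runs <- function(states, min_frames) {
  repeat {
    r <- rle(states)
    if (length(r$lengths) <= 1) return(states)
    short <- which(r$lengths < min_frames)
    if (length(short) == 0) return(states)
    k <- short[which.min(r$lengths[short])]
    nb <- if (k == 1) 2L else k - 1L
    r$values[k] <- r$values[nb]
    states <- inverse.rle(r)
  }
}

#' Segment trajectories into synaptic/extrasynaptic visits
#'
#' Labels every frame of each trajectory as synaptic (inside any region,
#' boundary included) or extrasynaptic, fills missed frames from their
#' neighbours (splitting at the midpoint when the flanking states disagree),
#' merges visits shorter than `min_visit_frames` into the adjoining state,
#' and returns the filtered visit list. A visit's duration is its frame
#' count times the frame interval, so a 3-frame visit at 50 ms spans 150 ms
#' and survives the "100 ms or less" filter. Trajectories qualify for
#' kinetics when they retain at least `min_transitions` transitions.
#'
#' @param traj Trajectory tibble.
#' @param regions Region table (Method 1 geometry by default; buffer the
#'   regions first for other definitions).
#' @param min_visit_frames Minimum visit length in frames (default 3).
#' @param frame_interval Frame interval in s (inferred from `t_s` if absent).
#' @param min_transitions Transitions needed to qualify (default 4).
#' @return Tibble of visits: track_id, state ("S"/"E"), start_frame,
#'   end_frame, n_frames, duration_s, with per-track metadata columns
#'   n_transitions and qualifies; frame interval stored in attribute
#'   `frame_interval`.
#' @export
segment_visits <- function(traj, regions, min_visit_frames = 3,
                           frame_interval = NULL, min_transitions = 4) {
  traj <- as_trajectories(traj)
  if (nrow(traj) == 0) abort("trajectory with no localized frames")
  dt <- traj_dt(traj, frame_interval)
  inside <- rep(FALSE, nrow(traj))
  for (i in seq_len(nrow(regions))) {
    poly <- as_ring(regions$polygon[[i]])
    inside <- inside | points_in_ring(traj$x_um, traj$y_um, poly)
  }
  traj$state <- ifelse(inside, "S", "E")
  one <- function(d) {
    f0 <- min(d$frame)
    span <- max(d$frame) - f0 + 1L
    states <- rep(NA_character_, span)
    states[d$frame - f0 + 1L] <- d$state
    states <- fill_missing_states(states)
    states <- merge_short_runs(states, min_visit_frames)
    v <- runs_to_visits(states, dt)
    v$start_frame <- v$start_frame + f0
    v$end_frame <- v$end_frame + f0
    v$n_transitions <- nrow(v) - 1L
    v$qualifies <- v$n_transitions[1] >= min_transitions
    v
  }
  out <- dplyr::ungroup(
    dplyr::group_modify(dplyr::group_by(traj, .data$track_id), ~ one(.x)))
  attr(out, "frame_interval") <- dt
  out
}

#' Per-trajectory kinetics summary
#'
#' Condenses a visit segmentation into one row per trajectory: transition
#' count, observed duration (first to last localized frame, inclusive),
#' synaptic residence time and synaptic-extrasynaptic exchange rate.
#' Residence time is the mean duration of synaptic visits, excluding the
#' first and last visit of the trajectory whose true length is censored by
#' the observation window (set `include_censored = TRUE` to keep them).
#' Non-qualifying trajectories get NA kinetics.
#'
#' @param visits Output of [segment_visits()].
#' @param include_censored Include boundary-truncated first/last visits in
#'   the residence-time mean (default FALSE).
#' @return Tibble: track_id, n_transitions, duration_s, residence_s,
#'   exchange_hz, qualifies.
#' @export
kinetics_summary <- function(visits, include_censored = FALSE) {
  dt <- attr(visits, "frame_interval")
  if (is.null(dt)) abort("visits must come from segment_visits()")
  one <- function(d) {
    n_trans <- d$n_transitions[1]
    qual <- d$qualifies[1]
    dur <- (max(d$end_frame) - min(d$start_frame) + 1L) * dt
    syn <- d[d$state == "S", ]
    if (!include_censored && nrow(d) > 1) {
      censored <- c(min(d$start_frame), max(d$start_frame))
      syn <- syn[!syn$start_frame %in% censored, ]
    }
    tibble::tibble(
      n_transitions = n_trans, duration_s = dur,
      residence_s = if (qual && nrow(syn) > 0) mean(syn$duration_s) else NA_real_,
      exchange_hz = if (qual) n_trans / dur else NA_real_,
      qualifies = qual
    )
  }
  dplyr::ungroup(
    dplyr::group_modify(dplyr::group_by(visits, .data$track_id), ~ one(.x)))
}

#' Synaptic residence time of qualifying trajectories
#'
#' @param visits Output of [segment_visits()].
#' @param include_censored See [kinetics_summary()].
#' @return Named numeric vector of residence times (s), one per qualifying
#'   trajectory.
#' @export
residence_time <- function(visits, include_censored = FALSE) {
  s <- kinetics_summary(visits, include_censored = include_censored)
  s <- s[s$qualifies & !is.na(s$residence_s), ]
  setNames(s$residence_s, s$track_id)
}

#' Synaptic-extrasynaptic exchange rate of qualifying trajectories
#'
#' Transitions divided by the observed trajectory duration.
#'
#' @param visits Output of [segment_visits()].
#' @return Named numeric vector of exchange rates (Hz), one per qualifying
#'   trajectory.
#' @export
exchange_rate <- function(visits) {
  s <- kinetics_summary(visits)
  s <- s[s$qualifies, ]
  setNames(s$exchange_hz, s$track_id)
}

#' Log-scale summary of a skewed positive variable
#'
#' Residence times and exchange rates are right-skewed; summaries are
#' computed on the natural-log scale (stabilizing the variance) and reported
#' back-transformed. Non-positive values are rejected.
#'
#' @param values Strictly positive numeric vector.
#' @param conf_level Confidence level for the mean (default 0.95).
#' @return Tibble: n, mean_log, sd_log, geo_mean, ci_lo, ci_hi, median.
#' @export
log_summary <- function(values, conf_level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("no values to summarise")
  if (any(values <= 0)) {
    abort("log_summary() requires strictly positive values")
  }
  lv <- log(values)
  n <- length(lv)
  se <- if (n > 1) sd(lv) / sqrt(n) else NA_real_
  tq <- if (n > 1) qt(1 - (1 - conf_level) / 2, n - 1) else NA_real_
  tibble::tibble(
    n = n, mean_log = mean(lv), sd_log = if (n > 1) sd(lv) else 0,
    geo_mean = exp(mean(lv)),
    ci_lo = exp(mean(lv) - tq * se), ci_hi = exp(mean(lv) + tq * se),
    median = median(values)
  )
}
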