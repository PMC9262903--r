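# Boundary tolerance for the inclusive AOI test: entry samples can lie
# exactly on the circle in exact arithmetic, so a bare `<=` would be at the
# mercy of floating-point rounding.
AOI_EPS <- 1e-9

#' Construct a gaze stream
#'
#' One trial's eye-tracker samples: nominally 60 Hz over a 10 s movie.
#' Coordinates are degrees of visual angle relative to screen center (see
#' [px_to_deg()] for the pixel dialect). Invalid samples (tracker dropouts)
#' carry undefined coordinates and never count as inside any AOI.
#'
#' @param t_s sample timestamps in seconds from stimulus onset; strictly
#'   increasing, within `[0, 10]`.
#' @param x_deg,y_deg gaze position in degrees (NA allowed where invalid).
#' @param valid logical vector; `FALSE` marks dropout samples.
#' @param trial_id,participant_id,age_group identifiers.
#' @param direction,speed,path condition labels (`"benchmark"` direction for
#'   benchmark trials).
#' @param nominal_rate_hz nominal sampling rate, 60 by default.
#' @return Object of class `gaze_stream`.
#' @export
gaze_stream <- function(t_s, x_deg, y_deg, valid = rep(TRUE, length(t_s)),
                        trial_id = NA_character_,
                        participant_id = NA_character_,
                        age_group = NA_character_,
                        direction = NA_character_, speed = NA_character_,
                        path = NA_character_, nominal_rate_hz = 60) {
  n <- length(t_s)
  stopifnot(length(x_deg) == n, length(y_deg) == n, length(valid) == n)
  if (n > 1 && any(diff(t_s) <= 0)) stop("timestamps must be strictly increasing")
  if (n > 0 && (min(t_s) < 0 || max(t_s) > 10 + 1e-9))
    stop("timestamps must lie in [0, 10] s")
  structure(list(t_s = as.numeric(t_s), x_deg = as.numeric(x_deg),
                 y_deg = as.numeric(y_deg), valid = as.logical(valid),
                 trial_id = trial_id, participant_id = participant_id,
                 age_group = age_group, direction = direction, speed = speed,
                 path = path, nominal_rate_hz = nominal_rate_hz),
            class = "gaze_stream")
}

#' Moving circular area of interest
#'
#' A circle of fixed diameter (9.2 deg in the study) locked to the focus of
#' the radial flow pattern (or the benchmark square), i.e. centered on
#' [focus_position()] of the given trajectory at every moment.
#'
#' @param trajectory a [focus_trajectory()].
#' @param diameter_deg AOI diameter in degrees.
#' @return Object of class `aoi_spec`.
#' @export
aoi_spec <- function(trajectory, diameter_deg = 9.2) {
  stopifnot(inherits(trajectory, "focus_trajectory"), diameter_deg > 0)
  structure(list(trajectory = trajectory, diameter_deg = diameter_deg,
                 radius_deg = diameter_deg / 2), class = "aoi_spec")
}

#' Test gaze samples against the moving AOI
#'
#' A sample is inside the AOI iff its Euclidean distance to the instantaneous
#' AOI center is at most the radius (boundary inclusive). Invalid samples are
#' never inside.
#'
#' @param x_deg,y_deg,t_s sample position and time (vectorized).
#' @param aoi an [aoi_spec()].
#' @param valid logical validity flags.
#' @return Logical vector.
#' @export
in_aoi <- function(x_deg, y_deg, t_s, aoi, valid = rep(TRUE, length(t_s))) {
  ctr <- focus_position(aoi$trajectory, t_s)
  d2 <- (x_deg - ctr[, 1])^2 + (y_deg - ctr[, 2])^2
  res <- d2 <= (aoi$radius_deg + AOI_EPS)^2
  res[!valid | is.na(res)] <- FALSE
  res
}

#' Total looking time at the moving AOI
#'
#' Sum of per-sample durations (1 / nominal rate, 1/60 s) over valid samples
#' inside the AOI; clamped to the trial duration. Dropout samples shorten the
#' total rather than being interpolated.
#'
#' @param stream a [gaze_stream()].
#' @param aoi an [aoi_spec()].
#' @return Looking time in seconds, in `[0, 10]`.
#' @export
looking_time <- function(stream, aoi) {
  if (length(stream$t_s) == 0L) return(0)
  hit <- in_aoi(stream$x_deg, stream$y_deg, stream$t_s, aoi, stream$valid)
  min(sum(hit) / stream$nominal_rate_hz, 10)
}

#' Latency of the first gaze into the AOI
#'
#' Timestamp (from stimulus onset) of the first valid sample inside the AOI;
#' censored at the 10 s trial duration if the AOI is never entered.
#'
#' @inheritParams looking_time
#' @return Latency in seconds, in `(0, 10]`.
#' @export
latency <- function(stream, aoi) {
  if (length(stream$t_s) == 0L) return(10)
  hit <- in_aoi(stream$x_deg, stream$y_deg, stream$t_s, aoi, stream$valid)
  i <- which(hit)[1]
  if (is.na(i)) 10 else stream$t_s[i]
}

#' Whole-screen looking time (AOIW)
#'
#' Total valid-sample time with gaze inside the stimulus background rectangle
#' (35.3 x 26.4 deg by default), the whole-screen AOI used to check that
#' focus-locked effects are not driven by overall screen attention.
#'
#' @inheritParams looking_time
#' @param field_deg background size `c(width, height)` in degrees.
#' @return Looking time in seconds.
#' @export
looking_time_whole <- function(stream, field_deg = c(35.3, 26.4)) {
  if (length(stream$t_s) == 0L) return(0)
  ok <- stream$valid &
    !is.na(stream$x_deg) & !is.na(stream$y_deg) &
    abs(stream$x_deg) <= field_deg[1] / 2 + AOI_EPS &
    abs(stream$y_deg) <= field_deg[2] / 2 + AOI_EPS
  min(sum(ok, na.rm = TRUE) / stream$nominal_rate_hz, 10)
}

#' Expansion/contraction asymmetry index
#'
#' Total looking time for expansion flow divided by the total for expansion
#' and contraction together. 0.5 indicates no bias; values above 0.5 an
#' expansion bias, below 0.5 a contraction bias. Undefined (NA) when both
#' totals are zero — such participants are excluded from index tests rather
#' than scored 0 or 0.5.
#'
#' @param total_exp_s,total_con_s total looking times (seconds), >= 0.
#' @return The index in `[0, 1]`, or `NA_real_` if both totals are zero.
#' @export
asymmetry_index <- function(total_exp_s, total_con_s) {
  stopifnot(all(total_exp_s >= 0, na.rm = TRUE),
            all(total_con_s >= 0, na.rm = TRUE))
  tot <- total_exp_s + total_con_s
  ifelse(tot > 0, total_exp_s / tot, NA_real_)
}

#' Analytic chance levels of the moving-AOI design
#'
#' For gaze fixed exactly at screen center: the nearest AOI edge starts
#' `|s| - r` deg away (134 px) and approaches at the sweep speed (107.2 px/s),
#' giving the chance latency; the full AOI diameter (268 px) then needs
#' `diameter / speed` s (2.5 s) to pass over the center, once outbound and
#' once on the return leg, giving a chance looking time of twice the crossing
#' time (5 s). All three are computed from the geometry, in pixels via the
#' single px/deg constant.
#'
#' @param aoi an [aoi_spec()].
#' @param px_per_deg pixels per degree.
#' @return A list with `chance_latency_s`, `aoi_crossing_time_s`,
#'   `chance_looking_time_s`, and the pixel geometry used.
#' @export
chance_levels <- function(aoi, px_per_deg = PX_PER_DEG) {
  v <- aoi$trajectory$sweep_speed_deg_s
  if (v <= 0) stop("trajectory speed must be positive")
  edge_px <- (abs(aoi$trajectory$start_offset_deg) - aoi$radius_deg) * px_per_deg
  speed_px_s <- v * px_per_deg
  diam_px <- aoi$diameter_deg * px_per_deg
  crossing <- diam_px / speed_px_s
  list(chance_latency_s = edge_px / speed_px_s,
       aoi_crossing_time_s = crossing,
       chance_looking_time_s = 2 * crossing,
       edge_distance_px = edge_px, aoi_speed_px_s = speed_px_s,
       aoi_diameter_px = diam_px)
}

#' Score a single trial
#'
#' Computes the per-trial dependent measures — AOI looking time, first-entry
#' latency, and whole-screen (AOIW) looking time — for one gaze stream
#' against the AOI implied by its condition labels.
#'
#' @param stream a [gaze_stream()] with condition labels set.
#' @param aoi an [aoi_spec()]; defaults to the 9.2-deg AOI on the stream's
#'   path.
#' @param field_deg background size for the AOIW measure.
#' @return One-row data.frame: participant_id, age_group, trial_id,
#'   direction, speed, path, looking_time_aoi_s, latency_aoi_s,
#'   looking_time_aoiw_s.
#' @export
score_trial <- function(stream, aoi = NULL, field_deg = c(35.3, 26.4)) {
  stopifnot(inherits(stream, "gaze_stream"))
  if (is.null(aoi)) {
    if (is.na(stream$path)) stop("stream has no path label and no AOI given")
    aoi <- aoi_spec(focus_trajectory(stream$path))
  }
  data.frame(participant_id = stream$participant_id,
             age_group = stream$age_group,
             trial_id = stream$trial_id,
             direction = stream$direction,
             speed = stream$speed,
             path = stream$path,
             looking_time_aoi_s = looking_time(stream, aoi),
             latency_aoi_s = latency(stream, aoi),
             looking_time_aoiw_s = looking_time_whole(stream, field_deg),
             stringsAsFactors = FALSE)
}

#' Score a set of trials
#'
#' Applies [score_trial()] to each stream and checks the design: a duplicate
#' (participant, direction, speed, path) experimental trial is an error.
#'
#' @param streams list of [gaze_stream()] objects.
#' @param field_deg background size for the AOIW measure.
#' @return data.frame of trial scores, one row per stream.
#' @export
score_dataset <- function(streams, field_deg = c(35.3, 26.4)) {
  scores <- do.call(rbind, lapply(streams, score_trial, field_deg = field_deg))
  expi <- scores$direction %in% c("expansion", "contraction")
  key <- with(scores[expi, ], paste(participant_id, direction, speed, path))
  if (anyDuplicated(key))
    stop("duplicate (participant, condition, repetition) trials: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  scores
}

#' Condition means per participant
#'
#' Averages the two repetitions (motion paths) of each experimental
#' condition, yielding four condition means per participant and measure — the
#' dependent-variable table for the group-level models. Benchmark trials are
#' excluded. Missing trials propagate as absent rows.
#'
#' @param scores data.frame from [score_dataset()].
#' @return Long data.frame: participant_id, age_group, direction, speed,
#'   looking_time_aoi_s, latency_aoi_s, looking_time_aoiw_s (repetition
#'   means).
#' @export
aggregate_scores <- function(scores) {
  ex <- scores[scores$direction %in% c("expansion", "contraction"), ]
  agg <- stats::aggregate(
    ex[, c("looking_time_aoi_s", "latency_aoi_s", "looking_time_aoiw_s")],
    by = list(participant_id = ex$participant_id, age_group = ex$age_group,
              direction = ex$direction, speed = ex$speed),
    FUN = mean)
  agg[order(agg$participant_id, agg$direction, agg$speed), ]
}

#' Per-participant asymmetry indices
#'
#' Computes the AOIW asymmetry index per participant and speed condition:
#' total expansion looking time over total looking time for both directions,
#' from the trial scores (totals over the two repetitions).
#'
#' @param scores data.frame from [score_dataset()].
#' @param measure which looking-time column to use (AOIW by default, as in
#'   the whole-screen analysis).
#' @return data.frame: participant_id, age_group, speed, index.
#' @export
asymmetry_table <- function(scores, measure = "looking_time_aoiw_s") {
  ex <- scores[scores$direction %in% c("expansion", "contraction"), ]
  tot <- stats::aggregate(ex[[measure]],
    by = list(participant_id = ex$participant_id, age_group = ex$age_group,
              speed = ex$speed, direction = ex$direction), FUN = sum)
  wide <- stats::reshape(tot, idvar = c("participant_id", "age_group", "speed"),
                         timevar = "direction", direction = "wide")
  data.frame(participant_id = wide$participant_id,
             age_group = wide$age_group, speed = wide$speed,
             index = asymmetry_index(wide$x.expansion, wide$x.contraction),
             stringsAsFactors = FALSE)
}
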