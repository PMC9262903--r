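#' Age-group labels of the study design
#'
#' Thirteen groups: 1- to 12-year-olds plus adults.
#' @export
AGE_GROUPS <- c(paste0(1:12, "y"), "adult")

#' Behavioral presets for the synthetic cohort
#'
#' Target gaze behavior per (age group, flow direction): the mean and
#' between-participant SD of AOI looking time, the lognormal orienting
#' latency (median and log-scale sigma), the per-sample probability of
#' leaving the AOI once engaged, fixation jitter, and tracker dropout rate.
#'
#' The shipped values encode the developmental pattern the pipeline is meant
#' to resolve: 1-year-olds look longer at the contraction focus than the
#' expansion focus, the bias reverses by age 5, and looking time for both
#' directions grows through early childhood before plateauing; latency
#' shortens and data quality improves with age. The numeric values themselves
#' are the generator's own calibration targets (no human dataset is bundled),
#' with every group given a bias of at least 1 s so that generating-truth
#' signs are recoverable at the design's sample size.
#'
#' @return data.frame with one row per age group x direction.
#' @export
behavior_presets <- function() {
  exp_mean <- c(2.4, 2.8, 3.2, 3.6, 5.6, 6.0, 6.2, 6.2, 6.4, 6.4, 6.5, 6.5, 6.6)
  con_mean <- c(3.9, 4.0, 4.2, 4.6, 4.6, 4.7, 4.8, 5.2, 4.9, 4.9, 5.0, 5.0, 5.0)
  lat_base <- c(2.0, 1.9, 1.8, 1.7, 1.5, 1.4, 1.35, 1.3, 1.25, 1.2, 1.15, 1.1, 1.0)
  p_inv <- c(0.12, 0.11, 0.10, 0.09, 0.08, 0.07, 0.07, 0.06, 0.06, 0.05, 0.05,
             0.05, 0.04)
  # the favored direction also gets the slightly faster first orienting saccade
  favored_exp <- exp_mean > con_mean
  d <- rbind(
    data.frame(age_group = AGE_GROUPS, direction = "expansion",
               mean_looking_s = exp_mean,
               latency_median_s = lat_base + ifelse(favored_exp, -0.1, 0.1)),
    data.frame(age_group = AGE_GROUPS, direction = "contraction",
               mean_looking_s = con_mean,
               latency_median_s = lat_base + ifelse(favored_exp, 0.1, -0.1)))
  d$sd_looking_s <- 0.8
  d$latency_sigma <- 0.5
  d$p_leave <- 0.01
  d$jitter_sd_deg <- 1.0
  d$p_invalid <- rep(p_inv, 2)
  rownames(d) <- NULL
  d
}

#' Cohort design
#'
#' The study design: 13 age groups x `n_per_group` participants; per
#' participant 8 experimental trials (expansion/contraction x low/high speed,
#' with the two repetitions of each condition running the two focus motion
#' paths RLR and LRL) in randomized order, followed by 2 benchmark trials
#' whose order is counterbalanced across participants.
#'
#' @param age_groups ordered age-group labels.
#' @param n_per_group participants per group.
#' @param include_benchmark generate the two benchmark trials as well.
#' @param trial_duration_s trial length in seconds.
#' @param sample_rate_hz gaze sampling rate.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(age_groups = AGE_GROUPS, n_per_group = 20L,
                          include_benchmark = TRUE, trial_duration_s = 10,
                          sample_rate_hz = 60) {
  stopifnot(n_per_group >= 1)
  structure(list(age_groups = age_groups,
                 n_per_group = as.integer(n_per_group),
                 include_benchmark = include_benchmark,
                 trial_duration_s = trial_duration_s,
                 sample_rate_hz = sample_rate_hz),
            class = "cohort_design")
}

# Expected number of in-AOI samples for a chain started in the engaged state
# and run for H samples: occupancy pi = pr/(pl+pr), relaxation rate
# lambda = pl+pr; sum_{k<H} [pi + (1-pi)(1-lambda)^k].
.chain_expected_in <- function(H, p_leave, p_return) {
  lam <- p_leave + p_return
  pi <- p_return / lam
  ifelse(H <= 0, 0, H * pi + (1 - pi) * (1 - (1 - lam)^pmax(H, 0)) / lam)
}

# Expected looking time (s) given dwell parameters, marginalized over the
# lognormal entry latency by midpoint-quantile quadrature; entries after the
# trial end contribute nothing (pre-entry gaze is never in the AOI).
.expected_looking <- function(p_return, p_leave, lat_median, lat_sigma,
                              p_invalid, n_samples = 600, rate = 60) {
  q <- (seq_len(64) - 0.5) / 64
  L <- stats::qlnorm(q, meanlog = log(lat_median), sdlog = lat_sigma)
  entry <- ceiling(L * rate)
  entry[entry < 1] <- 1
  H <- pmax(n_samples - entry + 1, 0)
  H[L > n_samples / rate] <- 0
  mean(.chain_expected_in(H, p_leave, p_return)) * (1 - p_invalid) / rate
}

# Solve the AOI-return probability that hits a target mean looking time;
# saturates at the bracket ends when the target is unreachable.
.calibrate_return_prob <- function(target_s, p_leave, lat_median, lat_sigma,
                                   p_invalid, n_samples = 600, rate = 60) {
  f <- function(pr) .expected_looking(pr, p_leave, lat_median, lat_sigma,
                                      p_invalid, n_samples, rate) - target_s
  lo <- 1e-5; hi <- 0.9
  if (f(hi) <= 0) return(hi)
  if (f(lo) >= 0) return(lo)
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Draw participant-level behavior parameters
#'
#' Individual parameters are drawn around the group presets as a single
#' participant-level deviation shared across the two flow directions: one
#' normal deviate shifts both looking-time targets (truncated to
#' (0.2, 9.5) s) and one lognormal deviate scales both latency medians. The
#' shared draw makes the participant effect a common intercept, matching the
#' random-intercept structure of the downstream mixed model (a
#' direction-specific participant draw would silently inflate the
#' age-by-direction interaction test). The AOI-return probability is then
#' calibrated by inverting the closed-form expected looking time of the
#' two-state dwell chain (marginalized over the latency distribution), so
#' each participant's generative process has the drawn target as its
#' analytic mean.
#'
#' @param group_presets rows of [behavior_presets()] for one age group (both
#'   directions).
#' @param participant_sd SD of the participant-level looking-time deviation;
#'   0 reproduces the group means exactly.
#' @param latency_jitter_sdlog log-scale SD of the participant latency
#'   deviation.
#' @return data.frame, one row per direction, with the drawn targets and the
#'   calibrated chain parameters. Uses the current RNG state.
#' @export
sample_participant <- function(group_presets, participant_sd = NULL,
                               latency_jitter_sdlog = 0.2) {
  stopifnot(nrow(group_presets) == 2)
  out <- group_presets
  if (is.null(participant_sd)) participant_sd <- group_presets$sd_looking_s[1]
  u_look <- stats::rnorm(1, 0, participant_sd)
  u_lat <- exp(stats::rnorm(1, 0, latency_jitter_sdlog))
  out$target_looking_s <- pmin(pmax(
    group_presets$mean_looking_s + u_look, 0.2), 9.5)
  out$latency_median_s <- group_presets$latency_median_s * u_lat
  out$p_return <- vapply(1:2, function(i)
    .calibrate_return_prob(out$target_looking_s[i], out$p_leave[i],
                           out$latency_median_s[i], out$latency_sigma[i],
                           out$p_invalid[i]), numeric(1))
  out
}

# Uniform field point guaranteed outside the AOI at sample times `idx`;
# used for excursion fixations (and resampled pointwise should the moving
# AOI overtake one).
.sample_off_aoi <- function(n, fx, radius, field_deg) {
  hw <- field_deg[1] / 2; hh <- field_deg[2] / 2
  x <- stats::runif(n, -hw, hw); y <- stats::runif(n, -hh, hh)
  bad <- (x - fx)^2 + y^2 <= radius^2
  guard <- 0L
  while (any(bad) && guard < 100L) {
    x[bad] <- stats::runif(sum(bad), -hw, hw)
    y[bad] <- stats::runif(sum(bad), -hh, hh)
    bad <- (x - fx)^2 + y^2 <= radius^2
    guard <- guard + 1L
  }
  cbind(x, y)
}

#' Simulate one trial's gaze stream
#'
#' Generative stand-in for human gaze on one 10 s trial: the gaze wanders
#' off-AOI until a first orienting saccade lands at the (moving) AOI center
#' at a latency drawn from the participant's lognormal; thereafter a
#' two-state Markov chain governs, per 60 Hz sample, whether gaze dwells in
#' the AOI (Gaussian jitter around the AOI center) or excurses to a uniform
#' off-AOI fixation point, held until the chain returns (or the moving AOI
#' overtakes it, in which case it is resampled). Samples are independently
#' flagged invalid with the participant's dropout probability.
#'
#' @param pp one row of [sample_participant()] output (one direction).
#' @param path focus motion path, `"RLR"` or `"LRL"`.
#' @param speed speed-condition label carried into the stream.
#' @param trial_id trial identifier.
#' @param participant_id,age_group identifiers carried into the stream.
#' @param n_samples samples per trial (600 = 10 s at 60 Hz).
#' @param rate_hz sampling rate.
#' @param aoi_diameter_deg AOI diameter.
#' @param field_deg background size.
#' @return A [gaze_stream()]. Uses the current RNG state.
#' @export
simulate_trial <- function(pp, path, speed = NA_character_,
                           trial_id = NA_character_,
                           participant_id = NA_character_,
                           age_group = NA_character_,
                           n_samples = 600L, rate_hz = 60,
                           aoi_diameter_deg = 9.2,
                           field_deg = c(35.3, 26.4)) {
  t <- seq_len(n_samples) / rate_hz
  traj <- focus_trajectory(path, duration_s = n_samples / rate_hz)
  fx <- focus_position(traj, t)[, 1]
  r <- aoi_diameter_deg / 2

  L <- stats::rlnorm(1, log(pp$latency_median_s), pp$latency_sigma)
  entry <- if (L > t[n_samples]) NA_integer_ else which(t >= L)[1]

  engaged <- rep(FALSE, n_samples)
  if (!is.na(entry)) {
    i <- entry; cur <- TRUE
    while (i <= n_samples) {
      p_switch <- if (cur) pp$p_leave else pp$p_return
      # a zero switching probability is an absorbing state
      dwell <- if (p_switch <= 0) n_samples else 1L + stats::rgeom(1L, p_switch)
      j <- min(i + dwell - 1L, n_samples)
      engaged[i:j] <- cur
      i <- j + 1L
      cur <- !cur
    }
  }

  x <- numeric(n_samples); y <- numeric(n_samples)
  n_in <- sum(engaged)
  if (n_in > 0) {
    x[engaged] <- fx[engaged] + stats::rnorm(n_in, 0, pp$jitter_sd_deg)
    y[engaged] <- stats::rnorm(n_in, 0, pp$jitter_sd_deg)
  }
  out_runs <- rle(!engaged)
  pos <- 1L
  for (k in seq_along(out_runs$lengths)) {
    len <- out_runs$lengths[k]
    idx <- pos:(pos + len - 1L)
    if (out_runs$values[k]) {
      pt <- .sample_off_aoi(1L, fx[idx[1]], r, field_deg)
      x[idx] <- pt[1]; y[idx] <- pt[2]
      overtaken <- (x[idx] - fx[idx])^2 + y[idx]^2 <= r^2
      if (any(overtaken)) {
        repl <- .sample_off_aoi(sum(overtaken), fx[idx][overtaken][1], r,
                                field_deg)
        # pointwise fix; re-check each replacement against its own AOI position
        xi <- idx[overtaken]
        x[xi] <- repl[, 1]; y[xi] <- repl[, 2]
        still <- (x[xi] - fx[xi])^2 + y[xi]^2 <= r^2
        guard <- 0L
        while (any(still) && guard < 100L) {
          sub <- xi[still]
          x[sub] <- stats::runif(length(sub), -field_deg[1] / 2, field_deg[1] / 2)
          y[sub] <- stats::runif(length(sub), -field_deg[2] / 2, field_deg[2] / 2)
          still <- (x[xi] - fx[xi])^2 + y[xi]^2 <= r^2
          guard <- guard + 1L
        }
      }
    }
    pos <- pos + len
  }

  valid <- stats::runif(n_samples) >= pp$p_invalid
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  gaze_stream(t, x, y, valid,
              trial_id = trial_id, participant_id = participant_id,
              age_group = age_group, direction = pp$direction,
              speed = speed, path = path, nominal_rate_hz = rate_hz)
}

#' Generate a full synthetic cohort
#'
#' Simulates gaze streams for every participant of the design: the 8
#' experimental trials (condition x path, randomized order) and, if enabled,
#' 2 benchmark trials with short, age-independent latency (order
#' counterbalanced across participants). Returns the streams together with a
#' truth table of each participant's generating parameters for recovery
#' tests.
#'
#' @param design a [cohort_design()].
#' @param presets a [behavior_presets()]-shaped data.frame.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param participant_sd between-participant SD passed to
#'   [sample_participant()] (`NULL` = preset column).
#' @return List with `streams` (list of [gaze_stream()]), `truth`
#'   (data.frame of generating parameters, one row per participant) and
#'   `design`.
#' @export
generate_cohort <- function(design = cohort_design(),
                            presets = behavior_presets(), seed = NULL,
                            participant_sd = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (!is.null(seed)) set.seed(seed)
  n_samples <- as.integer(round(design$trial_duration_s * design$sample_rate_hz))
  conds <- expand.grid(direction = c("expansion", "contraction"),
                       speed = c("low", "high"), path = c("RLR", "LRL"),
                       stringsAsFactors = FALSE)
  streams <- list(); truth <- list()
  bench <- data.frame(direction = "benchmark", latency_median_s = 0.9,
                      latency_sigma = 0.4, p_leave = 0.005, p_return = 0.2,
                      jitter_sd_deg = 0.8, p_invalid = 0.05)
  pidx <- 0L
  for (g in design$age_groups) {
    gp <- presets[presets$age_group == g, ]
    if (nrow(gp) != 2) stop("presets must have 2 rows (directions) for group ", g)
    for (j in seq_len(design$n_per_group)) {
      pidx <- pidx + 1L
      pid <- sprintf("%s_p%02d", g, j)
      pp <- sample_participant(gp, participant_sd = participant_sd)
      ie <- which(pp$direction == "expansion")
      ic <- which(pp$direction == "contraction")
      truth[[pid]] <- data.frame(
        participant_id = pid, age_group = g,
        target_looking_exp_s = pp$target_looking_s[ie],
        target_looking_con_s = pp$target_looking_s[ic],
        latency_median_exp_s = pp$latency_median_s[ie],
        latency_median_con_s = pp$latency_median_s[ic],
        p_return_exp = pp$p_return[ie], p_return_con = pp$p_return[ic],
        p_leave = pp$p_leave[1], p_invalid = pp$p_invalid[1])
      ord <- sample.int(nrow(conds))
      for (k in seq_along(ord)) {
        cc <- conds[ord[k], ]
        row <- pp[pp$direction == cc$direction, ]
        tid <- sprintf("%s_t%d", pid, k)
        streams[[tid]] <- simulate_trial(row, cc$path, speed = cc$speed,
                                         trial_id = tid, participant_id = pid,
                                         age_group = g,
                                         n_samples = n_samples,
                                         rate_hz = design$sample_rate_hz)
      }
      if (design$include_benchmark) {
        paths <- if (pidx %% 2L == 1L) c("RLR", "LRL") else c("LRL", "RLR")
        bp <- bench
        bp$p_invalid <- pp$p_invalid[1]
        for (b in 1:2) {
          tid <- sprintf("%s_b%d", pid, b)
          streams[[tid]] <- simulate_trial(bp, paths[b], speed = "none",
                                           trial_id = tid, participant_id = pid,
                                           age_group = g,
                                           n_samples = n_samples,
                                           rate_hz = design$sample_rate_hz)
        }
      }
    }
  }
  list(streams = streams, truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       design = design)
}
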