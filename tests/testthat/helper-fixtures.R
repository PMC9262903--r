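# Shared fixtures, all built in code.

# A 10 s, 60 Hz gaze stream nailed to the screen center.
center_stream <- function(n = 600, rate = 60) {
  gaze_stream((1:n) / rate, rep(0, n), rep(0, n),
              trial_id = "center", participant_id = "p0", age_group = "adult",
              direction = "expansion", speed = "low", path = "RLR")
}

# Random gaze stream over (and slightly beyond) the field, with dropouts.
random_stream <- function(n = 600, rate = 60, p_invalid = 0.1) {
  v <- runif(n) >= p_invalid
  x <- runif(n, -20, 20); y <- runif(n, -15, 15)
  x[!v] <- NA; y[!v] <- NA
  gaze_stream((1:n) / rate, x, y, valid = v, path = sample(c("RLR", "LRL"), 1))
}

# Per-sample loop oracle for looking time and latency, independent of the
# vectorized scoring path.
oracle_score <- function(stream, aoi) {
  lt <- 0; lat <- NA
  for (i in seq_along(stream$t_s)) {
    if (!stream$valid[i]) next
    ctr <- focus_position(aoi$trajectory, stream$t_s[i])
    d <- sqrt((stream$x_deg[i] - ctr[1])^2 + (stream$y_deg[i] - ctr[2])^2)
    if (d <= aoi$radius_deg + 1e-9) {
      lt <- lt + 1 / stream$nominal_rate_hz
      if (is.na(lat)) lat <- stream$t_s[i]
    }
  }
  list(looking = min(lt, 10), latency = if (is.na(lat)) 10 else lat)
}

# Small cohort for pipeline-level tests: fewer groups/participants, full
# trial structure.
small_design <- function(groups = c("1y", "5y", "adult"), n = 4,
                         benchmark = TRUE)
  cohort_design(age_groups = groups, n_per_group = n,
                include_benchmark = benchmark)
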