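# Single deg<->px conversion constant: the 9.2-deg AOI diameter corresponds to
# 268 px on the study monitor, so 268/9.2 px per degree everywhere.
PX_PER_DEG <- 268 / 9.2

#' Degree/pixel coordinate conversion
#'
#' Internal coordinates are degrees of visual angle with the origin at the
#' screen center, x rightward and y upward. Pixel coordinates follow raster
#' convention: origin at the top-left corner, y downward. A single conversion
#' constant (268 px / 9.2 deg) is used throughout.
#'
#' @param x,y coordinates (degrees for `deg_to_px`, pixels for `px_to_deg`).
#' @param screen_px integer vector `c(width, height)` of the display in pixels.
#' @param px_per_deg pixels per degree of visual angle.
#' @return A list with components `x` and `y` in the target system.
#' @export
deg_to_px <- function(x, y, screen_px = c(1024, 768), px_per_deg = PX_PER_DEG) {
  list(x = screen_px[1] / 2 + x * px_per_deg,
       y = screen_px[2] / 2 - y * px_per_deg)
}

#' @rdname deg_to_px
#' @export
px_to_deg <- function(x, y, screen_px = c(1024, 768), px_per_deg = PX_PER_DEG) {
  list(x = (x - screen_px[1] / 2) / px_per_deg,
       y = (screen_px[2] / 2 - y) / px_per_deg)
}

#' Stimulus parameters for one radial-flow movie
#'
#' Full parameterization of a single flow movie: a field of short-lifetime
#' dots moving radially away from (expansion) or toward (contraction) a focus
#' that translates horizontally across the screen. Dot speed is zero at the
#' focus and grows linearly with eccentricity, `speed = k * ecc`, with
#' k = 0.33 deg/s per deg (low speed) or 0.66 (high speed). The contraction
#' movie is produced by reverse play of an expansion frame set, never by
#' integrating inward motion.
#'
#' @param direction `"expansion"` or `"contraction"`.
#' @param speed `"low"` (k = 0.33) or `"high"` (k = 0.66).
#' @param path focus motion path: `"RLR"` starts 9.2 deg right of center,
#'   sweeps left and returns; `"LRL"` is the mirror image.
#' @param n_dots number of dots in the field.
#' @param speed_constant override for k (deg/s of dot speed per deg of
#'   eccentricity); defaults to the value implied by `speed`.
#' @param dot_lifetime_frames frames a dot lives before respawning.
#' @param movie_fps animation frame rate (frames per second).
#' @param movie_duration_s movie duration in seconds.
#' @param field_deg background size `c(width, height)` in degrees.
#' @param screen_px display resolution `c(width, height)` in pixels.
#' @param focus_offset_deg magnitude of the focus start offset from center.
#' @param aoi_diameter_deg diameter of the circular analysis AOI.
#' @param rng_seed integer seed used by [generate_expansion_frames()]; `NULL`
#'   leaves the RNG state alone.
#' @return An object of class `stimulus_params`.
#' @export
stimulus_params <- function(direction = c("expansion", "contraction"),
                            speed = c("low", "high"),
                            path = c("RLR", "LRL"),
                            n_dots = 500L,
                            speed_constant = NULL,
                            dot_lifetime_frames = 10L,
                            movie_fps = 30L,
                            movie_duration_s = 10,
                            field_deg = c(35.3, 26.4),
                            screen_px = c(1024L, 768L),
                            focus_offset_deg = 9.2,
                            aoi_diameter_deg = 9.2,
                            rng_seed = NULL) {
  direction <- match.arg(direction)
  speed <- match.arg(speed)
  path <- match.arg(path)
  if (is.null(speed_constant))
    speed_constant <- if (speed == "low") 0.33 else 0.66
  stopifnot(n_dots >= 0, speed_constant > 0, dot_lifetime_frames >= 1,
            movie_fps > 0, movie_duration_s > 0, all(field_deg > 0))
  structure(list(
    direction = direction, speed = speed, path = path,
    n_dots = as.integer(n_dots),
    speed_constant = speed_constant,
    dot_lifetime_frames = as.integer(dot_lifetime_frames),
    movie_fps = movie_fps, movie_duration_s = movie_duration_s,
    field_deg = field_deg, screen_px = screen_px,
    px_per_deg = PX_PER_DEG,
    focus_offset_deg = focus_offset_deg,
    aoi_diameter_deg = aoi_diameter_deg,
    rng_seed = rng_seed), class = "stimulus_params")
}

#' Focus trajectory of a radial-flow movie
#'
#' The focus starts `offset_deg` to the left or right of screen center, sweeps
#' at constant speed to the mirror position on the opposite side, and returns
#' to its start over the movie duration; the vertical offset is always zero.
#' The sweep speed is fixed at `v = 2 * offset / (T/2)` (3.68 deg/s for the
#' default 9.2 deg offset and 10 s duration) so the triangle wave closes
#' exactly.
#'
#' @param path `"RLR"` (start right) or `"LRL"` (start left).
#' @param offset_deg magnitude of the start offset (degrees).
#' @param duration_s trajectory period (seconds).
#' @return Object of class `focus_trajectory` with fields `start_offset_deg`
#'   (signed), `sweep_speed_deg_s` and `duration_s`.
#' @export
focus_trajectory <- function(path = c("RLR", "LRL"), offset_deg = 9.2,
                             duration_s = 10) {
  path <- match.arg(path)
  s <- if (path == "RLR") offset_deg else -offset_deg
  structure(list(start_offset_deg = s,
                 sweep_speed_deg_s = 2 * abs(s) / (duration_s / 2),
                 duration_s = duration_s),
            class = "focus_trajectory")
}

#' Focus position at time t
#'
#' Piecewise-linear triangle trajectory: outbound to the mirrored offset over
#' the first half of the movie, back to the start over the second half.
#'
#' @param traj a [focus_trajectory()].
#' @param t time in seconds (vectorized); must lie in `[0, duration_s]`.
#' @return A matrix with columns `x_deg`, `y_deg`, one row per time point.
#' @export
focus_position <- function(traj, t) {
  stopifnot(inherits(traj, "focus_trajectory"))
  if (any(t < 0 | t > traj$duration_s))
    stop("t outside [0, ", traj$duration_s, "]")
  s <- traj$start_offset_deg
  v <- traj$sweep_speed_deg_s
  half <- traj$duration_s / 2
  x <- ifelse(t <= half, s - sign(s) * v * t,
              -s + sign(s) * v * (t - half))
  cbind(x_deg = x, y_deg = rep(0, length(t)))
}

#' Initialize the dot field
#'
#' Dots are placed uniformly over the background field; ages are drawn
#' uniformly over `[0, lifetime)` so that respawns are desynchronized from the
#' first frame on.
#'
#' @param params a [stimulus_params()] object.
#' @return A matrix with columns `x_deg`, `y_deg`, `age` and
#'   `params$n_dots` rows. Uses the current RNG state.
#' @export
init_dots <- function(params) {
  n <- params$n_dots
  hw <- params$field_deg[1] / 2
  hh <- params$field_deg[2] / 2
  cbind(x_deg = stats::runif(n, -hw, hw),
        y_deg = stats::runif(n, -hh, hh),
        age = as.numeric(sample.int(params$dot_lifetime_frames, n,
                                    replace = TRUE) - 1L))
}

#' Advance the dot field by one frame
#'
#' Each dot moves radially away from the instantaneous focus along the
#' focus-to-dot ray by `k * ecc * dt`, where `ecc` is its Euclidean distance
#' from the focus in degrees; a dot exactly at the focus has zero speed and
#' stays in place. Ages are then incremented and dots whose lifetime has
#' expired, or which left the background field, respawn uniformly over the
#' field with age zero. Only expansion kinematics exist here: contraction is
#' produced by frame reversal ([make_contraction()]), never by integrating
#' inward motion.
#'
#' @param dots dot matrix as returned by [init_dots()].
#' @param focus numeric `c(x_deg, y_deg)` of the instantaneous focus.
#' @param params a [stimulus_params()] object.
#' @param dt frame interval in seconds (1 / `movie_fps`).
#' @return Updated dot matrix. Uses the current RNG state (for respawns).
#' @export
step_dots <- function(dots, focus, params, dt = 1 / params$movie_fps) {
  if (nrow(dots) == 0L) return(dots)
  dx <- dots[, "x_deg"] - focus[1]
  dy <- dots[, "y_deg"] - focus[2]
  ecc <- sqrt(dx^2 + dy^2)
  step <- params$speed_constant * ecc * dt
  nz <- ecc > 0
  x <- dots[, "x_deg"]
  y <- dots[, "y_deg"]
  x[nz] <- x[nz] + step[nz] * dx[nz] / ecc[nz]
  y[nz] <- y[nz] + step[nz] * dy[nz] / ecc[nz]
  age <- dots[, "age"] + 1
  hw <- params$field_deg[1] / 2
  hh <- params$field_deg[2] / 2
  dead <- age >= params$dot_lifetime_frames | abs(x) > hw | abs(y) > hh
  nd <- sum(dead)
  if (nd > 0L) {
    x[dead] <- stats::runif(nd, -hw, hw)
    y[dead] <- stats::runif(nd, -hh, hh)
    age[dead] <- 0
  }
  cbind(x_deg = x, y_deg = y, age = age)
}

#' Generate an expansion flow movie as a frame set
#'
#' Runs the forward-Euler dot integration at `movie_fps` against the moving
#' focus and records each frame's dot coordinates and the focus position. The
#' default parameters yield the study movie: 300 frames of 500 dots over 10 s.
#'
#' @param params a [stimulus_params()] with `direction = "expansion"`. If
#'   `params$rng_seed` is set, the generator seeds the RNG locally so the
#'   frame set is bit-reproducible.
#' @return A `frame_set`: list with `frames` (list of n_dots x 2 coordinate
#'   matrices), `focus_positions` (n_frames x 2), `t` (frame times, frame i
#'   displayed at (i-1)/fps) and `params`.
#' @export
generate_expansion_frames <- function(params) {
  stopifnot(inherits(params, "stimulus_params"))
  if (params$direction != "expansion")
    stop("frame sets are generated as expansion; use make_contraction()")
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  n_frames <- as.integer(round(params$movie_fps * params$movie_duration_s))
  traj <- focus_trajectory(params$path, params$focus_offset_deg,
                           params$movie_duration_s)
  t <- (seq_len(n_frames) - 1) / params$movie_fps
  fpos <- focus_position(traj, t)
  dots <- init_dots(params)
  frames <- vector("list", n_frames)
  frames[[1L]] <- dots[, c("x_deg", "y_deg"), drop = FALSE]
  if (n_frames > 1L) for (i in 2:n_frames) {
    dots <- step_dots(dots, fpos[i - 1L, ], params)
    frames[[i]] <- dots[, c("x_deg", "y_deg"), drop = FALSE]
  }
  structure(list(frames = frames, focus_positions = fpos, t = t,
                 params = params, trajectory = traj),
            class = "frame_set")
}

#' Build a contraction movie by reverse play
#'
#' Output frame i equals input frame N+1-i, bit-exactly; the recorded focus
#' positions are reversed the same way and the direction label flipped. The
#' two movies contain exactly the same images in opposite order.
#'
#' @param fs a `frame_set` generated as expansion.
#' @return A `frame_set` with `direction = "contraction"`.
#' @export
make_contraction <- function(fs) {
  stopifnot(inherits(fs, "frame_set"))
  n <- length(fs$frames)
  fs$frames <- fs$frames[n:1]
  fs$focus_positions <- fs$focus_positions[n:1, , drop = FALSE]
  fs$params$direction <-
    if (fs$params$direction == "expansion") "contraction" else "expansion"
  fs
}

#' Benchmark movie: a single square tracking the focus trajectory
#'
#' A control stimulus for basic gaze following: one white square (area
#' 1.9 deg^2, side sqrt(1.9) deg) whose center follows exactly the focus
#' trajectory of a flow movie with the same path.
#'
#' @param params a [stimulus_params()]; only geometry/path/timing fields are
#'   used.
#' @return A `frame_set` whose frames each hold the 1 x 2 square-center
#'   coordinate; `square_side_deg` gives the side length.
#' @export
make_benchmark <- function(params) {
  stopifnot(inherits(params, "stimulus_params"))
  n_frames <- as.integer(round(params$movie_fps * params$movie_duration_s))
  traj <- focus_trajectory(params$path, params$focus_offset_deg,
                           params$movie_duration_s)
  t <- (seq_len(n_frames) - 1) / params$movie_fps
  fpos <- focus_position(traj, t)
  frames <- lapply(seq_len(n_frames), function(i)
    matrix(fpos[i, ], nrow = 1, dimnames = list(NULL, c("x_deg", "y_deg"))))
  structure(list(frames = frames, focus_positions = fpos, t = t,
                 params = params, trajectory = traj,
                 square_side_deg = sqrt(1.9)),
            class = "frame_set")
}

#' Mean dot speed of a frame set
#'
#' The analytic per-dot speed `k * ecc` averaged over all dots and frames,
#' with eccentricity measured from the recorded focus of each frame. Reported
#' as a measured property of the simulated movie (the averaging convention
#' behind any nominal figure is left to the caller).
#'
#' @param fs a `frame_set`.
#' @return Mean speed in deg/s.
#' @export
mean_dot_speed <- function(fs) {
  stopifnot(inherits(fs, "frame_set"))
  k <- fs$params$speed_constant
  sp <- vapply(seq_along(fs$frames), function(i) {
    f <- fs$frames[[i]]
    mean(k * sqrt((f[, 1] - fs$focus_positions[i, 1])^2 +
                  (f[, 2] - fs$focus_positions[i, 2])^2))
  }, numeric(1))
  mean(sp)
}

#' Export a frame set to CSV
#'
#' Writes the movie as data: one row per dot per frame with columns
#' `frame_index`, `dot_id`, `x_deg`, `y_deg`, preceded by a commented metadata
#' block; optionally a companion trajectory CSV (`t_s`, `focus_x_deg`,
#' `focus_y_deg`).
#'
#' @param fs a `frame_set`.
#' @param file output CSV path.
#' @param trajectory_file optional path for the focus-trajectory CSV.
#' @return `file`, invisibly.
#' @export
write_frame_csv <- function(fs, file, trajectory_file = NULL) {
  p <- fs$params
  meta <- c(
    sprintf("# direction=%s speed=%s path=%s", p$direction, p$speed, p$path),
    sprintf("# n_dots=%d speed_constant=%g lifetime_frames=%d fps=%g duration_s=%g",
            p$n_dots, p$speed_constant, p$dot_lifetime_frames,
            p$movie_fps, p$movie_duration_s),
    sprintf("# field_deg=%gx%g px_per_deg=%.6f", p$field_deg[1], p$field_deg[2],
            p$px_per_deg))
  rows <- do.call(rbind, lapply(seq_along(fs$frames), function(i) {
    f <- fs$frames[[i]]
    data.frame(frame_index = i, dot_id = seq_len(nrow(f)),
               x_deg = f[, 1], y_deg = f[, 2])
  }))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(rows, con, row.names = FALSE)
  if (!is.null(trajectory_file)) {
    utils::write.csv(data.frame(t_s = fs$t,
                                focus_x_deg = fs$focus_positions[, 1],
                                focus_y_deg = fs$focus_positions[, 2]),
                     trajectory_file, row.names = FALSE)
  }
  invisible(file)
}
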