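test_that("focus trajectory is a closed triangle wave with exact sweep speed", {
  traj <- focus_trajectory("RLR")
  expect_equal(traj$sweep_speed_deg_s, 3.68)
  expect_equal(focus_position(traj, 0), cbind(x_deg = 9.2, y_deg = 0))
  expect_equal(focus_position(traj, 10), cbind(x_deg = 9.2, y_deg = 0))
  expect_equal(focus_position(traj, 5), cbind(x_deg = -9.2, y_deg = 0))
  # periodicity and mirror path
  expect_equal(focus_position(traj, 10)[1, 1], focus_position(traj, 0)[1, 1])
  trajL <- focus_trajectory("LRL")
  tt <- seq(0, 10, by = 0.25)
  expect_equal(focus_position(trajL, tt)[, 1], -focus_position(traj, tt)[, 1])
  # vertical offset is always zero
  expect_true(all(focus_position(traj, tt)[, 2] == 0))
  expect_error(focus_position(traj, -0.1), "outside")
  expect_error(focus_position(traj, 10.1), "outside")
})

test_that("dot initialization fills the field, staggers ages, and is seeded", {
  p <- stimulus_params()
  set.seed(11); d1 <- init_dots(p)
  set.seed(11); d2 <- init_dots(p)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 500)
  expect_true(all(abs(d1[, "x_deg"]) <= 35.3 / 2))
  expect_true(all(abs(d1[, "y_deg"]) <= 26.4 / 2))
  expect_true(all(d1[, "age"] >= 0 & d1[, "age"] < 10))
  expect_gt(length(unique(d1[, "age"])), 1)  # desynchronized respawns
  p0 <- stimulus_params(n_dots = 0)
  expect_equal(nrow(init_dots(p0)), 0)
})

test_that("dot kinematics: zero speed at focus, linear in eccentricity and k", {
  p_low <- stimulus_params(speed = "low")
  p_high <- stimulus_params(speed = "high")
  focus <- c(0, 0)
  dots <- cbind(x_deg = c(0, 10, 5), y_deg = c(0, 0, 0), age = c(0, 0, 0))
  s_low <- step_dots(dots, focus, p_low)
  s_high <- step_dots(dots, focus, p_high)
  # dot exactly at the focus does not move (documented tie-break)
  expect_equal(s_low[1, c("x_deg", "y_deg")], c(x_deg = 0, y_deg = 0))
  # k * ecc * dt = 0.33 * 10 / 30 = 0.11 deg per frame
  expect_equal(unname(s_low[2, "x_deg"]) - 10, 0.11, tolerance = 1e-12)
  # doubling k exactly doubles every displacement before respawn
  expect_equal(s_high[, "x_deg"] - dots[, "x_deg"],
               2 * (s_low[, "x_deg"] - dots[, "x_deg"]))
  # motion is radial: a dot off-axis moves along the focus->dot ray
  d2 <- cbind(x_deg = 3, y_deg = 4, age = 0)
  s2 <- step_dots(d2, focus, p_low)
  expect_equal(s2[1, "y_deg"] / s2[1, "x_deg"], 4 / 3, tolerance = 1e-12)
})

test_that("expansion frame sets have the study structure and stay in field", {
  p <- stimulus_params(rng_seed = 42)
  fs <- generate_expansion_frames(p)
  expect_s3_class(fs, "frame_set")
  expect_length(fs$frames, 300)
  expect_true(all(vapply(fs$frames, nrow, 1L) == 500))
  hw <- 35.3 / 2; hh <- 26.4 / 2
  inside <- vapply(fs$frames, function(f)
    all(abs(f[, 1]) <= hw & abs(f[, 2]) <= hh), logical(1))
  expect_true(all(inside))
  # seeded determinism: bit-identical frame sets
  fs2 <- generate_expansion_frames(stimulus_params(rng_seed = 42))
  expect_identical(fs$frames, fs2$frames)
  # short movie
  p1 <- stimulus_params(movie_duration_s = 1, rng_seed = 1)
  expect_length(generate_expansion_frames(p1)$frames, 30)
  expect_error(generate_expansion_frames(stimulus_params(direction = "contraction")),
               "expansion")
})

test_that("contraction is exact reverse play", {
  fs <- generate_expansion_frames(stimulus_params(rng_seed = 3))
  cs <- make_contraction(fs)
  expect_equal(cs$params$direction, "contraction")
  for (i in c(1, 7, 150, 300))
    expect_identical(cs$frames[[i]], fs$frames[[300 - i + 1]])
  expect_identical(cs$focus_positions[1, ], fs$focus_positions[300, ])
  # involution and identical frame multisets
  back <- make_contraction(cs)
  expect_identical(back$frames, fs$frames)
  expect_equal(back$params$direction, "expansion")
})

test_that("benchmark square rides the focus trajectory", {
  p <- stimulus_params(path = "LRL")
  bm <- make_benchmark(p)
  expect_length(bm$frames, 300)
  expect_equal(bm$frames[[1]][1, ], c(x_deg = -9.2, y_deg = 0))
  expect_equal(bm$square_side_deg^2, 1.9)
  fs <- generate_expansion_frames(stimulus_params(path = "LRL", rng_seed = 5))
  expect_equal(bm$focus_positions, fs$focus_positions)
})

test_that("mean dot speed scales exactly with the speed constant", {
  lo <- generate_expansion_frames(stimulus_params(speed = "low", rng_seed = 9))
  hi <- generate_expansion_frames(stimulus_params(speed = "high", rng_seed = 77))
  ratio <- mean_dot_speed(hi) / mean_dot_speed(lo)
  expect_equal(ratio, 2, tolerance = 0.05)
  expect_gt(mean_dot_speed(lo), 0)
})

test_that("frame CSV export writes coordinates and trajectory", {
  p <- stimulus_params(n_dots = 5, movie_duration_s = 0.2, rng_seed = 2)
  fs <- generate_expansion_frames(p)
  f <- tempfile(fileext = ".csv"); tf <- tempfile(fileext = ".csv")
  write_frame_csv(fs, f, trajectory_file = tf)
  d <- read.csv(f, comment.char = "#")
  expect_equal(nrow(d), 5 * 6)
  expect_equal(names(d), c("frame_index", "dot_id", "x_deg", "y_deg"))
  expect_equal(d$x_deg[d$frame_index == 3], unname(fs$frames[[3]][, 1]))
  tr <- read.csv(tf)
  expect_equal(tr$focus_x_deg, unname(fs$focus_positions[, 1]))
})

test_that("degree/pixel conversion round-trips and flips the y axis", {
  pts <- list(x = c(0, 9.2, -5), y = c(0, 3, -8))
  px <- deg_to_px(pts$x, pts$y)
  expect_equal(px$x[1], 512); expect_equal(px$y[1], 384)
  expect_equal(px$x[2], 512 + 268)
  expect_lt(px$y[2], 384)  # y up in degrees -> up the raster
  back <- px_to_deg(px$x, px$y)
  expect_equal(back$x, pts$x); expect_equal(back$y, pts$y)
})
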