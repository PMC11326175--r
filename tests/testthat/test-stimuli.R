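test_that("surrogate walkers match the configured bout statistics", {
  src <- surrogate_trajectories(3, 300, seed = 201)
  expect_setequal(unique(src$agent_id), 1:3)
  expect_true(all(sqrt(src$x_cm^2 + src$y_cm^2) <= 3.25 + 1e-9))

  # time spent bouting = bout rate x bout duration (busy-fraction identity
  # of the serially executing bout queue)
  expect_lt(abs(mean(src$bouting) - 1.64 * 0.32), 0.05)

  # zero bout size: trajectories are stationary
  still <- surrogate_trajectories(2, 10,
                                  config = group_config(bout_size_cm = 0),
                                  seed = 202)
  for (a in split(still, still$agent_id)) {
    expect_equal(length(unique(a$x_cm)), 1)
  }

  # deterministic given seed
  expect_identical(surrogate_trajectories(2, 20, seed = 203),
                   surrogate_trajectories(2, 20, seed = 203))
})

test_that("replay streams present one dot per fish at the recorded positions", {
  src <- surrogate_trajectories(4, 20, seed = 211)
  stim <- replay_stream(src)
  expect_equal(ncol(stim$X), 4)
  expect_true(all(stim$R == 0.75)) # radius = half the printed 1.5 cm diameter
  expect_equal(stim$frame_ref, "world")
  expect_equal(stim$X[10, 2], src$x_cm[src$agent_id == 2][10])

  # speedup presents every k-th source frame
  fast <- replay_stream(src, speedup = 4)
  expect_equal(nrow(fast$X), ceiling(nrow(stim$X) / 4))
  expect_equal(fast$X[2, 1], stim$X[5, 1])
})

test_that("stationary streams hold one frozen source frame", {
  src <- surrogate_trajectories(5, 20, seed = 221)
  frozen <- stationary_frame_stream(src, seed = 222)
  expect_equal(nrow(frozen$X), 1)
  expect_equal(ncol(frozen$X), 5)
  f <- frozen$params$source_frame
  expect_equal(as.vector(frozen$X), src$x_cm[src$time_s == sort(unique(src$time_s))[f]])
})

test_that("rotational rings move without looming", {
  src <- surrogate_trajectories(20, 60, seed = 231)
  rings <- rotational_rings(src, n_dots = 19, duration_s = 30, seed = 232)
  expect_equal(ncol(rings$X), 19)
  expect_equal(rings$frame_ref, "focal")

  # constant distance to the focal fish for every dot
  d <- sqrt(rings$X^2 + rings$Y^2)
  expect_true(all(abs(sweep(d, 2, d[1, ])) < 1e-9))

  # angular motion balanced between the two directions
  th <- atan2(rings$Y, rings$X)
  dth <- wrap_angle(diff(th) * 180 / pi)
  moving <- dth[abs(dth) > 1e-9]
  expect_gt(length(moving), 500)
  expect_lt(abs(mean(moving > 0) - 0.5), 0.1)

  # fed to the simulator: zero neighbor-induced looming (moving, not looming)
  run <- run_session(vr_config(), protocol_segment(30, rings), seed = 233)
  expect_true(all(run$states$input_deg == 0))

  expect_error(rotational_rings(surrogate_trajectories(5, 10, seed = 234),
                                n_dots = 19, duration_s = 10),
               "at least 20")
})

test_that("the looming hexagon looms without moving", {
  hx <- looming_hexagon(duration_s = 30, seed = 241)
  expect_equal(ncol(hx$X), 19)
  expect_true(all(hx$R >= 0.075 & hx$R <= 0.9))
  expect_true(all(apply(hx$X, 2, function(col) length(unique(col)) == 1)))
  expect_equal(nrow(unique(cbind(hx$X[1, ], hx$Y[1, ]))), 19)

  # fed to the simulator: strictly positive looming (looming, not moving)
  run <- run_session(vr_config(), protocol_segment(30, hx), seed = 242)
  expect_gt(sum(run$states$input_deg), 0)
  expect_true(all(run$trajectories$x_cm^2 + run$trajectories$y_cm^2 <=
                    3.25^2 + 1e-9))
})

test_that("single-dot protocols follow the printed geometry", {
  cfg <- vr_config()
  mv <- single_dot_stream("moving", duration_s = 100, seed = 251)
  ang <- 2 * atan(mv$R / sqrt(mv$X^2 + mv$Y^2)) * 180 / pi
  expect_true(all(abs(ang - 39.30765) < 1e-5)) # constant ~40 degrees

  mc <- single_dot_stream("moving_closer", duration_s = 10, seed = 252)
  ang_mc <- 2 * atan(mc$R / sqrt(mc$X^2 + mc$Y^2)) * 180 / pi
  tr1 <- ang_mc[1:250]
  expect_equal(tr1[1], 9.321091, tolerance = 1e-4)   # ~9 degrees
  expect_equal(max(tr1), 2 * atan(0.075 / 0.22) * 180 / pi,
               tolerance = 1e-6)                      # ~40 degrees
  expect_true(all(diff(tr1) > 0))

  mg <- single_dot_stream("moving_growing", duration_s = 10, seed = 253)
  ang_mg <- 2 * atan(mg$R / sqrt(mg$X^2 + mg$Y^2)) * 180 / pi
  expect_equal(ang_mg[1], 2 * atan(0.025 / 0.35) * 180 / pi)
  expect_equal(ang_mg[250], 2 * atan(0.13 / 0.35) * 180 / pi)

  # bearings stay between the start and end magnitudes; sides balanced
  many <- single_dot_stream("moving", duration_s = 1000, seed = 254)
  b <- abs(atan2(many$Y, many$X) * 180 / pi)
  expect_true(all(b >= 30 - 1e-9 & b <= 75 + 1e-9))
  sides <- many$params$sides
  expect_equal(length(sides), 200)
  expect_lt(abs(mean(sides > 0) - 0.5), 3 * 0.5 / sqrt(200))
})

test_that("stimulus CSV round trips are lossless", {
  src <- surrogate_trajectories(3, 10, seed = 261)
  stim <- replay_stream(src)
  path <- tempfile(fileext = ".csv")
  write_stimulus_csv(stim, path)
  back <- read_stimulus_csv(path)
  expect_lt(max(abs(back$X - stim$X)), 1e-6)
  expect_lt(max(abs(back$Y - stim$Y)), 1e-6)
  expect_lt(max(abs(back$R - stim$R)), 1e-6)
  expect_equal(back$period_s, stim$period_s)
  expect_equal(back$frame_ref, "world")
  unlink(path)
})
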