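test_that("sessions are reproducible and stay inside the arena", {
  cfg <- vr_config()
  r1 <- run_free_agent(300, cfg, seed = 101)
  r2 <- run_free_agent(300, cfg, seed = 101)
  expect_identical(r1$trajectories, r2$trajectories)
  expect_identical(r1$bouts, r2$bouts)
  expect_true(all(sqrt(r1$trajectories$x_cm^2 + r1$trajectories$y_cm^2) <=
                    cfg$arena_diameter_cm / 2 + 1e-9))

  g1 <- run_session(group_config(), protocol_segment(120, n_agents = 8),
                    seed = 102)
  g2 <- run_session(group_config(), protocol_segment(120, n_agents = 8),
                    seed = 102)
  expect_identical(g1$trajectories, g2$trajectories)
  expect_true(all(sqrt(g1$trajectories$x_cm^2 + g1$trajectories$y_cm^2) <=
                    3.25 + 1e-9))
})

test_that("bout primitives match their configured statistics", {
  cfg <- vr_config()
  set.seed(111)
  expect_false(any(decide_bout(simulation_config(bout_rate_hz = 0), 1000)))
  p_hat <- mean(decide_bout(cfg, 2e5))
  expect_lt(abs(p_hat - cfg$bout_rate_hz * cfg$dt_s), 3 * sqrt(0.0328 / 2e5))

  mags <- bout_turn_magnitude(5000, cfg)
  expect_true(all(mags >= 0))

  # wall probability: half-max at the ignore radius, ~1 at the wall
  expect_equal(wall_turn_probability(cfg$wall_ignore_bl, cfg), 0.5)
  expect_gt(wall_turn_probability(0, cfg), 0.99)
  expect_lt(wall_turn_probability(5, cfg), 0.01)

  # truncation keeps the agent on or inside the boundary
  res <- execute_bout_step(3.24, 0, 0.05, 0, 3.25)
  expect_true(res$truncated)
  expect_lte(sqrt(res$x^2 + res$y^2), 3.25)
  res2 <- execute_bout_step(0, 0, 0.00625, 0, 3.25)
  expect_false(res2$truncated)
  expect_equal(res2$x, 0.00625)
})

test_that("every bout lasts 320 ms and displaces 0.1 cm unless truncated", {
  cfg <- vr_config()
  run <- run_free_agent(600, cfg, seed = 121)
  expect_true(all(run$bouts$duration_ms == 320))

  steps <- round(cfg$bout_duration_ms / 1000 / cfg$dt_s)
  pos <- rbind(c(NA, NA),
               as.matrix(run$trajectories[, c("x_cm", "y_cm")]))
  set.seed(122)
  a0 <- NULL # first row displacement uses the (unknown) start pose; skip k0=0
  for (on in run$bouts$onset_s) {
    k0 <- round(on / cfg$dt_s)
    rows <- (k0 + 1):(k0 + steps) + 1 # +1 for the prepended start row
    if (k0 == 0 || max(rows) > nrow(pos)) next
    seg <- pos[(min(rows) - 1):max(rows), ]
    if (any(sqrt(seg[, 1]^2 + seg[, 2]^2) > 3.0)) next # possibly truncated
    path <- sum(sqrt(diff(seg[, 1])^2 + diff(seg[, 2])^2))
    expect_equal(path, cfg$bout_size_cm, tolerance = 1e-9)
  }
})

test_that("the emergent bout rate matches the configured rate", {
  run <- run_free_agent(2000, vr_config(), seed = 131, emit_every = 10L)
  rate <- nrow(run$bouts) / 2000
  se <- sqrt(1.64 / 2000) # Poisson counting error
  expect_lt(abs(rate - 1.64), 2 * se)
})

test_that("wall-avoidance bouts turn away from the nearest wall", {
  cfg <- vr_config()
  set.seed(141)
  agents <- init_agents(cfg, 1)
  agents$x_cm <- 3.1; agents$y_cm <- 0 # 0.375 body lengths from the wall
  run <- run_session(cfg, protocol_segment(300), seed = 141, agents = agents)
  wall_bouts <- run$bouts[run$bouts$wall_turn == 1, ]
  expect_gt(nrow(wall_bouts), 10)
  traj <- run$trajectories
  for (i in seq_len(nrow(wall_bouts))) {
    k <- round(wall_bouts$onset_s[i] / cfg$dt_s)
    if (k == 0) next
    p <- traj[k, ] # pose entering the bout step
    beta <- wrap_angle(atan2(p$y_cm, p$x_cm) * 180 / pi - p$heading_deg)
    expect_equal(sign(wall_bouts$turn_deg[i]), if (beta > 0) -1 else 1)
  }
})

test_that("a static scene leaves the integrator on its free decay", {
  cfg <- vr_config()
  set.seed(151)
  src <- surrogate_trajectories(5, 60, seed = 151)
  frozen <- stationary_frame_stream(src, seed = 152)
  run <- run_session(cfg, protocol_segment(120, frozen), seed = 153)
  expect_true(all(run$states$input_deg == 0))
  p <- config_integrator(cfg)
  expect_equal(run$states$s,
               run_integrator(cfg$s0, numeric(nrow(run$states)), cfg$dt_s, p),
               tolerance = 1e-12)
})

test_that("the compiled engine agrees with the R-level model components", {
  cfg <- vr_config()
  set.seed(161)
  src <- surrogate_trajectories(3, 30, seed = 161)
  stim <- replay_stream(src)
  seed <- 162
  run <- run_session(cfg, protocol_segment(10, stim), seed = seed)

  # reproduce the initial pose drawn inside run_session
  set.seed(seed)
  a0 <- init_agents(cfg, 1)
  traj <- run$trajectories
  states <- run$states
  n_frames <- nrow(stim$X)
  pose_at <- function(k) { # pose used for perception at step k (0-based)
    if (k == 0) c(a0$x_cm, a0$y_cm, a0$heading_deg)
    else unlist(traj[k, c("x_cm", "y_cm", "heading_deg")], use.names = FALSE)
  }
  frame_objs <- function(k) {
    f <- k %% n_frames + 1
    visual_objects(stim$X[f, ], stim$Y[f, ], stim$R[f, ])
  }

  # looming inputs, state trace and effective slope
  p <- config_integrator(cfg)
  for (k in c(1, 2, 5, 17, 100, 250, 499)) {
    li <- looming_from_scene(pose_at(k), pose_at(k - 1), frame_objs(k),
                             frame_objs(k - 1), mode = "neighbor_induced")
    expect_equal(states$input_deg[k + 1], li$value, tolerance = 1e-9)
  }
  expect_equal(states$input_deg[1], 0)
  expect_equal(states$s,
               run_integrator(cfg$s0, states$input_deg, cfg$dt_s, p),
               tolerance = 1e-12)
  expect_equal(states$a_eff, effective_slope(cfg$a, states$s, p),
               tolerance = 1e-12)

  # per-frame nearest-dot distance
  for (k in c(3, 50, 400)) {
    pp <- pose_at(k)
    ob <- frame_objs(k)
    expect_equal(states$nn_cm[k + 1],
                 min(sqrt((ob$x - pp[1])^2 + (ob$y - pp[2])^2)),
                 tolerance = 1e-9)
  }

  # the logged binocular drive equals the R-side occupancy drive
  for (i in seq_len(nrow(run$bouts))) {
    k <- round(run$bouts$onset_s[i] / cfg$dt_s)
    prof <- occupancy_profile(pose_at(k)[1], pose_at(k)[2], pose_at(k)[3],
                              frame_objs(k))
    expect_equal(run$bouts$drive_deg[i], occupancy_drive(prof),
                 tolerance = 1e-9)
  }
})

test_that("group resizing keeps survivors and samples newcomer states", {
  cfg <- group_config()
  set.seed(171)
  agents <- init_agents(cfg, 20)
  agents$s <- runif(20, 0.55, 0.75)

  small <- resize_group(agents, 5, cfg)
  expect_equal(nrow(small), 5)
  expect_true(all(small$x_cm %in% agents$x_cm))
  expect_true(all(small$s %in% agents$s))

  same <- agents[1:5, ]
  same$s <- 0.63
  grown <- resize_group(same, 20, cfg)
  expect_equal(nrow(grown), 20)
  expect_identical(grown[1:5, ], same)
  expect_true(all(grown$s[6:20] == 0.63)) # sd = 0 source distribution

  # sampled states match the source distribution: mean within 3 SE
  spread <- agents[1:5, ]
  draws <- replicate(300, mean(resize_group(spread, 25, cfg)$s[6:25]))
  se <- sd(spread$s) / sqrt(20) / sqrt(300) * sqrt(300) # per-draw SE
  expect_lt(abs(mean(draws) - mean(spread$s)), 3 * sd(draws) / sqrt(300) + se)

  expect_error(resize_group(agents[0, ], 5, cfg), "empty")
  expect_error(protocol_segment(0), "duration")
})

test_that("disabling the integrator removes history dependence", {
  # static-model null: with r = 0 the effective slope never moves, so the
  # nearest-neighbor change across a density switch is centered on zero
  cfg <- vr_config(r = 0)
  deltas <- vapply(1:6, function(i) {
    set.seed(180 + i)
    low <- replay_stream(surrogate_trajectories(4, 600, seed = 180 + i))
    high <- replay_stream(surrogate_trajectories(19, 600,
                                                 seed = 1800 + i))
    run <- run_density_switch(cfg, low, high, baseline_min = 8,
                              high_min = 10, zero_min = 0, probe_min = 8,
                              seed = 18000 + i)
    st <- run$states
    b <- mean(st$nn_cm[st$segment == 1 & st$time_s > 60], na.rm = TRUE)
    p <- mean(st$nn_cm[st$segment == 3 &
                         st$time_s > run$segments$start_s[3] + 60],
              na.rm = TRUE)
    p - b
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 3 * sd(deltas) / sqrt(length(deltas)) + 0.05)
})
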