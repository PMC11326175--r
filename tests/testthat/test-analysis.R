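test_that("central-difference kinematics recover known motion", {
  lin <- line_traj(speed = 1, n = 100)
  k <- kinematics(lin)
  expect_true(all(abs(k$speed_cm_s - 1) < 1e-10))
  expect_true(all(abs(k$motion_dir_deg) < 1e-10))
  expect_equal(nrow(k), 98) # endpoints dropped

  still <- static_traj(matrix(c(1, 1), 1))
  expect_true(all(kinematics(still)$speed_cm_s == 0))

  # circular motion: speed = R * omega with O(dt^2) error
  dt <- 0.02; omega <- 1; R <- 1.5
  t <- (0:200) * dt
  circ <- data.frame(time_s = t, agent_id = 1, x_cm = R * cos(omega * t),
                     y_cm = R * sin(omega * t), heading_deg = 0)
  kc <- kinematics(circ)
  expect_lt(max(abs(kc$speed_cm_s - R * omega)), R * omega * (omega * dt)^2)

  irr <- line_traj(n = 20)
  irr$time_s[10] <- irr$time_s[10] + 0.005
  expect_error(kinematics(irr), "irregular")
})

test_that("bout detection recovers the simulated ground truth", {
  # at a low bout rate chained bouts are rare, so detected episodes can be
  # compared against ground-truth episodes (logged bouts merged when their
  # gap is below the refractory period)
  cfg <- vr_config(bout_rate_hz = 0.4)
  run <- run_free_agent(300, cfg, seed = 301)
  det <- detect_bouts(run$trajectories, arena_diameter_cm = 6.5)
  onsets <- sort(run$bouts$onset_s)
  gaps <- diff(onsets)
  episodes <- 1 + sum(gaps > 0.32 + 0.1) # merged when within refractory
  expect_lt(abs(nrow(det) - episodes), max(2, 0.05 * episodes))

  still <- static_traj(matrix(c(0, 0), 1), n = 200)
  expect_equal(nrow(detect_bouts(still)), 0)
})

test_that("nearest-neighbor series and their invariances", {
  two <- static_traj(matrix(c(0, 0, 1, 0), 2, byrow = TRUE))
  nn <- nn_series(two)
  expect_true(all(nn$per_frame$nn_cm == 1))
  expect_true(all(nn$blocks$nn_cm == 1))

  three <- static_traj(matrix(c(0, 0, 1, 0, 3, 0), 3, byrow = TRUE))
  nn3 <- nn_series(three)
  expect_equal(unique(nn3$per_frame$nn_cm[nn3$per_frame$agent_id == 1]), 1)
  expect_equal(unique(nn3$per_frame$nn_cm[nn3$per_frame$agent_id == 2]), 1)
  expect_equal(unique(nn3$per_frame$nn_cm[nn3$per_frame$agent_id == 3]), 2)

  expect_error(nn_series(static_traj(matrix(c(0, 0), 1))), "2 animals")

  # rigid transforms leave the series unchanged; dilation scales it
  src <- surrogate_trajectories(5, 20, seed = 311)
  base <- nn_series(src)$group$nn_cm
  th <- 0.7
  rot <- src
  rot$x_cm <- cos(th) * src$x_cm - sin(th) * src$y_cm + 2
  rot$y_cm <- sin(th) * src$x_cm + cos(th) * src$y_cm - 1
  expect_equal(nn_series(rot)$group$nn_cm, base, tolerance = 1e-12)
  dil <- src
  dil$x_cm <- 2 * src$x_cm; dil$y_cm <- 2 * src$y_cm
  expect_equal(nn_series(dil)$group$nn_cm, 2 * base, tolerance = 1e-12)
})

test_that("shuffled controls are null for non-interacting animals", {
  tabs <- lapply(1:3, function(i) surrogate_trajectories(4, 60,
                                                         seed = 320 + i))
  sh <- shuffled_control(tabs, group_size = 4, n_shuffles = 30, seed = 324)
  observed <- mean(vapply(tabs, function(tb) {
    mean(nn_series(tb)$group$nn_cm)
  }, numeric(1)))
  expect_lt(abs(mean(sh$nn_cm) - observed),
            3 * sd(sh$nn_cm) / sqrt(nrow(sh)) + 0.1)

  expect_error(shuffled_control(tabs, 4, n_shuffles = 0), "n_shuffles")
  expect_error(shuffled_control(tabs[1], 4), "2 source groups")

  # repulsive agents keep larger distances than their shuffled controls
  reps <- lapply(1:3, function(i) {
    run_session(group_config(a = 0.03), protocol_segment(60, n_agents = 4),
                seed = 330 + i)$trajectories
  })
  obs_rep <- mean(vapply(reps, function(tb) mean(nn_series(tb)$group$nn_cm),
                         numeric(1)))
  sh_rep <- shuffled_control(reps, group_size = 4, n_shuffles = 30,
                             seed = 334)
  expect_gt(obs_rep, mean(sh_rep$nn_cm))
})

test_that("turn-probability maps bin and filter as specified", {
  ev <- data.frame(delta_occupancy_deg = runif(600, 0, 60),
                   turned_away = TRUE, distance_to_wall_bl = 2)
  fit <- turn_probability_map(ev, bin_width_deg = 5)
  expect_equal(nrow(fit$table), 12) # [0, 60) in 5-degree bins
  near_wall <- ev
  near_wall$distance_to_wall_bl <- 1
  expect_error(turn_probability_map(near_wall, 5), "no analyzable events")
})

test_that("protocol summaries and recovery fits behave on exact inputs", {
  s <- protocol_summary(c(1, 1.2), c(1, 1.2))
  expect_equal(s$delta_nn, 0)

  t <- seq(0, 80, 10)
  series <- 1.9 + (1.4 - 1.9) * exp(-t / 25)
  fit <- fit_recovery(t, series, baseline = 1.9)
  expect_equal(fit$lambda_min, 25, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # the fitted curve enters the 5% band where the closed form says it should
  t_true <- -25 * log((1.9 * 0.05) / 0.5)
  expect_equal(fit$t_cross_min, t_true, tolerance = 0.1)
  expect_error(fit_recovery(c(0, 10, 20), series[1:3], 1.9), "4 blocks")
})

test_that("exclusion filters implement the immobility and bout-rate rules", {
  stats <- data.frame(
    group_id = c(1, 1, 2, 2),
    animal_id = 1:4,
    bout_rate_hz = c(1.5, 1.2, 0.2, 1.4),
    immobile_frac = c(0.1, 0.6, 0.2, 0.1)
  )
  grp <- apply_filters(stats, "group")
  expect_equal(unique(grp$retained$group_id), 2)
  expect_true(all(grp$excluded$group_id == 1))

  single <- apply_filters(stats, "single")
  expect_equal(single$excluded$animal_id, 3) # bout rate 0.2 < 0.25 Hz
  expect_equal(nrow(single$retained), 3)

  active <- data.frame(group_id = 1, animal_id = 1:5,
                       bout_rate_hz = 1.6, immobile_frac = 0.05)
  expect_equal(nrow(apply_filters(active, "group")$retained), 5)
})

test_that("single-dot responses average over 60-trial blocks", {
  trials <- data.frame(trial = 1:150, side = rep(c(1, -1), 75),
                       n_left = 0, n_right = 0)
  trials$n_left <- ifelse(trials$side > 0, 0, 3) # always away
  trials$n_right <- ifelse(trials$side > 0, 3, 0)
  blk <- single_dot_blocks(trials)
  expect_equal(nrow(blk), 2) # 150 trials: two full blocks
  expect_true(all(blk$p_away == 1))
  expect_equal(length(attr(blk, "remainder")), 30)

  set.seed(341)
  rnd <- data.frame(trial = 1:120, side = 1,
                    n_left = rbinom(120, 10, 0.5))
  rnd$n_right <- 10 - rnd$n_left
  blk2 <- single_dot_blocks(rnd)
  expect_lt(abs(mean(blk2$p_away) - 0.5), 0.06)

  skip <- data.frame(trial = 1:2, side = 1, n_left = c(0, 2),
                     n_right = c(0, 1))
  expect_equal(attr(single_dot_blocks(skip, block_trials = 1), "skipped"), 1)
})
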