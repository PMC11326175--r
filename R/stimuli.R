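# Virtual-reality stimulus generators. A stimulus stream is a time-indexed
# dot field (position, radius per dot per frame) presented to the focal
# agent, either in world coordinates (trajectory replay, stationary frames,
# looming hexagon) or in the focal agent's heading frame (rotational rings,
# single-dot protocols), in which case the simulator re-anchors the dots to
# the focal pose every step, mirroring closed-loop VR.

#' Construct a stimulus stream
#'
#' @param X,Y,R numeric matrices (`n_frames x n_dots`) of dot centers (cm)
#'   and radii (cm); `NaN` marks an absent dot. Focal-frame streams give
#'   coordinates in the heading frame (+x ahead, +y left).
#' @param period_s frame period in seconds (> 0).
#' @param frame_ref `"world"` or `"focal"`.
#' @param protocol protocol name carried as metadata.
#' @param params named list of generator parameters (metadata).
#' @return object of class `stimulus_stream`. Streams presented for longer
#'   than their duration restart from the beginning (a momentary
#'   discontinuity, as in the rig).
#' @export
stimulus_stream <- function(X, Y, R, period_s, frame_ref = c("world", "focal"),
                            protocol = "custom", params = list()) {
  frame_ref <- match.arg(frame_ref)
  stopifnot(period_s > 0, nrow(X) >= 1,
            all(dim(X) == dim(Y)), all(dim(X) == dim(R)))
  if (any(R[!is.nan(R)] <= 0)) stop("dot radii must be > 0")
  structure(list(X = X, Y = Y, R = R, period_s = period_s,
                 frame_ref = frame_ref, protocol = protocol, params = params),
            class = "stimulus_stream")
}

#' @export
print.stimulus_stream <- function(x, ...) {
  cat(sprintf(
    "<stimulus_stream> %s: %d frames x %d dots @ %.0f Hz (%s frame, %.1f s)\n",
    x$protocol, nrow(x$X), ncol(x$X), 1 / x$period_s, x$frame_ref,
    nrow(x$X) * x$period_s))
  invisible(x)
}

stimulus_matrices <- function(stream) {
  stopifnot(inherits(stream, "stimulus_stream"))
  list(X = stream$X, Y = stream$Y, R = stream$R, period_s = stream$period_s,
       frame_ref = stream$frame_ref)
}

#' Stream duration in seconds
#' @param stream a [stimulus_stream()].
#' @export
stream_duration <- function(stream) nrow(stream$X) * stream$period_s

# wide position matrices (frames x animals) from a long trajectory table
traj_to_matrices <- function(traj) {
  ids <- sort(unique(traj$agent_id))
  tt <- sort(unique(traj$time_s))
  o <- order(traj$agent_id, traj$time_s)
  if (nrow(traj) != length(ids) * length(tt)) {
    stop("trajectory table is not a complete time x animal grid")
  }
  list(ids = ids, time = tt,
       X = matrix(traj$x_cm[o], nrow = length(tt)),
       Y = matrix(traj$y_cm[o], nrow = length(tt)))
}

traj_period <- function(traj) {
  tt <- sort(unique(traj$time_s))
  if (length(tt) < 2) stop("need at least 2 frames")
  median(diff(tt))
}

#' Surrogate fish trajectories
#'
#' Independent, non-interacting bout-walkers confined to the arena,
#' matching the configured bout statistics (rate, displacement, duration,
#' turn-angle distribution) and wall avoidance but with the social response
#' switched off. Used as replay material in place of recorded fish.
#'
#' @param n_fish number of fish (>= 1).
#' @param duration_s duration in seconds.
#' @param config a [simulation_config()]; the social slope and integrator
#'   input are zeroed internally.
#' @param seed optional seed (uses the current RNG state when `NULL`).
#' @return a trajectory table (`time_s`, `agent_id`, `x_cm`, `y_cm`,
#'   `heading_deg`, `bouting`).
#' @export
surrogate_trajectories <- function(n_fish, duration_s,
                                   config = group_config(), seed = NULL) {
  stopifnot(n_fish >= 1, duration_s > 0)
  cfg <- config
  cfg$a <- 0
  cfg$r <- 0
  cfg$mode <- "group"
  run <- run_session(cfg, protocol_segment(duration_s, n_agents = n_fish),
                     seed = seed)
  run$trajectories[, c("time_s", "agent_id", "x_cm", "y_cm", "heading_deg",
                       "bouting")]
}

#' Trajectory replay stream
#'
#' Presents each animal of a trajectory table as a dark dot at its position
#' (default diameter 1.5 cm, i.e. radius 0.75 cm). When presented for longer
#' than the source the stream restarts from its first frame.
#'
#' @param traj trajectory table.
#' @param dot_radius_cm dot radius (0.75 cm).
#' @param n_dots present only the first `n_dots` animals (default: all).
#' @param speedup integer factor: present every k-th source frame, making
#'   the virtual fish move k times faster.
#' @return a world-frame [stimulus_stream()].
#' @export
replay_stream <- function(traj, dot_radius_cm = 0.75, n_dots = NULL,
                          speedup = 1) {
  m <- traj_to_matrices(traj)
  keep <- seq_len(if (is.null(n_dots)) length(m$ids) else n_dots)
  idx <- seq(1, nrow(m$X), by = speedup)
  X <- m$X[idx, keep, drop = FALSE]
  Y <- m$Y[idx, keep, drop = FALSE]
  stimulus_stream(X, Y, matrix(dot_radius_cm, nrow(X), ncol(X)),
                  period_s = traj_period(traj), frame_ref = "world",
                  protocol = "replay",
                  params = list(dot_radius_cm = dot_radius_cm,
                                speedup = speedup))
}

#' Stationary-dot stream
#'
#' A single, randomly chosen frame of the source trajectories, held for the
#' whole presentation. Under neighbor-induced looming this stream generates
#' exactly zero integrator input.
#'
#' @inheritParams replay_stream
#' @param seed optional seed for the frame choice.
#' @return a world-frame [stimulus_stream()] with one (looped) frame.
#' @export
stationary_frame_stream <- function(traj, dot_radius_cm = 0.75, n_dots = NULL,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- traj_to_matrices(traj)
  keep <- seq_len(if (is.null(n_dots)) length(m$ids) else n_dots)
  f <- sample.int(nrow(m$X), 1)
  X <- m$X[f, keep, drop = FALSE]
  Y <- m$Y[f, keep, drop = FALSE]
  stimulus_stream(X, Y, matrix(dot_radius_cm, 1, ncol(X)),
                  period_s = traj_period(traj), frame_ref = "world",
                  protocol = "stationary",
                  params = list(source_frame = f,
                                dot_radius_cm = dot_radius_cm))
}

#' Rotational-ring stream (moving, not looming)
#'
#' Dots move on concentric rings centered on the focal fish: dot k sits at
#' the modal distance of the k-th nearest neighbor in the source
#' trajectories (histogram mode, 0.05 cm bins) and advances in bout-like
#' angular steps with a clockwise/counter-clockwise direction resampled per
#' bout. Distances to the focal fish are constant, so the neighbor-induced
#' looming input is identically zero.
#'
#' @param source_traj trajectory table with at least `n_dots + 1` animals,
#'   used to estimate the k-th nearest-neighbor distance modes.
#' @param n_dots number of ring dots (19).
#' @param duration_s stream duration.
#' @param dot_radius_cm dot radius (0.75 cm).
#' @param config a [simulation_config()] supplying the bout kinematics and
#'   frame period (`dt_s`).
#' @param seed optional seed.
#' @return a focal-frame [stimulus_stream()].
#' @export
rotational_rings <- function(source_traj, n_dots = 19, duration_s,
                             dot_radius_cm = 0.75, config = vr_config(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- traj_to_matrices(source_traj)
  if (length(m$ids) < n_dots + 1) {
    stop("need at least ", n_dots + 1, " source animals to estimate ",
         n_dots, " nearest-neighbor distance modes")
  }
  radii <- knn_distance_modes(m, k_max = n_dots, bin_cm = 0.05)
  period <- config$dt_s
  n_frames <- round(duration_s / period)
  bout_steps <- round(config$bout_duration_ms / 1000 / period)
  p_bout <- config$bout_rate_hz * period
  theta <- matrix(0, n_frames, n_dots)
  th <- runif(n_dots, -180, 180)
  left <- integer(n_dots)
  dstep <- numeric(n_dots)
  for (f in seq_len(n_frames)) {
    idle <- left == 0
    fire <- idle & (runif(n_dots) < p_bout)
    if (any(fire)) {
      dir <- ifelse(runif(sum(fire)) < 0.5, 1, -1) # CCW / CW
      arc <- config$bout_size_cm / radii[fire] * DEG
      dstep[fire] <- dir * arc / bout_steps
      left[fire] <- bout_steps
    }
    act <- left > 0
    th[act] <- wrap_angle(th[act] + dstep[act])
    left[act] <- left[act] - 1
    theta[f, ] <- th
  }
  rad <- matrix(radii, n_frames, n_dots, byrow = TRUE)
  stimulus_stream(rad * cos(theta / DEG), rad * sin(theta / DEG),
                  matrix(dot_radius_cm, n_frames, n_dots),
                  period_s = period, frame_ref = "focal",
                  protocol = "rotational_rings",
                  params = list(radii_cm = radii,
                                dot_radius_cm = dot_radius_cm))
}

# modal k-th nearest-neighbor distances from wide position matrices
knn_distance_modes <- function(m, k_max, bin_cm = 0.05, frame_stride = 25) {
  frames <- seq(1, nrow(m$X), by = frame_stride)
  n <- ncol(m$X)
  acc <- vector("list", length(frames) * n)
  ii <- 1
  for (f in frames) {
    p <- cbind(m$X[f, ], m$Y[f, ])
    d <- as.matrix(stats::dist(p))
    diag(d) <- Inf
    for (i in seq_len(n)) {
      acc[[ii]] <- sort(d[i, ])[seq_len(k_max)]
      ii <- ii + 1
    }
  }
  dk <- do.call(rbind, acc)
  vapply(seq_len(k_max), function(k) {
    b <- floor(dk[, k] / bin_cm)
    mode_bin <- as.numeric(names(which.max(table(b))))
    (mode_bin + 0.5) * bin_cm
  }, numeric(1))
}

#' Stationary looming-dot stream (looming, not moving)
#'
#' 19 dots in a hexagonal formation (a center dot plus two hexagonal
#' shells), fixed in space, whose radii grow and shrink between `r_min_cm`
#' and `r_max_cm`. The size dynamics follow an explicit grow/shrink/hold
#' Markov schedule with configurable switching rate and growth speed,
#' standing in for resampled recorded angular-size traces.
#'
#' @param n_dots number of dots; 19 fills two hexagonal shells.
#' @param duration_s stream duration.
#' @param r_min_cm,r_max_cm radius bounds (0.075 and 0.9 cm).
#' @param spacing_cm lattice spacing between neighboring dots.
#' @param switch_rate_hz rate of resampling each dot's grow/shrink/hold
#'   state.
#' @param grow_speed_cm_s radius growth/shrink speed.
#' @param config supplies the frame period (`dt_s`).
#' @param seed optional seed.
#' @return a world-frame [stimulus_stream()].
#' @export
looming_hexagon <- function(n_dots = 19, duration_s, r_min_cm = 0.075,
                            r_max_cm = 0.9, spacing_cm = 1.1,
                            switch_rate_hz = 1, grow_speed_cm_s = 0.25,
                            config = vr_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- hex_lattice(n_dots, spacing_cm)
  period <- config$dt_s
  n_frames <- round(duration_s / period)
  R <- matrix(0, n_frames, n_dots)
  r <- runif(n_dots, r_min_cm, r_max_cm)
  state <- sample(c(-1, 0, 1), n_dots, replace = TRUE)
  p_switch <- switch_rate_hz * period
  dr <- grow_speed_cm_s * period
  for (f in seq_len(n_frames)) {
    flip <- runif(n_dots) < p_switch
    if (any(flip)) state[flip] <- sample(c(-1, 0, 1), sum(flip), TRUE)
    r <- pmin(pmax(r + state * dr, r_min_cm), r_max_cm)
    R[f, ] <- r
  }
  X <- matrix(pos$x, n_frames, n_dots, byrow = TRUE)
  Y <- matrix(pos$y, n_frames, n_dots, byrow = TRUE)
  stimulus_stream(X, Y, R, period_s = period, frame_ref = "world",
                  protocol = "looming_hexagon",
                  params = list(r_min_cm = r_min_cm, r_max_cm = r_max_cm,
                                spacing_cm = spacing_cm,
                                switch_rate_hz = switch_rate_hz,
                                grow_speed_cm_s = grow_speed_cm_s))
}

# first n points of a hexagonal lattice, by distance from the center
hex_lattice <- function(n, spacing) {
  q <- rep(-3:3, each = 7)
  r <- rep(-3:3, times = 7)
  keep <- abs(q + r) <= 3
  q <- q[keep]; r <- r[keep]
  x <- spacing * (q + r / 2)
  y <- spacing * r * sqrt(3) / 2
  o <- order(x^2 + y^2)
  if (n > length(o)) stop("too many dots for the lattice")
  list(x = x[o][seq_len(n)], y = y[o][seq_len(n)])
}

#' Single-dot stimulus protocols
#'
#' Trials of 5 s in which one dot moves with fish-like bouts tangentially
#' around the fish from +/-75 deg to +/-30 deg bearing (presentation side
#' random per trial, no inter-trial gap). Variants:
#'
#' * `"moving"`: radius 0.15 cm at distance 0.42 cm — constant angular size
#'   of ~40 deg (translation only);
#' * `"moving_closer"`: radius 0.075 cm, distance shrinking 0.92 to 0.22 cm —
#'   angular size ~9 to ~40 deg;
#' * `"moving_growing"`: distance 0.35 cm, radius growing 0.025 to 0.13 cm —
#'   angular size ~8 to ~41 deg.
#'
#' @param kind `"moving"`, `"moving_closer"` or `"moving_growing"`.
#' @param duration_s total stream duration (whole trials).
#' @param trial_s trial length (5 s).
#' @param bearing_deg start and end bearing magnitudes (75, 30).
#' @param config supplies the frame period and bout kinematics.
#' @param seed optional seed.
#' @return a focal-frame [stimulus_stream()]; the per-trial presentation
#'   side is stored in `params$sides`.
#' @export
single_dot_stream <- function(kind = c("moving", "moving_closer",
                                       "moving_growing"),
                              duration_s, trial_s = 5,
                              bearing_deg = c(75, 30), config = vr_config(),
                              seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  period <- config$dt_s
  nf_trial <- round(trial_s / period)
  n_trials <- max(1, floor(round(duration_s / period) / nf_trial))
  frac <- (seq_len(nf_trial) - 1) / (nf_trial - 1)
  sched <- switch(kind,
    moving = list(d = rep(0.42, nf_trial), r = rep(0.15, nf_trial)),
    moving_closer = list(d = 0.92 + (0.22 - 0.92) * frac,
                         r = rep(0.075, nf_trial)),
    moving_growing = list(d = rep(0.35, nf_trial),
                          r = 0.025 + (0.13 - 0.025) * frac))
  bout_steps <- round(config$bout_duration_ms / 1000 / period)
  p_bout <- config$bout_rate_hz * period
  span <- bearing_deg[1] - bearing_deg[2]
  step_per_bout <- span / (config$bout_rate_hz * trial_s)
  sides <- ifelse(runif(n_trials) < 0.5, 1, -1)
  X <- Y <- R <- matrix(NA_real_, n_trials * nf_trial, 1)
  for (tr in seq_len(n_trials)) {
    mag <- bearing_deg[1]
    left <- 0
    rows <- (tr - 1) * nf_trial + seq_len(nf_trial)
    for (f in seq_len(nf_trial)) {
      if (left == 0 && runif(1) < p_bout) left <- bout_steps
      if (left > 0) {
        mag <- max(bearing_deg[2], mag - step_per_bout / bout_steps)
        left <- left - 1
      }
      b <- sides[tr] * mag / DEG
      X[rows[f], 1] <- sched$d[f] * cos(b)
      Y[rows[f], 1] <- sched$d[f] * sin(b)
      R[rows[f], 1] <- sched$r[f]
    }
  }
  stimulus_stream(X, Y, R, period_s = period, frame_ref = "focal",
                  protocol = paste0("single_dot_", kind),
                  params = list(kind = kind, trial_s = trial_s,
                                bearing_deg = bearing_deg, sides = sides))
}

#' Write / read a stimulus stream as CSV
#'
#' Long format with columns `time_s`, `dot_id`, `x_cm`, `y_cm`, `radius_cm`,
#' `frame_ref`; absent dots are omitted. Round-trips are lossless to well
#' below 1e-6 cm.
#'
#' @param stream a [stimulus_stream()].
#' @param path file path.
#' @return `write_stimulus_csv()` returns `path` invisibly;
#'   `read_stimulus_csv()` returns a `stimulus_stream`.
#' @export
write_stimulus_csv <- function(stream, path) {
  nf <- nrow(stream$X); nd <- ncol(stream$X)
  df <- data.frame(
    time_s = rep((seq_len(nf) - 1) * stream$period_s, times = nd),
    dot_id = rep(seq_len(nd), each = nf),
    x_cm = as.vector(stream$X), y_cm = as.vector(stream$Y),
    radius_cm = as.vector(stream$R),
    frame_ref = stream$frame_ref
  )
  df <- df[!is.nan(df$x_cm), , drop = FALSE]
  write.csv(format(df, digits = 12, scientific = FALSE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @export
read_stimulus_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_s", "dot_id", "x_cm", "y_cm", "radius_cm", "frame_ref")
  if (!all(req %in% names(df))) {
    stop("stimulus CSV must have columns: ", paste(req, collapse = ", "))
  }
  tt <- sort(unique(df$time_s))
  ids <- sort(unique(df$dot_id))
  period <- if (length(tt) > 1) median(diff(tt)) else 1
  X <- Y <- R <- matrix(NaN, length(tt), length(ids))
  fi <- match(df$time_s, tt)
  di <- match(df$dot_id, ids)
  X[cbind(fi, di)] <- df$x_cm
  Y[cbind(fi, di)] <- df$y_cm
  R[cbind(fi, di)] <- df$radius_cm
  stimulus_stream(X, Y, R, period_s = period,
                  frame_ref = df$frame_ref[1], protocol = "from_csv")
}
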