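# Agent dynamics: bout locomotion, wall avoidance and world stepping in
# VR-replay mode (one focal agent plus dot stimuli) and group mode
# (N interacting agents), plus density-switch plumbing.
#
# The per-step loop runs compiled (src/simulate.cpp); the R functions here
# define the world/agent containers, the protocol schedule, and reference
# implementations of the bout primitives used by the test suite to
# cross-check the compiled engine.

#' Initialize agents
#'
#' Places `n` agents uniformly within 0.9 x arena diameter with uniform
#' headings; internal state starts at `config$s0`.
#'
#' @param config a [simulation_config()].
#' @param n number of agents.
#' @return data.frame of agent states (one row per agent).
#' @export
init_agents <- function(config, n) {
  r_max <- 0.9 * config$arena_diameter_cm / 2
  rr <- r_max * sqrt(runif(n))
  th <- runif(n, -pi, pi)
  data.frame(
    x_cm = rr * cos(th), y_cm = rr * sin(th),
    heading_deg = wrap_angle(runif(n, 0, 360)),
    s = config$s0, bout_steps_left = 0, step_dx = 0, step_dy = 0,
    pending = 0, truncated = 0
  )
}

agents_matrix <- function(agents) {
  as.matrix(agents[, c("x_cm", "y_cm", "heading_deg", "s", "bout_steps_left",
                       "step_dx", "step_dy", "pending", "truncated")])
}

matrix_agents <- function(m) {
  out <- as.data.frame(m)
  names(out) <- c("x_cm", "y_cm", "heading_deg", "s", "bout_steps_left",
                  "step_dx", "step_dy", "pending", "truncated")
  out
}

#' Per-step bout decision
#'
#' The bout-decision clock is a Bernoulli process at `bout_rate * dt` per
#' simulation step (0.0328 at defaults), i.e. a discretized Poisson process
#' at the configured bout rate. Decisions arriving while a bout is executing
#' queue the next bout, so the emergent onset rate matches the configured
#' rate and every bout lasts the full configured duration.
#'
#' @param config a [simulation_config()].
#' @param n number of independent step decisions to draw.
#' @return logical vector.
#' @export
decide_bout <- function(config, n = 1) {
  runif(n) < config$bout_rate_hz * config$dt_s
}

#' Wall-avoidance turn probability
#'
#' Logistic in the distance to the nearest wall (body lengths), with
#' half-maximum at `wall_ignore_bl` and steepness `wall_steepness` per body
#' length. Within `wall_ignore_bl` of the wall neighbors are ignored.
#'
#' @param dist_bl distance to the wall in body lengths.
#' @param config a [simulation_config()].
#' @return probability that a bout is a wall-avoidance turn.
#' @export
wall_turn_probability <- function(dist_bl, config) {
  1 / (1 + exp(config$wall_steepness * (dist_bl - config$wall_ignore_bl)))
}

#' Sample turn-angle magnitudes
#'
#' Mixture of turn bouts (`|N(turn_mean, turn_sd)|`, weight `p_turn_bout`)
#' and forward bouts (`|N(0, forward_sd)|`); direction is applied by the
#' policy.
#'
#' @param n number of draws.
#' @param config a [simulation_config()].
#' @return magnitudes in degrees (>= 0).
#' @export
bout_turn_magnitude <- function(n, config) {
  turn <- runif(n) < config$p_turn_bout
  mag <- numeric(n)
  mag[turn] <- abs(rnorm(sum(turn), config$turn_mean_deg, config$turn_sd_deg))
  mag[!turn] <- abs(rnorm(sum(!turn), 0, config$forward_sd_deg))
  mag
}

#' Plan a bout (reference implementation)
#'
#' Chooses turn direction and magnitude for one bout: with probability
#' [wall_turn_probability()] the agent ignores its neighbors and turns away
#' from the nearest wall; otherwise, if it is farther than `wall_ignore_bl`
#' body lengths from the wall, it turns right with probability
#' `clamp(0.5 + a_eff * drive)` where `drive` is the [occupancy_drive()] of
#' the scene; near the wall without a wall turn the direction is random.
#'
#' @param x,y,heading focal pose.
#' @param profile per-object [occupancy_profile()] of the scene.
#' @param a_eff effective slope ([effective_slope()]).
#' @param config a [simulation_config()].
#' @return list with `turn_deg` (signed; negative = right/clockwise),
#'   `wall_turn`, `p_right`, `drive_deg`, `displacement_cm`, `duration_ms`.
#' @export
plan_bout <- function(x, y, heading, profile, a_eff, config) {
  rr <- sqrt(x^2 + y^2)
  dist_bl <- (config$arena_diameter_cm / 2 - rr) / config$fish_length_cm
  drive <- occupancy_drive(profile)
  wall <- runif(1) < wall_turn_probability(dist_bl, config)
  p_right <- 0.5
  if (wall) {
    beta <- if (rr > 0) wrap_angle(atan2(y, x) * DEG - heading) else 0
    sgn <- if (beta > 0) -1 else 1
  } else if (dist_bl < config$wall_ignore_bl) {
    sgn <- if (runif(1) < 0.5) -1 else 1
  } else {
    p_right <- min(1, max(0, 0.5 + a_eff * drive))
    sgn <- if (runif(1) < p_right) -1 else 1
  }
  list(turn_deg = sgn * bout_turn_magnitude(1, config), wall_turn = wall,
       p_right = p_right, drive_deg = drive,
       displacement_cm = config$bout_size_cm,
       duration_ms = config$bout_duration_ms)
}

#' Advance one in-bout displacement step (reference implementation)
#'
#' The heading rotates in full at bout onset; the displacement is spread
#' linearly over the bout duration. A step that would leave the arena disc
#' is truncated at the boundary and the remainder of the bout's displacement
#' is cancelled.
#'
#' @param x,y position (cm).
#' @param step_dx,step_dy per-step displacement (cm).
#' @param arena_radius_cm arena radius.
#' @return list `x`, `y`, `truncated`.
#' @export
execute_bout_step <- function(x, y, step_dx, step_dy, arena_radius_cm) {
  rlim <- arena_radius_cm * (1 - 1e-9)
  nx <- x + step_dx
  ny <- y + step_dy
  if (sqrt(nx^2 + ny^2) < rlim) {
    return(list(x = nx, y = ny, truncated = FALSE))
  }
  aa <- step_dx^2 + step_dy^2
  bb <- 2 * (x * step_dx + y * step_dy)
  cc <- x^2 + y^2 - rlim^2
  disc <- bb^2 - 4 * aa * cc
  if (aa > 0 && disc >= 0) {
    t <- (-bb + sqrt(disc)) / (2 * aa)
    if (t > 0 && t < 1) {
      x <- x + t * step_dx
      y <- y + t * step_dy
    }
  }
  list(x = x, y = y, truncated = TRUE)
}

#' Protocol schedules
#'
#' A protocol is an ordered list of segments. In VR mode each segment
#' presents a [stimulus stream][replay_stream()] (or nothing, for 0
#' neighbors) to the single focal agent; in group mode each segment holds
#' the group at a target agent count, resizing via [resize_group()] at the
#' boundary.
#'
#' @param duration_s segment duration in seconds (> 0).
#' @param stimulus a stimulus stream, or `NULL` for no stimulus.
#' @param n_agents target agent count (group mode).
#' @param label optional segment label carried into outputs.
#' @return `protocol_segment()` returns one segment; `sim_protocol(...)`
#'   collects segments into a protocol.
#' @export
protocol_segment <- function(duration_s, stimulus = NULL, n_agents = NULL,
                             label = NULL) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("segment duration must be > 0")
  }
  structure(list(duration_s = duration_s, stimulus = stimulus,
                 n_agents = n_agents, label = label),
            class = "protocol_segment")
}

#' @rdname protocol_segment
#' @param ... `protocol_segment` objects.
#' @export
sim_protocol <- function(...) {
  segs <- list(...)
  if (length(segs) == 1 && is.list(segs[[1]]) &&
      !inherits(segs[[1]], "protocol_segment")) {
    segs <- segs[[1]]
  }
  stopifnot(length(segs) > 0,
            all(vapply(segs, inherits, TRUE, "protocol_segment")))
  structure(segs, class = "sim_protocol")
}

empty_stim <- function() {
  z <- matrix(numeric(0), nrow = 1, ncol = 0)
  list(X = z, Y = z, R = z, period_s = 1, frame_ref = "world")
}

#' Resize a simulated group mid-session
#'
#' Shrinking removes uniformly sampled agents, leaving the survivors
#' untouched. Growing adds agents at uniform random positions (within 0.9 x
#' arena diameter, the initial-placement rule) and headings, with internal
#' states drawn from a normal distribution whose mean and SD are those of
#' the agents already swimming together (clamped to the state bounds).
#'
#' @param agents agent data.frame (as from [init_agents()]).
#' @param new_n target agent count (>= 1).
#' @param config a [simulation_config()].
#' @return resized agent data.frame.
#' @export
resize_group <- function(agents, new_n, config) {
  n <- nrow(agents)
  stopifnot(new_n >= 1)
  if (new_n == n) return(agents)
  if (new_n < n) {
    keep <- sort(sample.int(n, new_n))
    out <- agents[keep, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  if (n == 0) stop("cannot grow an empty group")
  fresh <- init_agents(config, new_n - n)
  mu <- mean(agents$s)
  sdev <- if (n > 1) sd(agents$s) else 0
  b <- state_bounds(config_integrator(config))
  fresh$s <- pmin(pmax(rnorm(new_n - n, mu, sdev), b[1]), b[2])
  out <- rbind(agents, fresh)
  rownames(out) <- NULL
  out
}

# run one segment through the compiled stepper; returns long-format frames
advance_segment <- function(agents, config, stimulus, duration_s, t0,
                            emit_every) {
  n_steps <- round(duration_s / config$dt_s)
  cfg <- cfg_vector(config)
  if (config$mode == "vr") {
    stim <- if (is.null(stimulus)) empty_stim() else stimulus_matrices(stimulus)
    res <- cpp_simulate_vr(as.numeric(agents_matrix(agents)[1, ]), cfg,
                           stim$X, stim$Y, stim$R,
                           as.integer(stim$frame_ref == "focal"),
                           stim$period_s, n_steps, t0, emit_every)
    traj <- as.data.frame(res$traj)
    traj$agent_id <- 1L
    states <- as.data.frame(res$state)
    states$agent_id <- 1L
    bouts <- as.data.frame(res$bouts)
    list(agents = matrix_agents(matrix(res$final, nrow = 1)),
         traj = traj[, c("time_s", "agent_id", "x_cm", "y_cm", "heading_deg",
                         "bouting")],
         states = states[, c("time_s", "agent_id", "s", "input_deg", "a_eff",
                             "nn_cm")],
         bouts = bouts)
  } else {
    res <- cpp_simulate_group(agents_matrix(agents), cfg, n_steps, t0,
                              emit_every)
    n <- nrow(agents)
    m <- length(res$time_s)
    tt <- rep(res$time_s, times = n)
    id <- rep(seq_len(n), each = m)
    traj <- data.frame(time_s = tt, agent_id = id,
                       x_cm = as.vector(res$x), y_cm = as.vector(res$y),
                       heading_deg = as.vector(res$heading),
                       bouting = as.vector(res$bouting))
    states <- data.frame(time_s = tt, agent_id = id, s = as.vector(res$s),
                         input_deg = as.vector(res$input),
                         a_eff = as.vector(res$a_eff),
                         nn_cm = as.vector(res$nn))
    list(agents = matrix_agents(res$final), traj = traj, states = states,
         bouts = as.data.frame(res$bouts))
  }
}

#' Run a full simulation session
#'
#' Executes a [protocol][sim_protocol()] segment by segment, carrying agent
#' and integrator state across boundaries, and emits trajectories, internal
#' state traces (with looming input, effective slope and nearest-neighbor
#' distance per frame) and the bout log. Given the same seed and
#' configuration the emitted tables are bitwise identical across runs.
#'
#' @param config a [simulation_config()].
#' @param protocol a [sim_protocol()] (a single segment is accepted).
#' @param seed integer seed; drawn at random (and recorded) when `NULL`.
#' @param agents optional starting agents (default: fresh [init_agents()];
#'   one agent in VR mode, the first segment's `n_agents` in group mode).
#' @param emit_every emit every k-th frame to the output tables (the
#'   simulation itself always runs at `1/dt` Hz).
#' @return list of class `sim_run` with elements `trajectories`, `states`,
#'   `bouts`, `segments`, `agents` (final), `config`, `seed`.
#' @export
run_session <- function(config, protocol, seed = NULL, agents = NULL,
                        emit_every = 1L) {
  if (inherits(protocol, "protocol_segment")) protocol <- sim_protocol(protocol)
  stopifnot(inherits(protocol, "sim_protocol"))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  set.seed(seed)
  if (is.null(agents)) {
    n0 <- if (config$mode == "vr") 1L else protocol[[1]]$n_agents
    if (is.null(n0)) stop("group-mode segments need n_agents")
    agents <- init_agents(config, n0)
  }
  clock <- 0
  traj <- list(); states <- list(); bouts <- list(); seginfo <- list()
  for (i in seq_along(protocol)) {
    seg <- protocol[[i]]
    if (config$mode == "group" && !is.null(seg$n_agents) &&
        seg$n_agents != nrow(agents)) {
      agents <- resize_group(agents, seg$n_agents, config)
    }
    res <- advance_segment(agents, config, seg$stimulus, seg$duration_s,
                           clock, emit_every)
    agents <- res$agents
    res$traj$segment <- i
    res$states$segment <- i
    if (nrow(res$bouts) > 0) res$bouts$segment <- i
    traj[[i]] <- res$traj; states[[i]] <- res$states; bouts[[i]] <- res$bouts
    seginfo[[i]] <- data.frame(
      segment = i, start_s = clock, end_s = clock + seg$duration_s,
      label = if (is.null(seg$label)) NA_character_ else seg$label,
      n_agents = nrow(agents),
      n_dots = if (is.null(seg$stimulus)) 0L else ncol(seg$stimulus$X)
    )
    clock <- clock + round(seg$duration_s / config$dt_s) * config$dt_s
  }
  structure(
    list(trajectories = do.call(rbind, traj),
         states = do.call(rbind, states),
         bouts = do.call(rbind, bouts[vapply(bouts, nrow, 0L) > 0]),
         segments = do.call(rbind, seginfo),
         agents = agents, config = config, seed = seed),
    class = "sim_run"
  )
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf(
    "<sim_run> %s mode, %d segment(s), %.1f s, %d emitted frames, %d bouts\n",
    x$config$mode, nrow(x$segments), max(x$segments$end_s),
    nrow(x$trajectories), if (is.null(x$bouts)) 0L else nrow(x$bouts)))
  invisible(x)
}

#' Turning events from a simulation bout log
#'
#' Converts the bout log of a [run_session()] into the event table consumed
#' by [estimate_slope()] / [turn_probability_map()]: the unsigned occupancy
#' difference between the more and less occupied eye, whether the bout
#' turned away from the more occupied eye (turning right means a negative
#' heading change), and the wall distance at onset. Wall-avoidance bouts and
#' bouts with zero binocular drive are dropped.
#'
#' @param bouts the `bouts` table of a `sim_run`.
#' @return data.frame with columns `delta_occupancy_deg`, `turned_away`,
#'   `distance_to_wall_bl`.
#' @export
bout_events <- function(bouts) {
  ev <- bouts[bouts$wall_turn == 0 & bouts$drive_deg != 0, , drop = FALSE]
  data.frame(
    delta_occupancy_deg = abs(ev$drive_deg),
    turned_away = (ev$drive_deg > 0) == (ev$turn_deg < 0),
    distance_to_wall_bl = ev$dist_wall_bl
  )
}
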