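# Trajectory-derived statistics: kinematics, bout detection,
# nearest-neighbor metrics with shuffled controls, turn-probability maps,
# before/after protocol summaries with exponential recovery fits, and the
# standard exclusion filters.

check_uniform_spacing <- function(t_s, tol = 1e-6) {
  d <- diff(t_s)
  if (any(d <= 0)) stop("time must be strictly increasing per animal")
  if (length(d) > 1 && diff(range(d)) > tol * median(d)) {
    stop("irregular frame spacing")
  }
  median(d)
}

#' Kinematics from a trajectory table
#'
#' Central-difference velocities
#' `v(t) = [x(t + dt) - x(t - dt)] / (2 dt)`, speeds and motion directions
#' per animal; the first and last frame of each animal are dropped.
#'
#' @param traj trajectory table (`time_s`, `agent_id`, `x_cm`, `y_cm`, ...).
#' @return data.frame with `time_s`, `agent_id`, `vx_cm_s`, `vy_cm_s`,
#'   `speed_cm_s`, `motion_dir_deg`.
#' @export
kinematics <- function(traj) {
  out <- lapply(split(traj, traj$agent_id), function(a) {
    a <- a[order(a$time_s), , drop = FALSE]
    if (nrow(a) < 3) stop("need at least 3 frames per animal")
    dt <- check_uniform_spacing(a$time_s)
    n <- nrow(a)
    i <- 2:(n - 1)
    vx <- (a$x_cm[i + 1] - a$x_cm[i - 1]) / (2 * dt)
    vy <- (a$y_cm[i + 1] - a$y_cm[i - 1]) / (2 * dt)
    data.frame(time_s = a$time_s[i], agent_id = a$agent_id[i],
               vx_cm_s = vx, vy_cm_s = vy,
               speed_cm_s = sqrt(vx^2 + vy^2),
               motion_dir_deg = ifelse(vx == 0 & vy == 0, NA_real_,
                                       wrap_angle(atan2(vy, vx) * DEG)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detect swim bouts from a trajectory
#'
#' Bouts are maximal intervals where the boxcar-smoothed speed exceeds a
#' threshold; intervals separated by less than the refractory period are
#' merged. The heading change of a bout is the wrapped difference between
#' the headings at offset and onset.
#'
#' @param traj trajectory table with a `heading_deg` column.
#' @param speed_threshold_cm_s speed threshold (0.15 cm/s).
#' @param refractory_s minimal separation between bouts (0.1 s).
#' @param smooth_frames boxcar width in frames (5).
#' @param body_length_cm body length for wall distances (0.4 cm).
#' @param arena_diameter_cm if given, `distance_to_wall_bl` is computed at
#'   bout onset.
#' @return data.frame of class `bout_events_detected`: `agent_id`,
#'   `onset_s`, `offset_s`, `turn_deg`, `distance_to_wall_bl` (NA without
#'   arena metadata), with per-animal bout rates in attribute `rates`.
#' @export
detect_bouts <- function(traj, speed_threshold_cm_s = 0.15,
                         refractory_s = 0.1, smooth_frames = 5,
                         body_length_cm = 0.4, arena_diameter_cm = NULL) {
  kin <- kinematics(traj)
  res <- lapply(split(seq_len(nrow(kin)), kin$agent_id), function(idx) {
    k <- kin[idx, , drop = FALSE]
    a <- traj[traj$agent_id == k$agent_id[1], , drop = FALSE]
    a <- a[order(a$time_s), , drop = FALSE]
    dt <- median(diff(k$time_s))
    sp <- as.numeric(stats::filter(k$speed_cm_s,
                                   rep(1 / smooth_frames, smooth_frames),
                                   sides = 2))
    sp[is.na(sp)] <- k$speed_cm_s[is.na(sp)]
    above <- sp > speed_threshold_cm_s
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    on <- starts[r$values]
    off <- ends[r$values]
    if (length(on) > 1) { # merge bouts separated by < refractory
      gap <- (k$time_s[on[-1]] - k$time_s[off[-length(off)]])
      merged_on <- on[c(TRUE, gap >= refractory_s)]
      merged_off <- off[c(gap >= refractory_s, TRUE)]
      on <- merged_on; off <- merged_off
    }
    if (length(on) == 0) return(NULL)
    h <- a$heading_deg[match(k$time_s, a$time_s)]
    d_wall <- NA_real_
    if (!is.null(arena_diameter_cm)) {
      rr <- sqrt(a$x_cm^2 + a$y_cm^2)[match(k$time_s[on], a$time_s)]
      d_wall <- (arena_diameter_cm / 2 - rr) / body_length_cm
    }
    data.frame(agent_id = k$agent_id[1],
               onset_s = k$time_s[on], offset_s = k$time_s[off],
               turn_deg = wrap_angle(h[off] - h[on]),
               distance_to_wall_bl = d_wall)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(agent_id = numeric(), onset_s = numeric(),
                      offset_s = numeric(), turn_deg = numeric(),
                      distance_to_wall_bl = numeric())
  }
  rownames(out) <- NULL
  span <- diff(range(traj$time_s))
  rates <- vapply(split(out$agent_id, out$agent_id), length, 0L) / span
  structure(out, rates = rates, class = c("bout_events_detected",
                                          "data.frame"))
}

#' Nearest-neighbor distance series
#'
#' Per-frame nearest-neighbor distance for every animal, the group mean per
#' frame, and non-overlapping block means.
#'
#' @param traj trajectory table with >= 2 animals on a complete frame grid.
#' @param block_s block length for averaging (60 s).
#' @return list of class `nn_series`: `per_frame` (`time_s`, `agent_id`,
#'   `nn_cm`), `group` (`time_s`, `nn_cm`), `blocks` (`block_start_s`,
#'   `nn_cm`).
#' @export
nn_series <- function(traj, block_s = 60) {
  m <- traj_to_matrices(traj)
  n <- ncol(m$X)
  if (n < 2) stop("nearest-neighbor distances need at least 2 animals")
  nf <- nrow(m$X)
  nn <- matrix(Inf, nf, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((m$X[, i] - m$X[, j])^2 + (m$Y[, i] - m$Y[, j])^2)
      nn[, i] <- pmin(nn[, i], d)
      nn[, j] <- pmin(nn[, j], d)
    }
  }
  per_frame <- data.frame(time_s = rep(m$time, n),
                          agent_id = rep(m$ids, each = nf),
                          nn_cm = as.vector(nn))
  group <- data.frame(time_s = m$time, nn_cm = rowMeans(nn))
  blk <- floor((m$time - m$time[1]) / block_s)
  blocks <- data.frame(
    block_start_s = m$time[1] + sort(unique(blk)) * block_s,
    nn_cm = as.numeric(tapply(rowMeans(nn), blk, mean))
  )
  structure(list(per_frame = per_frame, group = group, blocks = blocks),
            class = "nn_series")
}

#' Shuffled-control nearest-neighbor baseline
#'
#' Builds randomized pseudo-groups by mixing animals from separately
#' recorded groups and circularly shifting their time signatures, which
#' destroys interactions while preserving each animal's individual motion
#' statistics. Where composite groups need more animals than there are
#' source groups, animals from the same group are reused with shuffled
#' time.
#'
#' @param tables list of trajectory tables (>= 2 groups), all on the same
#'   frame grid.
#' @param group_size animals per pseudo-group.
#' @param n_shuffles number of pseudo-groups to build (> 0).
#' @param seed optional seed.
#' @return data.frame with one row per shuffle: `shuffle`, `nn_cm` (mean
#'   nearest-neighbor distance of the pseudo-group).
#' @export
shuffled_control <- function(tables, group_size, n_shuffles = 20,
                             seed = NULL) {
  if (n_shuffles <= 0) stop("n_shuffles must be > 0")
  if (length(tables) < 2) stop("need at least 2 source groups")
  if (!is.null(seed)) set.seed(seed)
  pool <- do.call(rbind, lapply(seq_along(tables), function(g) {
    tb <- tables[[g]]
    data.frame(group = g, animal = unique(tb$agent_id))
  }))
  if (nrow(pool) < group_size) stop("not enough animals across groups")
  res <- vapply(seq_len(n_shuffles), function(k) {
    # prefer one animal per distinct source group
    ord <- sample.int(nrow(pool))
    first <- ord[!duplicated(pool$group[ord])]
    pick <- head(c(first, setdiff(ord, first)), group_size)
    # animals reused from an already-represented group get their time
    # signature circularly shifted (the 20-fish rule)
    shift_needed <- duplicated(pool$group[pick])
    parts <- lapply(seq_along(pick), function(i) {
      row <- pool[pick[i], ]
      tb <- tables[[row$group]]
      a <- tb[tb$agent_id == row$animal, , drop = FALSE]
      a <- a[order(a$time_s), , drop = FALSE]
      if (shift_needed[i]) {
        off <- sample.int(nrow(a), 1)
        a$x_cm <- a$x_cm[c(off:nrow(a), seq_len(off - 1))]
        a$y_cm <- a$y_cm[c(off:nrow(a), seq_len(off - 1))]
      }
      a$agent_id <- i
      a
    })
    ns <- nn_series(do.call(rbind, parts), block_s = Inf)
    mean(ns$group$nn_cm)
  }, numeric(1))
  data.frame(shuffle = seq_len(n_shuffles), nn_cm = res)
}

#' Turn-probability map against binocular occupancy difference
#'
#' Bins turning events by the occupancy difference between the more and the
#' less occupied eye (5 deg bins at low density, 10 deg at high), after
#' discarding events closer than 1.25 body lengths to the wall, and fits
#' the response slope through [estimate_slope()].
#'
#' @param events event table as produced by [bout_events()] (columns
#'   `delta_occupancy_deg`, `turned_away`, `distance_to_wall_bl`).
#' @param bin_width_deg bin width in degrees.
#' @param wall_exclude_bl wall exclusion radius in body lengths (1.25).
#' @return a `response_fit` (see [estimate_slope()]).
#' @export
turn_probability_map <- function(events, bin_width_deg = 5,
                                 wall_exclude_bl = 1.25) {
  estimate_slope(events, bin_width_deg = bin_width_deg,
                 wall_exclude_bl = wall_exclude_bl)
}

#' Before/after protocol summary
#'
#' The change in nearest-neighbor distance between two labeled protocol
#' phases: `mean(after) - mean(before)`.
#'
#' @param nn_before,nn_after numeric vectors of nearest-neighbor distances
#'   (per frame or per block).
#' @return list with `nn_before`, `nn_after`, `delta_nn`.
#' @export
protocol_summary <- function(nn_before, nn_after) {
  list(nn_before = mean(nn_before), nn_after = mean(nn_after),
       delta_nn = mean(nn_after) - mean(nn_before))
}

#' Exponential recovery fit
#'
#' Least-squares fit of `N(t) = N_inf + (N0 - N_inf) exp(-t / lambda)` to a
#' block-mean recovery series, reporting the time constant, the coefficient
#' of determination, and the time to baseline: the first observation whose
#' value lies within a +/-`band` fraction of `baseline`, plus the
#' continuous time at which the fitted curve enters that band
#' (`t_cross_min`).
#'
#' @param t_min times of the series (minutes).
#' @param value series values (e.g. block-mean NN in cm).
#' @param baseline reference baseline value.
#' @param band tolerance band around baseline (fraction, 0.05).
#' @return list of class `recovery_fit`: `lambda_min`, `r_squared`,
#'   `n_inf`, `n0`, `t_baseline_min` (first observed time in band, NA if
#'   never), `t_cross_min` (fitted crossing, 0 if the fit starts in band),
#'   `fitted`.
#' @export
fit_recovery <- function(t_min, value, baseline, band = 0.05) {
  if (length(t_min) < 4) stop("recovery fit needs at least 4 blocks")
  o <- order(t_min)
  t_min <- t_min[o]; value <- value[o]
  n_inf0 <- value[length(value)]
  n00 <- value[1]
  lam0 <- max(diff(range(t_min)) / 3, 1e-3)
  fit <- minpack.lm::nlsLM(
    value ~ n_inf + (n0 - n_inf) * exp(-t_min / lambda),
    start = list(n_inf = n_inf0, n0 = n00, lambda = lam0),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- coef(fit)
  pred <- predict(fit)
  ss_res <- sum((value - pred)^2)
  ss_tot <- sum((value - mean(value))^2)
  r2 <- 1 - ss_res / ss_tot
  lo <- baseline * (1 - band)
  hi <- baseline * (1 + band)
  in_band <- value >= lo & value <= hi
  t_obs <- if (any(in_band)) t_min[which(in_band)[1]] else NA_real_
  f <- function(t) cf[["n_inf"]] + (cf[["n0"]] - cf[["n_inf"]]) *
    exp(-t / cf[["lambda"]])
  tg <- seq(min(t_min), max(t_min), length.out = 2000)
  fin <- f(tg) >= lo & f(tg) <= hi
  t_cross <- if (any(fin)) tg[which(fin)[1]] else NA_real_
  structure(list(lambda_min = cf[["lambda"]], r_squared = r2,
                 n_inf = cf[["n_inf"]], n0 = cf[["n0"]],
                 t_baseline_min = t_obs, t_cross_min = t_cross,
                 fitted = data.frame(t_min = t_min, value = value,
                                     fitted = pred)),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf(
    "<recovery_fit> lambda = %.1f min, R2 = %.3f, baseline reached at %.1f min\n",
    x$lambda_min, x$r_squared,
    if (is.na(x$t_cross_min)) NA else x$t_cross_min))
  invisible(x)
}

#' Standard exclusion filters
#'
#' Group mode drops whole groups in which any animal was immobile for more
#' than half of the recording; single-animal mode drops animals with bout
#' rates below 0.25 Hz.
#'
#' @param stats data.frame with columns `group_id`, `animal_id`,
#'   `bout_rate_hz`, `immobile_frac`.
#' @param mode `"group"` or `"single"`.
#' @param immobile_max maximal tolerated immobile fraction (0.5).
#' @param min_bout_rate_hz minimal bout rate (0.25 Hz).
#' @return list with `retained` (subset of `stats`) and `excluded`
#'   (`stats` rows plus a `reason` column).
#' @export
apply_filters <- function(stats, mode = c("group", "single"),
                          immobile_max = 0.5, min_bout_rate_hz = 0.25) {
  mode <- match.arg(mode)
  if (mode == "group") {
    bad_groups <- unique(stats$group_id[stats$immobile_frac > immobile_max])
    drop <- stats$group_id %in% bad_groups
    reason <- sprintf("group %s: an animal immobile > %d%% of frames",
                      stats$group_id[drop], round(100 * immobile_max))
  } else {
    drop <- stats$bout_rate_hz < min_bout_rate_hz
    reason <- sprintf("bout rate %.2f Hz < %.2f Hz",
                      stats$bout_rate_hz[drop], min_bout_rate_hz)
  }
  excluded <- stats[drop, , drop = FALSE]
  if (nrow(excluded) > 0) excluded$reason <- reason
  list(retained = stats[!drop, , drop = FALSE], excluded = excluded)
}

#' Block-averaged responses to the single-dot stimulus
#'
#' Per trial, the probability to turn away from the presented side among
#' left/right turns; trials without any turn are skipped and logged.
#' Trial probabilities are averaged over consecutive blocks of
#' `block_trials` trials (incomplete trailing blocks are dropped and
#' logged).
#'
#' @param trials data.frame with columns `trial`, `side` (+1 = left
#'   presentation, -1 = right), `n_left`, `n_right` (turn counts during the
#'   trial).
#' @param block_trials trials per block (60).
#' @return data.frame (`block`, `n_trials`, `p_away`) with attribute
#'   `skipped` (trial ids without turns) and `remainder` (trials beyond the
#'   last full block).
#' @export
single_dot_blocks <- function(trials, block_trials = 60) {
  turns <- trials$n_left + trials$n_right
  skipped <- trials$trial[turns == 0]
  tr <- trials[turns > 0, , drop = FALSE]
  away <- ifelse(tr$side > 0, tr$n_right, tr$n_left)
  p_away <- away / (tr$n_left + tr$n_right)
  blk <- floor((seq_len(nrow(tr)) - 1) / block_trials)
  full <- blk < floor(nrow(tr) / block_trials)
  remainder <- tr$trial[!full]
  out <- data.frame(
    block = sort(unique(blk[full])) + 1,
    n_trials = as.integer(table(blk[full])),
    p_away = as.numeric(tapply(p_away[full], blk[full], mean))
  )
  attr(out, "skipped") <- skipped
  attr(out, "remainder") <- remainder
  out
}

#' Block means of an arbitrary frame series
#'
#' @param t_s frame times.
#' @param x values.
#' @param block_s block length in seconds.
#' @return data.frame (`block_start_s`, `mean`).
#' @export
block_means <- function(t_s, x, block_s = 60) {
  blk <- floor((t_s - t_s[1]) / block_s)
  data.frame(block_start_s = t_s[1] + sort(unique(blk)) * block_s,
             mean = as.numeric(tapply(x, blk, mean)))
}
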