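# Canned experiment protocols: the density-switch, recovery, stationary
# control and group split/merge designs, run over seeded repetitions.
# These orchestrate run_session() and the stimulus generators and return
# tidy per-repetition summaries.

#' Derive per-repetition seeds from a master seed
#'
#' Draws `n` integer seeds from the RNG seeded with `master`, so a whole
#' repetition battery is reproducible from one number.
#'
#' @param master master seed.
#' @param n number of repetitions.
#' @return integer vector of length `n`.
#' @export
rep_seeds <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1, n)
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * k) %% (.Machine$integer.max - 1)) + 1L
}

# mean nearest-neighbor distance in one protocol segment, discarding the
# first settle_s seconds
segment_nn <- function(run, segment, settle_s = 60) {
  st <- run$states[run$states$segment == segment, , drop = FALSE]
  t0 <- run$segments$start_s[segment]
  mean(st$nn_cm[st$time_s >= t0 + settle_s], na.rm = TRUE)
}

#' Run a single free-swimming agent
#'
#' One agent, no stimulus: the null condition used to measure emergent bout
#' statistics.
#'
#' @param duration_s simulated time.
#' @param config a [simulation_config()].
#' @param seed seed.
#' @param emit_every output thinning (see [run_session()]).
#' @return a `sim_run`.
#' @export
run_free_agent <- function(duration_s, config = vr_config(), seed = NULL,
                           emit_every = 1L) {
  run_session(config, protocol_segment(duration_s, label = "free"),
              seed = seed, emit_every = emit_every)
}

# surrogate replay streams for a given neighbor count, built from a fresh
# surrogate group simulated with the group parameter set
surrogate_stream <- function(n_dots, duration_s, config, seed = NULL) {
  src <- surrogate_trajectories(n_dots, duration_s,
                                config = group_config(dt_s = config$dt_s),
                                seed = seed)
  replay_stream(src)
}

#' Density-switch session for one focal agent
#'
#' Baseline at low density, exposure to high density, an optional
#' zero-neighbor phase, then a low-density probe: the core design used to
#' characterize experience-dependent modulation.
#'
#' @param config a [simulation_config()] (VR mode).
#' @param low_stream,high_stream stimulus streams for the two densities.
#' @param baseline_min,high_min,zero_min,probe_min phase durations in
#'   minutes (`zero_min = 0` skips the zero-neighbor phase;
#'   `high_min = 0` skips the exposure).
#' @param seed seed.
#' @param emit_every output thinning.
#' @return a `sim_run`; segments are labeled `baseline`, `high`, `zero`,
#'   `probe`.
#' @export
run_density_switch <- function(config, low_stream, high_stream,
                               baseline_min = 10, high_min = 20,
                               zero_min = 0, probe_min = 10, seed = NULL,
                               emit_every = 5L) {
  segs <- list(protocol_segment(baseline_min * 60, low_stream,
                                label = "baseline"))
  if (high_min > 0) {
    segs <- c(segs, list(protocol_segment(high_min * 60, high_stream,
                                          label = "high")))
  }
  if (zero_min > 0) {
    segs <- c(segs, list(protocol_segment(zero_min * 60, NULL,
                                          label = "zero")))
  }
  segs <- c(segs, list(protocol_segment(probe_min * 60, low_stream,
                                        label = "probe")))
  run_session(config, sim_protocol(segs), seed = seed,
              emit_every = emit_every)
}

#' Recovery after high-density exposure
#'
#' For each repetition and each zero-neighbor duration: baseline at low
#' density, 20 min of high density, `zero_min` minutes with no stimulus,
#' then a low-density probe. The probe nearest-neighbor distance as a
#' function of the zero-neighbor time forms the recovery series that is
#' fitted with a single exponential by [recovery_summary()].
#'
#' @param n_rep repetitions (24).
#' @param zero_minutes zero-neighbor durations (minutes).
#' @param baseline_min,high_min,probe_min phase durations (minutes).
#' @param n_low,n_high virtual neighbor counts (4 and 19).
#' @param config a [simulation_config()] (VR mode).
#' @param seed master seed.
#' @param settle_s discarded at the start of measured phases.
#' @return data.frame (`rep`, `zero_min`, `baseline_nn`, `probe_nn`).
#' @export
run_recovery_experiment <- function(n_rep = 24, zero_minutes = seq(0, 80, 10),
                                    baseline_min = 10, high_min = 20,
                                    probe_min = 10, n_low = 4, n_high = 19,
                                    config = vr_config(), seed = 1,
                                    settle_s = 60) {
  seeds <- rep_seeds(seed, n_rep)
  out <- list()
  for (rep in seq_len(n_rep)) {
    low <- surrogate_stream(n_low, 1200, config, seed = seeds[rep])
    high <- surrogate_stream(n_high, 1200, config,
                             seed = derive_seed(seeds[rep], 1))
    for (ti in seq_along(zero_minutes)) {
      zm <- zero_minutes[ti]
      run <- run_density_switch(config, low, high,
                                baseline_min = baseline_min,
                                high_min = high_min, zero_min = zm,
                                probe_min = probe_min,
                                seed = derive_seed(seeds[rep], 10 + ti))
      probe_seg <- nrow(run$segments)
      out[[length(out) + 1]] <- data.frame(
        rep = rep, zero_min = zm,
        baseline_nn = segment_nn(run, 1, settle_s),
        probe_nn = segment_nn(run, probe_seg, settle_s)
      )
    }
  }
  do.call(rbind, out)
}

#' Summarize a recovery experiment
#'
#' Averages the probe series over repetitions and fits the exponential
#' recovery model against the mean pre-exposure baseline.
#'
#' @param df output of [run_recovery_experiment()].
#' @param band baseline tolerance band (fraction, 0.05).
#' @return list: `series` (mean probe NN per zero-neighbor time),
#'   `baseline_nn`, and `fit` (a [fit_recovery()] result).
#' @export
recovery_summary <- function(df, band = 0.05) {
  tm <- sort(unique(df$zero_min))
  series <- vapply(tm, function(z) mean(df$probe_nn[df$zero_min == z]),
                   numeric(1))
  baseline <- mean(df$baseline_nn)
  list(series = data.frame(zero_min = tm, probe_nn = series),
       baseline_nn = baseline,
       fit = fit_recovery(tm, series, baseline, band = band))
}

#' Effect of exposure time to high density
#'
#' Baseline at low density, `exposure_min` minutes of high density (a 5-min
#' high-density segment looped, so all exposure durations present the same
#' material), then a low-density probe.
#'
#' @param n_rep repetitions.
#' @param exposure_minutes exposure durations (minutes).
#' @inheritParams run_recovery_experiment
#' @return data.frame (`rep`, `exposure_min`, `baseline_nn`, `probe_nn`,
#'   `delta_nn`).
#' @export
run_exposure_experiment <- function(n_rep = 24,
                                    exposure_minutes = c(5, 10, 20, 40),
                                    baseline_min = 10, probe_min = 10,
                                    n_low = 4, n_high = 19,
                                    config = vr_config(), seed = 1,
                                    settle_s = 60) {
  seeds <- rep_seeds(seed, n_rep)
  out <- list()
  for (rep in seq_len(n_rep)) {
    low <- surrogate_stream(n_low, 1200, config, seed = seeds[rep])
    high <- surrogate_stream(n_high, 300, config,
                             seed = derive_seed(seeds[rep], 1))
    for (ei in seq_along(exposure_minutes)) {
      em <- exposure_minutes[ei]
      run <- run_density_switch(config, low, high,
                                baseline_min = baseline_min, high_min = em,
                                zero_min = 0, probe_min = probe_min,
                                seed = derive_seed(seeds[rep], 20 + ei))
      b <- segment_nn(run, 1, settle_s)
      p <- segment_nn(run, nrow(run$segments), settle_s)
      out[[length(out) + 1]] <- data.frame(
        rep = rep, exposure_min = em, baseline_nn = b, probe_nn = p,
        delta_nn = p - b
      )
    }
  }
  do.call(rbind, out)
}

#' Stationary-dot control
#'
#' As [run_exposure_experiment()] but the exposure presents a single frozen
#' frame of high-density neighbors. Under neighbor-induced looming this
#' stimulus generates no integrator input, so no modulation is expected.
#'
#' @inheritParams run_exposure_experiment
#' @param exposure_min exposure duration (minutes).
#' @return data.frame (`rep`, `baseline_nn`, `probe_nn`, `delta_nn`).
#' @export
run_stationary_experiment <- function(n_rep = 24, exposure_min = 20,
                                      baseline_min = 10, probe_min = 10,
                                      n_low = 4, n_high = 19,
                                      config = vr_config(), seed = 1,
                                      settle_s = 60) {
  seeds <- rep_seeds(seed, n_rep)
  out <- list()
  for (rep in seq_len(n_rep)) {
    low <- surrogate_stream(n_low, 1200, config, seed = seeds[rep])
    src <- surrogate_trajectories(n_high, 300,
                                  config = group_config(dt_s = config$dt_s),
                                  seed = derive_seed(seeds[rep], 1))
    frozen <- stationary_frame_stream(src)
    run <- run_density_switch(config, low, frozen,
                              baseline_min = baseline_min,
                              high_min = exposure_min, zero_min = 0,
                              probe_min = probe_min,
                              seed = derive_seed(seeds[rep], 30))
    b <- segment_nn(run, 1, settle_s)
    p <- segment_nn(run, nrow(run$segments), settle_s)
    out[[rep]] <- data.frame(rep = rep, baseline_nn = b, probe_nn = p,
                             delta_nn = p - b)
  }
  do.call(rbind, out)
}

#' Group split / merge experiment
#'
#' Groups of interacting agents acclimated at one density and then
#' resized to the other, against same-density controls:
#' `ctrl_low` (low throughout), `high_to_low` (high, then split to low),
#' `ctrl_high` (high throughout), `low_to_high` (low, then merged to high).
#'
#' @param n_rep repetitions.
#' @param n_low,n_high group sizes (5 and 20).
#' @param acclimate_min,measure_min phase durations (minutes).
#' @param config a [simulation_config()] (group mode; the group parameter
#'   set with `D = 0.1` matches the stronger responses of this design).
#' @param seed master seed.
#' @param settle_s discarded at the start of the measured phase.
#' @return data.frame (`rep`, `condition`, `nn_cm`).
#' @export
run_split_merge_experiment <- function(n_rep = 24, n_low = 5, n_high = 20,
                                       acclimate_min = 30, measure_min = 20,
                                       config = group_config(D = 0.1),
                                       seed = 1, settle_s = 60) {
  seeds <- rep_seeds(seed, n_rep)
  conds <- list(
    ctrl_low = c(n_low, n_low), high_to_low = c(n_high, n_low),
    ctrl_high = c(n_high, n_high), low_to_high = c(n_low, n_high)
  )
  out <- list()
  for (rep in seq_len(n_rep)) {
    for (ci in seq_along(conds)) {
      nn <- conds[[ci]]
      prot <- sim_protocol(
        protocol_segment(acclimate_min * 60, n_agents = nn[1],
                         label = "acclimate"),
        protocol_segment(measure_min * 60, n_agents = nn[2],
                         label = "measure")
      )
      run <- run_session(config, prot, seed = derive_seed(seeds[rep], ci),
                         emit_every = 5L)
      out[[length(out) + 1]] <- data.frame(
        rep = rep, condition = names(conds)[ci],
        nn_cm = segment_nn(run, 2, settle_s)
      )
    }
  }
  do.call(rbind, out)
}

#' Trial log from a single-dot session
#'
#' Assembles the per-trial turn counts consumed by [single_dot_blocks()]
#' from a simulation run driven by a [single_dot_stream()].
#'
#' @param run a `sim_run` whose stimulus was a single-dot stream.
#' @param stream the [single_dot_stream()] that was presented.
#' @return data.frame (`trial`, `side`, `n_left`, `n_right`).
#' @export
single_dot_trials <- function(run, stream) {
  trial_s <- stream$params$trial_s
  sides <- stream$params$sides
  n_trials <- length(sides)
  b <- run$bouts
  trial <- floor(b$onset_s / trial_s) %% n_trials + 1
  do.call(rbind, lapply(seq_len(n_trials), function(tr) {
    tb <- b[trial == tr, , drop = FALSE]
    data.frame(trial = tr, side = sides[tr],
               n_left = sum(tb$turn_deg > 0), n_right = sum(tb$turn_deg < 0))
  }))
}
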