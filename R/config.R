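# Simulation configuration: the model parameter set plus run options.
# Defaults are the values used for the single-agent virtual-reality
# simulations; group_config() switches to the interacting-group parameter
# set (weaker slope, lower fish height).

#' Simulation configuration
#'
#' All model parameters plus run options. The two stock parameter sets are
#' exposed as [vr_config()] (single agent responding to projected dots:
#' `a = 0.0104`, fish height 0.4 cm) and [group_config()] (interacting
#' agents: `a = 0.00372`, fish height 0.2 cm).
#'
#' @param arena_diameter_cm arena diameter (6.5 cm).
#' @param dt_s simulation time step (1/50 s).
#' @param fish_length_cm body length, used for wall distances (0.4 cm).
#' @param fish_height_cm vertical half-extent used when agents view each
#'   other (0.4 cm in VR parameter set, 0.2 cm in the group set).
#' @param bout_rate_hz mean bout rate (1.64 Hz).
#' @param bout_size_cm displacement per bout (0.1 cm).
#' @param bout_duration_ms bout duration (320 ms).
#' @param a slope of the occupancy response `p(turn right | v) = a v + 0.5`.
#' @param tau_hr,r,s_rest,s_start,D integrator parameters, see
#'   [integrator_params()].
#' @param looming_mode `"neighbor_induced"` (self-motion through a static
#'   scene generates no loom; the default) or `"raw"`.
#' @param per_second_input if `TRUE`, looming input is normalized to degrees
#'   per second instead of degrees per step before scaling by `r`.
#' @param blind_zone_deg total blind angle behind the fish (30 deg).
#' @param wall_ignore_bl wall distance (body lengths) below which neighbors
#'   are ignored, and the half-max point of the wall-avoidance probability
#'   (1.25 BL).
#' @param wall_steepness logistic steepness of the wall-avoidance
#'   probability, per body length (4).
#' @param p_turn_bout,turn_mean_deg,turn_sd_deg,forward_sd_deg turn-angle
#'   magnitude distribution: a mixture of turn bouts
#'   (`|N(turn_mean, turn_sd)|`, weight `p_turn_bout`) and forward bouts
#'   (`|N(0, forward_sd)|`); the direction sign comes from the policy.
#' @param s0 initial internal state (defaults to `s_start`).
#' @param mode `"vr"` or `"group"`.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(arena_diameter_cm = 6.5, dt_s = 1 / 50,
                              fish_length_cm = 0.4, fish_height_cm = 0.4,
                              bout_rate_hz = 1.64, bout_size_cm = 0.1,
                              bout_duration_ms = 320, a = 0.0104,
                              tau_hr = 6, r = 13, s_rest = 0, s_start = 0.6,
                              D = 0.19,
                              looming_mode = c("neighbor_induced", "raw"),
                              per_second_input = FALSE, blind_zone_deg = 30,
                              wall_ignore_bl = 1.25, wall_steepness = 4,
                              p_turn_bout = 0.5, turn_mean_deg = 35,
                              turn_sd_deg = 15, forward_sd_deg = 10,
                              s0 = s_start, mode = c("vr", "group")) {
  looming_mode <- match.arg(looming_mode)
  mode <- match.arg(mode)
  stopifnot(arena_diameter_cm > 0, dt_s > 0, fish_length_cm > 0,
            fish_height_cm > 0, bout_rate_hz >= 0, bout_size_cm >= 0,
            bout_duration_ms > 0, a >= 0, tau_hr > 0, D > 0,
            bout_rate_hz * dt_s < 1)
  cfg <- list(
    arena_diameter_cm = arena_diameter_cm, dt_s = dt_s,
    fish_length_cm = fish_length_cm, fish_height_cm = fish_height_cm,
    bout_rate_hz = bout_rate_hz, bout_size_cm = bout_size_cm,
    bout_duration_ms = bout_duration_ms, a = a, tau_hr = tau_hr, r = r,
    s_rest = s_rest, s_start = s_start, D = D, looming_mode = looming_mode,
    per_second_input = per_second_input, blind_zone_deg = blind_zone_deg,
    wall_ignore_bl = wall_ignore_bl, wall_steepness = wall_steepness,
    p_turn_bout = p_turn_bout, turn_mean_deg = turn_mean_deg,
    turn_sd_deg = turn_sd_deg, forward_sd_deg = forward_sd_deg,
    s0 = s0, mode = mode
  )
  structure(cfg, class = "sim_config")
}

#' @rdname simulation_config
#' @param ... overrides passed on to [simulation_config()].
#' @export
vr_config <- function(...) {
  args <- list(...)
  base <- list(a = 0.0104, fish_height_cm = 0.4, mode = "vr")
  do.call(simulation_config, utils::modifyList(base, args))
}

#' @rdname simulation_config
#' @export
group_config <- function(...) {
  args <- list(...)
  base <- list(a = 0.00372, fish_height_cm = 0.2, mode = "group")
  do.call(simulation_config, utils::modifyList(base, args))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s mode: arena %.1f cm, dt %.3f s, a = %g/deg,\n",
    x$mode, x$arena_diameter_cm, x$dt_s, x$a))
  cat(sprintf(
    "  bouts %.2f Hz x %.0f ms x %.2f cm; integrator tau = %g h, r = %g,\n",
    x$bout_rate_hz, x$bout_duration_ms, x$bout_size_cm, x$tau_hr, x$r))
  cat(sprintf("  s_rest = %g, s_start = %g, D = %g, looming %s\n",
              x$s_rest, x$s_start, x$D, x$looming_mode))
  invisible(x)
}

#' Integrator parameters of a configuration
#'
#' @param config a [simulation_config()].
#' @return the embedded [integrator_params()].
#' @export
config_integrator <- function(config) {
  integrator_params(config$tau_hr, config$r, config$s_rest,
                    config$s_start, config$D)
}

# numeric vector handed to the compiled stepper; order must match
# the CfgIdx enum in src/simulate.cpp
cfg_vector <- function(config) {
  bout_steps <- round(config$bout_duration_ms / 1000 / config$dt_s)
  c(config$dt_s, config$arena_diameter_cm / 2, config$fish_length_cm,
    config$bout_rate_hz, config$bout_size_cm, bout_steps, config$a,
    config$tau_hr * 3600, config$r, config$s_rest, config$s_start, config$D,
    if (config$looming_mode == "raw") 1 else 0,
    180 - config$blind_zone_deg / 2, config$wall_ignore_bl,
    config$wall_steepness, config$p_turn_bout, config$turn_mean_deg,
    config$turn_sd_deg, config$forward_sd_deg,
    if (isTRUE(config$per_second_input)) 1 else 0, config$fish_height_cm)
}

#' Read / write a configuration file
#'
#' Configurations are stored as YAML with the field names of
#' [simulation_config()].
#'
#' @param path file path.
#' @param config a [simulation_config()].
#' @return [read_config()] returns a `sim_config`;
#'   [write_config()] returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  }
  do.call(simulation_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
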