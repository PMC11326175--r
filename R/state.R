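# Leaky integrator of looming events and its coupling to the turning slope.
#
#   tau * ds/dt = s_rest - s(t) + r * Input(t)
#
# Input(t) is the maximal per-step increase in retinal occupancy of any
# neighbor (degrees per simulation step of 1/50 s by default); tau is very
# slow (~6 h), so over experimental time scales the integrator operates in
# its initial, approximately linear, domain. The state is clamped to
# [s_rest, s_start + D], which keeps the effective turning slope
# non-negative and never above a_base * (1 + s_start / D).

#' Integrator parameters
#'
#' @param tau_hr leak time constant in hours (6).
#' @param r dimensionless input scale (13), calibrated for per-step looming
#'   input in degrees at a 1/50 s time step.
#' @param s_rest resting value the state relaxes to without input (0).
#' @param s_start starting value of the integrator; the steady operating
#'   value for unperturbed low-density groups (0.6).
#' @param D scale linking the state to the turning slope (0.19; 0.1 for the
#'   group split/merge simulations).
#' @return list of class `integrator_params`.
#' @export
integrator_params <- function(tau_hr = 6, r = 13, s_rest = 0,
                              s_start = 0.6, D = 0.19) {
  stopifnot(tau_hr > 0, D > 0)
  structure(list(tau_hr = tau_hr, tau_s = tau_hr * 3600, r = r,
                 s_rest = s_rest, s_start = s_start, D = D),
            class = "integrator_params")
}

state_bounds <- function(params) {
  c(params$s_rest, params$s_start + params$D)
}

#' One forward-Euler step of the internal-state integrator
#'
#' `s <- s + (dt / tau) * (s_rest - s + r * input)`, then clamped to
#' `[s_rest, s_start + D]`. Deterministic; requires `dt` much smaller than
#' `tau` (errors when `dt >= tau`).
#'
#' @param s current state value(s).
#' @param input looming input in degrees per step (>= 0); either a scalar or
#'   a vector matching `s`.
#' @param dt time step in seconds.
#' @param params an [integrator_params()].
#' @return updated state value(s).
#' @export
step_integrator <- function(s, input, dt, params) {
  stopifnot(dt > 0)
  if (dt >= params$tau_s) {
    stop("dt >= tau: forward-Euler discretization is unstable")
  }
  s <- s + (dt / params$tau_s) * (params$s_rest - s + params$r * input)
  b <- state_bounds(params)
  pmin(pmax(s, b[1]), b[2])
}

#' Closed-form state trajectory under constant input
#'
#' Exact solution of the integrator ODE for a constant input `I`:
#' `s(t) = s_eq + (s0 - s_eq) * exp(-t / tau)` with
#' `s_eq = s_rest + r * I`. Used as the oracle the Euler stepper is checked
#' against; no clamping is applied.
#'
#' @param s0 initial state.
#' @param elapsed_s elapsed time in seconds (vectorized).
#' @param input constant input (degrees per step).
#' @param params an [integrator_params()].
#' @return state value(s) at `elapsed_s`.
#' @export
analytic_state <- function(s0, elapsed_s, input, params) {
  s_eq <- params$s_rest + params$r * input
  s_eq + (s0 - s_eq) * exp(-elapsed_s / params$tau_s)
}

#' Integrate a whole input series
#'
#' Runs [step_integrator()] over a vector of per-step inputs (compiled
#' loop), returning the state after every step.
#'
#' @param s0 initial state.
#' @param inputs per-step looming inputs (degrees per step).
#' @param dt time step in seconds.
#' @param params an [integrator_params()].
#' @return numeric vector of states, same length as `inputs`.
#' @export
run_integrator <- function(s0, inputs, dt, params) {
  stopifnot(dt > 0)
  if (dt >= params$tau_s) {
    stop("dt >= tau: forward-Euler discretization is unstable")
  }
  b <- state_bounds(params)
  cpp_integrate(s0, as.numeric(inputs), dt, params$tau_s, params$s_rest,
                params$r, b[1], b[2])
}

#' Effective turning slope at a given internal state
#'
#' `a' = a_base * (1 - (s - s_start) / D)`, floored at 0: at `s = s_start`
#' the response is unmodulated, at `s = s_start + D` it is fully suppressed.
#'
#' @param a_base baseline slope (probability per degree, >= 0).
#' @param s internal state value(s).
#' @param params an [integrator_params()].
#' @return effective slope(s), >= 0.
#' @export
effective_slope <- function(a_base, s, params) {
  stopifnot(a_base >= 0)
  pmax(0, a_base * (1 - (s - params$s_start) / params$D))
}

#' Fit a decay time constant to a zero-input state trace
#'
#' Least-squares fit of `s(t) = s0 * exp(-t / lambda)` to a decaying state
#' trace via linear regression on `log(s)` (valid for `s_rest = 0` traces).
#'
#' @param t_s time in seconds.
#' @param s state values (> 0).
#' @return fitted `lambda` in hours.
#' @export
fit_decay_tau <- function(t_s, s) {
  keep <- s > 0
  if (sum(keep) < 3) stop("need at least 3 positive state values")
  fit <- lm(log(s[keep]) ~ t_s[keep])
  -1 / coef(fit)[[2]] / 3600
}
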