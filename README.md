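# loomschool

Agent-based simulation and trajectory analysis of experience-dependent
schooling in larval zebrafish.

Seven-day-old zebrafish larvae keep away from their group mates by turning,
at each swim bout, away from the eye that carries more retinal occupancy.
`loomschool` implements a *time-varying* version of this policy: a slow
internal state `s(t)` integrates neighbor-evoked looming events (per-step
increases in retinal occupancy) and modulates the gain of the turning
response, so that simulated fish that have recently experienced high group
density avoid their neighbors less — and recover when visual input is
removed. The package is aimed at researchers modelling visually driven
collective behavior and at users of virtual-reality (VR) rigs who need the
corresponding stimulus protocols and trajectory statistics.

## The model

Vertical retinal occupancy of an object of half-extent `H` (cm) at distance
`d` is `v = 2·atan(H/d)` (degrees), over a visual field of ±165° with a 30°
blind zone behind the animal. The probability of turning right is

    p(right) = 0.5 + a' · [ Σ_left v_i²/Σv − Σ_right v_i²/Σv ],   clamped to [0, 1]

and the effective slope `a'` is driven by a leaky integrator of the maximal
per-step looming input:

    τ ds/dt = s_rest − s(t) + r · Input(t),      a' = a · [1 − (s − s_start)/D]

with defaults `τ = 6 h`, `r = 13`, `s_rest = 0`, `s_start = 0.6`,
`D = 0.19`, `a = 0.0104`/deg (single agent in VR) or `0.00372`/deg
(interacting groups). Agents swim in discrete bouts (1.64 Hz, 0.1 cm,
320 ms) inside a 6.5 cm circular arena with logistic wall avoidance.

Modules: retinal geometry (`occupancy_profile`, `looming_input`), the
turning policy (`p_turn_right`, `estimate_slope`), the integrator
(`step_integrator`, `analytic_state`, `effective_slope`), the simulator
(`run_session`, VR and group modes, density switches), every VR stimulus
generator (`replay_stream`, `stationary_frame_stream`, `rotational_rings`,
`looming_hexagon`, `single_dot_stream`, `surrogate_trajectories`), and the
trajectory statistics (`nn_series`, `shuffled_control`,
`turn_probability_map`, `fit_recovery`, `detect_bouts`, `apply_filters`).
See `vignettes/state-space-schooling.Rmd` for the full methods account.

## Worked example

A single simulated fish watches 19 virtual neighbors for 20 minutes,
then 4 neighbors; its internal state rises and its preferred
nearest-neighbor distance shrinks:

```r
library(loomschool)
cfg  <- vr_config()
low  <- replay_stream(surrogate_trajectories(4,  1200, seed = 42))
high <- replay_stream(surrogate_trajectories(19, 1200, seed = 43))
run  <- run_density_switch(cfg, low, high, baseline_min = 20,
                           high_min = 20, zero_min = 0, probe_min = 20,
                           seed = 44)
st <- run$states
for (sg in unique(st$segment)) {
  s <- st[st$segment == sg, ]
  cat(sprintf("%-8s  mean loom %.3f deg/step   s %.3f -> %.3f   NN %.2f cm\n",
              run$segments$label[sg], mean(s$input_deg),
              head(s$s, 1), tail(s$s, 1), mean(s$nn_cm, na.rm = TRUE)))
}
#> baseline  mean loom 0.055 deg/step   s 0.600 -> 0.606   NN 1.91 cm
#> high      mean loom 0.192 deg/step   s 0.606 -> 0.709   NN 0.77 cm
#> probe     mean loom 0.062 deg/step   s 0.709 -> 0.713   NN 1.71 cm
```

During the baseline the state barely moves and the fish keeps ~1.9 cm from
the nearest dot. Twenty minutes at high density triples the looming input
and raises `s` by ~0.1, halving the effective turning slope — in the probe
at the original density the fish now tolerates neighbors ~0.2 cm closer.
Removing all stimuli lets `s` decay back at the 6 h time constant
(`run_recovery_experiment()` runs the full battery).

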