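Package: loomschool
Title: Experience-Dependent Modulation of Collective Behavior in Larval
    Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulation and trajectory analysis of visually
    driven schooling in larval zebrafish. Implements a time-varying
    state-space model in which a binocular retinal-occupancy turning policy
    is modulated by a slow leaky integrator of neighbor-evoked looming
    events, together with virtual-reality stimulus generators (trajectory
    replay, stationary, rotational, looming and single-dot protocols) and
    the trajectory statistics used to characterize experience-dependent
    changes in group structure (nearest-neighbor distances with shuffled
    controls, turn-probability maps, exponential recovery fits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
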