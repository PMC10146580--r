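Package: splayflow
Title: Optic-Flow Invariants and Priority-Based Altitude Control in Tunnel Flight
Version: 0.1.0
Authors@R:
    person("Flight", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how a flying agent can regulate its altitude from
    two optic-flow invariants: the optical speed rate of change (OSRC) of the
    ground and the splay angle rate of change (SARC) of ground-parallel lines.
    Provides the invariant algebra, a model of a flight tunnel with movable splay
    rods and switchable ground texture, a closed-loop agent simulator with a
    priority-based controller that weights the two invariants by their
    accessibility, a trajectory pipeline (pixel calibration, 150 ms median
    binning, epoch matrices), enumeration-exact nonparametric tests (Friedman
    omnibus and all-pairs rank comparisons, Mann-Whitney), and a seeded synthetic
    cohort generator with CSV/JSON input-output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
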