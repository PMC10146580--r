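---
title: "Methods: optic-flow invariants, the priority controller, and the synthetic tunnel experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optic-flow invariants, the priority controller, and the synthetic tunnel experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splayflow)
```

## 1. The model

An agent flying over flat ground at forward speed $\dot x$ and altitude $z$
sees the ground scroll at the optical speed $\omega = \dot x / z$. Its
temporal derivative, the optical speed rate of change (OSRC), is
$\dot\omega = (z\ddot x - \dot x \dot z)/z^2$; with constant forward speed
this collapses to the relative rate

$$\frac{\dot\omega}{\omega} = -\frac{\dot z}{z}.$$

A ground line parallel to the flight path at lateral distance $y$ subtends
the splay angle $S = \arctan(y/z)$ at the vanishing point. Its rate of change
(SARC) is $\dot S = (-\dot z/z)\cos S \sin S + (\dot y/z)\cos^2 S$, and with
no lateral motion

$$\frac{2\dot S}{\sin 2S} = -\frac{\dot z}{z}.$$

Both invariants therefore expose the *same* behaviorally sufficient quantity,
the relative altitude-loss rate: an agent that nulls either one holds its
height without knowing its height. The interesting question — the one the
simulated experiment addresses — is what happens when the two channels
disagree.

Assumptions inherited from the experimental situation: forward speed is
constant within a flight (the tunnel's fixed width regulates it), the agent
stays laterally centered, and rotational flow components are ignored. The
invariants module evaluates the nadir expression $\omega = \dot x/z$; no
retinal sampling model is applied.

## 2. The tunnel and the manipulation

`tunnel_geometry()` defaults to the 220 × 71 × 25 cm tunnel with entry and
exit 14 cm above the floor. The floor texture switches the *accessibility*
of the optical-speed channel: `os_access` = 1.0 for the striped floor, 0.1
for the white one. The white value is a design choice: strictly positive
(a plain floor still supports some ground-following) but far below the 0.5
priority threshold. Accessibility scales only the weighting of the channel,
never the geometric values of $\omega,\dot\omega,S,\dot S$.

Rods along the floor–wall junctions provide the splay lines.
`rod_offset()` gives their geometric lateral offset: static modes hold their
configured offset; dynamic modes translate at `rate` (default 2 cm/s) from
`onset` (default 2 s), clamped to [0.5, 12.5] cm. The "narrow" control sits
at 8.5 cm, the end-state a converging trial reaches after the ~2 s of
post-onset flight a traverse allows.

**Dynamic stimulation is symmetric by stipulation.** The physical geometry
of the apparatus is under-determined (the walls bound the rods' travel, so a
literal "diverging" offset path saturates immediately), and the printed sign
convention for splay is internally inconsistent: under $S=\arctan(y/z)$ a
converging rod *decreases* $S$, yet the experimental design treats
convergence as the stimulus that *specifies a loss of altitude*. We therefore
stipulate the functional mapping rather than guess the optics: while the
motor runs, the perceived relative SARC acquires a bias of
$\pm\,\mathrm{rate}/(\mathrm{width}/2)$ — positive for convergence, negative
for divergence, identical magnitude for identical rates, for the same
duration (the full travel time) in both directions. This makes the
converging and diverging stimulations exact mirror images, which is what the
design's predictions require. The perceived low-order splay *value* keeps
the geometric $\arctan(y/z)$ form so the self-motion signs stay coherent;
consequently a statically converged rod yields a *smaller* splay value than
the parallel control. Nothing downstream depends on that value: the
controller consumes only rates.

## 3. The controller

`command_vertical_speed()` builds a scalar error $e$ (1/s, positive =
perceived altitude loss):

- if `os_access` $\ge$ `c_star` (default 0.5): $e$ = relative OSRC alone;
- otherwise $e$ is the blend
  $\big(w_\mathrm{osrc}\,c\,\hat e_\mathrm{OSRC} + w_\mathrm{sarc}\,\hat e_\mathrm{SARC}\big) / (w_\mathrm{osrc}\,c + w_\mathrm{sarc})$
  with $c$ the accessibility and default weights 0.5/0.5.

The command is $\dot z_\mathrm{cmd} = k\,e\,z$ (default $k$ = 2.5 /s),
clipped to ±30 cm/s. The **safety veto** implements the priority-to-safety
hypothesis: when the SARC channel is in use, a *descent* command is executed
only if the OSRC channel itself also reports a positive altitude error
(i.e. the descent is corroborated by the ground's own flow); otherwise it is
suppressed, as is any descent below `floor_margin` (2 cm). With the veto on,
diverging rods over white ground produce no response at any altitude — the
observed outcome; with it off, they produce the mirror-image descent — the
symmetric prediction. Both hypotheses ("no response" vs "response too small
to detect") remain expressible; the package decides neither.

**Actuator smoothing.** The command contains $-\dot z/z$ feedback of the
*current* vertical speed, so the continuous law is an implicit loop; a naive
explicit discretization alternates with factor $-k$ and is unstable for
$k > 1$. The realized vertical speed therefore relaxes toward the command at
`actuator_rate` (20 /s, i.e. a 50 ms actuator). This is also the physically
sensible reading of a velocity command. Closed-loop behavior: unperturbed
flights hold altitude to numerical precision; a converging trial over white
ground climbs $\approx$ 1.1 cm in the first 0.75 s and $\approx$ 2.5 cm by
the exit.

Gain, threshold, weights, cap and actuator rate are this package's choices —
the priority scheme is stated qualitatively in the literature, never with
constants. They were fixed once, at design time, so that (i) the climb is
clearly detectable within the 0.5–0.75 s latency window the experiments
report, and (ii) the with-veto-off converging/diverging responses stay
symmetric within 10% over that window (the exponential $\dot z \propto z$
dynamics make long-horizon symmetry impossible in principle: a climbing
agent's command grows with $z$, a descending one's shrinks).

## 4. The synthetic cohorts

`generate_cohort()` emulates the statistical structure of the recorded data:

- per-flight forward speed drawn once from N(55, 5²) cm/s truncated to
  [35, 75] (a constant within the flight);
- entry altitude N(14, 0.5²) cm;
- within-flight altitude jitter: a stationary AR(1) process about the
  controlled path, sd 0.25 cm, 50 ms correlation time;
- vertical pixel quantization to 71/210 cm (on by default);
- 100 Hz output; per-flight child seeds derived from the master seed and the
  (condition, flight) indices, so resizing a cohort never reshuffles other
  flights.

**Why stationary jitter rather than a random walk.** White noise added to
$\dot z$ would make altitude a random walk. Random-walk bins are not
exchangeable within a flight (drifting runs are overrepresented), and the
Friedman test's permutation null then fails: we measured a type-I rate of
0.025 at $\alpha = 0.01$ under that model, against 0.009–0.010 for the
stationary model — only the latter is compatible with validating the test at
its nominal level. Biologically, bees hover *about* the entrance height for
the few seconds of a traverse; a stationary fluctuation states that world, a
random walk does not.

What the generator does **not** emulate: between-bee individuality, lateral
or yaw dynamics, speed fluctuations within a flight, tracking dropouts,
learning across trials. A green pattern test therefore establishes that the
*model* reproduces the qualitative outcome grid under its stated noise — not
that real bees obey the controller, and not the published p-values, which
belong to the recorded animals.

## 5. The pipeline and statistics

`calibrate()` applies the linear map of the 620 × 210 px crop to
160 × 71 cm (one pixel row = 71/210 cm = 3.4 mm). `bin_median()` takes
medians of consecutive 15-sample (150 ms) groups, bins aligned to the
flight's first sample, partial trailing bins dropped. `epoch_split()`
assembles the flights × bins matrix: by default the 3 bins before and 3
after the onset (centers 1.575–2.325 s for a 2 s onset); the analysis layer
uses 6 post-onset bins (to 2.775 s) so the window covers the 0.5–0.75 s
response latency; a "table" grid reproduces the 0.25 s-spaced comparison
layout of published all-pairs tables by nearest-center selection (the exact
regridding used there is unstated; we do not invent it). The
ground-following filter (median altitude below half the tunnel height, no
sample within 0.5 cm of the ceiling) is this package's stand-in for an
unpublished criterion and is pluggable.

`friedman_test()` uses within-block midranks and the tie-corrected
chi-square-form statistic. Exact p-values enumerate all $(k!)^n$ equally
likely within-block orderings whenever that count is at most $10^6$; the
enumeration is organized as a convolution over column rank-sum vectors, so
the n = 10, k = 3 case ($6^{10}$ configurations) still runs in milliseconds.
`friedman_allpairs()` tests each pair by the absolute rank-sum difference
$D = |R_j - R_{j'}|$, with an exact convolution null under the same gate, a
seeded $\ge 10^5$-draw Monte Carlo fallback above it, and Bonferroni
adjustment (capped at 1; the adjustment used for the published table is
unstated, so both raw and adjusted values are reported). `mann_whitney()`
enumerates all $\binom{n_1+n_2}{n_1}$ labelings when untied and feasible,
else uses the tie-corrected normal approximation. All tests are two-sided;
rejection uses $p \le \alpha$, the exact-test convention. Tiny degenerate
inputs (constant blocks) yield statistic 0 and p = 1 rather than errors.
Distributional assumption checks (Shapiro–Wilk, Fligner–Killeen) are
delegated to base R and gate nothing: the nonparametric route is always used.

The decision rule for "a condition responded" mirrors the published
analysis: omnibus Friedman at $\alpha = 0.01$, then all-pairs comparisons,
with a cell called significant only if some pre-onset vs post-onset pair
survives adjustment; its direction is the sign of the post-minus-pre column
medians. Static-rod cells are tested between flights (Mann–Whitney on
per-flight median altitudes against the parallel control over the same
texture).

## 6. Numerical choices and degenerate inputs

- Angles in radians throughout; degrees only in presentation.
- `relative_sarc()` raises when $|\sin 2S| < 10^{-9}$; the controller treats
  such samples as zero error instead (a stalled channel, not a crash).
- Integration: explicit Euler at `dt` = 10 ms (must divide the output
  interval); halving `dt` changes noise-free solutions by < 0.05 cm.
- Enumeration gate $10^6$ configurations; Monte Carlo p-values use the
  add-one estimator $(1 + \#\{D^* \ge D\})/(B+1)$, which can never return 0.
- Exact p-value comparisons in tests use tolerance $10^{-12}$ (double
  rounding in the convolution), with observed-statistic comparisons shifted
  by $10^{-9}$ to make ties in the statistic robust.
- Altitudes are clamped to (0, height) with a 10⁻³ cm margin; commanded
  descent through the floor is impossible with the default floor margin.

## 7. Known limitations

- The controller is a one-degree-of-freedom model; it cannot express
  attention shifts, habituation, or inter-individual weighting differences.
- The symmetric-stimulation stipulation deliberately does not model the
  physical rod optics; a future perspective-projection module could replace
  it behind the same `perceived_invariants()` contract.
- The chi-square omnibus fallback is mildly conservative at n = 10; the
  acceptance suite validates its level empirically for the default design
  only.
- The published experiment's numeric p-values are not reproducible here:
  they require the recorded bee trajectories, which this package does not
  redistribute.
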