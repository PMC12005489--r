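---
title: "Modelling collective sperm search and selection in complex microenvironments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling collective sperm search and selection in complex microenvironments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermsim)
```

## The model

`spermsim` simulates populations of mammalian sperm as non-adaptive
self-propelled particles searching a bounded two-dimensional arena for a
single egg. Each agent represents a tracked sperm nucleus, in the spirit
of computer-aided sperm analysis (CASA), and carries a position
$(x_i, y_i)$ in micrometres, a heading $\theta_i$, a motility state, and a
calcium oscillator. The equations of motion per model step are

$$\theta_i \leftarrow \theta_i + s_k\,\omega + \sigma_\theta\,\eta_\theta,
\qquad
\Delta x_i = \cos\theta_i\,(v\,\tau + \sigma_r \sqrt{\tau}\,\eta_r),
\quad
\Delta y_i = \sin\theta_i\,(v\,\tau + \sigma_r \sqrt{\tau}\,\eta_r),$$

where $v$ is the nominal radial speed (um/s), $\omega$ the nominal
angular speed (degrees per step), $\sigma_r$ and $\sigma_\theta$ the
amplitudes of zero-mean uncorrelated Gaussian noises, and
$s_k = (-1)^k$ a flagellar drive that flips sign once per step. The same
radial draw $\eta_r$ enters both displacement components (the noise
perturbs the speed along the heading, not the direction). With the noise
switched off the trajectory is a sequence of alternating arcs oscillating
about a fixed mean direction; with $v = 0$, $\omega = 0$ and large
$\sigma_\theta$ the walk is diffusion-like. The root-mean-square
displacement scales as $t$ in the first regime and $\sqrt{t}$ in the
second, which `rmsd_scaling_exponent()` recovers from simulated
ensembles.

### Timescale and discretisation

One model step is one flagellar beat cross at the mean mouse beat-cross
frequency of 25.4 Hz, so $\tau = 1/25.4\ \mathrm{s} \approx 40$ ms
(`model_time_step()`). The continuous drive
$\mathrm{sgn}(\sin 2\pi t/\tau)$ is identically zero when sampled exactly
at step boundaries, so it is discretised as $s_k = (-1)^k$: each
advancement produces exactly one beat cross. Radial noise enters with
$\sqrt{\tau}$ (Wiener-type) scaling, consistent with its units of
um/s^1/2^; angular quantities are quoted per step and are applied
unscaled. Degrees are converted to radians once, at parameter-table
construction.

### Motility classes

Five calibrated classes (progressive, intermediate, hyperactive, slow,
weak) are built in (`builtin_classes()`), spanning fast straight
swimming to slow erratic movement:

```{r}
do.call(rbind, lapply(builtin_classes(), function(cl)
  data.frame(v = cl$v, sigma_r = cl$sigma_r, omega = cl$omega,
             sigma_theta = cl$sigma_theta)))
```

`casa_metrics()` summarises simulated tracks with the standard CASA
velocities: VCL (curvilinear), VSL (straight-line), VAP (average-path,
5-point moving average with symmetric edge truncation, the common CASA
smoother) and the ratios LIN and STR. ALH and BCF are not computed: a
point agent has no lateral head displacement, and the beat-cross rate is
fixed at one per step by construction.

## Environments and spatial complexity

Arenas are grids of square cells (default 40 um, 17 x 17 cells = 680 x
680 um, the field of view of a 10x objective). Cells are corridor or
barrier; one corridor cell is the egg and one or more form the start
region. Continuous positions map to half-open cells
$[i\cdot 40, (i+1)\cdot 40)$, so every point belongs to exactly one cell.
Maze files are ASCII grids (`#` barrier, `.` corridor, `S` start, `E`
egg) with an optional JSON graph sidecar.

A maze's *skeleton graph* has dead-ends (degree 1) and intersections
(degree >= 3) as vertices; straight runs of corridor collapse into
edges. Two complexity statistics are computed from it:

* **Total weighted complexity**, $TC_w = \sum_i d_i$, the sum of vertex
  degrees.
* **Direct-path probability**,
  $P(S \to E) = \prod_{i=1}^{k} 1/d_i$ over the $k$ vertices of the
  shortest start-to-egg path — the chance that a walker choosing
  uniformly among corridors at every vertex goes straight to the egg.

Two conventions deserve note. First, an arena containing any open 2 x 2
corridor block has no unit-width corridor structure to skeletonise; it is
treated as a single open region with one vertex of degree 1, so the open
arena has $TC_w = 1$ and $P(S\to E) = 1$. Second, shortest paths are
found by breadth-first search with lowest-vertex-id tie-breaking; the
bundled mazes are acyclic, so their start-to-egg path is unique and the
tie-break never fires, but the rule makes results on cyclic mazes
deterministic.

### The bundled mazes

Three arenas ship with the package: `maze_fixture("A")`, the open arena,
and two acyclic labyrinths `"B"` and `"C"`. B and C are *synthetic
reconstructions*: the published constraints — 17 x 17 cells, acyclic
corridors, egg in the bottom-right corner, $TC_w = 22$ and $54$, and for
maze C a shortest-path degree product of
$3^7 \cdot 4^2 = 34{,}992$ — pin the skeleton graphs but not the exact
drawn geometry, so the grids here are labyrinths constructed to satisfy
every printed statistic. The graph sidecars are generated from the same
designs, and the test suite checks the grid-extracted graphs against the
sidecars by isomorphism. Quantities that depend only on the graph
($TC_w$, path product) are exact; quantities that depend on corridor
lengths and geometry (absolute search times, variance shares) are
faithful to the model mechanics but not to any particular published
drawing, and the two-factor results below should be read with that in
mind.

```{r}
gC <- maze_to_graph(maze_fixture("C"))
c(TCw = total_weighted_complexity(gC),
  paths = 1 / direct_path_probability(gC))
```

## Phenotype dynamics

Each agent's intracellular calcium follows
$\mathrm{Ca}_i(t) = \tfrac12(1 - \cos 2\pi \Omega_i t)$, a squared sine
normalised to $[0, 1]$ with integer frequency $\Omega_i$ (Hz) drawn once
per agent from a Poisson distribution with mean $\lambda$. The printed
form of the oscillator leaves the angular units ambiguous;
$\Omega_i$ is interpreted as a cyclic frequency in Hz (phase
$2\pi\Omega_i t$), which keeps $\lambda$ in Hz as labelled. Poisson zeros
are kept: an $\Omega_i = 0$ agent never opens its calcium gate and stays
progressive forever, a mechanism that matters at $\lambda = 1$ (37 % of
agents).

Motility-state switching is a calcium-gated time-homogeneous Markov
chain over the five classes. At each sampled step with
$\mathrm{Ca}_i > 0.97$ (a configurable fraction of the maximum; the
source material states both 0.97 and "the upper 5 %", and the explicit
0.97 is used as the default) the agent draws its next state from its row
of the transition matrix (`default_transition_matrix()`); below the gate
the state is held. Calcium is sampled only at step times $k\tau$, with no
sub-step crossing detection; frequencies above the 12.7 Hz Nyquist limit
alias, which is accepted as part of the model's discrete nature.
Eligibility is re-drawn at every eligible step (not once per threshold
crossing). The weak state is nearly absorbing as printed (0.99
self-transition with a 0.01 exit to slow); the printed numbers are used
verbatim rather than the prose claim that weak is inescapable, and a
`strict_absorbing = TRUE` option zeroes the exit for the stricter
reading. The stationary distribution of the eligible-step chain
(`stationary_distribution()`, a left-eigenvector computation) puts most
mass on weak, so populations drain towards weak motility, and
`occupancy_timecourse()` reproduces that drainage from all-progressive
initial conditions.

## The world stepper

Each step updates every agent: (1) calcium gate and possible state
transition; (2) motion step with the current class's parameters; (3)
barrier handling; (4) coverage marking; (5) egg-contact accrual. A move
whose endpoint falls in a barrier cell or outside the arena is rejected:
the agent keeps its position and redraws its heading uniformly from the
half-circle centred on the inward normal of the blocked face (the
diagonal normal for corner hits), perturbed by its class's
$\sigma_\theta$. Collision detection is endpoint-based: with maximum step
length 16.5 um against 40 um cells an agent cannot tunnel through a cell,
though it may clip a barrier corner; coverage is likewise recorded from
step endpoints. Egg contact adds $\tau$ to an agent's contact time for
every step it ends on the egg cell.

Stop rules: `first_contact` (with the time and area searched at that
moment recorded), `cumulative_contact` — total contact time summed over
*all* agents reaching a threshold, 5 s by default (the alternative
per-agent reading of the threshold is not the default because the
source describes contacts "by one or more sperm" accumulating to a
single threshold) — and `fixed_duration`. Every run is capped at
`max_steps` (default $10^6$) and reports a `"timeout"` end reason rather
than raising, so sweeps can aggregate.

Agents never interact — they cross paths freely and share no dynamical
state — so the order in which agents are updated within a step cannot
affect any agent's trajectory. Draws are therefore made in fixed
agent-index order from one seeded RNG stream, which makes runs
bit-for-bit reproducible from a master seed and lets the compiled
(C++) stepper and the pure-R reference stepper replay the identical
stream; the test suite asserts their outputs are identical to the last
bit. The asynchronous random update sequence of the original
formulation is observationally equivalent for non-interacting agents.

## Selection statistics

A run's *initial* trait distribution $q$ is the empirical distribution
of oscillation frequencies among all $N$ agents; the *contactor*
distribution $q'$ is the same over agents with positive accrued contact
time, each counted once regardless of contact duration. Two statistics
quantify selection:

* **Posterior fitness** (Bayes):
  $P(\mathrm{contact} \mid q_i) = P(\mathrm{contact})\,
  P(q_i \mid \mathrm{contact}) / q_i$ with flat prior
  $P(\mathrm{contact}) = 1/N$. The identity
  $\sum_i P(\mathrm{contact}\mid q_i)\, q_i = 1/N$ holds exactly and is
  asserted on every run.
* **Relative information gain**:
  $D(q' \| q) = \sum_i q_i' \log_2 (q_i'/q_i)$ bits, with the
  $0 \log 0 = 0$ convention and no pseudocounts (contactors are a subset
  of the population, so $q_i = 0 \Rightarrow q_i' = 0$ and smoothing is
  unnecessary). It is nonnegative, zero exactly when $q' = q$, and
  asymmetric.

Selection statistics are computed per simulation and summarised across
replicates (rather than pooling contactors across replicates first);
both views are available from the sweep tables.

## Experiments and statistics

`sweep_heterogeneity()` runs the two-factor design: mazes A/B/C crossed
with $\lambda \in \{1, 10, 20\}$ Hz, by default 100 replicates per cell
of 100 markov-mode agents each under the cumulative 5 s stop rule, with
per-replicate seeds derived deterministically from the master seed and
logged in the output table. 100 agents keeps the sampled frequency
distributions consistent across replicates; placement is uniform within
the designated start cell of each maze, fixed across replicates. Search
times are right-skewed, so the variance decomposition uses
$\log_{10}$ search time (the base only relabels axes; F statistics and
variance shares are base-invariant). `two_way_anova()` wraps
`stats::aov()` and reports percent of total variation as
$100 \cdot SS_\mathrm{effect}/SS_\mathrm{total}$ — the convention under
which the published shares (which sum to less than 100) are interpreted,
not partial eta squared. `tukey_hsd()` wraps `stats::TukeyHSD()`.
`sweep_sperm_number()` runs the density experiment (progressive-only
populations, first-contact stop) and `sweep_motility_composition()` the
fixed-composition coverage experiment (2 s windows, the standard CASA
acquisition length, i.e. 51 steps).

Placement differs between experiments by design. The coverage
experiment scatters agents uniformly over the corridor (its question is
how a dispersed ensemble explores). The density and two-factor
experiments start all agents in the arena's designated start region:
this is the configuration in which the population must *travel* to the
egg, and it is what produces the density laws — first-contact time
falling and area-searched-at-first-contact rising with population size.
Under uniform placement the area law inverts (a large scattered
population contacts almost immediately, having searched almost
nothing), so start-region placement is the default for
`sweep_sperm_number()`.

Problem sizes: the full two-factor design (900 replicates of 100 agents)
runs in a few minutes with the compiled stepper and is used as-is by the
acceptance script and acceptance tests; the density experiment is run at
$N \in \{1, 10, 100, 1000\}$ with 50 replicates, which suffices for its
ordering and skewness diagnostics.

## What the generator does and does not emulate

The simulated populations emulate: the five-class structure of mouse
sperm motility with calibrated speeds and noise amplitudes; progressive
-to-degraded motility drift via calcium-gated switching; Poisson
heterogeneity of calcium oscillation frequencies; and crowding-free
collective search of bounded, internally structured arenas. They do not
emulate: adaptive behaviours (chemo-, rheo-, thermotaxis), hydrodynamic
or steric agent interactions, 3D flagellar mechanics, fluid flow,
mechanistic calcium signalling, or the geometry of real oviducts — the
mazes are deliberately abstract complexity standards, and B/C are
reconstructions pinned only by their graph statistics. Passing tests
therefore certify the model's internal laws (scaling exponents, Bayes
identities, chain convergence, variance-share orderings), not
quantitative predictions about live sperm.

## Known limitations

* Absolute search times and the exact ANOVA shares depend on corridor
  geometry that the graph statistics do not determine; with the
  reconstructed mazes the dominant orderings (maze complexity dominating
  heterogeneity for search time; comparable maze and heterogeneity
  shares for information gain) are reproduced, while the small published
  search-time shares for the heterogeneity factor and interaction are
  not matched numerically.
* Endpoint-based collision and coverage detection can clip barrier
  corners and undercount cells crossed mid-step.
* The reflecting half-circle reorientation is a modelling choice; real
  wall interactions of sperm are hydrodynamically attractive and more
  persistent.
* Runs with no contacting agent (possible only under `max_steps`
  timeouts) carry `NA` information gain and are excluded from the
  selection summaries.
```{r}
sessionInfo()
```
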