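---
title: "Attention-limited flocking in complex environments: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-limited flocking in complex environments: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`flockattn` simulates a group of $N$ self-propelled agents on an
$L \times L$ torus, together with $N_{DS}$ fixed, point-like *danger
sites*, each surrounded by a disc-shaped repulsion zone of radius $r$
(default $r = 1$; zones may overlap). The danger-site density is
$\rho_{DS} = N_{DS}/L^2$. Agents move at constant speed $v_0$ along a
heading $\varphi_i$,
$$\dot{\mathbf x}_i = v_0\,\hat u_i, \qquad
  \hat u_i = (\cos\varphi_i, \sin\varphi_i)^T,$$
and interact through a *finite attention capacity*: agent $i$ attends
only to its $k$ nearest objects (kNO) — other agents and danger sites
compete for the same $k$ slots, ranked purely by torus distance. A
danger site that occupies a slot but lies outside the repulsion radius
is perceived yet ignored, and still consumes a slot.

The heading obeys a stochastic differential equation,
$$\dot\varphi_i =
  (1-g_i)\Big[\frac{\gamma_s}{n_s}\sum_{j\in \mathrm{kNO}_i}
  \sin(\varphi_j-\varphi_i) + \gamma_p\sin(\varphi_p-\varphi_i)\Big]
  + g_i\,\frac{\gamma_l}{n_l}\sum_{l}\sin(\alpha_{il}-\varphi_i)
  + \eta\,\xi_i(t),$$
with $\xi_i$ unit-variance Gaussian white noise. The switch $g_i = 1$
iff at least one attended danger site lies strictly inside the
repulsion radius; while responding, the agent ignores all social cues
and its informed bias. $\alpha_{il}$ is the polar angle of the shortest
displacement *from* site $l$ *to* agent $i$, so the repulsion term turns
the agent away from the site. A fraction $R_{\mathrm{inf}}$ of agents is
*informed*: only they feel the bias $\gamma_p$ toward the global
preferred direction $\hat u_p$ (default $(1,0)$; $\varphi_p$ is its
angle).

One modeling point deserves emphasis because the defining equations can
be read two ways: the repulsion sum and its normalizer $n_l$ run only
over attended sites *inside* the repulsion radius. Perceived sites
outside the radius trigger no response, so letting them dilute the
normalization would mix a non-acting cue into an acting term. Empty sums
(no social neighbors, or no active site) contribute zero — an isolated
agent moves ballistically plus noise.

## Default parameters

| parameter | meaning | default |
|---|---|---|
| $v_0$ | speed (length/time) | 0.5 |
| $\gamma_s$ | alignment strength (1/time) | 1 |
| $\gamma_p$ | informed bias (1/time) | 0.1 |
| $\gamma_l$ | danger repulsion (1/time) | 1 |
| $\eta$ | angular noise strength | 0.25 |
| $k$ | attention capacity (slots) | — (required) |
| $dt$ | integration step (time) | 0.1 |
| $L$, $N$ | box and group size | 25, 625 (density 1) |
| $r$ | repulsion radius | 1 |

These are the standard study conditions at agent density
$N/L^2 = 1$; `flock_params()` exposes every one of them.

# Numerical scheme

The equations are integrated with the Euler–Maruyama method: per step
$$\varphi_i \leftarrow \varphi_i + \dot\varphi_i^{\det}\,dt +
  \eta\sqrt{dt}\,\mathcal N(0,1), \qquad
  \mathbf x_i \leftarrow \mathrm{wrap}(\mathbf x_i + v_0 \hat
  u_i(\varphi_i^{\mathrm{new}})\,dt).$$
The update is synchronous: every attention set, response flag and
turning rate is computed from the pre-step configuration before any
heading moves. Positions advance along the *post-update* heading, which
makes the per-step displacement exactly $v_0\,dt$ — speed conservation
is an identity of the scheme, and the test suite asserts it to
round-off. Headings are wrapped to $(-\pi, \pi]$ and positions to
$[0, L)$ after every step.

Distance ties in the kNO ranking are broken by object index (agents
before danger sites); for continuous positions ties are a measure-zero
event, the rule exists so that trajectories are bit-reproducible.

Two engines implement the same dynamics. The compiled engine uses a
periodic cell list (cells of about 1.5 length units) with expanding
Chebyshev ring search and falls back to a brute-force scan when the box
is too small for unambiguous rings; it handles the full
$N = 625$, $2\times 10^4$-step runs in seconds. The pure-R reference
integrator (`step_flock()`, `engine = "r"`) computes every attention set
through the exported module functions and consumes the identical RNG
stream — per step, one uniform per in-zone agent (direct-detection
variant only), then one normal per agent, in agent order — so matched
seeds give matching trajectories across engines; the suite checks
bitwise agreement for the base model. All randomness flows through R's
RNG: a single seed reproduces initial conditions and noise exactly.

# Environments

`env_random()` scatters sites uniformly; a seed makes the field
reproducible. `env_structured()` builds the circular danger-free-path
landscape: sites are drawn at the nominal density, then sites inside the
annulus `path_radius` $\pm$ `path_width`/2 are rejected *without*
redrawing, so the corridor is exactly empty and the realized global
density sits slightly below nominal — the simplest construction
consistent with a danger-free path, given that no geometry for it is
otherwise fixed. Defaults (`path_radius = L/3`, `path_width = 3`,
centered) are package choices, exposed as parameters.

# Observables

* **Accuracy** $C = \langle N^{-1}\sum_j \hat u_j\cdot\hat u_p\rangle$,
  a time average over recorded stationary frames.
* **Polarization** $\tilde C = \langle|N^{-1}\sum_j \hat u_j|\rangle$,
  the consensus order parameter; $C \le \tilde C$ always.
* **Avoidance** $\tilde A = 1 - \langle N_{rz}/N\rangle$, the fraction
  of agents outside all repulsion zones, and the ratio
  $A = \tilde A/\tilde A_{ni}$ against a *paired* non-interacting
  control: same environment, $\gamma_s = 0$, and unconditional response
  to any containing zone (no attention limit on detection). $A > 1$
  means social interaction helps avoidance.
* **Fitness** $F(C, A) = C + \beta(A-1)$, anchored so that solitary
  behavior ($C = 0$, $A = 1$) scores zero at every $\beta$. $\beta$
  enters only post hoc: sweeps store $(C, A)$ and evaluate $F$ without
  re-simulation.
* **Interaction networks**: a directed edge $i \to j$ when $j$ is in
  $i$'s social neighborhood and $g_i = 0$; responders have out-degree 0
  by construction but keep their in-degree. From these frames the
  package derives degree tables, connected components of the undirected
  projection, mean edge lifetimes, and the responder fractions $r_d$
  (direct, $g = 1$) and $r_i$ (first-order indirect: non-responders with
  at least one out-edge to a responder). Both fractions are per-frame
  proportions of the whole collective, averaged over frames — averaging
  the per-frame fraction rather than pooling, since the stationary
  per-frame quantity is what the order parameters describe.

Edge lifetimes are measured on the undirected projection at the
recording cadence; runs truncated by the observation window are included
at their observed length by default (`include_censored = FALSE` drops
them), since no censoring convention is canonical.

# Model variants

* `p_direct`: an agent inside a zone detects it with probability
  $P_{direct}$ per time step regardless of its attention set (one
  Bernoulli draw per in-zone agent per step — the time discretization of
  the probability is a package choice). $P_{direct} = 0$ recovers the
  base model exactly, draw-for-draw.
* `signaling`: responders advertise; non-responders connected to at
  least one responder put their full attention on the responder(s).
* `mode = "voronoi"`: social candidates restricted to the first Voronoi
  shell, extended by the second shell when the first holds fewer than
  $k$ agents; danger sites still compete by distance alone. The
  tessellation is agent-only, computed on a 3×3 tiling of the torus by
  half-plane clipping of each cell (no Delaunay library is required);
  degenerate configurations fall back to the base selection with a
  warning. This variant runs on the reference engine.

# Stationarity and run lengths

Published-scale comparisons use $N = 625$ and a 2000-time-unit schedule
whose second half is recorded (frames every 5 time units) — windowed
accuracy is flat well before recording starts for every configuration
with ample attention or many informed agents. The exception is the
minimal-attention, sparsely informed regime ($k = 1$ with 8 informed
agents of 625): directional information spreads only through
fission–fusion contact of tiny clusters, and windowed accuracy keeps
rising for roughly 3000 time units. Runs in that regime therefore use a
6000-time-unit schedule with a 3000-unit burn-in, so that the recorded
half is genuinely stationary. The test suite additionally scales some
qualitative-trend checks down to 1000-unit schedules and three
replicates, which is ample for orderings whose effect sizes span several
tenths in $C$.

# What the generator does and does not emulate

The synthetic environments and initial conditions reproduce the study
conditions: uniform random danger fields at prescribed density, uniform
initial positions and headings, an informed subset drawn without
replacement (`round(r_inf * N)`, round-half-to-even, or an exact count).
They do not emulate features of real animal groups — body size and
collision avoidance, inertia, speed variation, restricted fields of
view, or moving threats are all outside the model class (and explicitly
out of scope), so passing tests certify the self-organization mechanism,
not quantitative agreement with any particular species.

# Numerical and design choices worth knowing

* Integration step $dt = 0.1$ with noise increment $\eta\sqrt{dt}$;
  the originating study does not fix the scheme, so order-parameter
  comparisons carry a tolerance of a few hundredths.
* The control run matches the environment but draws its own initial
  agent placement; only the danger-site field must be paired for the
  avoidance ratio to be meaningful.
* Sweep seeds derive from a pure integer hash of (base seed, cell
  labels, replicate), so re-running any subset of a sweep reproduces it
  exactly and cells never share streams.
* Degenerate inputs: $n_s = 0$ or $n_l = 0$ contribute zero rate;
  duplicated positions break the Voronoi variant only, which then warns
  and falls back; non-finite state aborts with the offending agent
  named.

# Known limitations

* The Voronoi variant is reference-engine only and so is practical for
  moderate $N$; the base model runs at full scale.
* Edge lifetimes are resolved at the recording interval: connections
  shorter than one frame spacing are invisible.
* At extreme densities ($\rho_{DS} \gtrsim 1$) the repulsion-zone union
  covers nearly the whole box and $\tilde A_{ni} \to 0$ makes the
  avoidance ratio ill-conditioned; the package raises an error when the
  control avoidance is exactly zero.

# A worked example

```{r, eval = FALSE}
library(flockattn)

env <- env_random(n_ds = 125, box_size = 25, seed = 1)   # rho_DS = 0.2
run <- simulate_flock(env, flock_params(k = 24), n_agents = 625,
                      r_inf = 0.1, total_time = 2000, seed = 1)
ctrl <- simulate_control(env, flock_params(k = 24), n_agents = 625,
                         r_inf = 0.1, total_time = 2000, seed = 2)
run_summary(run, a_control = raw_avoidance(ctrl), beta = 1)
```

The summary row reports $C$, $\tilde C$, $\tilde A$, $A$, $F$, $r_d$,
$r_i$ and the mean component count; `run_sweep()` produces the same row
per grid cell with paired controls handled automatically.
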