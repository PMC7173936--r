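# flockattn

Agent-based simulation of collective motion under a hard attention
bottleneck, for researchers in collective animal behaviour, active
matter and swarm robotics who want to study how *cognitive* limits —
not sensory range — shape coordination in cluttered environments.

## The model

`N` self-propelled agents move at constant speed `v0` on an `L x L`
torus scattered with `N_DS` point-like **danger sites**, each wrapped in
a repulsion disc of radius `r`. Every agent can attend to only its `k`
**nearest objects** (kNO): social neighbours and danger sites compete
for the same `k` slots, ranked purely by distance. Headings follow a
stochastic differential equation,

    dphi_i/dt = (1 - g_i) [ (gamma_s / n_s) * sum_j sin(phi_j - phi_i)
                            + gamma_p * sin(phi_p - phi_i) ]
                + g_i * (gamma_l / n_l) * sum_l sin(alpha_il - phi_i)
                + eta * xi_i(t)

where `g_i = 1` iff an attended danger site lies inside the repulsion
radius (the agent then ignores all social cues and turns away from the
site), and only a fraction `R_inf` of *informed* agents feels the bias
`gamma_p` toward the preferred direction. The key observables are the
migration accuracy `C` (mean heading projection on the preferred
direction), polarization `C~`, the danger avoidance `A` normalized by a
paired non-interacting control, and the fitness `F = C + beta (A - 1)`.

The interesting physics is a coordination–responsiveness trade-off:
in dense danger fields, *small* `k` lets the group self-isolate from
distracting cues (high `C`, poor avoidance), while large `k` couples the
group to the environment (good avoidance, collapsed accuracy).

The simulation core is compiled (Rcpp) with a periodic cell-list
neighbour search; a pure-R reference integrator replays the identical
RNG stream for validation and powers the Voronoi-neighbourhood variant.
Model variants: probabilistic direct detection (`p_direct`), active
signaling by responders (`signaling`), Voronoi-restricted kNO
(`mode = "voronoi"`).

## A worked example

```r
library(flockattn)

env <- env_random(n_ds = 125, box_size = 25, seed = 1)  # rho_DS = 0.2
run <- simulate_flock(env, flock_params(k = 24), n_agents = 625,
                      r_inf = 0.1, total_time = 2000, seed = 1)
run
#> <flock_run> 625 agents (62 informed), 200 frames, k = 24, rho_ds = 0.2
#>   accuracy C = 0.126, polarization = 0.336, avoidance = 0.709

ctrl <- simulate_control(env, flock_params(k = 24), n_agents = 625,
                         r_inf = 0.1, total_time = 2000, seed = 2)
run_summary(run, a_control = raw_avoidance(ctrl), beta = 1)
#>           C  C_tilde    A_raw        A         F      r_d      r_i
#> 1 0.1262643 0.336238 0.709352 1.049474 0.1757382 0.266688 0.579896
#>   mean_components
#> 1            2.13
```

Read: with full attention capacity (`k = 24`) in a dense danger field,
only 10% informed agents cannot impose the migration direction
(`C ≈ 0.13`), but the group beats solitary agents at staying out of
danger (`A ≈ 1.05 > 1`); over half the collective are first-order
indirect responders (`r_i ≈ 0.58`). Re-running with `k = 1` flips the
picture: high `C`, `A < 1`.

`run_sweep()` automates grids over `(k, rho_ds, r_inf)` with paired
controls and per-cell reproducible seeds; `inst/cli/flockattn` exposes
`make-env`, `simulate`, `control`, `sweep` and `analyze` subcommands for
shell use. The methods vignette
(`vignettes/attention-limited-flocking.Rmd`) documents the equations,
numerical scheme, variants and design choices.

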