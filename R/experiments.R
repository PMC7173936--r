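#' Non-interacting control run
#'
#' Simulates the same number of agents in the same environment, but with
#' agents interacting exclusively with the environment: the social
#' coupling is switched off (`gamma_s = 0`) and every agent responds
#' unconditionally to any repulsion zone containing it -- the attention
#' limit does not apply to danger-site detection. Informed agents keep
#' their preferred-direction bias. This is the solitary-individual
#' reference against which the avoidance ratio `A` is normalized.
#'
#' @inheritParams simulate_flock
#' @return A `flock_run` (edges are never recorded; the social network is
#'   empty by construction).
#' @seealso [avoidance_ratio()]
#' @export
simulate_control <- function(env, params, n_agents, r_inf = 0.1,
                             n_informed = NULL, total_time = 2000,
                             burn_in = total_time / 2, record_every = 5,
                             seed = NULL, state0 = NULL) {
  p <- params
  p$gamma_s <- 0
  simulate_flock(env, p, n_agents, r_inf = r_inf, n_informed = n_informed,
                 total_time = total_time, burn_in = burn_in,
                 record_every = record_every, seed = seed, state0 = state0,
                 engine = "cpp", record_edges = FALSE, noninteracting = TRUE)
}

#' Derive a reproducible sub-seed from a base seed and labels
#'
#' Pure deterministic hash of the base seed and any number of labels
#' (numbers or strings) into an integer in `[1, 2^31 - 2]`, used to give
#' every sweep cell and replicate an independent, collision-resistant and
#' reproducible seed.
#'
#' @param base_seed Integer base seed.
#' @param ... Labels identifying the cell (coerced to character).
#' @return A single integer seed.
#' @export
derive_seed <- function(base_seed, ...) {
  key <- paste(c(format(base_seed), vapply(list(...), format, character(1))),
               collapse = "|")
  h <- 7
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h %% 2147483645 + 1)
}

#' Define a parameter sweep
#'
#' A full-factorial grid over attention capacity `k`, danger-site density
#' `rho_ds` and informed fraction `r_inf`, with `replicates` independent
#' realizations per cell. Each replicate of a `(rho_ds)` value uses its
#' own random environment, shared across `k` and `r_inf` and by the
#' paired non-interacting control, so that main and control runs see the
#' same danger-site field.
#'
#' @param k Vector of attention capacities.
#' @param rho_ds Vector of danger-site densities.
#' @param r_inf Vector of informed fractions.
#' @param replicates Replicates per cell (default 3).
#' @param base_params A `flock_params` providing all remaining parameters
#'   (its `k` is overridden cell by cell).
#' @param n_agents,box_size System size (defaults 625 agents, box 25).
#' @param total_time,burn_in,record_every Run schedule passed to
#'   [simulate_flock()].
#' @param base_seed Base seed for [derive_seed()].
#' @param beta Avoidance benefit used for the fitness column.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(k, rho_ds, r_inf, replicates = 3,
                         base_params = flock_params(k = 1),
                         n_agents = 625, box_size = 25,
                         total_time = 2000, burn_in = total_time / 2,
                         record_every = 5, base_seed = 1, beta = 1) {
  structure(list(k = k, rho_ds = rho_ds, r_inf = r_inf,
                 replicates = replicates, base_params = base_params,
                 n_agents = n_agents, box_size = box_size,
                 total_time = total_time, burn_in = burn_in,
                 record_every = record_every, base_seed = base_seed,
                 beta = beta),
            class = "sweep_config")
}

#' Run a parameter sweep
#'
#' Executes every `(k, rho_ds, r_inf, replicate)` cell of the grid plus
#' one paired non-interacting control per `(rho_ds, r_inf, replicate)`
#' (reused across `k`), and returns one row of scalar observables per
#' main run. With an output directory, completed cells are written as CSV
#' and skipped on re-run, making the sweep idempotent; a failed cell is
#' recorded with `NA` observables and the sweep continues.
#'
#' @param cfg A `sweep_config`.
#' @param out_dir Optional directory for per-cell CSV results.
#' @param record_edges Record interaction edges (needed for `r_i` and
#'   component columns; default `TRUE`).
#' @param progress Print one line per completed cell (default `FALSE`).
#' @return A data frame: the grid columns, `replicate`, `seed`, the
#'   [run_summary()] columns, and `A_raw_control`.
#' @export
run_sweep <- function(cfg, out_dir = NULL, record_edges = TRUE,
                      progress = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  grid <- expand.grid(k = cfg$k, rho_ds = cfg$rho_ds, r_inf = cfg$r_inf,
                      replicate = seq_len(cfg$replicates),
                      KEEP.OUT.ATTRS = FALSE)
  controls <- new.env(parent = emptyenv())
  envs <- new.env(parent = emptyenv())

  get_env <- function(rho, rep) {
    key <- paste(rho, rep)
    if (is.null(envs[[key]])) {
      n_ds <- round(rho * cfg$box_size^2)
      envs[[key]] <- env_random(n_ds, cfg$box_size,
                                seed = derive_seed(cfg$base_seed, "env",
                                                   rho, rep))
    }
    envs[[key]]
  }
  get_control <- function(rho, r_inf, rep) {
    key <- paste(rho, r_inf, rep)
    if (is.null(controls[[key]])) {
      ctrl <- simulate_control(
        get_env(rho, rep), cfg$base_params, cfg$n_agents, r_inf = r_inf,
        total_time = cfg$total_time, burn_in = cfg$burn_in,
        record_every = cfg$record_every,
        seed = derive_seed(cfg$base_seed, "control", rho, r_inf, rep))
      controls[[key]] <- raw_avoidance(ctrl)
    }
    controls[[key]]
  }

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    seed <- derive_seed(cfg$base_seed, cell$k, cell$rho_ds, cell$r_inf,
                        cell$replicate)
    cell_file <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("cell_k%s_rho%s_rinf%s_rep%d.csv",
                                 cell$k, cell$rho_ds, cell$r_inf,
                                 cell$replicate))
    if (!is.null(cell_file) && file.exists(cell_file))
      return(utils::read.csv(cell_file))
    row <- tryCatch({
      p <- cfg$base_params
      p$k <- as.integer(cell$k)
      env <- get_env(cell$rho_ds, cell$replicate)
      run <- simulate_flock(env, p, cfg$n_agents, r_inf = cell$r_inf,
                            total_time = cfg$total_time,
                            burn_in = cfg$burn_in,
                            record_every = cfg$record_every, seed = seed,
                            record_edges = record_edges)
      a_ctrl <- get_control(cell$rho_ds, cell$r_inf, cell$replicate)
      cbind(cell, seed = seed, run_summary(run, a_ctrl, cfg$beta),
            A_raw_control = a_ctrl)
    }, error = function(e) {
      warning(sprintf("sweep cell %d failed: %s", i, conditionMessage(e)))
      cbind(cell, seed = seed, C = NA, C_tilde = NA, A_raw = NA, A = NA,
            F = NA, r_d = NA, r_i = NA, mean_components = NA,
            A_raw_control = NA)
    })
    if (!is.null(cell_file))
      utils::write.csv(row, cell_file, row.names = FALSE)
    if (progress)
      message(sprintf("[%d/%d] k=%s rho=%s r_inf=%s rep=%d done",
                      i, nrow(grid), cell$k, cell$rho_ds, cell$r_inf,
                      cell$replicate))
    row
  })
  do.call(rbind, rows)
}
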