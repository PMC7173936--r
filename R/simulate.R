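#' Simulate the attention-limited flocking model
#'
#' Integrates the full system for `total_time` time units and records the
#' configuration (positions, headings, danger-response flags, number of
#' agents inside repulsion zones and, optionally, the social interaction
#' edges) every `record_every` time units once `burn_in` time units have
#' elapsed. All randomness -- initial condition and dynamics -- is drawn
#' from a single seeded stream, so matched seeds give identical
#' trajectories.
#'
#' Two engines are available: the compiled cell-list engine (`"cpp"`, the
#' default) and the pure-R reference integrator (`"r"`, see
#' [step_flock()]), which is required for the Voronoi attention mode and
#' produces the same trajectories as the compiled engine under matched
#' seeds (up to floating-point round-off).
#'
#' @param env A `flock_env`.
#' @param params A `flock_params`.
#' @param n_agents Number of agents.
#' @param r_inf Informed fraction (default 0.1); ignored when `state0` or
#'   `n_informed` is given.
#' @param n_informed Optional exact informed count (overrides `r_inf`).
#' @param total_time Simulated time in time units (default 2000).
#' @param burn_in Time discarded before recording starts (default half of
#'   `total_time`).
#' @param record_every Recording interval in time units (default 5).
#' @param seed Optional integer seed.
#' @param state0 Optional initial `flock_state` (default: drawn by
#'   [init_state()]).
#' @param engine `"auto"`, `"cpp"` or `"r"`.
#' @param record_edges Logical; record the social out-edges of every
#'   non-responding agent at each frame (needed for network observables;
#'   default `TRUE`).
#' @param noninteracting Logical; solitary-agent control dynamics (no
#'   social interactions, unconditional response to containing zones).
#' @return An object of class `flock_run`: a list with `times` (frame
#'   times), `phi`, `x`, `y`, `g` (frames x agents matrices), `nrz`
#'   (agents inside zones per frame), `edges` (matrix with columns
#'   `frame`, `from`, `to`, or `NULL`), `informed`, `env`, `params`,
#'   `seed`, `engine` and `final_state`.
#' @examples
#' env <- env_random(0, 10, seed = 1)
#' run <- simulate_flock(env, flock_params(k = 3), n_agents = 20,
#'                       total_time = 20, burn_in = 10, seed = 1)
#' accuracy(run)
#' @export
simulate_flock <- function(env, params, n_agents,
                           r_inf = 0.1, n_informed = NULL,
                           total_time = 2000, burn_in = total_time / 2,
                           record_every = 5, seed = NULL, state0 = NULL,
                           engine = c("auto", "cpp", "r"),
                           record_edges = TRUE, noninteracting = FALSE) {
  stopifnot(inherits(env, "flock_env"), inherits(params, "flock_params"))
  engine <- match.arg(engine)
  if (total_time <= burn_in)
    stop("'total_time' must exceed 'burn_in'")
  if (burn_in < 0 || record_every <= 0)
    stop("invalid 'burn_in' or 'record_every'")
  if (engine == "auto")
    engine <- if (params$mode == "voronoi") "r" else "cpp"
  if (engine == "cpp" && params$mode == "voronoi")
    stop("the Voronoi attention mode requires engine = \"r\"")

  if (!is.null(seed)) set.seed(seed)
  if (is.null(state0))
    state0 <- init_state(n_agents, env$L, r_inf, n_informed)
  stopifnot(nrow(state0$x) == n_agents)

  n_steps <- round(total_time / params$dt)
  burn_steps <- round(burn_in / params$dt)
  rec_steps <- max(1L, round(record_every / params$dt))

  if (engine == "cpp") {
    res <- simulate_cpp(state0$x[, 1], state0$x[, 2], state0$phi,
                        as.integer(state0$informed),
                        env$ds[, 1], env$ds[, 2], env$L, env$r,
                        params$v0, params$gamma_s, params$gamma_p,
                        params$gamma_l, params$eta, params$k, params$dt,
                        params$up_angle, n_steps, burn_steps, rec_steps,
                        params$p_direct, params$signaling, noninteracting,
                        record_edges)
  } else {
    res <- run_flock_r(state0, env, params, n_steps, burn_steps, rec_steps,
                       record_edges, noninteracting)
  }

  structure(list(
    times = res$times, phi = res$phi, x = res$x, y = res$y, g = res$g,
    nrz = res$nrz,
    edges = if (record_edges) res$edges else NULL,
    informed = state0$informed, env = env, params = params,
    n_agents = n_agents, seed = seed, engine = engine,
    noninteracting = noninteracting,
    final_state = structure(list(
      x = cbind(res$final_x, res$final_y), phi = res$final_phi,
      informed = state0$informed), class = "flock_state")),
    class = "flock_run")
}

# pure-R integration loop mirroring the compiled engine (identical RNG use)
run_flock_r <- function(state0, env, params, n_steps, burn_steps, rec_steps,
                        record_edges, noninteracting) {
  n <- nrow(state0$x)
  n_frames <- if (n_steps > burn_steps)
    (n_steps - 1 - burn_steps) %/% rec_steps + 1 else 0
  phi_rec <- x_rec <- y_rec <- matrix(NA_real_, n_frames, n)
  g_rec <- matrix(NA_integer_, n_frames, n)
  times <- numeric(n_frames)
  nrz <- integer(n_frames)
  edges <- vector("list", n_frames)

  state <- state0
  for (s in seq_len(n_steps) - 1L) {
    nxt <- step_flock(state, env, params, noninteracting = noninteracting)
    if (s >= burn_steps && (s - burn_steps) %% rec_steps == 0) {
      f <- (s - burn_steps) %/% rec_steps + 1
      times[f] <- s * params$dt
      phi_rec[f, ] <- state$phi
      x_rec[f, ] <- state$x[, 1]
      y_rec[f, ] <- state$x[, 2]
      g <- attr(nxt, "g")
      g_rec[f, ] <- g
      nrz[f] <- sum(vapply(seq_len(n), function(i)
        length(zones_containing_r(state$x[i, ], env)) > 0, logical(1)))
      if (record_edges) {
        soc <- attr(nxt, "soc")
        from <- rep.int(seq_len(n), lengths(soc))
        to <- unlist(soc, use.names = FALSE)
        keep <- g[from] == 0
        if (any(keep))
          edges[[f]] <- cbind(frame = f, from = from[keep], to = to[keep])
      }
    }
    state <- nxt
  }
  e <- do.call(rbind, edges)
  if (is.null(e)) e <- matrix(integer(0), 0, 3,
                              dimnames = list(NULL, c("frame", "from", "to")))
  list(times = times, phi = phi_rec, x = x_rec, y = y_rec, g = g_rec,
       nrz = nrz, edges = e, final_x = state$x[, 1], final_y = state$x[, 2],
       final_phi = state$phi)
}

#' @export
print.flock_run <- function(x, ...) {
  cat(sprintf(paste0("<flock_run> %d agents (%d informed), %d frames, ",
                     "k = %d, rho_ds = %.3g%s\n"),
              x$n_agents, sum(x$informed), length(x$times), x$params$k,
              x$env$rho_ds,
              if (isTRUE(x$noninteracting)) ", non-interacting control" else ""))
  if (length(x$times) > 0)
    cat(sprintf("  accuracy C = %.3f, polarization = %.3f, avoidance = %.3f\n",
                accuracy(x), polarization(x), raw_avoidance(x)))
  invisible(x)
}

#' Convert a run to a long data frame
#'
#' One row per (frame, agent) with columns `frame`, `time`, `agent_id`,
#' `x`, `y`, `phi`, `informed`, `g`.
#'
#' @param run A `flock_run`.
#' @return A data frame.
#' @export
run_to_df <- function(run) {
  nf <- length(run$times)
  n <- run$n_agents
  data.frame(
    frame = rep(seq_len(nf), n),
    time = rep(run$times, n),
    agent_id = rep(seq_len(n), each = nf),
    x = as.vector(run$x), y = as.vector(run$y), phi = as.vector(run$phi),
    informed = rep(run$informed, each = nf), g = as.vector(run$g))
}

#' Write a run to disk as CSV plus JSON metadata
#'
#' Writes `<stem>_trajectory.csv` (the [run_to_df()] table),
#' `<stem>_edges.csv` (when edges were recorded) and `<stem>_meta.json`
#' (parameters, environment, seed and engine).
#'
#' @param run A `flock_run`.
#' @param stem Output path stem.
#' @return The metadata path, invisibly.
#' @export
write_run <- function(run, stem) {
  utils::write.csv(run_to_df(run), paste0(stem, "_trajectory.csv"),
                   row.names = FALSE)
  if (!is.null(run$edges))
    utils::write.csv(as.data.frame(run$edges), paste0(stem, "_edges.csv"),
                     row.names = FALSE)
  meta <- list(
    n_agents = run$n_agents, n_informed = sum(run$informed),
    seed = run$seed, engine = run$engine,
    noninteracting = isTRUE(run$noninteracting),
    params = unclass(run$params)[c("k", "v0", "gamma_s", "gamma_p",
                                   "gamma_l", "eta", "dt", "u_p", "mode",
                                   "p_direct", "signaling")],
    env = list(L = run$env$L, r = run$env$r, n_ds = nrow(run$env$ds),
               rho_ds = run$env$rho_ds),
    package_version = as.character(utils::packageVersion("flockattn")))
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(stem, "_meta.json"))
}

#' Plot a snapshot of a recorded frame
#'
#' Draws danger sites with their repulsion zones and agents as arrows
#' (red: responding to a danger site; filled: informed).
#'
#' @param x A `flock_run`.
#' @param frame Frame index (default: last recorded frame).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.flock_run <- function(x, frame = length(x$times), ...) {
  run <- x
  L <- run$env$L
  graphics::plot(NA, xlim = c(0, L), ylim = c(0, L), asp = 1,
                 xlab = "x", ylab = "y",
                 main = sprintf("t = %g", run$times[frame]), ...)
  if (nrow(run$env$ds) > 0) {
    th <- seq(0, 2 * pi, length.out = 40)
    for (l in seq_len(nrow(run$env$ds)))
      graphics::polygon(run$env$ds[l, 1] + run$env$r * cos(th),
                        run$env$ds[l, 2] + run$env$r * sin(th),
                        col = grDevices::adjustcolor("skyblue", 0.3),
                        border = NA)
    graphics::points(run$env$ds, pch = 16, cex = 0.4, col = "blue")
  }
  px <- run$x[frame, ]; py <- run$y[frame, ]; ph <- run$phi[frame, ]
  col <- ifelse(run$g[frame, ] == 1, "red", "black")
  graphics::arrows(px, py, px + 0.4 * cos(ph), py + 0.4 * sin(ph),
                   length = 0.03, col = col)
  graphics::points(px, py, pch = ifelse(run$informed, 16, 1), cex = 0.3,
                   col = col)
  invisible(run)
}
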