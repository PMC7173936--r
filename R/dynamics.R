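#' Model parameters
#'
#' Bundles the parameters of the stochastic heading dynamics. An agent
#' \eqn{i} moves at constant speed \eqn{v_0} along heading \eqn{\varphi_i}
#' and turns according to
#' \deqn{\dot\varphi_i = (1-g_i)\left[\frac{\gamma_s}{n_s}\sum_{j}
#'   \sin(\varphi_j-\varphi_i) + \gamma_p\sin(\varphi_p-\varphi_i)\right]
#'   + g_i\frac{\gamma_l}{n_l}\sum_{l}\sin(\alpha_{il}-\varphi_i)
#'   + \eta\,\xi_i(t),}
#' where the alignment sum runs over the agents in the focal attention set,
#' the repulsion sum over the attended danger sites strictly inside the
#' repulsion radius (each sum normalized by its own count, empty sums
#' contributing zero), \eqn{\alpha_{il}} is the polar angle of the shortest
#' displacement from site \eqn{l} to agent \eqn{i}, and \eqn{\xi_i} is unit
#' Gaussian white noise. The preferred-direction bias \eqn{\gamma_p} acts
#' on informed agents only.
#'
#' @param k Attention capacity (positive integer). Required.
#' @param v0 Speed (default 0.5).
#' @param gamma_s Alignment strength (default 1).
#' @param gamma_p Preferred-direction bias of informed agents (default 0.1).
#' @param gamma_l Danger-site repulsion strength (default 1).
#' @param eta Angular noise strength (default 0.25).
#' @param dt Integration time step (default 0.1).
#' @param u_p Preferred direction, a unit 2-vector (default `c(1, 0)`).
#' @param mode Attention mode, `"knn"` (base model) or `"voronoi"`
#'   (candidates restricted to Voronoi shells, see [voronoi_kno()]).
#' @param p_direct Direct-detection probability per time step (default 0,
#'   the base model).
#' @param signaling Logical; active signaling by direct responders
#'   (default `FALSE`).
#' @return An object of class `flock_params`.
#' @export
flock_params <- function(k, v0 = 0.5, gamma_s = 1, gamma_p = 0.1,
                         gamma_l = 1, eta = 0.25, dt = 0.1,
                         u_p = c(1, 0), mode = c("knn", "voronoi"),
                         p_direct = 0, signaling = FALSE) {
  mode <- match.arg(mode)
  if (length(k) != 1 || is.na(k) || k < 1 || k != round(k))
    stop("'k' must be a single positive integer")
  if (v0 <= 0) stop("'v0' must be positive")
  if (dt <= 0) stop("'dt' must be positive")
  if (eta < 0) stop("'eta' must be non-negative")
  if (p_direct < 0 || p_direct > 1)
    stop("'p_direct' must be a probability in [0, 1]")
  nu <- sqrt(sum(u_p^2))
  if (abs(nu - 1) > 1e-8) stop("'u_p' must be a unit vector")
  structure(list(k = as.integer(k), v0 = v0, gamma_s = gamma_s,
                 gamma_p = gamma_p, gamma_l = gamma_l, eta = eta, dt = dt,
                 u_p = u_p, up_angle = atan2(u_p[2], u_p[1]),
                 mode = mode, p_direct = p_direct,
                 signaling = isTRUE(signaling)),
            class = "flock_params")
}

#' @export
print.flock_params <- function(x, ...) {
  cat(sprintf(paste0("<flock_params> k = %d, v0 = %g, gamma_s = %g, ",
                     "gamma_p = %g, gamma_l = %g, eta = %g, dt = %g\n"),
              x$k, x$v0, x$gamma_s, x$gamma_p, x$gamma_l, x$eta, x$dt))
  if (x$mode != "knn" || x$p_direct > 0 || x$signaling)
    cat(sprintf("  variants: mode = %s, p_direct = %g, signaling = %s\n",
                x$mode, x$p_direct, x$signaling))
  invisible(x)
}

#' Initialize an agent state
#'
#' Positions are uniform on the box, headings uniform on \eqn{(-\pi, \pi]},
#' and `round(r_inf * n_agents)` agents (round-half-to-even) are marked as
#' informed, chosen uniformly without replacement. Alternatively an exact
#' `n_informed` count may be given.
#'
#' @param n_agents Number of agents.
#' @param box_size Side length of the periodic box.
#' @param r_inf Informed fraction in `[0, 1]` (default 0.1).
#' @param n_informed Optional exact number of informed agents; overrides
#'   `r_inf`.
#' @param seed Optional seed (leaves the caller's RNG untouched); when
#'   `NULL`, draws come from the current RNG stream.
#' @return An object of class `flock_state`: a list with `x` (n x 2
#'   positions), `phi` (headings) and `informed` (logical).
#' @export
init_state <- function(n_agents, box_size, r_inf = 0.1, n_informed = NULL,
                       seed = NULL) {
  if (is.null(n_informed)) {
    if (r_inf < 0 || r_inf > 1) stop("'r_inf' must be in [0, 1]")
    n_informed <- round(r_inf * n_agents)
  }
  if (n_informed > n_agents) stop("more informed agents than agents")
  draw <- function() {
    x <- matrix(stats::runif(2 * n_agents, 0, box_size), ncol = 2)
    phi <- stats::runif(n_agents, -pi, pi)
    informed <- logical(n_agents)
    informed[sample.int(n_agents, n_informed)] <- TRUE
    list(x = x, phi = phi, informed = informed)
  }
  s <- with_seed_local(seed, draw())
  structure(s, class = "flock_state")
}

#' @export
print.flock_state <- function(x, ...) {
  cat(sprintf("<flock_state> %d agents, %d informed\n",
              nrow(x$x), sum(x$informed)))
  invisible(x)
}

#' Deterministic turning rate of one agent
#'
#' Evaluates the drift part of the heading equation for a focal agent given
#' its attention set (see [flock_params()] for the expression). When the
#' agent responds to danger (`g = 1`) only the repulsion term acts;
#' otherwise the alignment term and, for informed agents, the
#' preferred-direction bias act. Empty sums contribute zero.
#'
#' @param focal Focal agent index.
#' @param att The focal agent's `attention_set` (after any variant
#'   modifications).
#' @param state A `flock_state`.
#' @param env A `flock_env` (needed for danger-site geometry).
#' @param params A `flock_params`.
#' @return The angular rate in radians per unit time.
#' @export
turning_rate <- function(focal, att, state, env, params) {
  phi_i <- state$phi[focal]
  if (att$g == 1) {
    ids <- att$active_ds
    disp <- minimum_image(env$ds[ids, , drop = FALSE],
                          state$x[rep(focal, length(ids)), , drop = FALSE],
                          env$L)
    alpha <- atan2(disp[, 2], disp[, 1])
    return(params$gamma_l * mean(sin(alpha - phi_i)))
  }
  rate <- 0
  soc <- att$entries$id[att$entries$kind == "agent"]
  if (length(soc) > 0)
    rate <- params$gamma_s * mean(sin(state$phi[soc] - phi_i))
  if (state$informed[focal])
    rate <- rate + params$gamma_p * sin(params$up_angle - phi_i)
  rate
}

#' Advance the whole system by one time step (reference integrator)
#'
#' Pure-R synchronous Euler-Maruyama step: all attention sets, response
#' flags and turning rates are computed from the pre-step configuration,
#' then every heading is updated as
#' `phi + rate * dt + eta * sqrt(dt) * noise` and every position advances
#' by `v0 * dt` along the post-update heading, wrapped onto the torus.
#' This is the slow reference implementation against which the compiled
#' engine is validated; it is also the engine used for the Voronoi
#' attention mode.
#'
#' RNG draws (in order): for `p_direct > 0`, one uniform per agent inside
#' at least one repulsion zone, in agent order; then one standard normal
#' per agent (skipped when `noise` is supplied).
#'
#' @param state A `flock_state`.
#' @param env A `flock_env`.
#' @param params A `flock_params`.
#' @param noise Optional vector of standard-normal increments (one per
#'   agent), for matched-noise experiments.
#' @param noninteracting Logical; when `TRUE` agents ignore each other and
#'   respond unconditionally to every repulsion zone containing them (the
#'   solitary-agent control dynamics).
#' @return The new `flock_state`, with attributes `g` (response flags) and
#'   `soc` (the per-agent social neighborhoods used, a list) describing the
#'   pre-step configuration.
#' @export
step_flock <- function(state, env, params, noise = NULL,
                       noninteracting = FALSE) {
  n <- nrow(state$x)
  if (any(!is.finite(state$x)) || any(!is.finite(state$phi)))
    stop("non-finite state for agent ",
         which(!is.finite(state$phi) | rowSums(!is.finite(state$x)) > 0)[1])
  soc <- vector("list", n)
  act <- vector("list", n)
  g <- integer(n)

  if (noninteracting) {
    for (i in seq_len(n)) {
      act[[i]] <- zones_containing_r(state$x[i, ], env)
      soc[[i]] <- integer(0)
      g[i] <- as.integer(length(act[[i]]) > 0)
    }
  } else {
    adj <- if (params$mode == "voronoi") voronoi_adjacency(state$x, env$L)
    for (i in seq_len(n)) {
      att <- if (params$mode == "voronoi")
        voronoi_kno(i, state, env, params$k, adjacency = adj)
      else select_kno(i, state, env, params$k)
      soc[[i]] <- att$entries$id[att$entries$kind == "agent"]
      act[[i]] <- att$active_ds
      g[i] <- att$g
    }
    if (params$p_direct > 0) {
      for (i in seq_len(n)) {
        inside <- zones_containing_r(state$x[i, ], env)
        if (length(inside) > 0 && stats::runif(1) < params$p_direct) {
          g[i] <- 1L
          act[[i]] <- inside
        }
      }
    }
    if (params$signaling) {
      soc_new <- soc
      for (i in seq_len(n)) {
        if (g[i] == 1) next
        sig <- soc[[i]][g[soc[[i]]] == 1]
        if (length(sig) > 0) soc_new[[i]] <- sig
      }
      soc <- soc_new
    }
  }

  rate <- numeric(n)
  for (i in seq_len(n)) {
    if (g[i] == 1) {
      ids <- act[[i]]
      disp <- minimum_image(env$ds[ids, , drop = FALSE],
                            state$x[rep(i, length(ids)), , drop = FALSE],
                            env$L)
      alpha <- atan2(disp[, 2], disp[, 1])
      rate[i] <- params$gamma_l * mean(sin(alpha - state$phi[i]))
    } else {
      r_al <- if (length(soc[[i]]) > 0)
        params$gamma_s * mean(sin(state$phi[soc[[i]]] - state$phi[i])) else 0
      r_p <- if (state$informed[i])
        params$gamma_p * sin(params$up_angle - state$phi[i]) else 0
      rate[i] <- r_al + r_p
    }
  }

  if (is.null(noise)) noise <- stats::rnorm(n)
  phi_new <- wrap_angle(state$phi + rate * params$dt +
                          params$eta * sqrt(params$dt) * noise)
  x_new <- (state$x + params$v0 * params$dt * cbind(cos(phi_new),
                                                    sin(phi_new))) %% env$L
  out <- structure(list(x = x_new, phi = phi_new, informed = state$informed),
                   class = "flock_state")
  attr(out, "g") <- g
  attr(out, "soc") <- soc
  out
}

# wrap angles into (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi)
  w[w <= 0] <- w[w <= 0] + 2 * pi
  w - pi
}
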