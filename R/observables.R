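#' Collective accuracy, polarization, avoidance and fitness
#'
#' `accuracy` is the stationary collective accuracy
#' \eqn{C = \langle N^{-1}\sum_j \hat u_j \cdot \hat u_p \rangle}: the
#' time average over recorded frames of the mean projection of unit
#' headings on the preferred direction. `polarization` is
#' \eqn{\tilde C = \langle |N^{-1}\sum_j \hat u_j| \rangle}, the
#' time-averaged magnitude of the mean heading vector (the consensus
#' order parameter, informative also when no agent is informed).
#' `raw_avoidance` is \eqn{\tilde A = 1 - \langle N_{rz}(t)/N \rangle}
#' with \eqn{N_{rz}} the number of agents inside at least one repulsion
#' zone; `avoidance_ratio` rescales it by the same quantity for
#' non-interacting agents, \eqn{A = \tilde A / \tilde A_{ni}}, so that
#' \eqn{A = 1} means parity with solitary individuals. `fitness` is
#' \eqn{F(C, A) = C + \beta (A - 1)}: zero for the solitary reference
#' point \eqn{(C, A) = (0, 1)} at every \eqn{\beta}.
#'
#' @param run A `flock_run`, or for the matrix methods a frames x agents
#'   matrix of headings.
#' @param u_p Preferred direction (default: the run's parameter).
#' @return A single number.
#' @name order_parameters
NULL

#' @rdname order_parameters
#' @export
accuracy <- function(run, u_p = NULL) {
  phi <- frame_headings(run)
  if (is.null(u_p))
    u_p <- if (inherits(run, "flock_run")) run$params$u_p else c(1, 0)
  up_angle <- atan2(u_p[2], u_p[1])
  mean(rowMeans(cos(phi - up_angle)))
}

#' @rdname order_parameters
#' @export
polarization <- function(run) {
  phi <- frame_headings(run)
  mean(sqrt(rowMeans(cos(phi))^2 + rowMeans(sin(phi))^2))
}

frame_headings <- function(run) {
  phi <- if (inherits(run, "flock_run")) run$phi else run
  if (!is.matrix(phi)) phi <- matrix(phi, nrow = 1)
  if (nrow(phi) == 0) stop("no recorded frames")
  phi
}

#' @rdname order_parameters
#' @param env Optional `flock_env`; when supplied, zone membership is
#'   recomputed from the recorded positions instead of using the per-frame
#'   counts stored in the run (useful to re-score a trajectory against a
#'   different danger-site field).
#' @export
raw_avoidance <- function(run, env = NULL) {
  stopifnot(inherits(run, "flock_run"))
  if (length(run$nrz) == 0) stop("no recorded frames")
  if (is.null(env)) return(1 - mean(run$nrz / run$n_agents))
  if (nrow(env$ds) == 0) return(1)
  inside <- vapply(seq_along(run$times), function(f) {
    p <- cbind(run$x[f, ], run$y[f, ])
    in_zone <- rep(FALSE, nrow(p))
    for (l in seq_len(nrow(env$ds))) {
      d <- torus_distance(p, env$ds[rep(l, nrow(p)), , drop = FALSE], env$L)
      in_zone <- in_zone | d < env$r
    }
    sum(in_zone)
  }, numeric(1))
  1 - mean(inside / run$n_agents)
}

#' @rdname order_parameters
#' @param a_main,a_control Raw avoidance of the focal run and of the
#'   paired non-interacting control.
#' @export
avoidance_ratio <- function(a_main, a_control) {
  if (any(a_control == 0)) stop("control avoidance is zero; ratio undefined")
  a_main / a_control
}

#' @rdname order_parameters
#' @param C,A Accuracy and avoidance ratio.
#' @param beta Relative benefit of avoidance versus accuracy.
#' @export
fitness <- function(C, A, beta) C + beta * (A - 1)

#' Build the social interaction network of one frame
#'
#' Directed graph with an edge `i -> j` for every agent `j` in agent `i`'s
#' social out-neighborhood at that frame; agents responding to a danger
#' site have out-degree zero (they ignore their neighbors) but may retain
#' a positive in-degree. Vertex attributes `informed` and `g` are set.
#'
#' @param run A `flock_run` recorded with `record_edges = TRUE`.
#' @param frame Frame index.
#' @return An [igraph::graph] object with `run$n_agents` vertices.
#' @export
interaction_network <- function(run, frame) {
  e <- frame_edges(run, frame)
  gr <- igraph::graph_from_edgelist(e, directed = TRUE)
  gr <- igraph::add_vertices(gr, max(0, run$n_agents - igraph::vcount(gr)))
  igraph::set_vertex_attr(
    igraph::set_vertex_attr(gr, "informed", value = run$informed),
    "g", value = run$g[frame, ])
}

frame_edges <- function(run, frame) {
  if (is.null(run$edges))
    stop("run was recorded without edges (record_edges = FALSE)")
  e <- run$edges[run$edges[, "frame"] == frame, c("from", "to"), drop = FALSE]
  e
}

#' Connected components of the interaction network over time
#'
#' Components of the undirected projection of each frame's interaction
#' network (isolated agents count as their own component).
#'
#' @param run A `flock_run` recorded with edges.
#' @param frames Frame indices (default: all).
#' @return A list with `n_components` (per frame), `mean_components`, and
#'   `sizes` (list of per-frame component size vectors).
#' @export
component_stats <- function(run, frames = seq_along(run$times)) {
  sizes <- lapply(frames, function(f) {
    gr <- igraph::as_undirected(interaction_network(run, f), mode = "collapse")
    as.integer(igraph::components(gr)$csize)
  })
  n_comp <- lengths(sizes)
  list(n_components = n_comp, mean_components = mean(n_comp), sizes = sizes)
}

#' Fractions of direct and first-order indirect responders
#'
#' Per frame, `r_d` is the fraction of agents directly responding to a
#' danger site (`g = 1`) and `r_i` the fraction of agents that are not
#' responding themselves but pay attention to at least one direct
#' responder (an out-edge to a `g = 1` agent). Both are averaged over the
#' recorded frames; fractions are of the entire collective.
#'
#' @param run A `flock_run` recorded with edges.
#' @return A list with `r_d`, `r_i` (time averages) and the per-frame
#'   vectors `r_d_t`, `r_i_t`.
#' @export
responder_fractions <- function(run) {
  nf <- length(run$times)
  n <- run$n_agents
  r_d_t <- rowMeans(run$g == 1)
  r_i_t <- vapply(seq_len(nf), function(f) {
    e <- frame_edges(run, f)
    if (nrow(e) == 0) return(0)
    resp <- run$g[f, ] == 1
    length(unique(e[resp[e[, 2]], 1])) / n
  }, numeric(1))
  list(r_d = mean(r_d_t), r_i = mean(r_i_t), r_d_t = r_d_t, r_i_t = r_i_t)
}

#' Pooled in/out-degree distribution of the interaction network
#'
#' Degrees are taken on the directed network of each recorded frame and
#' pooled over frames.
#'
#' @param run A `flock_run` recorded with edges.
#' @return A data frame `(degree_in, degree_out, count)` over pooled
#'   (frame, agent) observations.
#' @export
degree_table <- function(run) {
  nf <- length(run$times)
  n <- run$n_agents
  din <- dout <- integer(0)
  for (f in seq_len(nf)) {
    e <- frame_edges(run, f)
    dout <- c(dout, tabulate(e[, 1], nbins = n))
    din <- c(din, tabulate(e[, 2], nbins = n))
  }
  agg <- stats::aggregate(
    list(count = rep(1L, length(din))),
    by = list(degree_in = din, degree_out = dout), FUN = sum)
  agg[order(agg$degree_in, agg$degree_out), ]
}

#' Mean lifetime of interaction-network edges
#'
#' An undirected edge's lifetime is the length of a maximal run of
#' consecutive recorded frames in which it is present, multiplied by the
#' frame spacing. Runs touching the first or last recorded frame are
#' censored: by default they are included at their observed length.
#'
#' @param run A `flock_run` with at least two recorded frames, equally
#'   spaced.
#' @param include_censored Logical; include runs truncated by the
#'   observation window (default `TRUE`).
#' @return Mean lifetime in time units (`NA` if no runs qualify).
#' @export
edge_lifetime <- function(run, include_censored = TRUE) {
  nf <- length(run$times)
  if (nf < 2) stop("edge lifetimes require at least two recorded frames")
  spacing <- diff(run$times)
  if (max(abs(spacing - spacing[1])) > 1e-9)
    stop("recorded frames are not equally spaced")
  e <- run$edges
  if (is.null(e)) stop("run was recorded without edges")
  key <- (pmin(e[, "from"], e[, "to"]) - 1) * run$n_agents +
    pmax(e[, "from"], e[, "to"])
  u <- !duplicated(cbind(e[, "frame"], key))
  fr <- e[u, "frame"]
  key <- key[u]
  o <- order(key, fr)
  fr <- fr[o]; key <- key[o]
  new_run <- c(TRUE, diff(key) != 0 | diff(fr) != 1)
  run_id <- cumsum(new_run)
  len <- tabulate(run_id)
  if (!include_censored) {
    first <- fr[new_run]
    last <- first + len - 1
    len <- len[first > 1 & last < nf]
  }
  if (length(len) == 0) return(NA_real_)
  mean(len) * spacing[1]
}

#' Summarize a run into its scalar observables
#'
#' @param run A `flock_run`.
#' @param a_control Optional raw avoidance of a paired non-interacting
#'   control; enables `A` and `F`.
#' @param beta Avoidance benefit used for the fitness value (default 1).
#' @return A one-row data frame with `C`, `C_tilde`, `A_raw`, `A`, `F`,
#'   `r_d`, `r_i`, and `mean_components` (network columns are `NA` when
#'   edges were not recorded).
#' @export
run_summary <- function(run, a_control = NULL, beta = 1) {
  a_raw <- raw_avoidance(run)
  A <- if (is.null(a_control)) NA_real_ else avoidance_ratio(a_raw, a_control)
  has_edges <- !is.null(run$edges)
  rf <- if (has_edges) responder_fractions(run) else list(r_d = mean(run$g == 1),
                                                          r_i = NA_real_)
  data.frame(
    C = accuracy(run), C_tilde = polarization(run), A_raw = a_raw, A = A,
    F = if (is.na(A)) NA_real_ else fitness(accuracy(run), A, beta),
    r_d = rf$r_d, r_i = rf$r_i,
    mean_components = if (has_edges) component_stats(run)$mean_components
                      else NA_real_)
}
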