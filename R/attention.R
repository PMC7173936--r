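#' Select the k nearest objects of a focal agent
#'
#' Implements the attention bottleneck at the heart of the model: a focal
#' agent can attend to at most `k` objects simultaneously, and those slots
#' are filled by the `k` globally nearest objects -- other agents (social
#' cues) and danger sites (non-social cues) compete for the same slots,
#' ranked purely by torus distance. A danger site beyond the repulsion
#' radius still occupies a slot even though the agent never reacts to it.
#'
#' Exact distance ties are broken by object index (agents in index order
#' first, then danger sites in index order), which makes the selection
#' deterministic; for continuous positions ties are a measure-zero event.
#'
#' @param focal Index of the focal agent (1-based).
#' @param state A `flock_state` (see [init_state()]).
#' @param env A `flock_env` (see [env_random()]).
#' @param k Attention capacity (number of slots), a positive integer.
#' @return An object of class `attention_set`: a list with
#'   \describe{
#'     \item{focal}{the focal index,}
#'     \item{entries}{a data frame `(id, kind, dist)` ordered by increasing
#'       distance, `kind` either `"agent"` or `"ds"`,}
#'     \item{n_s}{number of agent entries,}
#'     \item{n_l_active}{number of danger-site entries with `dist < r`,}
#'     \item{g}{binary response flag (1 iff `n_l_active >= 1`),}
#'     \item{active_ds}{ids of the danger sites the agent responds to.}
#'   }
#' @seealso [danger_response()], [voronoi_kno()]
#' @export
select_kno <- function(focal, state, env, k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k != round(k))
    stop("'k' must be a single positive integer")
  n <- nrow(state$x)
  others <- setdiff(seq_len(n), focal)
  p <- state$x[rep(focal, length(others) + nrow(env$ds)), , drop = FALSE]
  obj <- rbind(state$x[others, , drop = FALSE], env$ds)
  dist <- torus_distance(p, obj, env$L)
  kind <- rep(c("agent", "ds"), c(length(others), nrow(env$ds)))
  id <- c(others, seq_len(nrow(env$ds)))
  # tie-break on the combined object index: agents before danger sites
  ord <- order(dist, c(others, n + seq_len(nrow(env$ds))))
  take <- ord[seq_len(min(k, length(ord)))]
  entries <- data.frame(id = id[take], kind = kind[take], dist = dist[take])
  new_attention_set(focal, entries, env$r)
}

new_attention_set <- function(focal, entries, r) {
  active <- entries$kind == "ds" & entries$dist < r
  structure(list(
    focal = focal, entries = entries,
    n_s = sum(entries$kind == "agent"),
    n_l_active = sum(active),
    g = as.integer(any(active)),
    active_ds = entries$id[active]), class = "attention_set")
}

#' Evaluate the danger-response switch of an attention set
#'
#' An agent responds to danger (`g = 1`) iff at least one danger site both
#' occupies one of its attention slots and lies strictly inside the
#' repulsion radius `r`. While responding, the agent ignores all social
#' cues. Sites in the attention set but outside the repulsion zone are
#' perceived-but-ignored.
#'
#' @param att An `attention_set`.
#' @param r Repulsion radius.
#' @return A list with `g` (0/1) and `active_ds` (ids of sites with
#'   `dist < r` among the entries; empty when `g = 0`).
#' @export
danger_response <- function(att, r) {
  stopifnot(inherits(att, "attention_set"))
  active <- att$entries$kind == "ds" & att$entries$dist < r
  list(g = as.integer(any(active)), active_ds = att$entries$id[active])
}

#' Direct detection of danger sites (attention-bias variant)
#'
#' In the direct-detection variant an agent standing inside at least one
#' repulsion zone detects the danger with probability `p_direct` per time
#' step, regardless of whether any site occupies an attention slot. A
#' successful draw forces `g = 1` with the active set equal to all zones
#' containing the agent. With `p_direct = 0` the base model is recovered;
#' `p_direct = 1` is perfect detection.
#'
#' One Bernoulli draw is consumed from the R RNG if and only if the focal
#' agent is inside at least one zone.
#'
#' @param focal Focal agent index.
#' @param state A `flock_state`.
#' @param env A `flock_env`.
#' @param p_direct Detection probability per time step, in `[0, 1]`.
#' @return A list with `override` (logical) and `active_ds` (ids of all
#'   zones containing the agent when `override` is `TRUE`).
#' @export
direct_detection <- function(focal, state, env, p_direct) {
  if (length(p_direct) != 1 || is.na(p_direct) || p_direct < 0 || p_direct > 1)
    stop("'p_direct' must be a probability in [0, 1]")
  inside <- zones_containing_r(state$x[focal, ], env)
  if (length(inside) == 0 || !(p_direct > 0))
    return(list(override = FALSE, active_ds = integer(0)))
  if (stats::runif(1) < p_direct)
    list(override = TRUE, active_ds = inside)
  else
    list(override = FALSE, active_ds = integer(0))
}

# ids of danger sites whose repulsion zone strictly contains point `p`
zones_containing_r <- function(p, env) {
  if (nrow(env$ds) == 0) return(integer(0))
  d <- torus_distance(matrix(p, nrow(env$ds), 2, byrow = TRUE), env$ds, env$L)
  which(d < env$r)
}

#' Active signaling by direct responders
#'
#' In the signaling variant, agents responding to a danger site advertise
#' it: every non-responding agent whose social neighborhood contains at
#' least one responder puts its full attention on the responder(s) and
#' ignores all other social cues. Responders themselves are unchanged.
#'
#' @param att_list List of `attention_set`s, one per agent (in agent order).
#' @param g Integer vector of response flags, one per agent.
#' @return The modified list of attention sets: for affected agents the
#'   agent entries are reduced to the signaling neighbors (`n_s` updated);
#'   danger-site entries are kept.
#' @export
apply_signaling <- function(att_list, g) {
  stopifnot(length(att_list) == length(g))
  lapply(att_list, function(att) {
    if (att$g == 1) return(att)
    e <- att$entries
    is_sig <- e$kind == "agent" & g[ifelse(e$kind == "agent", e$id, 1)] == 1
    if (!any(is_sig)) return(att)
    att$entries <- e[is_sig | e$kind == "ds", , drop = FALSE]
    att$n_s <- sum(is_sig)
    att
  })
}

#' @export
print.attention_set <- function(x, ...) {
  cat(sprintf("<attention_set> focal %d: %d entries (%d agents, %d sites), g = %d\n",
              x$focal, nrow(x$entries), x$n_s,
              sum(x$entries$kind == "ds"), x$g))
  invisible(x)
}
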