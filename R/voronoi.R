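#' Voronoi adjacency of agents on the torus
#'
#' Computes, for every agent, the set of first-shell Voronoi neighbors
#' (agents whose Voronoi cells share an edge with the focal cell). The
#' periodic tessellation is obtained by tiling the box 3 x 3 and clipping
#' each focal cell by the perpendicular-bisector half-planes of nearby
#' points (Sutherland-Hodgman polygon clipping); a tiled point contributes
#' a neighbor when one of the resulting cell edges lies on its bisector.
#' Danger sites take no part in the tessellation.
#'
#' @param x An n x 2 matrix of agent positions in `[0, L)^2`.
#' @param box_size Side length of the periodic box.
#' @return A list of integer vectors, element `i` holding the sorted agent
#'   indices adjacent to agent `i`. Degenerate configurations (duplicated
#'   positions, or a numerically collapsed cell) raise an error of class
#'   `flockattn_degenerate`.
#' @export
voronoi_adjacency <- function(x, box_size) {
  n <- nrow(x)
  if (n < 4) stop("Voronoi tessellation requires at least 4 agents")
  if (anyDuplicated(round(x / (1e-12 * box_size))) > 0)
    stop(structure(class = c("flockattn_degenerate", "error", "condition"),
                   list(message = "duplicated agent positions", call = NULL)))
  off <- as.matrix(expand.grid(ox = c(-1, 0, 1) * box_size,
                               oy = c(-1, 0, 1) * box_size))
  tiled <- x[rep(seq_len(n), nrow(off)), , drop = FALSE] +
    off[rep(seq_len(nrow(off)), each = n), , drop = FALSE]
  owner <- rep(seq_len(n), nrow(off))
  tol <- 1e-9 * box_size
  lapply(seq_len(n), function(i) {
    p0 <- x[i, ]
    d2 <- (tiled[, 1] - p0[1])^2 + (tiled[, 2] - p0[2])^2
    ord <- order(d2)
    ord <- ord[d2[ord] > tol^2]      # drop the focal point itself
    # starting cell: a square certainly containing the true Voronoi cell
    poly <- cbind(p0[1] + c(-1, 1, 1, -1) * box_size,
                  p0[2] + c(-1, -1, 1, 1) * box_size)
    for (j in ord) {
      dq <- sqrt(d2[j])
      vmax2 <- max((poly[, 1] - p0[1])^2 + (poly[, 2] - p0[2])^2)
      if (dq * dq > 4 * vmax2) break  # bisector cannot cut the cell
      poly <- clip_halfplane(poly, p0, tiled[j, ])
      if (nrow(poly) < 3)
        stop(structure(class = c("flockattn_degenerate", "error", "condition"),
                       list(message = "degenerate Voronoi cell", call = NULL)))
    }
    # neighbors: tiled points with a cell vertex on their bisector
    v2_focal <- (poly[, 1] - p0[1])^2 + (poly[, 2] - p0[2])^2
    nb <- integer(0)
    for (j in ord) {
      if (d2[j] > 4 * max(v2_focal)) break
      v2_q <- (poly[, 1] - tiled[j, 1])^2 + (poly[, 2] - tiled[j, 2])^2
      if (min(abs(v2_q - v2_focal)) < tol * box_size) nb <- c(nb, owner[j])
    }
    sort(unique(setdiff(nb, i)))
  })
}

# clip convex polygon to the half-plane of points closer to `a` than `b`
clip_halfplane <- function(poly, a, b) {
  m <- (a + b) / 2
  nrm <- b - a                      # constraint: (p - m) . nrm <= 0
  s <- (poly[, 1] - m[1]) * nrm[1] + (poly[, 2] - m[2]) * nrm[2]
  np <- nrow(poly)
  out <- matrix(numeric(0), 0, 2)
  for (v in seq_len(np)) {
    w <- if (v == np) 1L else v + 1L
    if (s[v] <= 0) out <- rbind(out, poly[v, ])
    if ((s[v] <= 0) != (s[w] <= 0)) {
      t <- s[v] / (s[v] - s[w])
      out <- rbind(out, poly[v, ] + t * (poly[w, ] - poly[v, ]))
    }
  }
  out
}

#' Voronoi-restricted k-nearest-object selection
#'
#' Variant of [select_kno()] in which the candidate social neighbors are
#' restricted to the focal agent's first Voronoi shell, extended by the
#' second shell (Voronoi neighbors of first-shell members) when the first
#' shell holds fewer than `k` agents. Danger sites are treated as in the
#' base model: they compete for attention slots by distance alone. Among
#' the admissible objects the `k` nearest are selected.
#'
#' If the tessellation is degenerate the function falls back to the base
#' [select_kno()] selection with a warning.
#'
#' @inheritParams select_kno
#' @param adjacency Optional precomputed result of [voronoi_adjacency()]
#'   (avoids retessellating when selecting for many focal agents).
#' @return An `attention_set`; see [select_kno()].
#' @export
voronoi_kno <- function(focal, state, env, k, adjacency = NULL) {
  if (length(k) != 1 || is.na(k) || k < 1 || k != round(k))
    stop("'k' must be a single positive integer")
  adj <- adjacency
  if (is.null(adj)) {
    adj <- tryCatch(voronoi_adjacency(state$x, env$L),
                    flockattn_degenerate = function(e) NULL)
    if (is.null(adj)) {
      warning("degenerate Voronoi configuration; falling back to base kNO")
      return(select_kno(focal, state, env, k))
    }
  }
  cand <- adj[[focal]]
  if (length(cand) < k)
    cand <- sort(unique(setdiff(c(cand, unlist(adj[cand])), focal)))
  n <- nrow(state$x)
  p <- state$x[rep(focal, length(cand) + nrow(env$ds)), , drop = FALSE]
  obj <- rbind(state$x[cand, , drop = FALSE], env$ds)
  dist <- torus_distance(p, obj, env$L)
  kind <- rep(c("agent", "ds"), c(length(cand), nrow(env$ds)))
  id <- c(cand, seq_len(nrow(env$ds)))
  ord <- order(dist, c(cand, n + seq_len(nrow(env$ds))))
  take <- ord[seq_len(min(k, length(ord)))]
  new_attention_set(focal,
                    data.frame(id = id[take], kind = kind[take],
                               dist = dist[take]),
                    env$r)
}
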