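# Fixture constructors and independent brute-force oracles used across the
# suite. The oracles deliberately avoid the package's own geometry helpers:
# torus distances are computed by enumerating the nine periodic images.

manual_state <- function(x, phi, informed = rep(FALSE, nrow(x))) {
  structure(list(x = x, phi = phi, informed = informed),
            class = "flock_state")
}

manual_env <- function(ds, L, r = 1) {
  if (!is.matrix(ds)) ds <- matrix(ds, ncol = 2, byrow = TRUE)
  flockattn:::new_flock_env(L, r, ds)
}

# minimal flock_run for observable unit tests
manual_run <- function(phi, g = NULL, edges = NULL, nrz = NULL,
                       times = NULL, informed = NULL, x = NULL, y = NULL,
                       env = manual_env(matrix(numeric(0), 0, 2), 10)) {
  phi <- as.matrix(phi)
  nf <- nrow(phi); n <- ncol(phi)
  if (is.null(g)) g <- matrix(0L, nf, n)
  if (is.null(nrz)) nrz <- integer(nf)
  if (is.null(times)) times <- seq_len(nf)
  if (is.null(informed)) informed <- rep(FALSE, n)
  if (!is.null(edges)) colnames(edges) <- c("frame", "from", "to")
  structure(list(times = times, phi = phi,
                 x = if (is.null(x)) phi * 0 else x,
                 y = if (is.null(y)) phi * 0 else y,
                 g = g, nrz = nrz, edges = edges, informed = informed,
                 env = env, params = flock_params(k = 1), n_agents = n),
            class = "flock_run")
}

# torus distance by explicit enumeration of the nine periodic images
image_distance <- function(a, b, L) {
  best <- Inf
  for (ox in c(-L, 0, L)) for (oy in c(-L, 0, L)) {
    d <- sqrt((b[1] + ox - a[1])^2 + (b[2] + oy - a[2])^2)
    if (d < best) best <- d
  }
  best
}

# exhaustive-sort oracle for k-nearest-object selection
bf_kno <- function(focal, state, env, k) {
  n <- nrow(state$x)
  ids <- kinds <- c(); dists <- numeric(0); combined <- c()
  for (j in seq_len(n)) {
    if (j == focal) next
    ids <- c(ids, j); kinds <- c(kinds, "agent"); combined <- c(combined, j)
    dists <- c(dists, image_distance(state$x[focal, ], state$x[j, ], env$L))
  }
  for (l in seq_len(nrow(env$ds))) {
    ids <- c(ids, l); kinds <- c(kinds, "ds"); combined <- c(combined, n + l)
    dists <- c(dists, image_distance(state$x[focal, ], env$ds[l, ], env$L))
  }
  ord <- order(dists, combined)
  take <- ord[seq_len(min(k, length(ord)))]
  data.frame(id = ids[take], kind = kinds[take], dist = dists[take])
}

# flood-fill (BFS) connected-components oracle on an undirected edge list
bf_components <- function(n, edges) {
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n); sizes <- integer(0)
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; size <- 0
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]; size <- size + 1
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# Voronoi adjacency oracle: two points are neighbors iff their bisector
# carries a segment closer to them than to every other tiled point
# (linear-constraint interval intersection; independent of polygon clipping)
bf_voronoi_adjacency <- function(x, L) {
  n <- nrow(x)
  off <- as.matrix(expand.grid(c(-1, 0, 1) * L, c(-1, 0, 1) * L))
  tiled <- x[rep(seq_len(n), nrow(off)), , drop = FALSE] +
    off[rep(seq_len(nrow(off)), each = n), , drop = FALSE]
  owner <- rep(seq_len(n), nrow(off))
  lapply(seq_len(n), function(i) {
    a <- x[i, ]
    nb <- integer(0)
    for (j in seq_len(nrow(tiled))) {
      b <- tiled[j, ]
      if (sum((b - a)^2) < 1e-18) next
      m <- (a + b) / 2
      u <- c(-(b - a)[2], (b - a)[1])
      u <- u / sqrt(sum(u^2))
      lo <- -3 * L; hi <- 3 * L
      for (s in seq_len(nrow(tiled))) {
        p <- tiled[s, ]
        if (sum((p - a)^2) < 1e-18 || sum((p - b)^2) < 1e-18) next
        # require |q - a|^2 < |q - p|^2 for q = m + t u: c0 + c1 t < 0
        c0 <- sum((m - a)^2) - sum((m - p)^2)
        c1 <- 2 * sum(u * (p - a))
        if (abs(c1) < 1e-14) {
          if (c0 >= 0) { lo <- 1; hi <- 0; break }
        } else if (c1 > 0) hi <- min(hi, -c0 / c1)
        else lo <- max(lo, -c0 / c1)
        if (lo >= hi) break
      }
      if (lo < hi - 1e-12) nb <- c(nb, owner[j])
    }
    sort(unique(setdiff(nb, i)))
  })
}
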