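#' Generate a random danger-site field
#'
#' Creates a square periodic arena of side `box_size` containing `n_ds`
#' point-like danger sites placed independently and uniformly at random.
#' Each site is surrounded by a disc-shaped repulsion zone of radius
#' `repulsion_radius`; zones may overlap. Site positions are fixed for the
#' lifetime of the environment.
#'
#' @param n_ds Number of danger sites (non-negative integer).
#' @param box_size Side length \eqn{L} of the periodic box.
#' @param repulsion_radius Repulsion-zone radius \eqn{r} (default 1).
#' @param seed Optional integer seed; when given, site placement is
#'   reproducible and the caller's RNG state is left untouched.
#' @return An object of class `flock_env`: a list with elements `L`, `r`,
#'   `ds` (an `n_ds` x 2 matrix of coordinates in `[0, L)`), and the derived
#'   areal density `rho_ds = n_ds / L^2`.
#' @examples
#' env <- env_random(125, 25, seed = 1)
#' env$rho_ds  # 0.2
#' @export
env_random <- function(n_ds, box_size, repulsion_radius = 1, seed = NULL) {
  if (length(n_ds) != 1 || is.na(n_ds) || n_ds < 0 || n_ds != round(n_ds))
    stop("'n_ds' must be a single non-negative integer")
  check_box(box_size, repulsion_radius)
  ds <- with_seed_local(seed, {
    matrix(stats::runif(2 * n_ds, 0, box_size), ncol = 2)
  })
  new_flock_env(box_size, repulsion_radius, ds)
}

#' Generate a structured environment with a circular danger-free path
#'
#' Danger sites are drawn uniformly over the box at areal density
#' `ds_density`, then every site whose center falls inside the annulus
#' `path_radius` +/- `path_width / 2` around `path_center` is rejected
#' (not re-drawn), leaving an exactly danger-free circular corridor. The
#' realized global density is therefore slightly below nominal.
#'
#' @param box_size Side length \eqn{L} of the periodic box.
#' @param ds_density Nominal areal danger-site density \eqn{\rho_{DS}}.
#' @param path_center Center of the circular path; default the box center.
#' @param path_radius Mid-line radius of the path; default `box_size / 3`.
#' @param path_width Radial width of the danger-free corridor; default 3.
#' @param repulsion_radius Repulsion-zone radius \eqn{r} (default 1).
#' @param seed Optional integer seed.
#' @return A `flock_env` object; see [env_random()].
#' @export
env_structured <- function(box_size, ds_density,
                           path_center = c(box_size / 2, box_size / 2),
                           path_radius = box_size / 3, path_width = 3,
                           repulsion_radius = 1, seed = NULL) {
  check_box(box_size, repulsion_radius)
  if (ds_density < 0) stop("'ds_density' must be non-negative")
  if (path_width < 0) stop("'path_width' must be non-negative")
  if (path_radius - path_width / 2 <= 0 ||
      path_radius + path_width / 2 >= box_size / 2)
    stop("circular path (radius ", path_radius, ", width ", path_width,
         ") does not fit in a box of size ", box_size)
  n_try <- round(ds_density * box_size^2)
  ds <- with_seed_local(seed, {
    matrix(stats::runif(2 * n_try, 0, box_size), ncol = 2)
  })
  if (n_try > 0) {
    d <- torus_distance(ds, matrix(path_center, nrow(ds), 2, byrow = TRUE),
                        box_size)
    keep <- abs(d - path_radius) > path_width / 2
    ds <- ds[keep, , drop = FALSE]
  }
  env <- new_flock_env(box_size, repulsion_radius, ds)
  env$path <- list(center = path_center, radius = path_radius,
                   width = path_width)
  env
}

new_flock_env <- function(L, r, ds) {
  stopifnot(is.matrix(ds), ncol(ds) == 2)
  structure(list(L = L, r = r, ds = ds, rho_ds = nrow(ds) / L^2),
            class = "flock_env")
}

check_box <- function(box_size, repulsion_radius) {
  if (length(box_size) != 1 || is.na(box_size) || box_size <= 0)
    stop("'box_size' must be a single positive number")
  if (repulsion_radius <= 0) stop("'repulsion_radius' must be positive")
  invisible(TRUE)
}

# evaluate `expr` under a temporary seed without disturbing the caller's RNG
with_seed_local <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Shortest displacement and distance on the torus
#'
#' `minimum_image(a, b, L)` returns the shortest displacement from `a` to
#' `b` under periodic boundary conditions, each component in
#' `[-L/2, L/2)`. `torus_distance` is its Euclidean norm. Both accept
#' single points (length-2 vectors) or n x 2 matrices.
#'
#' @param a,b Points in `[0, L)^2`: length-2 vectors or n x 2 matrices.
#' @param box_size Side length \eqn{L} of the periodic box.
#' @return `minimum_image`: a vector or matrix of displacements;
#'   `torus_distance`: a numeric vector of distances.
#' @examples
#' minimum_image(c(0.5, 0.5), c(24.9, 0.5), 25)  # c(-0.6, 0)
#' @export
minimum_image <- function(a, b, box_size) {
  d <- b - a
  ((d + box_size / 2) %% box_size) - box_size / 2
}

#' @rdname minimum_image
#' @export
torus_distance <- function(a, b, box_size) {
  d <- minimum_image(a, b, box_size)
  if (is.matrix(d)) sqrt(rowSums(d^2)) else sqrt(sum(d^2))
}

#' Read or write an environment as JSON
#'
#' The on-disk format is `{"L": ..., "r": ..., "ds": [[x, y], ...]}`.
#'
#' @param env A `flock_env` object.
#' @param path File path.
#' @return `env_read_json` returns a `flock_env`; `env_write_json` returns
#'   `path` invisibly.
#' @export
env_write_json <- function(env, path) {
  stopifnot(inherits(env, "flock_env"))
  jsonlite::write_json(
    list(L = env$L, r = env$r, ds = unname(env$ds)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname env_write_json
#' @export
env_read_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ds <- if (length(j$ds) == 0) matrix(numeric(0), 0, 2) else
    matrix(as.numeric(j$ds), ncol = 2)
  new_flock_env(j$L, j$r, ds)
}

#' @export
print.flock_env <- function(x, ...) {
  cat(sprintf("<flock_env> L = %g, r = %g, %d danger sites (rho_ds = %.4g)\n",
              x$L, x$r, nrow(x$ds), x$rho_ds))
  if (!is.null(x$path))
    cat(sprintf("  danger-free circular path: radius %g, width %g\n",
                x$path$radius, x$path$width))
  invisible(x)
}
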