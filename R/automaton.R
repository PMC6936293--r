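#' Automaton parameters
#'
#' The excitable automaton is governed by three integers: the excitation
#' threshold `theta` (a resting voxel excites iff its count of excited
#' neighbours is *strictly* greater than `theta`), the refractory delay
#' `delta` (an excited voxel stays refractory for `delta + 1` steps before
#' resting again), and the neighbourhood radius `radius` (Euclidean, in
#' voxel index units). The defaults `theta = 7`, `delta = 20`,
#' `radius = 3` are the machine-construction values selected by gate-count
#' maximization on the laboratory network.
#'
#' @param theta Non-negative integer excitation threshold.
#' @param delta Non-negative integer refractory delay.
#' @param radius Positive integer neighbourhood radius.
#' @return An object of class `ca_params`.
#' @export
ca_params <- function(theta = 7L, delta = 20L, radius = 3L) {
  theta <- as.integer(theta); delta <- as.integer(delta)
  radius <- as.integer(radius)
  if (is.na(theta) || theta < 0L) stop("`theta` must be >= 0", call. = FALSE)
  if (is.na(delta) || delta < 0L) stop("`delta` must be >= 0", call. = FALSE)
  if (is.na(radius) || radius < 1L) stop("`radius` must be >= 1", call. = FALSE)
  structure(list(theta = theta, delta = delta, radius = radius),
            class = "ca_params")
}

#' Integer offsets of a Euclidean ball neighbourhood
#'
#' All integer displacement vectors `(dx, dy, dz)` other than the origin
#' with `dx^2 + dy^2 + dz^2 <= radius^2`. The set is symmetric under
#' negation. Sizes are 6, 32 and 122 for radii 1, 2 and 3.
#'
#' @param radius Positive integer radius.
#' @return Integer matrix, one offset per row, columns `dx`, `dy`, `dz`.
#' @export
neighbourhood_offsets <- function(radius) {
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) stop("`radius` must be >= 1", call. = FALSE)
  s <- -radius:radius
  off <- as.matrix(expand.grid(dx = s, dy = s, dz = s))
  off <- off[rowSums(off^2) <= radius^2 & rowSums(off != 0L) > 0L, ,
             drop = FALSE]
  storage.mode(off) <- "integer"
  rownames(off) <- NULL
  off
}

#' Compile a conductive matrix into a simulation network
#'
#' Extracts the conductive voxels and precomputes the sparse neighbourhood
#' adjacency (voxel pairs at Euclidean distance `<= radius`). Positions
#' outside the grid and non-conductive voxels are inert: they never excite
#' and contribute nothing to neighbour counts, so they are simply absent
#' from the compiled network.
#'
#' @param mat A [conductive_matrix].
#' @param radius Neighbourhood radius (see [ca_params()]).
#' @return An object of class `ca_network` with fields `coords` (n x 3
#'   integer voxel coordinates), `adj` (sparse n x n pattern adjacency),
#'   `dims`, `id` (3D array mapping voxel coordinates to row index, 0 for
#'   non-conductive) and `n`.
#' @export
ca_network <- function(mat, radius = 3L) {
  stopifnot(inherits(mat, "conductive_matrix"))
  dims <- dim(mat$grid)
  coords <- which(mat$grid, arr.ind = TRUE)
  colnames(coords) <- c("i", "j", "z")
  storage.mode(coords) <- "integer"
  n <- nrow(coords)
  id <- array(0L, dim = dims)
  id[coords] <- seq_len(n)

  off <- neighbourhood_offsets(radius)
  ii <- vector("list", nrow(off)); jj <- vector("list", nrow(off))
  for (k in if (n > 0L) seq_len(nrow(off)) else integer(0)) {
    shifted <- coords + matrix(off[k, ], n, 3, byrow = TRUE)
    ok <- shifted[, 1] >= 1L & shifted[, 1] <= dims[1] &
          shifted[, 2] >= 1L & shifted[, 2] <= dims[2] &
          shifted[, 3] >= 1L & shifted[, 3] <= dims[3]
    nb <- integer(n)
    nb[ok] <- id[shifted[ok, , drop = FALSE]]
    hit <- nb > 0L
    ii[[k]] <- which(hit)
    jj[[k]] <- nb[hit]
  }
  adj <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                              x = rep(1, length(unlist(ii))),
                              dims = c(n, n))
  structure(list(coords = coords, adj = adj, dims = dims, id = id, n = n,
                 radius = as.integer(radius),
                 voxel_size = mat$voxel_size),
            class = "ca_network")
}

#' @export
print.ca_network <- function(x, ...) {
  cat(sprintf("<ca_network> %d conductive voxels on a %d x %d x %d grid, r = %d\n",
              x$n, x$dims[1], x$dims[2], x$dims[3], x$radius))
  invisible(x)
}

# state codes over conductive voxels
ST_RESTING <- 0L
ST_EXCITED <- 1L
ST_REFRACTORY <- 2L

#' Create a resting lattice state
#'
#' @param net A [ca_network].
#' @return An object of class `ca_lattice`: per-conductive-voxel state
#'   (`0` resting, `1` excited, `2` refractory), refractory counter `h`,
#'   and step index `t`.
#' @export
new_lattice <- function(net) {
  stopifnot(inherits(net, "ca_network"))
  structure(list(state = integer(net$n), h = integer(net$n), t = 0L),
            class = "ca_lattice")
}

#' Advance the automaton by one synchronous step
#'
#' All conductive voxels update in parallel by one rule: a resting voxel
#' excites iff its number of excited neighbours strictly exceeds `theta`;
#' an excited voxel becomes refractory with counter `h = delta`; a
#' refractory voxel with `h > 0` stays refractory and decrements `h`;
#' a refractory voxel with `h = 0` returns to resting (and may be excited
#' again one step later at the earliest).
#'
#' @param lattice A `ca_lattice`.
#' @param net The [ca_network] the lattice lives on.
#' @param params A [ca_params].
#' @return The updated `ca_lattice`.
#' @export
ca_step <- function(lattice, net, params) {
  if (length(lattice$state) != net$n)
    stop("lattice does not match the network size", call. = FALSE)
  state <- lattice$state
  h <- lattice$h
  excited <- state == ST_EXCITED
  sigma <- as.integer(round(as.numeric(net$adj %*% excited)))

  to_excite <- state == ST_RESTING & sigma > params$theta
  to_refract <- excited | (state == ST_REFRACTORY & h > 0L)

  new_state <- integer(net$n)
  new_state[to_refract] <- ST_REFRACTORY
  new_state[to_excite] <- ST_EXCITED

  new_h <- integer(net$n)
  fresh <- to_refract & excited
  holding <- to_refract & !excited & h > 0L
  new_h[fresh] <- params$delta
  new_h[holding] <- h[holding] - 1L

  structure(list(state = new_state, h = new_h, t = lattice$t + 1L),
            class = "ca_lattice")
}

#' Run the automaton for a fixed number of steps
#'
#' Applies [ca_step()] `steps` times. After each step the optional
#' `observer` is called with the updated lattice and the step index; the
#' electrode recorder uses this hook. The evolution is fully
#' deterministic.
#'
#' @param lattice Initial `ca_lattice`.
#' @param net A [ca_network].
#' @param params A [ca_params].
#' @param steps Positive integer number of steps.
#' @param observer Optional `function(lattice, t)`.
#' @return The final `ca_lattice`.
#' @export
ca_run <- function(lattice, net, params, steps, observer = NULL) {
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L) stop("`steps` must be >= 1", call. = FALSE)
  for (t in seq_len(steps)) {
    lattice <- ca_step(lattice, net, params)
    if (!is.null(observer)) observer(lattice, lattice$t)
  }
  lattice
}

#' Per-step excited-voxel counts
#'
#' Convenience trajectory summary: runs the automaton and returns the
#' total number of excited voxels after each step.
#'
#' @inheritParams ca_run
#' @return Integer vector of length `steps`.
#' @export
excitation_trajectory <- function(lattice, net, params, steps) {
  counts <- integer(steps)
  ca_run(lattice, net, params, steps,
         observer = function(l, t) counts[t] <<- sum(l$state == ST_EXCITED))
  counts
}
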