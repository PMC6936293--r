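#' Specification for a synthetic conductive network
#'
#' Synthetic networks stand in for laboratory confocal stacks: droplet
#' networks of regularly spaced actin bundles are emulated as sparse 3D
#' tube networks (edges of a Delaunay triangulation over random points,
#' rasterized as digital tubes), and two degenerate geometries — a
#' 1-voxel-wide line and a closed 1-voxel-wide ring — provide fixtures
#' with closed-form behaviour.
#'
#' @param kind `"delaunay"`, `"line"` or `"ring"`.
#' @param extent Integer length-3 grid shape `(n_x, n_y, n_z)`.
#' @param n_points Number of random points (delaunay kind; >= 4).
#' @param tube_radius Tube radius in voxels (delaunay kind; >= 0; 0 gives
#'   1-voxel-wide digital segments).
#' @param seed Integer RNG seed; a fixed seed makes the output
#'   deterministic.
#' @param axis Line axis, `"x"`, `"y"` or `"z"` (line kind).
#' @param length Line length in voxels (line kind).
#' @param origin Integer start voxel of the line; default centres the line
#'   in the extent.
#' @param radius Ring radius in voxels (ring kind).
#' @param centre Integer ring centre voxel; default the grid centre.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(kind = c("delaunay", "line", "ring"),
                       extent = c(64L, 64L, 8L),
                       n_points = 40L, tube_radius = 2, seed = 1L,
                       axis = "x", length = NULL, origin = NULL,
                       radius = NULL, centre = NULL) {
  kind <- match.arg(kind)
  extent <- as.integer(extent)
  if (length(extent) != 3L || any(extent < 1L))
    stop("`extent` must be three positive integers", call. = FALSE)
  if (tube_radius < 0) stop("`tube_radius` must be >= 0", call. = FALSE)
  if (kind == "delaunay" && n_points < 4L)
    stop("delaunay networks need at least 4 points", call. = FALSE)
  structure(list(kind = kind, extent = extent,
                 n_points = as.integer(n_points), tube_radius = tube_radius,
                 seed = as.integer(seed), axis = axis, length = length,
                 origin = origin, radius = radius, centre = centre),
            class = "synth_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic conductive network
#'
#' @param spec A [synth_spec].
#' @return A [conductive_matrix] with provenance `"synthetic"`.
#' @seealso [synth_spec()] for the geometry kinds.
#' @export
synth_network <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  grid <- switch(spec$kind,
    line = synth_line(spec),
    ring = synth_ring(spec),
    delaunay = synth_delaunay(spec)
  )
  conductive_matrix(grid, provenance = "synthetic")
}

synth_line <- function(spec) {
  ext <- spec$extent
  L <- spec$length
  if (is.null(L) || L < 1L) stop("line kind needs `length` >= 1", call. = FALSE)
  ax <- match(spec$axis, c("x", "y", "z"))
  if (is.na(ax)) stop("`axis` must be x, y or z", call. = FALSE)
  origin <- spec$origin
  if (is.null(origin)) {
    origin <- pmax(1L, ext %/% 2L)
    origin[ax] <- max(1L, (ext[ax] - L) %/% 2L + 1L)
  }
  origin <- as.integer(origin)
  end <- origin
  end[ax] <- origin[ax] + L - 1L
  if (any(origin < 1L) || any(end > ext))
    stop("line geometry exceeds the extent", call. = FALSE)
  grid <- array(FALSE, dim = ext)
  idx <- matrix(rep(origin, L), ncol = 3, byrow = TRUE)
  idx[, ax] <- origin[ax] + 0:(L - 1L)
  grid[idx] <- TRUE
  grid
}

# Digital circle in the L1 metric: |di| + |dj| == R in a single z-plane.
# Every voxel of the loop has exactly two conductive 26-neighbours, for any
# R >= 1, which makes the ring a clean closed-path fixture.
synth_ring <- function(spec) {
  ext <- spec$extent
  R <- spec$radius
  if (is.null(R) || R < 1L) stop("ring kind needs `radius` >= 1", call. = FALSE)
  centre <- spec$centre
  if (is.null(centre)) centre <- pmax(1L, ext %/% 2L)
  centre <- as.integer(centre)
  if (centre[1] - R < 1L || centre[1] + R > ext[1] ||
      centre[2] - R < 1L || centre[2] + R > ext[2] ||
      centre[3] < 1L || centre[3] > ext[3])
    stop("ring geometry exceeds the extent", call. = FALSE)
  grid <- array(FALSE, dim = ext)
  di <- rep(-R:R, each = 2L * R + 1L)
  dj <- rep(-R:R, times = 2L * R + 1L)
  keep <- abs(di) + abs(dj) == R
  grid[cbind(centre[1] + di[keep], centre[2] + dj[keep], centre[3])] <- TRUE
  grid
}

synth_delaunay <- function(spec) {
  ext <- spec$extent
  pad <- max(1, ceiling(spec$tube_radius))
  if (any(ext < 2 * pad + 2))
    stop("extent too small for the requested tube radius", call. = FALSE)
  pts <- with_seed(spec$seed, {
    cbind(stats::runif(spec$n_points, 1 + pad, ext[1] - pad),
          stats::runif(spec$n_points, 1 + pad, ext[2] - pad),
          stats::runif(spec$n_points, 1 + pad, ext[3] - pad))
  })
  edges <- delaunay_edges(pts)
  grid <- array(FALSE, dim = ext)
  for (e in seq_len(nrow(edges))) {
    vox <- rasterize_segment(pts[edges[e, 1], ], pts[edges[e, 2], ],
                             spec$tube_radius, ext)
    if (nrow(vox)) grid[vox] <- TRUE
  }
  grid
}

#' Rasterize a segment as a digital tube
#'
#' Marks every voxel whose centre lies within `radius` (squared Euclidean
#' point-to-segment distance `<= radius^2`, in voxel index units) of the
#' segment `p`–`q`, clipped to the grid extent.
#'
#' @param p,q Numeric length-3 segment end points (voxel coordinates).
#' @param radius Tube radius in voxels.
#' @param extent Integer grid shape.
#' @return Integer matrix of voxel coordinates, one row per voxel.
#' @export
rasterize_segment <- function(p, q, radius, extent) {
  lo <- pmax(1L, floor(pmin(p, q) - radius))
  hi <- pmin(as.integer(extent), ceiling(pmax(p, q) + radius))
  if (any(lo > hi)) return(matrix(integer(0), ncol = 3))
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                z = lo[3]:hi[3]))
  d <- q - p
  len2 <- sum(d^2)
  rel <- sweep(cand, 2, p)
  tt <- if (len2 == 0) rep(0, nrow(cand)) else
    pmin(1, pmax(0, as.numeric(rel %*% d) / len2))
  closest <- outer(tt, d)
  dist2 <- rowSums((rel - closest)^2)
  cand[dist2 <= radius^2 + 1e-9, , drop = FALSE]
}

#' Delaunay edges of a 3D point set
#'
#' Incremental Bowyer–Watson tetrahedralization; returns the unique vertex
#' pairs of the final tetrahedra. Points are assumed to be in general
#' position (random continuous coordinates); exactly cospherical inputs
#' may yield an arbitrary triangulation among the valid ones.
#'
#' @param pts Numeric matrix, one 3D point per row (>= 4 rows).
#' @return Integer two-column matrix of edges, each row `i < j`, ordered
#'   lexicographically.
#' @export
delaunay_edges <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4L) stop("need at least 4 points", call. = FALSE)

  ctr <- colMeans(pts)
  rad <- sqrt(max(rowSums(sweep(pts, 2, ctr)^2)))
  if (rad == 0) stop("points are coincident", call. = FALSE)
  # super-tetrahedron comfortably containing every circumsphere of interest
  K <- 1000 * rad
  super <- rbind(ctr + K * c(1, 1, 1), ctr + K * c(1, -1, -1),
                 ctr + K * c(-1, 1, -1), ctr + K * c(-1, -1, 1))
  P <- rbind(pts, super)
  sup_idx <- n + 1:4

  orient3 <- function(a, b, c, d)
    det(rbind(P[b, ] - P[a, ], P[c, ] - P[a, ], P[d, ] - P[a, ]))
  # tetra stored positively oriented; p inside circumsphere iff det < 0
  make_tet <- function(v) {
    if (orient3(v[1], v[2], v[3], v[4]) < 0) v[c(1, 2)] <- v[c(2, 1)]
    v
  }
  insphere <- function(v, p) {
    M <- P[v, , drop = FALSE] - matrix(P[p, ], 4, 3, byrow = TRUE)
    det(cbind(M, rowSums(M^2))) < 0
  }

  tets <- list(make_tet(sup_idx))
  for (p in seq_len(n)) {
    bad <- vapply(tets, insphere, TRUE, p = p)
    if (!any(bad)) next  # numerically degenerate; skip (generic inputs: never)
    faces <- do.call(rbind, lapply(tets[bad], function(v)
      rbind(v[-1], v[-2], v[-3], v[-4])))
    faces_key <- apply(t(apply(faces, 1, sort)), 1, paste, collapse = ",")
    boundary <- faces[faces_key %in% names(which(table(faces_key) == 1L)), ,
                      drop = FALSE]
    tets <- tets[!bad]
    for (f in seq_len(nrow(boundary)))
      tets[[length(tets) + 1L]] <- make_tet(c(boundary[f, ], p))
  }

  keep <- vapply(tets, function(v) all(v <= n), TRUE)
  if (!any(keep)) return(matrix(integer(0), ncol = 2))
  pairs <- do.call(rbind, lapply(tets[keep], function(v)
    t(utils::combn(sort(v), 2L))))
  pairs <- unique(pairs)
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}
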