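# Independent reference implementations used as oracles.  They share no
# code with the package's fast paths: the automaton reference is a plain
# per-voxel loop over neighbour lists built from pairwise distances, the
# Delaunay oracle enumerates empty circumspheres exhaustively, and the
# minimization oracle searches all product terms.

# ---- naive excitable automaton ------------------------------------------

# neighbour lists by brute-force pairwise distance among conductive voxels
naive_network <- function(grid, radius) {
  coords <- which(grid, arr.ind = TRUE)
  n <- nrow(coords)
  nbrs <- vector("list", n)
  for (v in seq_len(n)) {
    d2 <- (coords[, 1] - coords[v, 1])^2 + (coords[, 2] - coords[v, 2])^2 +
          (coords[, 3] - coords[v, 3])^2
    nbrs[[v]] <- which(d2 <= radius^2 & d2 > 0)
  }
  list(coords = coords, nbrs = nbrs, n = n)
}

# one synchronous update, voxel by voxel
naive_step <- function(state, h, nbrs, theta, delta) {
  n <- length(state)
  ns <- integer(n); nh <- integer(n)
  sigma <- vapply(nbrs, function(ix) sum(state[ix] == 1L), 0L)
  for (v in seq_len(n)) {
    if (state[v] == 0L) {
      if (sigma[v] > theta) ns[v] <- 1L
    } else if (state[v] == 1L) {
      ns[v] <- 2L; nh[v] <- delta
    } else {                          # refractory
      if (h[v] > 0L) { ns[v] <- 2L; nh[v] <- h[v] - 1L }
    }
  }
  list(state = ns, h = nh)
}

naive_run <- function(state, h, nbrs, theta, delta, steps) {
  for (t in seq_len(steps)) {
    upd <- naive_step(state, h, nbrs, theta, delta)
    state <- upd$state; h <- upd$h
  }
  list(state = state, h = h)
}

# random lattice state with legal h (h > 0 only where refractory)
random_state <- function(n, delta) {
  state <- sample(0:2, n, replace = TRUE, prob = c(0.7, 0.15, 0.15))
  h <- integer(n)
  refr <- state == 2L
  h[refr] <- sample(0:max(1L, delta), sum(refr), replace = TRUE)
  list(state = state, h = h)
}

# ---- brute-force 3D Delaunay edges --------------------------------------

brute_delaunay_edges <- function(pts) {
  n <- nrow(pts)
  edges <- matrix(integer(0), 0, 2)
  for (cmb in utils::combn(n, 4, simplify = FALSE)) {
    A <- pts[cmb, , drop = FALSE]
    M <- 2 * (A[2:4, ] - matrix(A[1, ], 3, 3, byrow = TRUE))
    if (abs(det(M)) < 1e-9) next                     # flat tetrahedron
    ctr <- solve(M, rowSums(A[2:4, ]^2) - sum(A[1, ]^2))
    r2 <- sum((A[1, ] - ctr)^2)
    d2 <- rowSums(sweep(pts, 2, ctr)^2)
    if (all(d2[-cmb] > r2 - 1e-9))
      edges <- rbind(edges, t(utils::combn(cmb, 2)))
  }
  edges <- unique(edges)
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# voxels within `radius` of segment pq, by scanning the whole grid
brute_tube_voxels <- function(p, q, radius, extent) {
  cand <- as.matrix(expand.grid(i = 1:extent[1], j = 1:extent[2],
                                z = 1:extent[3]))
  d <- q - p; len2 <- sum(d^2)
  rel <- sweep(cand, 2, p)
  tt <- if (len2 == 0) rep(0, nrow(cand)) else
    pmin(1, pmax(0, as.numeric(rel %*% d) / len2))
  dist2 <- rowSums((rel - outer(tt, d))^2)
  cand[dist2 <= radius^2 + 1e-9, , drop = FALSE]
}

# ---- brute-force spike grouping -----------------------------------------

# transitive closure of the "closer than window" relation on spike pairs
brute_groups <- function(times, window) {
  n <- length(times)
  if (n == 0L) return(integer(0))
  adj <- abs(outer(times, times, "-")) < window
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n); cid <- 0L
  for (v in seq_len(n)) if (comp[v] == 0L) {
    cid <- cid + 1L
    comp[which(reach[v, ])] <- cid
  }
  comp
}

# ---- exhaustive DNF minimization oracle ---------------------------------

# enumerate all 3^k product terms (each variable: absent / positive /
# negated), keep the implicants of the table, reduce to maximal ones, and
# search minimal covers by increasing subset size
brute_min_dnf_size <- function(values, k) {
  a <- 0:(2^k - 1)
  ones <- a[!is.na(values) & values == 1L]
  zeros <- a[!is.na(values) & values == 0L]
  if (length(ones) == 0L) return(0L)
  bit <- function(x, v) bitwAnd(bitwShiftR(x, k - 1L - v), 1L)
  terms <- expand.grid(rep(list(c(-1L, 0L, 1L)), k))   # -1 absent
  covers <- function(term, x) {
    for (v in seq_len(k))
      if (term[v] >= 0L && bit(x, v - 1L) != term[v]) return(FALSE)
    TRUE
  }
  term_cov <- lapply(seq_len(nrow(terms)), function(ti)
    vapply(ones, function(x) covers(as.integer(terms[ti, ]), x), TRUE))
  implicant <- vapply(seq_len(nrow(terms)), function(ti)
    !any(vapply(zeros, function(x) covers(as.integer(terms[ti, ]), x), TRUE)),
    TRUE)
  useful <- which(implicant & vapply(term_cov, any, TRUE))
  # maximal implicants only (drop terms whose cover is a subset of another)
  covmat <- do.call(rbind, term_cov[useful])
  keep <- rep(TRUE, length(useful))
  for (aix in seq_along(useful)) for (bix in seq_along(useful)) {
    if (aix != bix && keep[aix] &&
        all(covmat[bix, ] >= covmat[aix, ]) &&
        any(covmat[bix, ] > covmat[aix, ])) keep[aix] <- FALSE
  }
  covmat <- covmat[keep, , drop = FALSE]
  for (size in seq_len(nrow(covmat))) {
    for (s in utils::combn(nrow(covmat), size, simplify = FALSE))
      if (all(apply(covmat[s, , drop = FALSE], 2, any))) return(size)
  }
  nrow(covmat)
}

# random truth table with don't-cares
random_table <- function(k, p_dc = 0.2) {
  v <- sample(c(0L, 1L), 2^k, replace = TRUE)
  v[stats::runif(2^k) < p_dc] <- NA_integer_
  v[1] <- 0L
  actomaton::truth_table(v, k)
}
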