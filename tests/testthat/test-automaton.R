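full_net <- function(dims, radius = 3) {
  ca_network(conductive_matrix(array(TRUE, dims)), radius)
}

test_that("neighbourhood offsets match brute-force enumeration", {
  for (r in 1:3) {
    off <- neighbourhood_offsets(r)
    s <- -r:r
    ref <- as.matrix(expand.grid(s, s, s))
    ref <- ref[rowSums(ref^2) <= r^2 & rowSums(ref != 0) > 0, ]
    expect_identical(nrow(off), nrow(ref))
    expect_setequal(apply(off, 1, paste, collapse = ","),
                    apply(ref, 1, paste, collapse = ","))
    # symmetric under negation, centre excluded
    expect_setequal(apply(-off, 1, paste, collapse = ","),
                    apply(off, 1, paste, collapse = ","))
    expect_false(any(rowSums(off != 0) == 0))
  }
  expect_identical(nrow(neighbourhood_offsets(1)), 6L)
  expect_identical(nrow(neighbourhood_offsets(2)), 32L)
  expect_identical(nrow(neighbourhood_offsets(3)), 122L)
  expect_error(neighbourhood_offsets(0), ">= 1")
})

test_that("excitation requires strictly more than theta excited neighbours", {
  net <- full_net(c(7, 7, 7))
  centre <- net$id[4, 4, 4]
  nbr_ids <- which(as.logical(net$adj[centre, ]))
  for (m in c(3L, 7L)) {
    lat <- new_lattice(net)
    lat$state[nbr_ids[seq_len(m)]] <- 1L
    at_theta <- ca_step(lat, net, ca_params(theta = m, delta = 2))
    expect_identical(at_theta$state[centre], 0L)       # sigma == theta: stays
    below <- ca_step(lat, net, ca_params(theta = m - 1L, delta = 2))
    expect_identical(below$state[centre], 1L)          # sigma > theta: fires
  }
})

test_that("excited voxels turn refractory with the counter set to delta", {
  net <- full_net(c(3, 3, 3), radius = 1)
  lat <- new_lattice(net)
  v <- net$id[2, 2, 2]
  lat$state[v] <- 1L
  nxt <- ca_step(lat, net, ca_params(theta = 99, delta = 20))
  expect_identical(nxt$state[v], 2L)
  expect_identical(nxt$h[v], 20L)
})

test_that("a voxel is refractory for exactly delta + 1 steps", {
  mat <- conductive_matrix(array(TRUE, c(1, 1, 1)))
  net <- ca_network(mat, 3)
  for (delta in c(0L, 1L, 2L, 20L)) {
    lat <- new_lattice(net)
    lat$state[1] <- 1L
    states <- integer(delta + 3L)
    for (t in seq_along(states)) {
      lat <- ca_step(lat, net, ca_params(theta = 0, delta = delta))
      states[t] <- lat$state[1]
    }
    expect_identical(states[seq_len(delta + 1L)], rep(2L, delta + 1L))
    expect_identical(states[delta + 2L], 0L)
  }
})

test_that("a quiescent lattice never excites spontaneously", {
  net <- full_net(c(5, 5, 5))
  lat <- ca_run(new_lattice(net), net, ca_params(theta = 0, delta = 2), 10)
  expect_true(all(lat$state == 0L))
  expect_true(all(lat$h == 0L))
})

test_that("evolution is deterministic", {
  set.seed(42)
  grid <- array(runif(8^3) < 0.5, c(8, 8, 8))
  net <- ca_network(conductive_matrix(grid), 2)
  init <- new_lattice(net)
  init$state[sample(net$n, 20)] <- 1L
  p <- ca_params(theta = 2, delta = 3, radius = 2)
  a <- ca_run(init, net, p, 25)
  b <- ca_run(init, net, p, 25)
  expect_identical(a, b)
})

test_that("a wave on a 1-voxel line advances 3 voxels per step", {
  spec <- synth_spec("line", extent = c(40, 5, 5), axis = "x", length = 31,
                     origin = c(3, 3, 3))
  net <- ca_network(synth_network(spec), 3)
  lat <- new_lattice(net)
  lat$state[net$id[3, 3, 3]] <- 1L
  far <- net$id[33, 3, 3]
  p <- ca_params(theta = 0, delta = 20)
  first <- NA_integer_
  for (t in 1:15) {
    lat <- ca_step(lat, net, p)
    if (is.na(first) && lat$state[far] == 1L) first <- t
  }
  expect_identical(first, 10L)                         # ceil(30 / 3)
})

test_that("fast step equals the naive per-voxel reference", {
  set.seed(1)
  for (trial in 1:4) {
    grid <- array(runif(8^3) < 0.5, c(8, 8, 8))
    nref <- naive_network(grid, 2)
    net <- ca_network(conductive_matrix(grid), 2)
    # same voxel ordering: which(..., arr.ind) in both
    expect_identical(unname(nref$coords), unname(net$coords))
    for (params in list(c(1L, 2L), c(3L, 0L))) {
      init <- random_state(net$n, params[2])
      lat <- structure(list(state = init$state, h = init$h, t = 0L),
                       class = "ca_lattice")
      p <- ca_params(params[1], params[2], radius = 2)
      fast <- ca_run(lat, net, p, 20)
      ref <- naive_run(init$state, init$h, nref$nbrs, params[1], params[2], 20)
      expect_identical(fast$state, ref$state)
      expect_identical(fast$h, ref$h)
    }
  }
})

test_that("states stay legal along a random evolution", {
  set.seed(8)
  grid <- array(runif(10^3) < 0.4, c(10, 10, 10))
  net <- ca_network(conductive_matrix(grid), 3)
  lat <- new_lattice(net)
  lat$state[sample(net$n, 30)] <- 1L
  p <- ca_params(theta = 1, delta = 4)
  for (t in 1:15) {
    prev <- lat
    lat <- ca_step(lat, net, p)
    expect_true(all(lat$state[lat$h > 0L] == 2L))      # h>0 implies refractory
    # every newly excited voxel had sigma > theta, recomputed independently
    sigma <- as.integer(net$adj %*% (prev$state == 1L))
    newly <- which(lat$state == 1L)
    expect_true(all(prev$state[newly] == 0L))
    expect_true(all(sigma[newly] > p$theta))
  }
})

test_that("mismatched lattice and network are rejected", {
  net <- full_net(c(3, 3, 3), radius = 1)
  lat <- new_lattice(net)
  lat$state <- lat$state[-1]
  expect_error(ca_step(lat, net, ca_params()), "match")
})
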