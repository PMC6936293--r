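test_that("shipped electrode tables parse and fit the full-size grid", {
  e1 <- read_electrodes(system.file("extdata", "electrodes_E1.csv",
                                    package = "actomaton"))
  e2 <- read_electrodes(system.file("extdata", "electrodes_E2.csv",
                                    package = "actomaton"))
  expect_identical(nrow(e1), 10L)
  expect_identical(nrow(e2), 8L)
  expect_silent(validate_electrodes(e1, c(1024L, 1024L, 30L)))
  expect_silent(validate_electrodes(e2, c(1024L, 1024L, 30L)))
  expect_true(all(e1$radius == 4))
  # the six-electrode wiring reuses coordinates of the ten-electrode one
  key <- function(df) paste(df$i, df$j, df$z)
  expect_true(all(key(e2) %in% key(e1)))
  expect_error(validate_electrodes(e1, c(500L, 1024L, 30L)), "outside")
})

test_that("bit/decimal encoding round-trips with e0 as the MSB", {
  for (v in 0:63) expect_identical(pattern_decimal(pattern_bits(v, 6)), v)
  expect_identical(pattern_bits(1, 6), c(0L, 0L, 0L, 0L, 0L, 1L))  # e5 only
  expect_identical(pattern_bits(32, 6), c(1L, 0L, 0L, 0L, 0L, 0L)) # e0 only
  expect_error(pattern_bits(64, 6), "range")
})

test_that("stimulation excites exactly the open electrode sphere", {
  net <- ca_network(conductive_matrix(array(TRUE, c(15, 15, 15))), 3)
  el <- electrode_table("e0", 8, 8, 8, radius = 4)
  lat <- stimulate(new_lattice(net), net, el, bits = 1L)
  # strict d < 4 on the integer lattice means d^2 <= 15: 251 voxels
  expect_identical(sum(lat$state == 1L), 251L)
  d2 <- rowSums(sweep(net$coords, 2, c(8, 8, 8))^2)
  expect_identical(which(lat$state == 1L), which(d2 < 16))

  # all-zero pattern leaves the lattice untouched
  lat0 <- stimulate(new_lattice(net), net, el, bits = 0L)
  expect_true(all(lat0$state == 0L))
})

test_that("stimulation only reaches conductive voxels and spares refractory ones", {
  grid <- array(FALSE, c(15, 15, 15))
  grid[1, 1, 1] <- TRUE                        # far from the electrode
  net <- ca_network(conductive_matrix(grid), 3)
  el <- electrode_table("e0", 8, 8, 8, radius = 4)
  lat <- stimulate(new_lattice(net), net, el, bits = 1L)
  expect_true(all(lat$state == 0L))            # nothing conductive in range

  net2 <- ca_network(conductive_matrix(array(TRUE, c(9, 9, 9))), 3)
  lat2 <- new_lattice(net2)
  lat2$state[] <- 2L; lat2$h[] <- 5L           # everything refractory
  el2 <- electrode_table("e0", 5, 5, 5, radius = 4)
  out <- stimulate(lat2, net2, el2, bits = 1L)
  expect_true(all(out$state == 2L))            # refractory never overridden
})

test_that("adding a 1-bit never shrinks the initially excited set", {
  set.seed(19)
  grid <- array(runif(12^3) < 0.6, c(12, 12, 12))
  net <- ca_network(conductive_matrix(grid), 3)
  el <- electrode_table(c("e0", "e1", "e2"), c(3, 6, 9), c(3, 6, 9),
                        c(3, 6, 9), radius = 4)
  for (v in 0:6) {
    bits <- pattern_bits(v, 3)
    more <- pmin(bits + pattern_bits(1, 3), 1L)
    a <- which(stimulate(new_lattice(net), net, el, bits)$state == 1L)
    b <- which(stimulate(new_lattice(net), net, el, more)$state == 1L)
    expect_true(all(a %in% b))
  }
})

test_that("recording counts excited voxels strictly inside the radius", {
  net <- ca_network(conductive_matrix(array(TRUE, c(15, 15, 15))), 3)
  el <- electrode_table("e0", 8, 8, 8, radius = 4)
  lat <- new_lattice(net)
  expect_identical(record_potential(lat, net, el), 0L)

  lat$state[] <- 1L
  expect_identical(record_potential(lat, net, el), 251L)

  lat2 <- new_lattice(net)
  lat2$state[net$id[12, 8, 8]] <- 1L           # distance exactly 4
  expect_identical(record_potential(lat2, net, el), 0L)
  lat2$state[net$id[11, 8, 8]] <- 1L           # distance 3
  expect_identical(record_potential(lat2, net, el), 1L)
})

test_that("experiments are quiescent for input 0 and deterministic", {
  spec <- synth_spec("delaunay", extent = c(24, 24, 8), n_points = 10,
                     tube_radius = 1.5, seed = 5)
  net <- ca_network(synth_network(spec), 3)
  el <- place_electrodes(net, 3, 4)
  p <- ca_params(theta = 2, delta = 8)
  z <- run_experiment(net, el, c(0L, 0L, 0L), p, 40)
  expect_true(all(z == 0L))
  a <- run_experiment(net, el, c(1L, 0L, 1L), p, 40)
  b <- run_experiment(net, el, c(1L, 0L, 1L), p, 40)
  expect_identical(a, b)
  # potential never exceeds the conductive sphere content
  vox <- electrode_voxels(net, el)
  for (cix in seq_len(ncol(a))) expect_true(all(a[, cix] <= length(vox[[cix]])))
})

test_that("wavefront arrival at a far electrode matches the naive oracle", {
  spec <- synth_spec("line", extent = c(40, 5, 5), axis = "x", length = 36,
                     origin = c(3, 3, 3))
  mat <- synth_network(spec)
  net <- ca_network(mat, 3)
  el <- electrode_table(c("near", "far"), c(4, 37), c(3, 3), c(3, 3),
                        radius = 2)
  p <- ca_params(theta = 0, delta = 20)
  tr <- run_experiment(net, el, c(1L, 0L), p, 25)

  # oracle: naive simulation from the same initial excitation
  nref <- naive_network(mat$grid, 3)
  init <- integer(nref$n)
  d2 <- rowSums(sweep(nref$coords, 2, c(4, 3, 3))^2)
  init[d2 < 4] <- 1L
  h <- integer(nref$n)
  far_ids <- which(rowSums(sweep(nref$coords, 2, c(37, 3, 3))^2) < 4)
  state <- init
  arrival <- NA_integer_
  for (t in 1:25) {
    upd <- naive_step(state, h, nref$nbrs, 0L, 20L)
    state <- upd$state; h <- upd$h
    if (is.na(arrival) && any(state[far_ids] == 1L)) arrival <- t
  }
  expect_identical(min(which(tr[, "far"] > 0L)), arrival)
})
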