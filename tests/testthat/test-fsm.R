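mk_train <- function(...) {
  tr <- list(...)
  structure(tr, amp_threshold = 1, window = 6L, class = "spike_train")
}

test_that("machine states decode pooled spikes with e0 as MSB", {
  labels <- paste0("e", 0:5)
  only_e5 <- mk_train(e0 = integer(0), e1 = integer(0), e2 = integer(0),
                      e3 = integer(0), e4 = integer(0), e5 = 40L)
  expect_identical(states_from_spikes(only_e5, 6)$state, 1L)

  only_e0 <- mk_train(e0 = 40L, e1 = integer(0), e2 = integer(0),
                      e3 = integer(0), e4 = integer(0), e5 = integer(0))
  expect_identical(states_from_spikes(only_e0, 6)$state, 32L)

  none <- mk_train(e0 = integer(0), e1 = integer(0), e2 = integer(0),
                   e3 = integer(0), e4 = integer(0), e5 = integer(0))
  expect_identical(nrow(states_from_spikes(none, 6)), 0L)
})

test_that("synthetic spike trains round-trip a known state sequence", {
  set.seed(91)
  k <- 6L
  for (trial in 1:20) {
    n_ev <- sample(1:8, 1)
    states <- sample(1:63, n_ev, replace = TRUE)
    times <- cumsum(sample(7:30, n_ev, replace = TRUE))  # gaps > 6
    trains <- lapply(seq_len(k) - 1L, function(e) {
      has <- vapply(states, function(s) pattern_bits(s, k)[e + 1L] == 1L, TRUE)
      times[has]
    })
    names(trains) <- paste0("e", seq_len(k) - 1L)
    got <- states_from_spikes(trains, k)
    expect_identical(got$state, states)
    expect_identical(got$time, times)
  }
})

test_that("transition graphs link consecutive events", {
  s <- structure(data.frame(time = c(10L, 30L, 50L), state = c(8L, 16L, 8L)),
                 class = c("state_sequence", "data.frame"))
  g <- transition_graph(s)
  ed <- igraph::as_data_frame(g)
  expect_setequal(paste(ed$from, ed$to), c("8 16", "16 8"))

  one <- structure(data.frame(time = 10L, state = 5L),
                   class = c("state_sequence", "data.frame"))
  g1 <- transition_graph(one)
  expect_equal(igraph::vcount(g1), 1)
  expect_equal(igraph::ecount(g1), 0)

  g0 <- transition_graph(structure(data.frame(time = integer(0),
                                              state = integer(0)),
                                   class = c("state_sequence", "data.frame")))
  expect_equal(igraph::vcount(g0), 0)
})

test_that("weighted graphs normalize outgoing counts", {
  mkseq <- function(states) structure(
    data.frame(time = seq_along(states) * 10L, state = as.integer(states)),
    class = c("state_sequence", "data.frame"))

  g <- weighted_global_graph(list(mkseq(c(3, 5))))
  ed <- igraph::as_data_frame(g)
  expect_identical(ed$weight, 1)

  # a->b twice, a->c once across inputs
  g2 <- weighted_global_graph(list(mkseq(c(1, 2)), mkseq(c(1, 2)),
                                   mkseq(c(1, 4))))
  ed2 <- igraph::as_data_frame(g2)
  expect_equal(ed2$weight[ed2$to == "2"], 2 / 3)
  expect_equal(ed2$weight[ed2$to == "4"], 1 / 3)

  # terminal nodes have no outgoing edges; no division by zero
  expect_false("2" %in% ed2$from)
})

test_that("outgoing weights sum to one on randomized transition logs", {
  set.seed(55)
  for (trial in 1:40) {
    seqs <- lapply(seq_len(sample(2:6, 1)), function(i) {
      n <- sample(2:15, 1)
      structure(data.frame(time = cumsum(sample(7:20, n, replace = TRUE)),
                           state = sample(1:63, n, replace = TRUE)),
                class = c("state_sequence", "data.frame"))
    })
    g <- weighted_global_graph(seqs)
    ed <- igraph::as_data_frame(g)
    sums <- tapply(ed$weight, ed$from, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
})

test_that("pruning keeps one maximum-weight edge per node", {
  mkg <- function(df) {
    tot <- tapply(df$count, df$from, sum)
    df$weight <- df$count / as.numeric(tot[df$from])
    igraph::graph_from_data_frame(df)
  }
  g <- mkg(data.frame(from = c("1", "1"), to = c("2", "3"),
                      count = c(7, 3), stringsAsFactors = FALSE))
  ed <- igraph::as_data_frame(prune_graph(g))
  expect_identical(ed$to, "2")

  # tie: smallest successor decimal wins
  gt <- mkg(data.frame(from = c("5", "5"), to = c("9", "3"),
                       count = c(1, 1), stringsAsFactors = FALSE))
  edt <- igraph::as_data_frame(prune_graph(gt))
  expect_identical(edt$to, "3")
})

test_that("pruned graphs classify nodes and bound out-degree by one", {
  set.seed(17)
  for (trial in 1:15) {
    seqs <- lapply(1:5, function(i) {
      n <- sample(2:12, 1)
      structure(data.frame(time = cumsum(sample(7:20, n, replace = TRUE)),
                           state = sample(1:20, n, replace = TRUE)),
                class = c("state_sequence", "data.frame"))
    })
    p <- prune_graph(weighted_global_graph(seqs))
    expect_true(all(igraph::degree(p, mode = "out") <= 1))
    nc <- node_classes(p)
    # garden-of-eden set and nodes-with-predecessors partition the nodes
    goe <- nc$state[nc$indegree == 0]
    withpred <- nc$state[nc$indegree > 0]
    expect_identical(sort(c(goe, withpred)), sort(nc$state))
    expect_length(intersect(goe, withpred), 0L)
    # fixed points have a self-edge or no outgoing edge
    for (st in nc$state[nc$class == "fixed_point"]) {
      out_e <- igraph::incident(p, as.character(st), mode = "out")
      expect_true(length(out_e) == 0 ||
                  igraph::are_adjacent(p, as.character(st), as.character(st)))
    }
  }
})

test_that("richness aligns the t-th response over all inputs", {
  mkseq <- function(states) structure(
    data.frame(time = seq_along(states) * 10L, state = as.integer(states)),
    class = c("state_sequence", "data.frame"))

  same <- richness(list(`1` = mkseq(8), `2` = mkseq(8)))
  expect_identical(same$by_step$mu, 1L)
  expect_identical(same$by_step$states[[1]], 8L)

  two <- richness(list(`1` = mkseq(8), `2` = mkseq(16)))
  expect_identical(two$by_step$mu, 2L)

  ragged <- richness(list(`1` = mkseq(c(8, 16)), `2` = mkseq(8)))
  expect_identical(ragged$by_step$t, c(1L, 2L))
  # t = 1 sees {8, 8}; t = 2 only input 1 responds, with state 16
  expect_identical(ragged$by_step$mu, c(1L, 1L))
  expect_identical(ragged$by_step$states[[2]], 16L)
  expect_identical(ragged$per_input$n_states, c(2L, 1L))
  expect_identical(ragged$per_state$n_inputs[ragged$per_state$state == 8L], 2L)
})

test_that("g(t) maps inputs with enough events and drops the rest", {
  mkseq <- function(states) structure(
    data.frame(time = seq_along(states) * 10L, state = as.integer(states)),
    class = c("state_sequence", "data.frame"))
  seqs <- list(`3` = mkseq(c(8, 16)), `5` = mkseq(4))
  g1 <- g_of_t(seqs, 1)
  expect_identical(g1, c(`3` = 8L, `5` = 4L))
  g2 <- g_of_t(seqs, 2)
  expect_identical(g2, c(`3` = 16L))
  expect_error(g_of_t(seqs, 0), ">= 1")
})
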