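#' Machine states from pooled spike trains
#'
#' The machine state at a response moment is the k-bit string whose i-th
#' bit is 1 iff electrode `i` spiked within that coincidence group. With
#' `e0` as the most significant bit, a spike only on the last electrode
#' `e(k-1)` encodes state 1. All-zero states never arise (a group
#' contains at least one spike) and only responding moments enter the
#' sequence.
#'
#' @param trains A `spike_train` whose elements are ordered `e0 ..
#'   e(k-1)`.
#' @param k Number of electrodes; defaults to `length(trains)`.
#' @param window Coincidence window.
#' @return A `state_sequence`: data frame with columns `time`
#'   (representative group time, strictly increasing) and `state`
#'   (decimal encoding).
#' @export
states_from_spikes <- function(trains, k = length(trains), window = 6L) {
  stopifnot(length(trains) == k)
  groups <- group_coincident(trains, window)
  labels <- names(trains)
  rows <- lapply(groups, function(g) {
    bits <- as.integer(labels %in% g$members$electrode)
    data.frame(time = g$time, state = pattern_decimal(bits))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = integer(0), state = integer(0))
  out <- out[out$state != 0L, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, k = k, class = c("state_sequence", "data.frame"))
}

#' Transition graph of one state sequence
#'
#' Directed simple graph with an edge `a -> b` for every consecutive
#' event pair of the sequence; repeats collapse to a single edge, with
#' the observation count kept as the edge attribute `count`.
#'
#' @param seq A `state_sequence`.
#' @return An [igraph::igraph] whose vertex names are decimal state
#'   encodings.
#' @export
transition_graph <- function(seq) {
  states <- as.character(seq$state)
  verts <- unique(states)
  if (length(states) < 2L)
    return(igraph::make_empty_graph(directed = TRUE) +
             igraph::vertices(verts))
  ed <- data.frame(from = states[-length(states)], to = states[-1],
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(count = rep(1L, nrow(ed))),
                          by = ed, FUN = sum)
  igraph::graph_from_data_frame(agg, directed = TRUE,
                                vertices = data.frame(name = verts))
}

#' Weighted global transition graph over all inputs
#'
#' Transition counts are pooled over every input's event sequence; the
#' weight of edge `a -> b` is the number of observed `a -> b` transitions
#' divided by the total number of transitions leaving `a` (self
#' transitions included in the normalization). Outgoing weights of every
#' non-terminal node therefore sum to 1.
#'
#' @param sequences List of `state_sequence` objects, one per input.
#' @return An [igraph::igraph] with edge attributes `count` and `weight`.
#' @export
weighted_global_graph <- function(sequences) {
  pairs <- lapply(sequences, function(s) {
    st <- as.character(s$state)
    if (length(st) < 2L) return(NULL)
    data.frame(from = st[-length(st)], to = st[-1], stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  verts <- unique(unlist(lapply(sequences, function(s) as.character(s$state))))
  if (is.null(pairs) || length(verts) == 0L) {
    g <- igraph::make_empty_graph(directed = TRUE)
    if (length(verts)) g <- g + igraph::vertices(verts)
    return(g)
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(pairs))),
                          by = pairs, FUN = sum)
  tot <- tapply(agg$count, agg$from, sum)
  agg$weight <- agg$count / as.numeric(tot[agg$from])
  igraph::graph_from_data_frame(agg, directed = TRUE,
                                vertices = data.frame(name = verts))
}

#' Prune a weighted transition graph to its most likely transitions
#'
#' Keeps, for each node with outgoing edges, exactly the outgoing edge of
#' maximum weight (ties broken towards the smallest successor decimal, so
#' the result is deterministic). Nodes are then classified on the pruned
#' graph: `garden_of_eden` nodes have no predecessors, a `fixed_point`
#' has no outgoing edge or only a self-edge, all others are `ordinary`.
#' A fixed point that happens to have no predecessors is reported as a
#' fixed point; the `indegree` attribute always identifies the
#' Garden-of-Eden set as `indegree == 0`.
#'
#' @param graph A weighted graph from [weighted_global_graph()].
#' @return An [igraph::igraph] with out-degree at most 1 everywhere and
#'   vertex attributes `class` and `indegree`.
#' @export
prune_graph <- function(graph) {
  verts <- igraph::V(graph)$name
  if (length(verts) == 0L) {
    g <- igraph::make_empty_graph(directed = TRUE)
    return(g)
  }
  ed <- igraph::as_data_frame(graph, what = "edges")
  keep <- integer(0)
  if (nrow(ed)) {
    for (src in unique(ed$from)) {
      cand <- which(ed$from == src)
      cand <- cand[ed$weight[cand] == max(ed$weight[cand])]
      keep <- c(keep, cand[which.min(as.numeric(ed$to[cand]))])
    }
  }
  g <- igraph::graph_from_data_frame(ed[keep, , drop = FALSE],
                                     directed = TRUE,
                                     vertices = data.frame(name = verts))
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  self <- vapply(verts, function(v)
    igraph::are_adjacent(g, v, v), TRUE)
  cls <- ifelse(outdeg == 0L | self, "fixed_point",
                ifelse(indeg == 0L, "garden_of_eden", "ordinary"))
  igraph::V(g)$class <- unname(cls)
  igraph::V(g)$indegree <- unname(indeg)
  g
}

#' Node classification table of a pruned graph
#'
#' @param pruned Output of [prune_graph()].
#' @return Data frame with `state`, `class` and `indegree`, ordered by
#'   state decimal.
#' @export
node_classes <- function(pruned) {
  if (igraph::vcount(pruned) == 0L)
    return(data.frame(state = integer(0), class = character(0),
                      indegree = integer(0), stringsAsFactors = FALSE))
  df <- data.frame(state = as.integer(igraph::V(pruned)$name),
                   class = igraph::V(pruned)$class,
                   indegree = igraph::V(pruned)$indegree,
                   stringsAsFactors = FALSE)
  df[order(df$state), , drop = FALSE]
}

#' Richness of the machine's responses
#'
#' Aligns the t-th non-zero response event of every input and reports,
#' per transition step t, the number `mu` of distinct states over all
#' inputs and the state set `P`. Also tabulates the number of distinct
#' states each input generates and the number of inputs that reach each
#' state.
#'
#' @param sequences Named list of `state_sequence` objects (names:
#'   decimal input encodings).
#' @return List with `by_step` (data frame `t`, `mu`, list column
#'   `states`), `per_input` (data frame `input`, `n_states`) and
#'   `per_state` (data frame `state`, `n_inputs`).
#' @export
richness <- function(sequences) {
  lens <- vapply(sequences, nrow, 0L)
  tmax <- if (length(lens)) max(lens) else 0L
  steps <- which(vapply(seq_len(tmax), function(t) any(lens >= t), TRUE))
  by_step <- data.frame(t = steps, mu = integer(length(steps)))
  by_step$states <- vector("list", length(steps))
  for (ix in seq_along(steps)) {
    t <- steps[ix]
    st <- unlist(lapply(sequences, function(s)
      if (nrow(s) >= t) s$state[t] else NULL))
    uq <- sort(unique(st))
    by_step$mu[ix] <- length(uq)
    by_step$states[[ix]] <- uq
  }
  per_input <- data.frame(
    input = if (is.null(names(sequences))) as.character(seq_along(sequences))
            else names(sequences),
    n_states = unname(vapply(sequences, function(s)
      length(unique(s$state)), 0L)),
    stringsAsFactors = FALSE, row.names = NULL)
  all_states <- unlist(lapply(sequences, function(s) unique(s$state)))
  tab <- table(all_states)
  per_state <- data.frame(state = as.integer(names(tab)),
                          n_inputs = as.integer(tab), row.names = NULL)
  per_state <- per_state[order(per_state$state), , drop = FALSE]
  list(by_step = by_step, per_input = per_input, per_state = per_state)
}

#' The response map g at transition step t
#'
#' Maps each input whose sequence has at least `t` events to its t-th
#' event state; inputs with fewer events are absent from the map (and
#' become don't-cares in downstream Boolean reconstruction).
#'
#' @param sequences Named list of `state_sequence` objects (names:
#'   decimal input encodings).
#' @param t Event index, `t >= 1`.
#' @return Named integer vector, names = input decimals.
#' @export
g_of_t <- function(sequences, t) {
  t <- as.integer(t)
  if (is.na(t) || t < 1L) stop("`t` must be >= 1", call. = FALSE)
  have <- vapply(sequences, function(s) nrow(s) >= t, TRUE)
  vapply(sequences[have], function(s) s$state[t], 0L)
}

#' Run the machine over a set of input strings
#'
#' For every input decimal, stimulates the network with the
#' corresponding impulse pattern, records the potential at every
#' electrode for `steps` steps, extracts spike trains and the machine
#' state sequence.
#'
#' @param net A [ca_network].
#' @param electrodes An [electrode_table] (k rows; all electrodes are
#'   both inputs and outputs).
#' @param params A [ca_params].
#' @param steps Automaton steps per input.
#' @param inputs Integer input decimals (default all non-zero strings).
#' @param amp_threshold,window Spike-detection parameters.
#' @param keep_traces Keep the raw potential traces in the result.
#' @return List with `sequences` (named list of `state_sequence`),
#'   `trains` (named list of `spike_train`), and optionally `traces`.
#' @export
run_machine <- function(net, electrodes, params, steps,
                        inputs = seq_len(2^nrow(electrodes) - 1L),
                        amp_threshold = 1, window = 6L,
                        keep_traces = FALSE) {
  k <- nrow(electrodes)
  sequences <- list(); trains <- list(); traces <- list()
  for (dec in inputs) {
    bits <- pattern_bits(dec, k)
    tr <- run_experiment(net, electrodes, bits, params, steps)
    sp <- detect_spikes(tr, amp_threshold, window)
    key <- as.character(dec)
    sequences[[key]] <- states_from_spikes(sp, k, window)
    trains[[key]] <- sp
    if (keep_traces) traces[[key]] <- tr
  }
  out <- list(sequences = sequences, trains = trains)
  if (keep_traces) out$traces <- traces
  out
}
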