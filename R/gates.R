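#' Classify a two-input one-output gate from its response triple
#'
#' The three stimulations `(x, y) = (0,1), (1,0), (1,1)` either do or do
#' not produce an output spike in one coincidence-aligned window; the
#' `(0,0)` stimulation is identically silent because the automaton has no
#' spontaneous excitation. The eight response triples therefore map onto
#' seven realizable gates plus the silent case: gates whose output is
#' true on `(0,0)` (nor, xnor, nand, not, true) are unreachable, which is
#' why the gate set has exactly seven labels.
#'
#' @param z01,z10,z11 Logical: output spike present for inputs `(0,1)`,
#'   `(1,0)`, `(1,1)`.
#' @return One of `"OR"`, `"AND"`, `"XOR"`, `"NOTAND"` (x̄y), `"ANDNOT"`
#'   (x ȳ), `"SELECT_X"`, `"SELECT_Y"`, `"NONE"`.
#' @export
classify_gate <- function(z01, z10, z11) {
  key <- paste0(as.integer(z01), as.integer(z10), as.integer(z11))
  switch(key,
    "111" = "OR", "001" = "AND", "110" = "XOR",
    "100" = "NOTAND", "010" = "ANDNOT",
    "011" = "SELECT_X", "101" = "SELECT_Y",
    "000" = "NONE")
}

#' Mine Boolean gates from the spike responses of one output electrode
#'
#' Takes the potential traces of three runs that differ only in the input
#' pattern — `(x, y) = (0,1)`, `(1,0)` and `(1,1)` — detects spikes on
#' the output electrode in each, aligns them across runs by coincidence
#' grouping on the pooled spike set, and classifies each aligned window
#' with [classify_gate()]. Windows with no spike in any run cannot occur
#' and `NONE` records are dropped.
#'
#' @param traces01,traces10,traces11 `potential_trace` matrices of equal
#'   length from the three runs.
#' @param output Column name (electrode label) of the output electrode.
#' @param amp_threshold,window Spike-detection parameters, see
#'   [detect_spikes()].
#' @return Data frame with columns `t` (window time), `z01`, `z10`,
#'   `z11`, `label`; zero rows if the electrode never spikes.
#' @export
mine_gates <- function(traces01, traces10, traces11, output,
                       amp_threshold = 1, window = 6L) {
  if (nrow(traces01) != nrow(traces10) || nrow(traces10) != nrow(traces11))
    stop("traces must have identical lengths", call. = FALSE)
  runs <- list(z01 = traces01[, output], z10 = traces10[, output],
               z11 = traces11[, output])
  spikes <- lapply(runs, function(v)
    detect_spikes(v, amp_threshold, window)[[1]])
  groups <- group_coincident(spikes, window)
  if (length(groups) == 0L)
    return(data.frame(t = integer(0), z01 = logical(0), z10 = logical(0),
                      z11 = logical(0), label = character(0),
                      stringsAsFactors = FALSE))
  rec <- lapply(groups, function(g) {
    present <- c("z01", "z10", "z11") %in% g$members$electrode
    data.frame(t = g$time, z01 = present[1], z10 = present[2],
               z11 = present[3],
               label = classify_gate(present[1], present[2], present[3]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  out[out$label != "NONE", , drop = FALSE]
}

#' Sweep automaton parameters and tabulate mined gates
#'
#' For every `(theta, delta)` pair the network is stimulated with the
#' three input patterns of each admissible `(i, j, k)` electrode triple
#' and the output spikes are classified. Two wirings are supported:
#' `"fixed_inputs"` keeps two designated input electrodes and treats
#' every other electrode as an output; `"all_triples"` enumerates every
#' ordered triple of distinct electrodes as `(x-input, y-input, output)`.
#' Runs are cached by stimulated electrode set, so the sweep is
#' deterministic and does not repeat simulations.
#'
#' @param net A [ca_network].
#' @param electrodes An [electrode_table].
#' @param wiring `"fixed_inputs"` or `"all_triples"`.
#' @param theta_list,delta_list Integer vectors of parameter values; each
#'   pair of the cross product is run.
#' @param steps Automaton steps per run.
#' @param radius Neighbourhood radius.
#' @param input_labels For `fixed_inputs`: labels of the x- and y-input
#'   electrodes (default: first and last table rows).
#' @param amp_threshold,window Spike-detection parameters.
#' @return List with `records` (one row per mined gate: `theta`, `delta`,
#'   `i`, `j`, `k`, `t`, `label`), `counts` (gates per
#'   `theta`/`delta`/`label`), `nu_electrode` (mean gate count per output
#'   electrode for each `theta`/`delta`) and `nu_triple` (mean gate count
#'   per `(i,j,k)` triple).
#' @export
sweep_params <- function(net, electrodes, wiring = c("fixed_inputs", "all_triples"),
                         theta_list, delta_list, steps,
                         radius = net$radius, input_labels = NULL,
                         amp_threshold = 1, window = 6L) {
  wiring <- match.arg(wiring)
  if (length(theta_list) == 0L || length(delta_list) == 0L)
    stop("parameter lists must be non-empty", call. = FALSE)
  labels <- electrodes$label
  if (wiring == "fixed_inputs") {
    if (is.null(input_labels))
      input_labels <- labels[c(1L, length(labels))]
    stopifnot(length(input_labels) == 2L, all(input_labels %in% labels))
    triples <- expand.grid(i = input_labels[1], j = input_labels[2],
                           k = setdiff(labels, input_labels),
                           stringsAsFactors = FALSE)
  } else {
    triples <- expand.grid(i = labels, j = labels, k = labels,
                           stringsAsFactors = FALSE)
    triples <- triples[triples$i != triples$j & triples$i != triples$k &
                       triples$j != triples$k, , drop = FALSE]
  }

  records <- list()
  for (theta in theta_list) for (delta in delta_list) {
    params <- ca_params(theta, delta, radius)
    cache <- new.env(parent = emptyenv())
    run_for <- function(stim_labels) {
      key <- paste(sort(stim_labels), collapse = "|")
      if (!is.null(cache[[key]])) return(cache[[key]])
      bits <- as.integer(labels %in% stim_labels)
      tr <- run_experiment(net, electrodes, bits, params, steps)
      cache[[key]] <- tr
      tr
    }
    for (r in seq_len(nrow(triples))) {
      i <- triples$i[r]; j <- triples$j[r]; k <- triples$k[r]
      rec <- mine_gates(run_for(j), run_for(i), run_for(c(i, j)), k,
                        amp_threshold, window)
      if (nrow(rec))
        records[[length(records) + 1L]] <-
          cbind(data.frame(theta = theta, delta = delta, i = i, j = j,
                           k = k, stringsAsFactors = FALSE), rec)
    }
  }

  records <- if (length(records)) do.call(rbind, records) else
    data.frame(theta = integer(0), delta = integer(0), i = character(0),
               j = character(0), k = character(0), t = integer(0),
               z01 = logical(0), z10 = logical(0), z11 = logical(0),
               label = character(0), stringsAsFactors = FALSE)
  rownames(records) <- NULL

  grid <- expand.grid(theta = theta_list, delta = delta_list)
  counts <- do.call(rbind, lapply(seq_len(nrow(grid)), function(gi) {
    sub <- records[records$theta == grid$theta[gi] &
                   records$delta == grid$delta[gi], , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    agg <- as.data.frame(table(label = sub$label), stringsAsFactors = FALSE)
    data.frame(theta = grid$theta[gi], delta = grid$delta[gi],
               label = agg$label, n = agg$Freq, stringsAsFactors = FALSE)
  }))
  if (is.null(counts))
    counts <- data.frame(theta = integer(0), delta = integer(0),
                         label = character(0), n = integer(0))

  n_outputs <- length(unique(triples$k))
  n_triples <- nrow(triples)
  nu <- function(denom) {
    out <- grid
    out$nu <- vapply(seq_len(nrow(grid)), function(gi)
      sum(records$theta == grid$theta[gi] &
          records$delta == grid$delta[gi]) / denom, 0)
    out
  }
  list(records = records, counts = counts,
       nu_electrode = nu(n_outputs), nu_triple = nu(n_triples))
}
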