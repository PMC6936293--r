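#' Number of machine states
#'
#' A machine interfaced through `k` electrodes has state set `{0,1}^k`,
#' i.e. `2^k` states; 64 for the six-electrode droplet machine.
#'
#' @param k Positive integer number of electrodes.
#' @return Integer `2^k`.
#' @export
machine_state_count <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (k > 30L) stop("`k` too large for an integer state count", call. = FALSE)
  as.integer(2^k)
}

#' Physical throughput estimate of a droplet machine
#'
#' Back-of-the-envelope operating speed: a signal crossing a droplet of
#' linear size `machine_size` at `signal_speed` bounds the input rate at
#' `signal_speed / machine_size` parallel inputs per second; with the
#' network stable for `stability_window` seconds, the machine executes
#' `inputs_per_second * stability_window` computation cycles before
#' reconfiguration. With the conservative action-potential speed of
#' 1e5 um/s over a 250 um droplet this gives 400 inputs/s (0.4 kHz), and
#' 4e3 cycles within a 10 s stability window.
#'
#' @param signal_speed Signal propagation speed, um/s.
#' @param machine_size Maximum linear droplet size, um.
#' @param stability_window Time the network stays fixed, s.
#' @return List with `inputs_per_second` and `cycles_in_window`.
#' @export
throughput_estimate <- function(signal_speed = 1e5, machine_size = 250,
                                stability_window = 10) {
  if (machine_size <= 0) stop("`machine_size` must be > 0", call. = FALSE)
  if (signal_speed <= 0) stop("`signal_speed` must be > 0", call. = FALSE)
  if (stability_window < 0)
    stop("`stability_window` must be >= 0", call. = FALSE)
  ips <- signal_speed / machine_size
  list(inputs_per_second = ips, cycles_in_window = ips * stability_window)
}

#' Write a potential trace to CSV
#'
#' One row per time step, one column per electrode, plus a leading `t`
#' column.
#'
#' @param trace A `potential_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(t = seq_len(nrow(trace)), unclass(trace),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a richness table to CSV
#'
#' Columns `t`, `mu`, `states` (comma-joined decimals).
#'
#' @param rich Output of [richness()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_richness_csv <- function(rich, path) {
  df <- data.frame(
    t = rich$by_step$t, mu = rich$by_step$mu,
    states = vapply(rich$by_step$states, paste, "", collapse = ","))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a transition graph
#'
#' @param graph An igraph transition graph.
#' @param path Output path.
#' @param format `"dot"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_transition_graph <- function(graph, path,
                                   format = c("dot", "graphml")) {
  format <- match.arg(format)
  igraph::write_graph(graph, path, format = format)
  invisible(path)
}

#' Run the full droplet-machine pipeline
#'
#' Orchestrates network construction (or loading), per-input
#' stimulation, spike extraction, transition-graph analysis, richness
#' statistics and Boolean-function reconstruction, writing every
#' artifact plus a manifest (parameters and md5 checksums) to
#' `out_dir`. Deterministic for a fixed configuration.
#'
#' @param matrix A [conductive_matrix], or a [synth_spec] to generate
#'   one.
#' @param electrodes An [electrode_table], or `NULL` to place `k`
#'   electrodes with [place_electrodes()].
#' @param out_dir Output directory (created if missing).
#' @param k Number of electrodes when `electrodes` is `NULL`.
#' @param params A [ca_params].
#' @param steps Automaton steps per input.
#' @param inputs Input decimals (default all non-zero k-bit strings).
#' @param r_e Electrode radius for placed electrodes.
#' @param amp_threshold,window Spike-detection parameters.
#' @param g_step Event index at which Boolean functions are
#'   reconstructed; default the step of maximum richness.
#' @return Invisibly, a list with the compiled network, electrode table,
#'   machine outputs, graphs, richness, reconstructed DNFs and the
#'   manifest path.
#' @export
run_pipeline <- function(matrix, electrodes = NULL, out_dir, k = 6L,
                         params = ca_params(), steps = 300L,
                         inputs = NULL, r_e = 4,
                         amp_threshold = 1, window = 6L, g_step = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(matrix, "synth_spec")) matrix <- synth_network(matrix)
  stopifnot(inherits(matrix, "conductive_matrix"))
  net <- ca_network(matrix, params$radius)
  if (is.null(electrodes)) electrodes <- place_electrodes(net, k, r_e)
  k <- nrow(electrodes)
  if (is.null(inputs)) inputs <- seq_len(2L^k - 1L)

  utils::write.csv(as.data.frame(electrodes),
                   file.path(out_dir, "electrodes.csv"), row.names = FALSE)

  machine <- run_machine(net, electrodes, params, steps, inputs,
                         amp_threshold, window, keep_traces = TRUE)
  for (key in names(machine$traces))
    write_trace_csv(machine$traces[[key]],
                    file.path(out_dir, sprintf("trace_%s.csv", key)))
  for (key in names(machine$trains))
    write_spikes_json(machine$trains[[key]],
                      file.path(out_dir, sprintf("spikes_%s.json", key)))

  seq_df <- do.call(rbind, lapply(names(machine$sequences), function(key) {
    s <- machine$sequences[[key]]
    if (nrow(s) == 0L) return(NULL)
    data.frame(input = key, event = seq_len(nrow(s)), time = s$time,
               state = s$state, stringsAsFactors = FALSE)
  }))
  if (is.null(seq_df))
    seq_df <- data.frame(input = character(0), event = integer(0),
                         time = integer(0), state = integer(0))
  utils::write.csv(seq_df, file.path(out_dir, "state_sequences.csv"),
                   row.names = FALSE)

  G <- weighted_global_graph(machine$sequences)
  Gstar <- prune_graph(G)
  rich <- richness(machine$sequences)
  write_transition_graph(G, file.path(out_dir, "graph_G.dot"), "dot")
  write_transition_graph(G, file.path(out_dir, "graph_G.graphml"), "graphml")
  write_transition_graph(Gstar, file.path(out_dir, "graph_Gstar.dot"), "dot")
  utils::write.csv(node_classes(Gstar),
                   file.path(out_dir, "node_classes.csv"), row.names = FALSE)
  write_richness_csv(rich, file.path(out_dir, "richness.csv"))

  dnfs <- list(); g_map <- integer(0)
  if (nrow(rich$by_step) > 0L) {
    if (is.null(g_step)) g_step <- rich$by_step$t[which.max(rich$by_step$mu)]
    g_map <- g_of_t(machine$sequences, g_step)
    dnf_txt <- character(k)
    for (e in seq_len(k) - 1L) {
      tab <- table_from_g(g_map, e, k)
      dnfs[[e + 1L]] <- minimize_dnf(tab)
      dnf_txt[e + 1L] <- sprintf("f%d = %s", e, dnf_to_string(dnfs[[e + 1L]]))
    }
    writeLines(dnf_txt, file.path(out_dir, "dnf.txt"))
    jsonlite::write_json(
      list(t = g_step,
           g = as.list(stats::setNames(as.integer(g_map), names(g_map)))),
      file.path(out_dir, sprintf("g_t%d.json", g_step)),
      auto_unbox = TRUE, digits = NA)
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    parameters = list(theta = params$theta, delta = params$delta,
                      radius = params$radius, steps = steps,
                      k = k, inputs = inputs, r_e = r_e,
                      amp_threshold = amp_threshold, window = window),
    network = list(dims = net$dims, conductive = net$n),
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(net = net, electrodes = electrodes, machine = machine,
                 G = G, Gstar = Gstar, richness = rich, dnfs = dnfs,
                 g_step = if (length(g_map)) g_step else NA_integer_,
                 manifest = manifest_path))
}
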