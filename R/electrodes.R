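#' Electrode tables
#'
#' Electrodes are spherical voxel domains used both to inject impulses
#' (setting conductive voxels excited) and to record potential (counting
#' excited voxels). Both operations use the strict criterion
#' `d(centre, voxel) < radius` with the default radius of 4 voxels.
#'
#' `electrode_table()` builds a table from vectors; `read_electrodes()`
#' reads the CSV format `label,i,j,z,radius` (comment lines start with
#' `#`). Two fixture tables are shipped with the package: `electrodes_E1`
#' (ten electrodes; by convention `e0` and `e9` are inputs and the rest
#' outputs) and `electrodes_E2` (the six-electrode machine wiring in which
#' every electrode is both input and output; the shipped file carries all
#' eight parseable coordinate rows, and configurations select which six
#' labels form the machine).
#'
#' @param label Character electrode labels.
#' @param i,j,z Integer voxel coordinates of the electrode centres.
#' @param radius Electrode radius in voxels (recycled).
#' @return A `data.frame` of class `electrode_table`.
#' @export
electrode_table <- function(label, i, j, z, radius = 4) {
  df <- data.frame(label = as.character(label), i = as.integer(i),
                   j = as.integer(j), z = as.integer(z),
                   radius = as.numeric(radius),
                   stringsAsFactors = FALSE)
  if (anyNA(df)) stop("electrode table contains missing values", call. = FALSE)
  if (any(df$radius <= 0)) stop("electrode radius must be > 0", call. = FALSE)
  if (anyDuplicated(df$label)) stop("duplicate electrode labels", call. = FALSE)
  class(df) <- c("electrode_table", "data.frame")
  df
}

#' @rdname electrode_table
#' @param path CSV file path.
#' @export
read_electrodes <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("label", "i", "j", "z")
  if (!all(need %in% names(df)))
    stop("electrode CSV must have columns label,i,j,z[,radius]", call. = FALSE)
  if (is.null(df$radius)) df$radius <- 4
  electrode_table(df$label, df$i, df$j, df$z, df$radius)
}

#' Check electrodes against a grid
#'
#' @param electrodes An [electrode_table].
#' @param dims Integer grid shape.
#' @return `electrodes`, invisibly; errors if any centre lies outside.
#' @export
validate_electrodes <- function(electrodes, dims) {
  bad <- electrodes$i < 1 | electrodes$i > dims[1] |
         electrodes$j < 1 | electrodes$j > dims[2] |
         electrodes$z < 1 | electrodes$z > dims[3]
  if (any(bad))
    stop("electrode(s) outside the grid: ",
         paste(electrodes$label[bad], collapse = ", "), call. = FALSE)
  invisible(electrodes)
}

#' Binary input strings and their decimal encoding
#'
#' Input (and machine-state) strings use `e0` as the most significant
#' bit: the string with a single 1 on the last electrode `e(k-1)` encodes
#' decimal 1, a single 1 on `e0` encodes `2^(k-1)`.
#'
#' @param decimal Integer in `0 .. 2^k - 1`.
#' @param k Number of electrodes / string length.
#' @return `pattern_bits()`: integer 0/1 vector of length `k`;
#'   `pattern_decimal()`: integer.
#' @export
pattern_bits <- function(decimal, k) {
  decimal <- as.integer(decimal)
  if (decimal < 0L || decimal > 2^k - 1)
    stop("`decimal` out of range for k = ", k, call. = FALSE)
  as.integer(intToBits(decimal))[k:1]
}

#' @rdname pattern_bits
#' @param bits Integer 0/1 vector, `bits[1]` addressed to `e0`.
#' @export
pattern_decimal <- function(bits) {
  bits <- as.integer(bits)
  if (any(!bits %in% c(0L, 1L))) stop("`bits` must be 0/1", call. = FALSE)
  as.integer(sum(bits * 2^(rev(seq_along(bits)) - 1L)))
}

electrode_voxel_ids <- function(net, centre, radius) {
  d2 <- (net$coords[, 1] - centre[1])^2 + (net$coords[, 2] - centre[2])^2 +
        (net$coords[, 3] - centre[3])^2
  which(d2 < radius^2)
}

#' Conductive voxels belonging to each electrode sphere
#'
#' @param net A [ca_network].
#' @param electrodes An [electrode_table].
#' @return Named list of integer voxel-id vectors (strict `d < radius`).
#' @export
electrode_voxels <- function(net, electrodes) {
  validate_electrodes(electrodes, net$dims)
  out <- lapply(seq_len(nrow(electrodes)), function(r)
    electrode_voxel_ids(net, c(electrodes$i[r], electrodes$j[r],
                               electrodes$z[r]), electrodes$radius[r]))
  names(out) <- electrodes$label
  out
}

#' Apply an input impulse pattern
#'
#' For every electrode whose bit is 1, all conductive voxels strictly
#' closer than the electrode radius to its centre are set excited.
#' Refractory voxels are not overridden; bit-0 electrodes leave the
#' lattice untouched.
#'
#' @param lattice A `ca_lattice`.
#' @param net A [ca_network].
#' @param electrodes An [electrode_table] with one row per bit.
#' @param bits Integer 0/1 vector, `bits[i]` addressed to electrode row
#'   `i`.
#' @return The stimulated `ca_lattice`.
#' @export
stimulate <- function(lattice, net, electrodes, bits) {
  if (length(bits) != nrow(electrodes))
    stop("pattern length must equal the number of electrodes", call. = FALSE)
  vox <- electrode_voxels(net, electrodes)
  for (idx in seq_along(bits)) {
    if (bits[idx] == 1L) {
      ids <- vox[[idx]]
      ids <- ids[lattice$state[ids] == ST_RESTING]
      lattice$state[ids] <- ST_EXCITED
    }
  }
  lattice
}

#' Record the potential at one electrode
#'
#' The potential is the count of excited voxels strictly closer than the
#' electrode radius to its centre.
#'
#' @param lattice A `ca_lattice`.
#' @param net A [ca_network].
#' @param electrode One-row [electrode_table] (or a row of one).
#' @return Integer count.
#' @export
record_potential <- function(lattice, net, electrode) {
  validate_electrodes(electrode, net$dims)
  ids <- electrode_voxel_ids(net, c(electrode$i[1], electrode$j[1],
                                    electrode$z[1]), electrode$radius[1])
  sum(lattice$state[ids] == ST_EXCITED)
}

#' Run one stimulation experiment and record potential traces
#'
#' Starts from an all-resting lattice, applies the input impulse pattern
#' at step 0 (optionally repeating it for the first `stim_steps` steps),
#' runs the automaton for `steps` steps and records the potential at
#' every electrode after each step.
#'
#' @param net A [ca_network].
#' @param electrodes An [electrode_table].
#' @param bits Integer 0/1 input pattern, one bit per electrode row.
#' @param params A [ca_params].
#' @param steps Number of automaton steps `T`.
#' @param record Optional [electrode_table] of recording electrodes;
#'   defaults to `electrodes`.
#' @param stim_steps Impulse duration in steps (default 1: a single-step
#'   impulse at `t = 0`).
#' @return A `potential_trace`: integer matrix with `steps` rows (time
#'   `t = 1..T`) and one column per recording electrode.
#' @export
run_experiment <- function(net, electrodes, bits, params, steps,
                           record = electrodes, stim_steps = 1L) {
  validate_electrodes(electrodes, net$dims)
  validate_electrodes(record, net$dims)
  rec_vox <- electrode_voxels(net, record)
  trace <- matrix(0L, nrow = steps, ncol = nrow(record),
                  dimnames = list(NULL, record$label))
  lattice <- stimulate(new_lattice(net), net, electrodes, bits)
  for (t in seq_len(steps)) {
    lattice <- ca_step(lattice, net, params)
    if (t < stim_steps)
      lattice <- stimulate(lattice, net, electrodes, bits)
    exc <- lattice$state == ST_EXCITED
    trace[t, ] <- vapply(rec_vox, function(ids) sum(exc[ids]), 0L)
  }
  structure(trace, class = c("potential_trace", class(trace)))
}

#' Deterministically place electrodes on a network
#'
#' Farthest-point sampling over the conductive voxels: the first
#' electrode is the conductive voxel nearest the grid centre, each
#' further electrode the voxel maximizing the minimum distance to those
#' already chosen (smallest voxel id on ties). Useful for synthetic
#' networks that come without a laboratory electrode table.
#'
#' @param net A [ca_network].
#' @param k Number of electrodes.
#' @param radius Electrode radius in voxels.
#' @return An [electrode_table] with labels `e0 .. e(k-1)`.
#' @export
place_electrodes <- function(net, k, radius = 4) {
  if (net$n < k) stop("fewer conductive voxels than electrodes", call. = FALSE)
  ctr <- (net$dims + 1) / 2
  d2c <- rowSums(sweep(net$coords, 2, ctr)^2)
  chosen <- which.min(d2c)
  mind2 <- rowSums(sweep(net$coords, 2, net$coords[chosen, ])^2)
  while (length(chosen) < k) {
    nxt <- which.max(mind2)
    chosen <- c(chosen, nxt)
    mind2 <- pmin(mind2, rowSums(sweep(net$coords, 2, net$coords[nxt, ])^2))
  }
  electrode_table(paste0("e", seq_len(k) - 1L),
                  net$coords[chosen, 1], net$coords[chosen, 2],
                  net$coords[chosen, 3], radius)
}
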