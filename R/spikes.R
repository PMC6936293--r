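#' Detect spikes in potential traces
#'
#' A spike is registered at each local maximum of a per-electrode
#' potential series whose value reaches `amp_threshold`. Since potentials
#' are integer excited-voxel counts, the default threshold of 1 treats
#' any non-zero local peak as an impulse passing the electrode. On a
#' plateau of equal consecutive values the first step of the plateau is
#' taken as the spike time. Spikes closer than `window` iterations are
#' then merged, keeping the earlier time, so consecutive spike times in
#' the result always differ by at least `window`.
#'
#' @param trace A `potential_trace` matrix (time x electrode) or a single
#'   numeric series.
#' @param amp_threshold Non-negative amplitude threshold.
#' @param window Positive integer coincidence window (default 6
#'   iterations).
#' @return A `spike_train`: named list of strictly increasing integer
#'   spike-time vectors, one per electrode, with the detection parameters
#'   as attributes.
#' @export
detect_spikes <- function(trace, amp_threshold = 1, window = 6L) {
  if (amp_threshold < 0) stop("`amp_threshold` must be >= 0", call. = FALSE)
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("`window` must be >= 1", call. = FALSE)
  if (is.null(dim(trace))) trace <- matrix(trace, ncol = 1,
                                           dimnames = list(NULL, "e0"))
  labels <- colnames(trace)
  if (is.null(labels)) labels <- paste0("e", seq_len(ncol(trace)) - 1L)
  out <- lapply(seq_len(ncol(trace)), function(cix)
    detect_spikes_series(trace[, cix], amp_threshold, window))
  names(out) <- labels
  structure(out, amp_threshold = amp_threshold, window = window,
            class = "spike_train")
}

detect_spikes_series <- function(v, amp_threshold, window) {
  if (length(v) == 0L) return(integer(0))
  r <- rle(as.numeric(v))
  k <- length(r$values)
  starts <- cumsum(c(1L, r$lengths[-k]))
  prev <- c(-Inf, r$values[-k])
  nxt <- c(r$values[-1], -Inf)
  peak <- r$values > prev & r$values > nxt &
          r$values >= amp_threshold & r$values > 0
  merge_spike_times(starts[peak], window)
}

merge_spike_times <- function(times, window) {
  times <- sort(as.integer(times))
  if (length(times) <= 1L) return(times)
  keep <- times[1]
  for (t in times[-1])
    if (t - keep[length(keep)] >= window) keep <- c(keep, t)
  keep
}

#' Group spikes into coincidence events
#'
#' Spikes less than `window` iterations apart are treated as happening at
#' the same moment. Grouping is single-linkage on the time axis with
#' linking distance strictly below `window`, across all electrodes: a
#' chain of spikes each within `window - 1` steps of the next forms one
#' group. Each spike belongs to exactly one group; groups are ordered by
#' their representative (earliest member) time.
#'
#' @param trains A `spike_train` (or named list of spike-time vectors).
#' @param window Positive integer coincidence window.
#' @return An object of class `coincidence_groups`: a list of groups,
#'   each with `time` (earliest member time) and `members` (data frame
#'   with columns `electrode`, `time`).
#' @export
group_coincident <- function(trains, window = 6L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("`window` must be >= 1", call. = FALSE)
  df <- data.frame(
    electrode = rep(names(trains), lengths(trains)),
    time = as.integer(unlist(trains, use.names = FALSE)),
    stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    return(structure(list(), window = window, class = "coincidence_groups"))
  df <- df[order(df$time, df$electrode), , drop = FALSE]
  gap <- c(0L, diff(df$time))
  df$group <- cumsum(gap >= window) + 1L
  groups <- lapply(split(df[c("electrode", "time")], df$group), function(m) {
    rownames(m) <- NULL
    list(time = min(m$time), members = m)
  })
  names(groups) <- NULL
  structure(groups, window = window, class = "coincidence_groups")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d electrode(s), threshold %.3g, window %d\n",
              length(x), attr(x, "amp_threshold"), attr(x, "window")))
  for (e in names(x))
    cat(sprintf("  %s: %s\n", e,
                if (length(x[[e]])) paste(x[[e]], collapse = " ") else "-"))
  invisible(x)
}

#' Serialize spike trains to JSON
#'
#' Writes `{electrode: [times], ...}` together with the detection
#' metadata.
#'
#' @param trains A `spike_train`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spikes_json <- function(trains, path) {
  obj <- list(spikes = lapply(unclass(trains), as.integer),
              amp_threshold = attr(trains, "amp_threshold"),
              window = attr(trains, "window"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
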