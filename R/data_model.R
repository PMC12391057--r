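#' Spike train within one analysis window
#'
#' A spike train is the ordered sequence of action-potential times emitted by
#' one neuron within one fixed-duration window, with times in seconds
#' relative to the window start.
#'
#' @param times numeric vector of spike times (seconds), sorted
#'   non-decreasing, all within `[0, duration]`. Simultaneous duplicate
#'   times are kept (the edit-distance metric handles multisets) but trigger
#'   a warning.
#' @param duration window length in seconds, `> 0`.
#' @return An object of class `spike_train`: a list with elements `times`
#'   and `duration`.
#' @export
spike_train <- function(times = numeric(0), duration = 1) {
  times <- as.numeric(times)
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0)
    stop("'duration' must be a single positive number (seconds)")
  if (anyNA(times)) stop("spike times must not contain NA")
  if (is.unsorted(times)) stop("spike times must be sorted non-decreasing")
  if (length(times) && (times[1L] < 0 || times[length(times)] > duration))
    stop("spike times must lie within [0, duration]")
  if (anyDuplicated(times))
    warning("duplicate spike times kept")
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes in %.3g s\n", length(x$times),
              x$duration))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Ensemble recording: N neurons x S equal-duration windows
#'
#' The input object of the pipeline: a complete grid of spike trains for `N`
#' simultaneously recorded neurons over `S` equal-duration time windows
#' (trials or arbitrary segments). Empty trains are allowed; missing grid
#' entries are not.
#'
#' @param trains list of length `N` (one element per neuron, names are
#'   neuron ids), each a list of length `S` of numeric spike-time vectors
#'   (seconds, relative to window start).
#' @param duration common window duration in seconds.
#' @param windows optional data frame with columns `window_id` and
#'   optionally `label` (condition), `start_s`. Defaults to ids `w1..wS`.
#' @param neuron_ids optional character vector overriding `names(trains)`.
#' @return Object of class `ensemble_recording` with elements `trains`
#'   (N-list of S-lists of numeric vectors), `neuron_ids`, `windows`
#'   (data frame), `duration`, `n_neurons`, `n_windows`.
#' @export
ensemble_recording <- function(trains, duration, windows = NULL,
                               neuron_ids = NULL) {
  if (!is.list(trains) || length(trains) < 2L)
    stop("need at least N = 2 neurons")
  n <- length(trains)
  if (is.null(neuron_ids)) neuron_ids <- names(trains)
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(n))
  s_per <- vapply(trains, length, 0L)
  if (length(unique(s_per)) != 1L)
    stop("incomplete grid: neurons have differing window counts (",
         paste(unique(s_per), collapse = ", "), ")")
  s <- s_per[[1L]]
  if (s < 3L) stop("need at least S = 3 windows")
  trains <- lapply(trains, function(tr) lapply(tr, function(t) {
    t <- as.numeric(t)
    if (is.unsorted(t)) t <- sort(t)
    if (length(t) && (t[1L] < 0 || t[length(t)] > duration))
      stop("spike time outside [0, duration = ", duration, "]")
    t
  }))
  if (is.null(windows)) {
    windows <- data.frame(window_id = paste0("w", seq_len(s)),
                          stringsAsFactors = FALSE)
  }
  windows <- as.data.frame(windows)
  if (nrow(windows) != s)
    stop("'windows' has ", nrow(windows), " rows but trains have ", s,
         " windows")
  if (is.null(windows$window_id))
    windows$window_id <- paste0("w", seq_len(s))
  names(trains) <- neuron_ids
  structure(list(trains = trains, neuron_ids = neuron_ids, windows = windows,
                 duration = duration, n_neurons = n, n_windows = s),
            class = "ensemble_recording")
}

#' @export
print.ensemble_recording <- function(x, ...) {
  cat(sprintf("<ensemble_recording> N = %d neurons x S = %d windows of %.3g s\n",
              x$n_neurons, x$n_windows, x$duration))
  if (!is.null(x$windows$label))
    cat("  conditions:", paste(unique(x$windows$label), collapse = ", "), "\n")
  invisible(x)
}

#' Read a long-format spike table
#'
#' Reads a delimited file with header columns `neuron_id`, `window_id`,
#' `spike_time_s` (one row per spike, times relative to window start) into
#' an [ensemble_recording]. Neurons and windows are ordered by first
#' appearance; a (neuron, window) pair with no rows yields an empty train
#' provided the window is known (declared in the sidecar or appearing for
#' another neuron).
#'
#' @param path path to the spike table.
#' @param windows optional window sidecar: a data frame or path to a
#'   delimited file with columns `window_id`, `duration_s`, and optionally
#'   `label`, `start_s`. All durations must be equal.
#' @param duration common window duration in seconds; required when no
#'   sidecar supplies `duration_s`.
#' @param sep field separator; `NULL` (default) auto-detects `,` vs tab.
#' @return An [ensemble_recording].
#' @export
read_spike_table <- function(path, windows = NULL, duration = NULL,
                             sep = NULL) {
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("neuron_id", "window_id", "spike_time_s")
  if (!all(need %in% names(df)))
    stop("spike table must have columns: ", paste(need, collapse = ", "))
  win_df <- NULL
  if (!is.null(windows)) {
    win_df <- if (is.character(windows))
      read.table(windows, header = TRUE, sep = sniff_sep(windows),
                 stringsAsFactors = FALSE)
    else as.data.frame(windows)
    if (!is.null(win_df$duration_s)) {
      durs <- unique(win_df$duration_s)
      if (length(durs) > 1L)
        stop("windows must share one duration; offending window_id(s): ",
             paste(win_df$window_id[win_df$duration_s != durs[1L]],
                   collapse = ", "))
      duration <- durs[1L]
    }
  }
  if (is.null(duration))
    stop("supply 'duration' or a windows sidecar with a duration_s column")
  bad <- which(df$spike_time_s < 0 | df$spike_time_s > duration)
  if (length(bad))
    stop("spike_time_s outside [0, ", duration, "] at data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (anyDuplicated(df[need]))
    warning("duplicate (neuron, window, time) rows kept")
  neuron_ids <- unique(as.character(df$neuron_id))
  window_ids <- if (!is.null(win_df)) as.character(win_df$window_id)
                else unique(as.character(df$window_id))
  unknown <- setdiff(unique(as.character(df$window_id)), window_ids)
  if (length(unknown))
    stop("window id(s) in spike table but not in sidecar: ",
         paste(unknown, collapse = ", "))
  trains <- lapply(neuron_ids, function(nid) {
    sub <- df[df$neuron_id == nid, , drop = FALSE]
    lapply(window_ids, function(wid)
      sort(sub$spike_time_s[sub$window_id == wid]))
  })
  names(trains) <- neuron_ids
  wdf <- data.frame(window_id = window_ids, stringsAsFactors = FALSE)
  if (!is.null(win_df$label)) wdf$label <- win_df$label
  if (!is.null(win_df$start_s)) wdf$start_s <- win_df$start_s
  ensemble_recording(trains, duration = duration, windows = wdf)
}

#' Write an ensemble recording as a long-format spike table
#'
#' Inverse of [read_spike_table()]: one row per spike with columns
#' `neuron_id`, `window_id`, `spike_time_s`.
#'
#' @param rec an [ensemble_recording].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "ensemble_recording"))
  rows <- do.call(rbind, lapply(seq_along(rec$trains), function(i) {
    tr <- rec$trains[[i]]
    do.call(rbind, lapply(seq_along(tr), function(j) {
      if (!length(tr[[j]])) return(NULL)
      data.frame(neuron_id = rec$neuron_ids[i],
                 window_id = rec$windows$window_id[j],
                 spike_time_s = tr[[j]], stringsAsFactors = FALSE)
    }))
  }))
  write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a structured JSON spike document
#'
#' Reads a JSON document of the form
#' `{"duration_s": ..., "windows": [{"window_id": ..., "label": ...}, ...],
#'   "neurons": {"<id>": {"<window_id>": [times], ...}, ...}}`
#' into an [ensemble_recording]. Windows absent from a neuron's entry yield
#' empty trains.
#'
#' @param path path to the JSON file.
#' @return An [ensemble_recording].
#' @export
read_spike_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$duration_s) || is.null(doc$neurons))
    stop("JSON document must contain duration_s and neurons")
  wdf <- as.data.frame(doc$windows)
  window_ids <- as.character(wdf$window_id)
  trains <- lapply(doc$neurons, function(nw)
    lapply(window_ids, function(wid) {
      t <- nw[[wid]]
      if (is.null(t)) numeric(0) else sort(as.numeric(t))
    }))
  ensemble_recording(trains, duration = doc$duration_s, windows = wdf)
}

#' Segment continuous spike streams into equal-duration windows
#'
#' Extracts, for each neuron and each window, the spikes falling in the
#' half-open interval `[start_s, start_s + duration_s)` on the global clock,
#' re-referenced to the window start. A spike exactly at a window's end
#' boundary belongs to the following window only. Overlapping windows are
#' permitted (spikes are duplicated across them) and reported via a message.
#'
#' @param streams named list of sorted numeric spike-time vectors, one per
#'   neuron, on a common clock (seconds).
#' @param windows data frame with columns `window_id`, `start_s`,
#'   `duration_s` (all durations equal) and optionally `label`.
#' @return An [ensemble_recording].
#' @export
segment_stream <- function(streams, windows) {
  windows <- as.data.frame(windows)
  stopifnot(all(c("window_id", "start_s", "duration_s") %in% names(windows)))
  durs <- unique(windows$duration_s)
  if (length(durs) != 1L)
    stop("windows must share one duration; offending window_id(s): ",
         paste(windows$window_id[windows$duration_s != durs[1L]],
               collapse = ", "))
  dur <- durs[1L]
  o <- order(windows$start_s)
  if (any(diff(windows$start_s[o]) < dur - 1e-12))
    message("overlapping windows: spikes will be duplicated across windows")
  trains <- lapply(streams, function(st) {
    st <- sort(as.numeric(st))
    lapply(seq_len(nrow(windows)), function(i) {
      s0 <- windows$start_s[i]
      st[st >= s0 & st < s0 + dur] - s0
    })
  })
  ensemble_recording(trains, duration = dur, windows = windows)
}

#' Write / read a square labelled matrix
#'
#' Writes a numeric matrix as a delimited table with row and column headers;
#' non-finite entries are a hard error. `read_matrix()` is the inverse.
#'
#' @param m square numeric matrix with finite entries.
#' @param path output (input) file path.
#' @param sep field separator.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()` the
#'   matrix.
#' @export
write_matrix <- function(m, path, sep = ",") {
  m <- as.matrix(m)
  if (!all(is.finite(m))) stop("matrix contains non-finite entries")
  if (is.null(rownames(m))) {
    rn <- paste0("r", seq_len(nrow(m)))
    dimnames(m) <- list(rn, rn)
  }
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, sep = ",") {
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

sniff_sep <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (grepl("\t", l1)) "\t" else ","
}
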