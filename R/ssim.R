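#' Per-neuron spike-train similarity (SSIM) matrices
#'
#' Computes, for every neuron in the recording, the `S x S` matrix of
#' Victor-Purpura distances among its `S` spike trains — the neuron's
#' "computational fingerprint". Each matrix captures the intrinsic geometry
#' of that neuron's output space: which windows evoked similar spiking and
#' which did not, without reference to any external labels.
#'
#' Exactly `N * S * (S - 1) / 2` pairwise spike-train comparisons are
#' performed (linear in the number of neurons); the count is recorded in the
#' result.
#'
#' @param rec an [ensemble_recording].
#' @param q Victor-Purpura shift cost rate (1/seconds); temporal accuracy of
#'   the comparison is `1/q`. See [vp_distance()].
#' @return An object of class `ssim_set`: list with `matrices` (named list
#'   of `S x S` symmetric matrices, zero diagonal), `window_ids`, `q`,
#'   `degenerate` (ids of neurons whose off-diagonal is constant, e.g.
#'   fully silent neurons), and `n_comparisons`.
#' @export
compute_ssims <- function(rec, q) {
  stopifnot(inherits(rec, "ensemble_recording"))
  check_q(q)
  wids <- as.character(rec$windows$window_id)
  mats <- lapply(rec$trains, function(tr) {
    m <- .vp_distance_matrix_cpp(tr, q)
    dimnames(m) <- list(wids, wids)
    m
  })
  names(mats) <- rec$neuron_ids
  degen <- names(mats)[vapply(mats, function(m)
    sd(m[upper.tri(m)]) == 0, TRUE)]
  s <- rec$n_windows
  structure(list(matrices = mats, window_ids = wids, q = q,
                 degenerate = degen,
                 n_comparisons = rec$n_neurons * s * (s - 1) / 2),
            class = "ssim_set")
}

#' @export
print.ssim_set <- function(x, ...) {
  cat(sprintf("<ssim_set> %d neurons x (%d x %d) VP distance matrices, q = %g\n",
              length(x$matrices), length(x$window_ids), length(x$window_ids),
              x$q))
  if (length(x$degenerate))
    cat("  degenerate (constant) fingerprints:",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Combined SSIM matrix for a subset of neurons
#'
#' Extends the single-neuron fingerprint to the meso/population scale: the
#' combined output-space distance between two windows is the sum over the
#' selected neurons of their single-neuron Victor-Purpura distances (the
#' additive, labelled-line extension; a single-neuron subset reproduces that
#' neuron's own SSIM matrix exactly).
#'
#' @param rec an [ensemble_recording].
#' @param neurons character vector of neuron ids (or integer indices).
#' @param q Victor-Purpura shift cost rate (1/seconds).
#' @return `S x S` symmetric matrix, zero diagonal.
#' @export
subset_ssim <- function(rec, neurons, q) {
  stopifnot(inherits(rec, "ensemble_recording"))
  if (is.numeric(neurons)) neurons <- rec$neuron_ids[neurons]
  if (!length(neurons)) stop("'neurons' must be non-empty")
  bad <- setdiff(neurons, rec$neuron_ids)
  if (length(bad)) stop("unknown neuron id(s): ", paste(bad, collapse = ", "))
  check_q(q)
  wids <- as.character(rec$windows$window_id)
  acc <- NULL
  for (nid in neurons) {
    m <- .vp_distance_matrix_cpp(rec$trains[[nid]], q)
    acc <- if (is.null(acc)) m else acc + m
  }
  dimnames(acc) <- list(wids, wids)
  acc
}

#' Low-dimensional map of one SSIM matrix
#'
#' Embeds the `S` windows of a single (or combined) SSIM matrix into 2-D or
#' 3-D coordinates, so that nearby points correspond to windows in which the
#' neuron emitted similar spike trains. A thin wrapper around [embed_map()].
#'
#' @param m `S x S` SSIM matrix (as from [compute_ssims()] or
#'   [subset_ssim()]).
#' @param dims 2 or 3 output dimensions (default 2 for single-neuron maps).
#' @param ... further arguments passed to [embed_map()] (`perplexity`,
#'   `seed`, `method`, `max_iter`).
#' @return matrix of coordinates, one row per window.
#' @export
ssim_map <- function(m, dims = 2, ...) {
  embed_map(m, dims = dims, ...)
}
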