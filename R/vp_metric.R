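#' Victor-Purpura edit distance between two spike trains
#'
#' Computes the minimum total cost of transforming one spike train into
#' another through single-spike edits: inserting or deleting a spike costs 1,
#' and shifting a spike by \eqn{\Delta t} seconds costs \eqn{q\,\Delta t}.
#' The cost rate `q` (1/seconds) sets the temporal accuracy of the
#' comparison, `1/q`: at `q = 0` the distance reduces to the difference in
#' spike counts (a pure rate comparison), while large `q` makes the metric
#' sensitive to fine spike timing, approaching
#' \eqn{|a| + |b| - 2 \times} (number of exactly coincident spikes).
#'
#' The distance is computed with the standard dynamic program over spike
#' indices, which is exact and runs in `O(length(a) * length(b))`.
#'
#' @param a,b numeric vectors of sorted spike times (seconds), or
#'   [spike_train] objects.
#' @param q non-negative shift cost rate in 1/seconds; temporal accuracy is
#'   `1/q`.
#' @return A single non-negative number, bounded by `length(a) + length(b)`.
#'   The distance is a proper metric on spike trains (symmetric, zero iff
#'   equal, triangle inequality).
#' @examples
#' vp_distance(c(0.1, 0.5), c(0.1, 0.5), q = 10)  # identical -> 0
#' vp_distance(c(0.1), c(0.3), q = 2)             # shift: 2 * 0.2 = 0.4
#' vp_distance(c(0.1), c(0.3), q = 20)            # delete + insert = 2
#' @seealso [vp_distance_matrix()] for all pairwise distances among a set of
#'   trains, [compute_ssims()] for per-neuron fingerprints.
#' @export
vp_distance <- function(a, b, q) {
  a <- spike_times(a)
  b <- spike_times(b)
  check_q(q)
  .vp_distance_cpp(a, b, q)
}

#' Pairwise Victor-Purpura distance matrix for a set of spike trains
#'
#' Evaluates [vp_distance()] over all `S(S-1)/2` unique pairs of trains and
#' returns the symmetric `S x S` matrix with zero diagonal. This is the
#' spike-train similarity (SSIM) matrix of one neuron when the trains are
#' that neuron's windows.
#'
#' @param trains list of numeric spike-time vectors (or [spike_train]s),
#'   `S >= 3`.
#' @param q shift cost rate (1/seconds), see [vp_distance()].
#' @param ids optional character vector of row/column names.
#' @return `S x S` symmetric numeric matrix, zero diagonal.
#' @export
vp_distance_matrix <- function(trains, q, ids = NULL) {
  if (!is.list(trains) || length(trains) < 3L)
    stop("'trains' must be a list of at least 3 spike trains")
  tt <- lapply(trains, spike_times)
  check_q(q)
  m <- .vp_distance_matrix_cpp(tt, q)
  if (!is.null(ids)) dimnames(m) <- list(ids, ids)
  m
}

# Coerce to a sorted-spike-time vector, validating order.
spike_times <- function(x) {
  if (inherits(x, "spike_train")) x <- x$times
  x <- as.numeric(x)
  if (anyNA(x)) stop("spike times must not contain NA")
  if (is.unsorted(x)) stop("spike times must be sorted non-decreasing")
  x
}

check_q <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0)
    stop("'q' must be a single finite non-negative number (1/seconds)")
  invisible(q)
}
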