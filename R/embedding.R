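#' Deterministic MDS initialization for t-SNE
#'
#' Classical (metric) multidimensional scaling of a precomputed distance
#' matrix — double-centered Gram eigendecomposition — taken as the
#' "PCA-style" non-random initialization for t-SNE. Since the pipeline works
#' on distance matrices rather than a raw feature table, classical MDS plays
#' the role PCA plays for tabular data, and makes the embedding fully
#' reproducible. Axis signs are fixed so that each axis's largest-magnitude
#' coordinate is positive; coordinates are rescaled to the small magnitude
#' (sd 1e-4 on the first axis) conventionally used to initialize t-SNE.
#'
#' @param d square symmetric distance matrix with zero diagonal.
#' @param dims number of output dimensions.
#' @param scale logical; rescale to t-SNE init magnitude (default `TRUE`).
#'   With `scale = FALSE` the raw MDS configuration is returned (used by the
#'   exact-MDS embedding method).
#' @return `P x dims` coordinate matrix.
#' @export
mds_initialize <- function(d, dims = 2, scale = TRUE) {
  d <- check_dist_matrix(d)
  p <- nrow(d)
  y <- suppressWarnings(cmdscale(stats::as.dist(d), k = min(dims, p - 1)))
  if (ncol(y) < dims)  # rank-deficient configurations: pad with zeros
    y <- cbind(y, matrix(0, p, dims - ncol(y)))
  for (j in seq_len(dims)) {
    i <- which.max(abs(y[, j]))
    if (length(i) && y[i, j] < 0) y[, j] <- -y[, j]
  }
  if (scale) {
    s <- sd(y[, 1L])
    if (s > 0) y <- y * (1e-4 / s)
  }
  rownames(y) <- rownames(d)
  y
}

#' Embed a distance matrix into low-dimensional map coordinates
#'
#' Projects a precomputed dissimilarity matrix (a computational-similarity
#' distance across neurons, or a single-neuron SSIM matrix across windows)
#' into 2-D or 3-D coordinates with exact t-SNE initialized from classical
#' MDS ([mds_initialize()]). The non-random initialization and the exact
#' (theta = 0) gradient make the result fully deterministic for fixed input
#' and parameters. `method = "mds"` returns the classical MDS configuration
#' itself, which reproduces Euclidean configurations exactly up to rigid
#' motion.
#'
#' @param d square symmetric dissimilarity matrix with zero diagonal.
#' @param dims 2 or 3.
#' @param perplexity t-SNE perplexity; default `min(30, floor((P - 1) / 3))`
#'   where `P` is the number of points. Values too large for `P` are clamped
#'   with a warning.
#' @param seed integer RNG seed (defensive; the run is deterministic anyway).
#' @param method `"tsne"` (default) or `"mds"`.
#' @param max_iter t-SNE iteration count.
#' @return `P x dims` numeric coordinate matrix with the input's row names;
#'   attribute `"params"` records the effective parameters.
#' @export
embed_map <- function(d, dims = 2, perplexity = NULL, seed = 1,
                      method = c("tsne", "mds"), max_iter = 1000) {
  method <- match.arg(method)
  d <- check_dist_matrix(d)
  p <- nrow(d)
  if (!dims %in% c(2, 3)) stop("'dims' must be 2 or 3")
  if (method == "mds") {
    y <- mds_initialize(d, dims, scale = FALSE)
    attr(y, "params") <- list(method = "mds", dims = dims)
    return(y)
  }
  pmax_allowed <- floor((p - 1) / 3)
  if (pmax_allowed < 1) stop("too few points (", p, ") for a t-SNE embedding")
  if (is.null(perplexity)) perplexity <- min(30, pmax_allowed)
  if (perplexity > pmax_allowed) {
    warning("perplexity ", perplexity, " too large for ", p,
            " points; clamped to ", pmax_allowed)
    perplexity <- pmax_allowed
  }
  init <- mds_initialize(d, dims, scale = TRUE)
  set.seed(seed)
  fit <- Rtsne::Rtsne(d, dims = dims, perplexity = perplexity, theta = 0,
                      is_distance = TRUE, Y_init = init, max_iter = max_iter,
                      pca = FALSE, check_duplicates = FALSE, verbose = FALSE)
  y <- fit$Y
  rownames(y) <- rownames(d)
  attr(y, "params") <- list(method = "tsne", dims = dims,
                            perplexity = perplexity, seed = seed,
                            max_iter = max_iter)
  y
}

check_dist_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (!all(is.finite(d))) stop("distance matrix must be finite")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  d
}
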