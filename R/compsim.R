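#' Computational similarity between two neuron fingerprints
#'
#' The second-order comparison at the heart of the framework: the Pearson
#' correlation between two neurons' SSIM matrices, computed over the
#' vectorized strict upper triangle (the structurally-zero diagonal is
#' excluded so it cannot inflate the correlation). Because Pearson
#' correlation is invariant to positive affine transforms, two neurons whose
#' output-space geometries are proportional — even at very different absolute
#' firing scales — score 1: the comparison is about the *relations* among a
#' neuron's responses, not their magnitudes.
#'
#' @param a,b `S x S` SSIM matrices over the same windows in the same order.
#' @return Pearson r in `[-1, 1]`, or `NA` if either off-diagonal is
#'   constant (degenerate fingerprint, e.g. a silent neuron).
#' @export
cs_score <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("SSIM matrices must have equal dimensions")
  ut <- upper.tri(a)
  x <- a[ut]; y <- b[ut]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' N x N computational similarity (CS) matrix
#'
#' Correlates every pair of single-neuron SSIM matrices ([cs_score()]) and
#' assembles the symmetric `N x N` CS matrix with unit diagonal. Neurons
#' with degenerate (constant off-diagonal) fingerprints carry no relational
#' information; under the default policy they are excluded from the matrix
#' (with their ids and reasons recorded), under `"zero"` they are retained
#' with similarity 0 to every other neuron.
#'
#' @param ssims an `ssim_set` from [compute_ssims()], or a named list of
#'   SSIM matrices.
#' @param degenerate policy for degenerate neurons: `"exclude"` (default)
#'   or `"zero"`.
#' @return Object of class `cs_matrix`: list with `values` (`N x N`
#'   correlation matrix), `neuron_ids`, `excluded` (data frame of excluded
#'   neuron ids and reasons), `q`.
#' @export
cs_matrix <- function(ssims, degenerate = c("exclude", "zero")) {
  degenerate <- match.arg(degenerate)
  q <- if (inherits(ssims, "ssim_set")) ssims$q else NA_real_
  mats <- if (inherits(ssims, "ssim_set")) ssims$matrices else ssims
  if (is.null(names(mats))) names(mats) <- paste0("n", seq_along(mats))
  ut <- upper.tri(mats[[1L]])
  tri <- vapply(mats, function(m) m[ut], numeric(sum(ut)))
  degen <- colnames(tri)[apply(tri, 2L, sd) == 0]
  excluded <- data.frame(neuron_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (length(degen) && degenerate == "exclude") {
    excluded <- data.frame(neuron_id = degen,
                           reason = "constant SSIM off-diagonal",
                           stringsAsFactors = FALSE)
    tri <- tri[, setdiff(colnames(tri), degen), drop = FALSE]
  }
  if (ncol(tri) < 2L)
    stop("fewer than 2 usable (non-degenerate) neurons")
  keep_degen <- intersect(colnames(tri), degen)  # non-empty under "zero"
  r <- suppressWarnings(cor(tri))
  if (length(keep_degen)) {
    r[keep_degen, ] <- 0
    r[, keep_degen] <- 0
  }
  diag(r) <- 1
  structure(list(values = r, neuron_ids = colnames(tri), excluded = excluded,
                 q = q),
            class = "cs_matrix")
}

#' @export
print.cs_matrix <- function(x, ...) {
  cat(sprintf("<cs_matrix> %d x %d Pearson correlations of SSIM matrices\n",
              nrow(x$values), ncol(x$values)))
  if (nrow(x$excluded))
    cat("  excluded:", paste(x$excluded$neuron_id, collapse = ", "), "\n")
  invisible(x)
}

#' Computational dissimilarity matrix
#'
#' Converts the CS correlation matrix to the dissimilarity `d = 1 - r` used
#' for embedding and clustering (zero diagonal, range `[0, 2]`).
#' Anticorrelated fingerprints are treated as maximally computationally
#' dissimilar.
#'
#' @param cs a `cs_matrix` (or a plain correlation matrix).
#' @return `N x N` symmetric dissimilarity matrix with zero diagonal.
#' @export
cs_to_distance <- function(cs) {
  r <- if (inherits(cs, "cs_matrix")) cs$values else as.matrix(cs)
  d <- 1 - r
  diag(d) <- 0
  d
}
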