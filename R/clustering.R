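#' Silhouette curve over a range of cluster numbers
#'
#' Runs k-means (best of `restarts` random starts by within-cluster sum of
#' squares) for each `k` in `k_range` on the map coordinates and records the
#' mean silhouette width — the Silhouette Coefficient (SC) — at each `k`.
#' Silhouettes are computed with Euclidean distance in map space unless a
#' precomputed dissimilarity matrix is supplied via `dist` (used by the
#' permutation test's fast path, where cluster labels come from a classical
#' MDS projection but silhouettes are evaluated on the computational
#' similarity distance itself).
#'
#' @param coords `P x d` coordinate matrix (e.g. from [embed_map()]).
#' @param k_range integer vector of candidate cluster counts, all `>= 2`.
#' @param restarts number of k-means restarts per `k`.
#' @param seed integer seed fixing the k-means RNG stream.
#' @param dist optional `P x P` dissimilarity matrix for the silhouette
#'   computation (default: Euclidean distance between `coords` rows).
#' @return Object of class `silhouette_curve`: list with `k` (vector),
#'   `sc` (mean silhouette per k), `labels` (`P x length(k)` matrix of
#'   cluster labels per k), and `sil` (list of per-point silhouette widths
#'   per k).
#' @export
silhouette_curve <- function(coords, k_range = 2:10, restarts = 20,
                             seed = 1, dist = NULL) {
  coords <- as.matrix(coords)
  p <- nrow(coords)
  if (any(k_range < 2)) stop("cluster counts below 2 are not meaningful")
  if (max(k_range) >= p) {
    warning("k_max >= number of points; clamping to ", p - 1)
    k_range <- k_range[k_range < p]
  }
  if (!length(k_range)) stop("empty k_range after clamping")
  if (all(apply(coords, 2L, sd) == 0))
    stop("all points identical: no cluster structure to assess")
  dmat <- if (is.null(dist)) as.matrix(stats::dist(coords))
          else check_dist_matrix(dist)
  set.seed(seed)
  labels <- matrix(NA_integer_, p, length(k_range),
                   dimnames = list(rownames(coords), paste0("k", k_range)))
  sc <- rep(NA_real_, length(k_range))
  sil <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    km <- tryCatch(
      kmeans(coords, centers = k, nstart = restarts, iter.max = 50),
      error = function(e) NULL)
    if (is.null(km)) next  # fewer distinct points than centers
    s <- cluster::silhouette(km$cluster, dmatrix = dmat)
    labels[, i] <- km$cluster
    sil[[i]] <- s[, "sil_width"]
    sc[i] <- mean(s[, "sil_width"])
  }
  structure(list(k = k_range, sc = sc, labels = labels, sil = sil),
            class = "silhouette_curve")
}

#' @export
print.silhouette_curve <- function(x, ...) {
  cat("<silhouette_curve>\n")
  print(data.frame(k = x$k, SC = round(x$sc, 4)), row.names = FALSE)
  invisible(x)
}

#' Select the cluster number maximizing the mean silhouette
#'
#' Returns the `k` with the highest Silhouette Coefficient; ties are broken
#' toward the smallest `k` (parsimony).
#'
#' @param curve a [silhouette_curve()].
#' @return integer `Ksc`.
#' @export
select_k <- function(curve) {
  stopifnot(inherits(curve, "silhouette_curve"))
  ok <- which(!is.na(curve$sc))
  if (!length(ok)) stop("silhouette curve is empty")
  best <- ok[which.max(curve$sc[ok])]  # which.max takes the first maximum
  curve$k[best]
}

#' K-means clustering of map coordinates
#'
#' Partitions the map into `k` clusters with the best of `restarts` k-means
#' runs and reports per-point silhouette widths. Deterministic for a fixed
#' seed. Cluster labels are arbitrary up to permutation; compare partitions
#' with a label-invariant index (e.g. the adjusted Rand index), never by
#' raw equality.
#'
#' @param coords `P x d` coordinate matrix.
#' @param k number of clusters, `>= 2` (silhouettes are undefined at k = 1).
#' @param restarts,seed,dist as in [silhouette_curve()].
#' @return Object of class `cluster_result`: list with `k`, `labels`
#'   (integer vector in `1..k`, named by point), `sc` (mean silhouette),
#'   `silhouettes` (per point).
#' @export
cluster_map <- function(coords, k, restarts = 20, seed = 1, dist = NULL) {
  coords <- as.matrix(coords)
  if (k < 2) stop("'k' must be at least 2 (silhouette undefined at k = 1)")
  if (k >= nrow(coords)) stop("'k' must be below the number of points")
  dmat <- if (is.null(dist)) as.matrix(stats::dist(coords))
          else check_dist_matrix(dist)
  set.seed(seed)
  km <- kmeans(coords, centers = k, nstart = restarts, iter.max = 50)
  s <- cluster::silhouette(km$cluster, dmatrix = dmat)
  labels <- km$cluster
  names(labels) <- rownames(coords)
  structure(list(k = k, labels = labels, sc = mean(s[, "sil_width"]),
                 silhouettes = s[, "sil_width"]),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, SC = %.4f, sizes: %s\n", x$k, x$sc,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}
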