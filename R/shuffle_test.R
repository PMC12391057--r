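#' Mantel-style permutation of an SSIM matrix
#'
#' Applies one random permutation jointly to the rows and columns of a
#' spike-train distance matrix, as in the Mantel test. This randomizes which
#' windows a neuron "considers similar" while exactly preserving the matrix
#' symmetry, the zero diagonal, and the multiset of off-diagonal distances —
#' so each surrogate neuron keeps its own output-space geometry but loses
#' any dependency shared with other neurons.
#'
#' @param m `S x S` symmetric distance matrix.
#' @param perm optional integer permutation of `1:S`; drawn uniformly at
#'   random from the current RNG stream when `NULL`.
#' @return Permuted matrix with the same dimnames as `m`.
#' @export
permute_ssim <- function(m, perm = NULL) {
  m <- as.matrix(m)
  s <- nrow(m)
  if (is.null(perm)) perm <- sample.int(s)
  if (length(perm) != s || !identical(sort(perm), seq_len(s)))
    stop("'perm' must be a permutation of 1:", s)
  out <- m[perm, perm]
  dimnames(out) <- dimnames(m)
  out
}

#' Empirical null distribution of silhouette scores under fingerprint
#' permutation
#'
#' The cluster-validation statistic of the pipeline. Each of `M` surrogate
#' data sets independently permutes every neuron's SSIM matrix (rows and
#' columns jointly, [permute_ssim()]), rebuilds the computational similarity
#' matrix, projects it, and recomputes the silhouette curve. The central
#' `confidence` interval of surrogate SC values per `k` forms the acceptance
#' band; the headline p-value compares the observed SC at its selected
#' `Ksc` against the conservative max-over-k surrogate statistic, with the
#' add-one estimator `p = (1 + #{max SC_surr >= SC_obs}) / (1 + M)` (so
#' `p >= 1/(M+1)`, never zero).
#'
#' Two projection modes are available. `"fast"` (default) assigns k-means
#' labels in a 3-D classical-MDS projection of each CS distance matrix and
#' evaluates silhouettes on the CS distance itself, avoiding a t-SNE run per
#' surrogate; `"embed"` re-runs the full t-SNE embedding for every surrogate
#' and evaluates silhouettes in map space. The *observed* curve used for the
#' comparison is always computed through the same route as the surrogates,
#' so observed and surrogate statistics are exchangeable under the null.
#'
#' @param ssims an `ssim_set` from [compute_ssims()].
#' @param M number of surrogates (`>= 1`; 1000 recommended).
#' @param confidence acceptance-band coverage (default 0.99).
#' @param k_range,restarts candidate cluster counts and k-means restarts.
#' @param mode `"fast"` or `"embed"` (see Details).
#' @param dims,perplexity,max_iter embedding parameters (mode `"embed"`;
#'   `dims` also sets the MDS projection dimension in fast mode).
#' @param degenerate degenerate-neuron policy, as in [cs_matrix()].
#' @param seed master seed; one independent sub-stream is derived per
#'   surrogate index, so results do not depend on evaluation order.
#' @param check_invariants assert symmetry/diagonal/multiset preservation on
#'   every surrogate matrix (debug aid; default `FALSE`).
#' @return Object of class `simnets_null`: list with `M`, `k`,
#'   `surrogate_sc` (`M x length(k)` matrix), `band` (data frame `k`,
#'   `lower`, `upper`), `observed` (the observed [silhouette_curve()] on the
#'   null route), `ksc`, `sc_obs`, `p_value`, `mode`, `confidence`.
#' @export
shuffle_test <- function(ssims, M = 1000, confidence = 0.99,
                         k_range = 2:10, restarts = 10,
                         mode = c("fast", "embed"), dims = 3,
                         perplexity = NULL, max_iter = 1000,
                         degenerate = c("exclude", "zero"), seed = 1,
                         check_invariants = FALSE) {
  stopifnot(inherits(ssims, "ssim_set"))
  mode <- match.arg(mode)
  degenerate <- match.arg(degenerate)
  if (!is.numeric(M) || M < 1) stop("'M' must be at least 1")
  M <- as.integer(M)

  null_curve <- function(mats) {
    cs <- cs_matrix(mats, degenerate = degenerate)
    d <- cs_to_distance(cs)
    if (mode == "fast") {
      coords <- mds_initialize(d, dims, scale = FALSE)
      silhouette_curve(coords, k_range, restarts, seed = seed, dist = d)
    } else {
      coords <- embed_map(d, dims = dims, perplexity = perplexity,
                          seed = seed, max_iter = max_iter)
      silhouette_curve(coords, k_range, restarts, seed = seed)
    }
  }

  observed <- suppressWarnings(null_curve(ssims$matrices))
  ksc <- select_k(observed)
  sc_obs <- observed$sc[observed$k == ksc]

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, M)
  surrogate_sc <- matrix(NA_real_, M, length(observed$k),
                         dimnames = list(NULL, paste0("k", observed$k)))
  for (m in seq_len(M)) {
    set.seed(sub_seeds[m])
    perm_mats <- lapply(ssims$matrices, function(x)
      permute_ssim(x, sample.int(nrow(x))))
    if (check_invariants) {
      ok <- vapply(seq_along(perm_mats), function(i) {
        a <- ssims$matrices[[i]]; b <- perm_mats[[i]]
        isTRUE(all.equal(b, t(b))) && all(diag(b) == 0) &&
          identical(sort(a[upper.tri(a)]), sort(b[upper.tri(b)]))
      }, TRUE)
      if (!all(ok)) stop("surrogate invariant violated")
    }
    cur <- suppressWarnings(null_curve(perm_mats))
    surrogate_sc[m, ] <- cur$sc
  }
  alpha2 <- (1 - confidence) / 2
  band <- data.frame(
    k = observed$k,
    lower = apply(surrogate_sc, 2L, quantile, probs = alpha2, na.rm = TRUE),
    upper = apply(surrogate_sc, 2L, quantile, probs = 1 - alpha2,
                  na.rm = TRUE))
  max_stat <- apply(surrogate_sc, 1L, max, na.rm = TRUE)
  p_value <- (1 + sum(max_stat >= sc_obs)) / (1 + M)
  structure(list(M = M, k = observed$k, surrogate_sc = surrogate_sc,
                 band = band, observed = observed, ksc = ksc,
                 sc_obs = sc_obs, p_value = p_value, mode = mode,
                 confidence = confidence),
            class = "simnets_null")
}

#' @export
print.simnets_null <- function(x, ...) {
  cat(sprintf(
    "<simnets_null> M = %d surrogates (%s mode): observed SC = %.3f at k = %d, p = %.4g\n",
    x$M, x$mode, x$sc_obs, x$ksc, x$p_value))
  invisible(x)
}

#' Significance verdict for an observed silhouette curve
#'
#' Compares an observed silhouette curve against the permutation null: per
#' `k`, the observed SC is flagged significant when it exceeds the upper
#' acceptance-band bound; the overall verdict at the selected `Ksc` uses the
#' conservative max-statistic p-value from [shuffle_test()].
#'
#' @param observed a [silhouette_curve()] over the same `k` range as the
#'   null (defaults to the null's own observed curve).
#' @param null a `simnets_null` from [shuffle_test()].
#' @param alpha significance level (default 0.01, matching a 99% band).
#' @return list with `per_k` (data frame `k`, `sc`, `upper`, `significant`),
#'   `ksc`, `p_value`, and `significant` (overall verdict).
#' @export
decide_significance <- function(null, observed = NULL, alpha = 0.01) {
  stopifnot(inherits(null, "simnets_null"))
  if (is.null(observed)) observed <- null$observed
  if (!identical(as.integer(observed$k), as.integer(null$k)))
    stop("observed curve and null have mismatched k ranges")
  per_k <- data.frame(k = null$k, sc = observed$sc, upper = null$band$upper,
                      significant = observed$sc > null$band$upper)
  list(per_k = per_k, ksc = null$ksc, p_value = null$p_value,
       significant = null$p_value < alpha)
}
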