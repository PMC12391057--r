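#' Run the full similarity-network analysis pipeline
#'
#' Executes the complete analysis on an [ensemble_recording]:
#' per-neuron SSIM matrices ([compute_ssims()]) -> computational similarity
#' matrix ([cs_matrix()]) -> dissimilarity ([cs_to_distance()]) -> map
#' embedding ([embed_map()]) -> silhouette curve, `Ksc` selection and
#' k-means clustering ([silhouette_curve()], [select_k()], [cluster_map()])
#' -> permutation significance test ([shuffle_test()],
#' [decide_significance()]). Fully deterministic for a fixed `seed`.
#'
#' @param rec an [ensemble_recording].
#' @param q Victor-Purpura shift cost rate (1/seconds); temporal accuracy
#'   `1/q`.
#' @param dims embedding dimension for the population map (default 3).
#' @param perplexity t-SNE perplexity (default `min(30, floor((N-1)/3))`).
#' @param max_iter t-SNE iterations.
#' @param k_range candidate cluster numbers (default `2:min(20, N - 1)`).
#' @param restarts k-means restarts per `k`.
#' @param shuffles number of permutation surrogates `M` (0 skips the test).
#' @param confidence acceptance-band coverage for the permutation test.
#' @param shuffle_mode `"fast"` or `"embed"`, see [shuffle_test()].
#' @param degenerate degenerate-neuron policy, see [cs_matrix()].
#' @param embed_method `"tsne"` (default) or `"mds"`.
#' @param alpha significance level for the verdict.
#' @param seed master seed for embedding, clustering and surrogates.
#' @return Object of class `simnets_result`: list with `ssims`, `cs`,
#'   `cs_dist`, `coords`, `curve`, `ksc`, `clusters`, `null` (or `NULL`),
#'   `verdict` (or `NULL`), and `manifest` (parameters, versions, seed,
#'   comparison counts, exclusions).
#' @examples
#' sim <- simulate_population(sim_config(neurons_per_scheme = 2,
#'                                       trials_per_condition = 4, seed = 7))
#' res <- run_simnets(sim$recording, q = 10, shuffles = 20, seed = 7)
#' res$ksc
#' @export
run_simnets <- function(rec, q = 10, dims = 3, perplexity = NULL,
                        max_iter = 1000, k_range = NULL, restarts = 20,
                        shuffles = 1000, confidence = 0.99,
                        shuffle_mode = c("fast", "embed"),
                        degenerate = c("exclude", "zero"),
                        embed_method = c("tsne", "mds"), alpha = 0.01,
                        seed = 42) {
  stopifnot(inherits(rec, "ensemble_recording"))
  shuffle_mode <- match.arg(shuffle_mode)
  degenerate <- match.arg(degenerate)
  embed_method <- match.arg(embed_method)
  t0 <- proc.time()[["elapsed"]]

  ssims <- compute_ssims(rec, q)
  cs <- cs_matrix(ssims, degenerate = degenerate)
  d <- cs_to_distance(cs)
  n_used <- nrow(d)
  if (is.null(k_range)) k_range <- 2:min(20, n_used - 1)
  coords <- embed_map(d, dims = dims, perplexity = perplexity, seed = seed,
                      method = embed_method, max_iter = max_iter)
  curve <- silhouette_curve(coords, k_range = k_range, restarts = restarts,
                            seed = seed)
  ksc <- select_k(curve)
  clusters <- cluster_map(coords, k = ksc, restarts = restarts, seed = seed)

  null <- verdict <- NULL
  if (shuffles > 0) {
    null <- shuffle_test(ssims, M = shuffles, confidence = confidence,
                         k_range = k_range, restarts = max(5, restarts %/% 2),
                         mode = shuffle_mode, dims = dims,
                         perplexity = perplexity, max_iter = max_iter,
                         degenerate = degenerate, seed = seed)
    verdict <- decide_significance(null, alpha = alpha)
  }

  manifest <- list(
    package = "simnets",
    version = as.character(packageVersion("simnets")),
    r_version = as.character(getRversion()),
    q = q, dims = dims,
    perplexity = attr(coords, "params")$perplexity,
    max_iter = max_iter, embed_method = embed_method,
    k_range = as.integer(range(k_range)), restarts = restarts,
    shuffles = shuffles, confidence = confidence,
    shuffle_mode = shuffle_mode, degenerate_policy = degenerate,
    alpha = alpha, seed = seed,
    n_neurons = rec$n_neurons, n_windows = rec$n_windows,
    window_duration_s = rec$duration,
    vp_comparisons = ssims$n_comparisons,
    excluded_neurons = cs$excluded$neuron_id,
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))

  structure(list(ssims = ssims, cs = cs, cs_dist = d, coords = coords,
                 curve = curve, ksc = ksc, clusters = clusters, null = null,
                 verdict = verdict, manifest = manifest),
            class = "simnets_result")
}

#' @export
print.simnets_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<simnets_result> N = %d neurons, S = %d windows, q = %g (1/q = %s)\n",
              m$n_neurons, m$n_windows, m$q,
              if (m$q > 0) sprintf("%g ms", 1000 / m$q) else "Inf"))
  if (length(m$excluded_neurons))
    cat("  excluded degenerate neurons:",
        paste(m$excluded_neurons, collapse = ", "), "\n")
  cat(sprintf("  Ksc = %d clusters (SC = %.3f), sizes: %s\n", x$ksc,
              x$clusters$sc, paste(table(x$clusters$labels), collapse = "/")))
  if (!is.null(x$verdict))
    cat(sprintf("  permutation test: p = %.4g (%s at alpha = %g, M = %d)\n",
                x$verdict$p_value,
                if (x$verdict$significant) "significant" else "not significant",
                m$alpha, x$null$M))
  invisible(x)
}

#' Write a pipeline result to a directory
#'
#' Persists every component of a [run_simnets()] result as plain-text
#' artifacts: the CS and CS-distance matrices, map coordinates, cluster
#' labels, the silhouette curve, the permutation acceptance band (when the
#' test was run), and a JSON manifest recording parameters, versions, seed
#' and exclusions.
#'
#' @param res a `simnets_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simnets_result <- function(res, dir) {
  stopifnot(inherits(res, "simnets_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_matrix(res$cs$values, fp("cs_matrix.csv"))
  write_matrix(res$cs_dist, fp("cs_distance.csv"))
  co <- data.frame(point_id = rownames(res$coords), res$coords)
  names(co)[-1L] <- c("x", "y", "z")[seq_len(ncol(res$coords))]
  write.table(co, fp("coordinates.csv"), sep = ",", row.names = FALSE,
              quote = FALSE)
  write.table(data.frame(neuron_id = names(res$clusters$labels),
                         cluster = unname(res$clusters$labels),
                         silhouette = unname(res$clusters$silhouettes)),
              fp("labels.csv"), sep = ",", row.names = FALSE, quote = FALSE)
  write.table(data.frame(k = res$curve$k, sc = res$curve$sc),
              fp("silhouette_curve.csv"), sep = ",", row.names = FALSE,
              quote = FALSE)
  manifest <- res$manifest
  if (!is.null(res$null)) {
    write.table(res$null$band, fp("null_band.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
    manifest$p_value <- res$null$p_value
    manifest$significant <- res$verdict$significant
  }
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Plot a population map with cluster labels
#'
#' Scatter of the first two map dimensions, colored by cluster assignment.
#'
#' @param x a `simnets_result`.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.simnets_result <- function(x, ...) {
  graphics::plot(x$coords[, 1L], x$coords[, 2L],
                 col = x$clusters$labels, pch = 19,
                 xlab = "map dim 1", ylab = "map dim 2", ...)
  invisible(x)
}
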