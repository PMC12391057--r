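#' Configuration for the ground-truth population simulator
#'
#' Describes a simulated population organized into computationally distinct
#' subnetworks. Each subnetwork has one "preferred" experimental condition
#' (subnetwork i prefers condition i) and contains equal numbers of neurons
#' using three encoding schemes:
#'
#' * **rate** coders: homogeneous Poisson, `baseline_rate_hz` on
#'   non-preferred trials and `preferred_rate_hz` on preferred trials;
#' * **temporal** coders: a frozen *baseline* spike-time template realized
#'   (with per-spike Gaussian jitter) on both non-preferred conditions and a
#'   distinct *preferred* template on preferred trials, with equal template
#'   spike counts — so condition information lives purely in spike timing;
#' * **mixed** coders: templates as for temporal coders, but the preferred
#'   template carries the elevated `preferred_rate_hz` spike count — both
#'   rate and timing are informative.
#'
#' Template-based trains additionally receive condition-independent spike
#' deletion/insertion noise (`noise_prob`), so spike counts fluctuate
#' trial-to-trial without carrying condition information; this keeps
#' temporal coders' fingerprints non-degenerate yet uninformative in the
#' pure-rate (`q = 0`) regime.
#'
#' The default configuration is the validation population used throughout:
#' 3 subnetworks x 3 schemes x 20 neurons = 180 neurons, 3 conditions x 10
#' trials of 1-s windows (S = 30).
#'
#' @param n_subnetworks number of subnetworks (= number of conditions).
#' @param neurons_per_scheme neurons per (subnetwork, scheme) cell.
#' @param schemes encoding schemes to include.
#' @param trials_per_condition trials (windows) per condition.
#' @param duration_s window duration in seconds.
#' @param baseline_rate_hz expected rate on non-preferred trials (all
#'   schemes) and on preferred trials of temporal coders.
#' @param preferred_rate_hz expected rate on preferred trials of rate and
#'   mixed coders.
#' @param template_jitter_ms per-trial Gaussian jitter sd applied to
#'   template spike times (milliseconds), truncated to the window.
#' @param noise_prob per-spike deletion probability for template trains;
#'   matched in expectation by uniformly-timed insertions.
#' @param shuffle_windows randomize window order (results must not depend
#'   on it); default keeps windows blocked by condition.
#' @param seed integer seed for [simulate_population()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subnetworks = 3, neurons_per_scheme = 20,
                       schemes = c("rate", "temporal", "mixed"),
                       trials_per_condition = 10, duration_s = 1,
                       baseline_rate_hz = 10, preferred_rate_hz = 20,
                       template_jitter_ms = 3, noise_prob = 0.1,
                       shuffle_windows = FALSE, seed = 1) {
  cfg <- list(n_subnetworks = n_subnetworks,
              neurons_per_scheme = neurons_per_scheme,
              schemes = match.arg(schemes, c("rate", "temporal", "mixed"),
                                  several.ok = TRUE),
              trials_per_condition = trials_per_condition,
              duration_s = duration_s,
              baseline_rate_hz = baseline_rate_hz,
              preferred_rate_hz = preferred_rate_hz,
              template_jitter_ms = template_jitter_ms,
              noise_prob = noise_prob,
              shuffle_windows = isTRUE(shuffle_windows),
              seed = seed)
  counts <- c("n_subnetworks", "neurons_per_scheme", "trials_per_condition")
  bad <- counts[vapply(cfg[counts], function(v) v < 1, TRUE)]
  rates <- c("baseline_rate_hz", "preferred_rate_hz")
  bad <- c(bad, rates[vapply(cfg[rates], function(v) v <= 0, TRUE)])
  if (cfg$duration_s <= 0) bad <- c(bad, "duration_s")
  if (cfg$template_jitter_ms < 0) bad <- c(bad, "template_jitter_ms")
  if (cfg$noise_prob < 0 || cfg$noise_prob >= 1) bad <- c(bad, "noise_prob")
  if (length(bad))
    stop("invalid sim_config field(s): ", paste(unique(bad), collapse = ", "))
  structure(cfg, class = "sim_config")
}

#' Simulate a ground-truth population of coding subnetworks
#'
#' Generates an [ensemble_recording] following a [sim_config()], together
#' with the ground truth needed to score recovery: each neuron's subnetwork
#' and encoding scheme, and each window's condition. Deterministic for a
#' fixed `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `recording` (an [ensemble_recording]; windows carry
#'   condition labels) and `truth` (data frame `neuron_id`, `subnetwork`,
#'   `scheme`).
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  dur <- cfg$duration_s
  jit <- cfg$template_jitter_ms / 1000
  conds <- seq_len(cfg$n_subnetworks)
  wcond <- rep(conds, each = cfg$trials_per_condition)
  if (cfg$shuffle_windows) wcond <- sample(wcond)
  s <- length(wcond)

  poisson_train <- function(rate) sort(runif(rpois(1L, rate * dur), 0, dur))
  draw_template <- function(rate)
    sort(runif(max(1L, rpois(1L, rate * dur)), 0, dur))
  realize <- function(tmpl) {
    t <- tmpl + rnorm(length(tmpl), 0, jit)
    t <- pmin(pmax(t, 0), dur)
    if (cfg$noise_prob > 0) {
      t <- t[runif(length(t)) >= cfg$noise_prob]
      t <- c(t, runif(rpois(1L, cfg$noise_prob * length(tmpl)), 0, dur))
    }
    sort(t)
  }

  trains <- list(); truth <- list()
  for (sn in conds) {
    for (scheme in cfg$schemes) {
      for (j in seq_len(cfg$neurons_per_scheme)) {
        nid <- sprintf("sn%d_%s_%02d", sn, scheme, j)
        tr <- switch(scheme,
          rate = lapply(wcond, function(cnd)
            poisson_train(if (cnd == sn) cfg$preferred_rate_hz
                          else cfg$baseline_rate_hz)),
          temporal = {
            # equal counts on both templates: timing is the only signal
            base <- draw_template(cfg$baseline_rate_hz)
            pref <- sort(runif(length(base), 0, dur))
            lapply(wcond, function(cnd)
              realize(if (cnd == sn) pref else base))
          },
          mixed = {
            base <- draw_template(cfg$baseline_rate_hz)
            pref <- draw_template(cfg$preferred_rate_hz)
            lapply(wcond, function(cnd)
              realize(if (cnd == sn) pref else base))
          })
        trains[[nid]] <- tr
        truth[[nid]] <- data.frame(neuron_id = nid, subnetwork = sn,
                                   scheme = scheme, stringsAsFactors = FALSE)
      }
    }
  }
  windows <- data.frame(window_id = sprintf("w%02d", seq_len(s)),
                        label = paste0("C", wcond), stringsAsFactors = FALSE)
  rec <- ensemble_recording(trains, duration = dur, windows = windows)
  list(recording = rec,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Simulate orientation-tuned Poisson neurons
#'
#' A small demonstration generator: neurons fire as condition-dependent
#' Poisson processes whose rate follows a Gaussian tuning curve over a
#' circular stimulus variable (e.g. grating orientation, period 180
#' degrees). Used for single-neuron SSIM map examples; an untuned neuron
#' (`tuning_depth = 0`) provides the matching null case.
#'
#' @param n_neurons number of neurons; preferred orientations are spread
#'   evenly over the circle.
#' @param orientations stimulus orientations (degrees), one condition each.
#' @param trials trials per orientation.
#' @param duration window duration (seconds).
#' @param baseline_rate_hz,max_rate_hz rate at the tuning floor and peak.
#' @param tuning_width_deg Gaussian tuning sd (degrees).
#' @param tuning_depth 0..1 scaling of the tuned component (0 = untuned).
#' @param seed integer seed.
#' @return list with `recording` (windows labelled by orientation) and
#'   `truth` (data frame `neuron_id`, `preferred_deg`).
#' @export
simulate_tuned_poisson <- function(n_neurons = 6,
                                   orientations = seq(0, 150, by = 30),
                                   trials = 10, duration = 1,
                                   baseline_rate_hz = 5, max_rate_hz = 30,
                                   tuning_width_deg = 30, tuning_depth = 1,
                                   seed = 1) {
  set.seed(seed)
  period <- 180
  prefs <- seq(0, period, length.out = n_neurons + 1L)[seq_len(n_neurons)]
  wori <- rep(orientations, each = trials)
  circ <- function(a, b) {
    d <- abs(a - b) %% period
    pmin(d, period - d)
  }
  trains <- lapply(seq_len(n_neurons), function(i) {
    rate <- baseline_rate_hz + tuning_depth * (max_rate_hz - baseline_rate_hz) *
      exp(-0.5 * (circ(wori, prefs[i]) / tuning_width_deg)^2)
    lapply(rate, function(r) sort(runif(rpois(1L, r * duration), 0, duration)))
  })
  names(trains) <- sprintf("n%02d", seq_len(n_neurons))
  windows <- data.frame(window_id = sprintf("w%03d", seq_along(wori)),
                        label = paste0("ori", wori), stringsAsFactors = FALSE)
  rec <- ensemble_recording(trains, duration = duration, windows = windows)
  list(recording = rec,
       truth = data.frame(neuron_id = names(trains), preferred_deg = prefs,
                          stringsAsFactors = FALSE))
}
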