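test_that("spike_train validates its invariants", {
  st <- spike_train(c(0.1, 0.5), duration = 1)
  expect_s3_class(st, "spike_train")
  expect_length(st, 2L)
  expect_error(spike_train(c(0.5, 1.2), duration = 1), "within")
  expect_error(spike_train(c(0.5, 0.1), duration = 1), "sorted")
  expect_error(spike_train(0.1, duration = 0), "positive")
  expect_warning(spike_train(c(0.2, 0.2), duration = 1), "duplicate")
})

test_that("ensemble_recording enforces a complete equal-duration grid", {
  tr <- list(n1 = list(0.1, c(0.2, 0.4), numeric(0)),
             n2 = list(0.9, 0.5, 0.7))
  rec <- ensemble_recording(tr, duration = 1)
  expect_identical(rec$n_neurons, 2L)
  expect_identical(rec$n_windows, 3L)
  expect_error(ensemble_recording(tr[1], duration = 1), "N = 2")
  expect_error(
    ensemble_recording(list(n1 = list(0.1, 0.2), n2 = list(0.1, 0.2)),
                       duration = 1), "S = 3")
  tr$n2 <- tr$n2[1:2]
  expect_error(ensemble_recording(tr, duration = 1), "incomplete grid")
})

test_that("long-table reader builds the grid and applies the completeness rule", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("neuron_id,window_id,spike_time_s",
               "n1,w1,0.10", "n1,w1,0.50", "n1,w2,0.30", "n1,w3,0.90",
               "n2,w1,0.20", "n2,w1,0.70", "n2,w2,0.40"), f)
  rec <- read_spike_table(f, duration = 1)
  expect_identical(rec$n_neurons, 2L)
  expect_identical(rec$n_windows, 3L)
  # n2 absent from w3 but w3 appears for n1 -> empty train
  expect_identical(rec$trains$n2[[3]], numeric(0))
  expect_identical(rec$trains$n1[[1]], c(0.1, 0.5))
})

test_that("long-table reader errors name the offending rows and windows", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("neuron_id,window_id,spike_time_s",
               "n1,w1,0.1", "n1,w2,1.2", "n2,w1,0.2", "n2,w2,0.3",
               "n1,w3,0.4", "n2,w3,0.5"), f)
  expect_error(read_spike_table(f, duration = 1), "row\\(s\\): 2")
  w <- tempfile(fileext = ".csv")
  writeLines(c("window_id,duration_s", "w1,1", "w2,1", "w3,2"), w)
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("neuron_id,window_id,spike_time_s",
               "n1,w1,0.1", "n2,w2,0.3", "n1,w3,0.4", "n2,w3,0.5"), f2)
  expect_error(read_spike_table(f2, windows = w), "w3")
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("neuron_id,window_id,spike_time_s",
               "n1,w1,0.1", "n1,w1,0.1", "n1,w2,0.3", "n1,w3,0.4",
               "n2,w1,0.2", "n2,w2,0.3", "n2,w3,0.4"), f3)
  expect_warning(read_spike_table(f3, duration = 1), "duplicate")
})

test_that("spike tables and JSON documents round-trip", {
  rec <- poisson_recording(4, 5, rate = 8, seed = 31)
  f <- tempfile(fileext = ".csv")
  write_spike_table(rec, f)
  rec2 <- read_spike_table(f, duration = 1)
  for (i in 1:4) for (j in 1:5)
    expect_equal(rec2$trains[[i]][[j]], rec$trains[[i]][[j]],
                 tolerance = 1e-9)
  # JSON route
  doc <- list(duration_s = rec$duration,
              windows = rec$windows,
              neurons = lapply(rec$trains, function(tr) {
                names(tr) <- rec$windows$window_id
                tr
              }))
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, fj, auto_unbox = TRUE, digits = NA)
  rec3 <- read_spike_json(fj)
  expect_identical(rec3$n_neurons, rec$n_neurons)
  for (i in 1:4) for (j in 1:5)
    expect_equal(rec3$trains[[i]][[j]], rec$trains[[i]][[j]],
                 tolerance = 1e-9)
})

test_that("segment_stream uses half-open windows and conserves spikes", {
  win <- data.frame(window_id = c("w1", "w2", "w3"),
                    start_s = c(0, 1, 2), duration_s = 1)
  recs <- segment_stream(list(a = c(0.5, 1.5, 2.5), b = c(0.2, 1.0, 2.9)),
                         windows = win)
  expect_equal(recs$trains$a, list(0.5, 0.5, 0.5))
  # boundary spike at t = start + duration belongs to the following window
  expect_equal(recs$trains$b, list(0.2, 0, 0.9))
  # window beyond the last spike -> empty train
  win4 <- rbind(win, data.frame(window_id = "w4", start_s = 50,
                                duration_s = 1))
  rec4 <- segment_stream(list(a = c(0.5, 1.5, 2.5), b = 0.1), win4)
  expect_identical(rec4$trains$a[[4]], numeric(0))
  # disjoint covering windows conserve total spike count
  set.seed(9)
  stream <- sort(runif(200, 0, 3))
  rec5 <- segment_stream(list(a = stream, b = stream + 1e-6), win)
  expect_identical(sum(lengths(rec5$trains$a)), 200L)
  # overlap is permitted but reported
  wo <- data.frame(window_id = c("w1", "w2", "w3"),
                   start_s = c(0, 0.5, 1.0), duration_s = 1)
  expect_message(segment_stream(list(a = c(0.6, 1.2), b = 0.1), wo),
                 "overlap")
})

test_that("matrix writer round-trips and rejects non-finite entries", {
  set.seed(4)
  m <- matrix(runif(16), 4)
  m <- m + t(m); diag(m) <- 0
  dimnames(m) <- list(paste0("w", 1:4), paste0("w", 1:4))
  f <- tempfile(fileext = ".csv")
  write_matrix(m, f)
  expect_equal(read_matrix(f), m, tolerance = 1e-12)
  m[2, 3] <- NaN
  expect_error(write_matrix(m, f), "non-finite")
})
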