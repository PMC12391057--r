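test_that("vp_distance handles closed-form cases", {
  # identity
  t1 <- c(0.1, 0.4, 0.9)
  expect_identical(vp_distance(t1, t1, q = 7), 0)
  # q = 0 reduces to the spike-count difference
  expect_identical(vp_distance(sort(runif(5)), sort(runif(2)), q = 0), 3)
  # single-spike pair: min(indel pair = 2, shift = q * dt)
  expect_equal(vp_distance(0.1, 0.3, q = 2), 0.4)
  expect_equal(vp_distance(0.1, 0.3, q = 20), 2.0)
  # empty trains forced by the DP base cases
  expect_identical(vp_distance(numeric(0), numeric(0), q = 5), 0)
  expect_identical(vp_distance(numeric(0), c(0.2, 0.3, 0.4), q = 5), 3)
})

test_that("vp_distance equals the brute-force optimal-matching oracle", {
  set.seed(101)
  for (i in 1:1000) {
    a <- random_train(4)
    b <- random_train(4)
    q <- runif(1, 0, 50)
    expect_equal(vp_distance(a, b, q), vp_brute(a, b, q), tolerance = 1e-9)
  }
})

test_that("vp_distance agrees with an independent reference DP", {
  set.seed(202)
  for (i in 1:1000) {
    a <- sort(runif(rpois(1, 8)))
    b <- sort(runif(rpois(1, 8)))
    q <- runif(1, 0, 300)
    expect_equal(vp_distance(a, b, q), vp_ref(a, b, q), tolerance = 1e-9)
  }
})

test_that("vp_distance satisfies the metric axioms", {
  set.seed(303)
  for (i in 1:200) {
    a <- random_train(6); b <- random_train(6); cc <- random_train(6)
    q <- runif(1, 0, 100)
    dab <- vp_distance(a, b, q)
    expect_gte(dab, 0)
    expect_equal(dab, vp_distance(b, a, q), tolerance = 1e-12)
    expect_lte(dab, vp_distance(a, cc, q) + vp_distance(cc, b, q) + 1e-9)
    expect_identical(vp_distance(a, a, q), 0)
  }
})

test_that("vp_distance is nondecreasing in q with the stated limits", {
  set.seed(404)
  for (i in 1:50) {
    a <- random_train(6); b <- random_train(6)
    qs <- sort(runif(5, 0, 500))
    d <- vapply(qs, function(q) vp_distance(a, b, q), 0)
    expect_true(all(diff(d) >= -1e-12))
    expect_equal(vp_distance(a, b, 0), abs(length(a) - length(b)))
  }
  # q -> Inf limit: |a| + |b| - 2 * (exactly coincident spikes)
  a <- c(0.1, 0.2, 0.5)
  b <- c(0.2, 0.7)
  expect_identical(vp_distance(a, b, q = 1e9), 3 + 2 - 2 * 1)
})

test_that("vp_distance validates its inputs", {
  expect_error(vp_distance(c(0.1, 0.2), c(0.3), q = -1), "non-negative")
  expect_error(vp_distance(c(0.5, 0.1), c(0.3), q = 1), "sorted")
})

test_that("vp_distance_matrix matches elementwise calls and trivial cases", {
  # S identical trains -> all zeros
  tr <- replicate(4, c(0.2, 0.6), simplify = FALSE)
  expect_true(all(vp_distance_matrix(tr, q = 11) == 0))
  # counts (0, 1, 2) at q = 0 -> off-diagonals (1, 2, 1)
  m <- vp_distance_matrix(list(numeric(0), 0.5, c(0.2, 0.8)), q = 0)
  expect_equal(m[upper.tri(m)], c(1, 2, 1))
  # consistency with vp_distance, symmetry, zero diagonal
  set.seed(7)
  tr <- replicate(6, random_train(8), simplify = FALSE)
  m <- vp_distance_matrix(tr, q = 30, ids = paste0("w", 1:6))
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))
  for (i in 1:5) for (j in (i + 1):6)
    expect_identical(m[i, j], vp_distance(tr[[i]], tr[[j]], q = 30))
  expect_identical(rownames(m), paste0("w", 1:6))
  expect_error(vp_distance_matrix(list(0.1, 0.2), q = 1), "at least 3")
})
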