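test_that("euclidean and modified distances match hand-computed values", {
  expect_equal(euclidean_distance(c(1, -1, 1), c(1, -1, 1)), 0)
  expect_equal(euclidean_distance(c(1, 1), c(-1, -1)), 2 * sqrt(2))
  expect_equal(euclidean_distance(c(1, 0), c(0, 1)), sqrt(2))
  expect_error(euclidean_distance(c(1, 2), c(1, 2, 3)), "length")

  ## same-label branch sqrt(1 - e^-d), different-label branch sqrt(e^-d)
  expect_equal(modified_distance(c(1, 1), c(1, 1), same_label = TRUE), 0)
  expect_equal(modified_distance(c(1, 1), c(1, 1), same_label = FALSE), 1)
  a <- c(log(2), 0); b <- c(0, 0)  # d = ln 2
  expect_equal(modified_distance(a, b, same_label = FALSE), sqrt(0.5))
  ## monotonicity: same-label non-decreasing, different-label non-increasing in d
  ds <- seq(0, 5, by = 0.25)
  same <- sapply(ds, function(d) modified_distance(c(d, 0), b, TRUE))
  diff <- sapply(ds, function(d) modified_distance(c(d, 0), b, FALSE))
  expect_true(all(diff(same) >= 0))
  expect_true(all(diff(diff) <= 0))
  ## swap flag exchanges the branches
  expect_equal(modified_distance(a, b, TRUE, swap = TRUE),
               modified_distance(a, b, FALSE))
})

test_that("heat-kernel pair similarity matches closed forms and bounds", {
  expect_equal(heterogeneous_pair_similarity(c(1, 1), c(1, 1), TRUE, tau = 5), 1)
  expect_equal(heterogeneous_pair_similarity(c(1, 1), c(1, 1), FALSE, tau = 1),
               exp(-1))
  ## exp(-(1 - e^(-2 sqrt 2)))
  expect_equal(heterogeneous_pair_similarity(c(1, 1), c(-1, -1), TRUE, tau = 1),
               0.3902786712, tolerance = 1e-9)
  expect_error(heterogeneous_pair_similarity(c(1, 1), c(1, 1), TRUE, tau = 0),
               "tau")
  ## same-label value is non-increasing in d, with max 1 at d = 0;
  ## different-label is non-decreasing with min e^(-1/tau) at d = 0
  for (tau in c(0.5, 1, 2)) {
    v_same <- sapply(seq(0, 6, 0.5), function(d)
      heterogeneous_pair_similarity(c(d, 0), c(0, 0), TRUE, tau))
    v_diff <- sapply(seq(0, 6, 0.5), function(d)
      heterogeneous_pair_similarity(c(d, 0), c(0, 0), FALSE, tau))
    expect_true(all(diff(v_same) <= 0))
    expect_true(all(diff(v_diff) >= 0))
    expect_equal(v_same[1], 1)
    expect_equal(v_diff[1], exp(-1 / tau))
    expect_true(all(c(v_same, v_diff) > 0 & c(v_same, v_diff) <= 1))
  }
})

test_that("heterogeneous similarity matrix handles labels, shape and transpose", {
  expect_equal(heterogeneous_similarity(matrix(c(1, 1), 1), matrix(c(1, 1), 1),
                                        labels = 1L),
               matrix(1), ignore_attr = TRUE)
  ## duplicate codes everywhere, labels (A, B): d = 0 between the
  ## different-label pair, so off-diagonals equal e^(-1/tau)
  cm <- matrix(c(1, 1, 1, 1), 2, byrow = TRUE)
  S <- heterogeneous_similarity(cm, cm, labels = c(1, 2), tau = 2)
  expect_equal(S[1, 2], exp(-1 / 2))
  expect_equal(S[2, 1], exp(-1 / 2))
  ## swapping the matrices transposes the result
  A <- random_pm1(3, 4, seed = 2); B <- random_pm1(3, 4, seed = 3)
  expect_equal(heterogeneous_similarity(A, B, c(1, 1, 2)),
               t(heterogeneous_similarity(B, A, c(1, 1, 2))))
  expect_error(heterogeneous_similarity(A, B, c(1, 2)), "length")
})

test_that("homogeneous similarity is cosine with guarded degenerate input", {
  h <- c(1, 1, -1, -1)
  S <- homogeneous_similarity(rbind(h, -h, c(1, -1, 1, -1)))
  expect_equal(diag(S), c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(S[1, 2], -1)
  expect_equal(S[1, 3], 0)
  expect_true(isSymmetric(S))
  expect_error(homogeneous_similarity(rbind(h, c(0, 0, 0, 0))), "zero norm")
})

test_that("assembled multi-manifold similarity satisfies its invariants", {
  ## M = 1 reduces to the homogeneous block
  A <- random_pm1(4, 6, seed = 5)
  expect_equal(unclass(multi_manifold_similarity(list(A), rep(1, 4))),
               homogeneous_similarity(A), ignore_attr = TRUE)
  ## M = 2, N = 1, identical unit codes, one class: all-ones 2x2
  u <- matrix(c(1, 0), 1)
  expect_equal(unclass(multi_manifold_similarity(list(u, u), 1L)),
               matrix(1, 2, 2), ignore_attr = TRUE)
  ## random instances vs the scalar entry-by-entry oracle
  for (cfg in list(c(2, 3, 4), c(3, 5, 2), c(2, 4, 3))) {
    M <- cfg[1]; n <- cfg[2]; K <- cfg[3]
    codes <- random_codes(M, n, K, seed = M * 100 + n)
    classes <- with_seed_test(n, sample(1:2, n, replace = TRUE))
    S <- multi_manifold_similarity(codes, classes, tau = 0.8)
    expect_equal(unclass(S), oracle_multi_manifold(codes, classes, tau = 0.8),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_lt(max(abs(S - t(S))), 1e-12)
    ## block ranges
    diag_idx <- rep(seq_len(M), each = n)
    for (m in seq_len(M)) for (mn in seq_len(M)) {
      blk <- S[diag_idx == m, diag_idx == mn]
      if (m == mn) {
        expect_true(all(blk >= -1 & blk <= 1))
        expect_equal(diag(blk), rep(1, n), ignore_attr = TRUE)
      } else {
        expect_true(all(blk > 0 & blk <= 1))
      }
    }
  }
  expect_error(multi_manifold_similarity(list(matrix(1, 2, 2),
                                              matrix(1, 3, 2)), c(1, 2)),
               "same N")
})
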