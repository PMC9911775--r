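test_that("semantic consistency loss matches closed-form cases", {
  ## perfect predictions vanish
  L <- one_hot_labels <- rbind(c(1, 0), c(0, 1))
  expect_equal(semantic_consistency_loss(list(L), list(L), c(1, 2)), 0)
  ## worked two-class example: ||y-l|| = sqrt 2, ||r-l|| = 0, ||y-r|| = sqrt 2
  y <- matrix(c(1, 0), 1); r <- matrix(c(0, 1), 1)
  expect_equal(semantic_consistency_loss(list(y), list(r), 2L), 2 * sqrt(2))
  ## duplicating every sample doubles the loss
  y2 <- rbind(y, y); r2 <- rbind(r, r)
  expect_equal(semantic_consistency_loss(list(y2), list(r2), c(2, 2)),
               2 * semantic_consistency_loss(list(y), list(r), 2L))
  expect_error(semantic_consistency_loss(list(y), list(r[, 1, drop = FALSE]),
                                         2L), "N x C")
})

test_that("per-pair similarity loss term is log 2 at s = 0 and non-negative", {
  expect_equal(similarity_pair_loss(0, TRUE), log(2))
  expect_equal(similarity_pair_loss(0, FALSE), log(2))
  s <- seq(-4, 4, by = 0.25)
  expect_true(all(similarity_pair_loss(s, TRUE) >= 0))
  expect_true(all(similarity_pair_loss(s, FALSE) >= 0))
})

test_that("manifold-preserving loss sums pair terms over the block similarity", {
  codes <- random_codes(2, 4, 3, seed = 11)
  classes <- c(1, 2, 1, 2)
  S <- oracle_multi_manifold(codes, classes, tau = 1.3)
  I <- outer(rep(classes, 2), rep(classes, 2), "==")
  expect_equal(manifold_preserving_loss(codes, classes, tau = 1.3),
               sum(similarity_pair_loss(S, I)), tolerance = 1e-10)
  ## self-pair exclusion removes exactly MN constant terms of value log(1+e)-1
  expect_equal(manifold_preserving_loss(codes, classes, tau = 1.3,
                                        include_self = FALSE),
               manifold_preserving_loss(codes, classes, tau = 1.3) -
                 8 * (log1p(exp(1)) - 1), tolerance = 1e-10)
})

test_that("Laplacian embedding loss matches hand-computed orthonormal case", {
  ## all codes identical: zero
  same <- list(rbind(c(1, 1), c(2, 2)))  # same direction after normalization
  S1 <- matrix(1, 2, 2)
  expect_equal(laplacian_embedding_loss(same, S1), 0)
  ## two orthonormal codes with all-ones similarity: ordered pairs sum to 2
  orth <- list(rbind(c(1, 0), c(0, 1)))
  expect_equal(laplacian_embedding_loss(orth, S1), 2)
  ## scaling any row leaves the loss unchanged
  codes <- random_codes(2, 3, 4, seed = 3)
  classes <- c(1, 1, 2)
  S <- unclass(multi_manifold_similarity(codes, classes))
  scaled <- codes; scaled[[1]][2, ] <- 7.3 * scaled[[1]][2, ]
  expect_equal(laplacian_embedding_loss(codes, S),
               laplacian_embedding_loss(scaled, S))
  expect_error(laplacian_embedding_loss(codes, S[-1, -1]), "MN x MN")
})

test_that("quantization regularizer matches closed forms in both countings", {
  ones8 <- matrix(1, 1, 8)
  expect_equal(quantization_regularizer(ones8), 0)
  expect_equal(quantization_regularizer(-ones8), 16)              # 2K, once
  expect_equal(quantization_regularizer(0 * ones8), 8)            # K
  ## printed pairwise double sum multiplies each code by 2MN
  codes <- list(-ones8, 0 * ones8)
  expect_equal(quantization_regularizer(codes, count = "pairwise"),
               2 * 2 * 1 * (16 + 8))
  ## magnitude form is zero at any +-1 code
  expect_equal(quantization_regularizer(-ones8, form = "magnitude"), 0)
  expect_equal(quantization_regularizer(0 * ones8, form = "magnitude"), 8)
})

test_that("total objective recomposes from its components and ablations", {
  codes <- random_codes(2, 5, 4, seed = 21)
  classes <- c(1, 2, 3, 1, 2)
  y <- lapply(1:2, function(m) with_seed_test(m, softmax <- {
    z <- matrix(stats::rnorm(15), 5, 3); exp(z) / rowSums(exp(z))
  }))
  r <- lapply(3:4, function(m) with_seed_test(m, {
    z <- matrix(stats::rnorm(15), 5, 3); exp(z) / rowSums(exp(z))
  }))
  for (w in list(c(0.3, 1), c(0, 1), c(0.7, 0), c(0, 0))) {
    tot <- total_objective(y, r, codes, classes, alpha = w[1], beta = w[2],
                           tau = 0.9)
    by_hand <- w[1] * semantic_consistency_loss(y, r, classes) +
      w[2] * manifold_preserving_loss(codes, classes, tau = 0.9) +
      quantization_regularizer(codes)
    expect_equal(as.numeric(tot), by_hand, tolerance = 1e-10)
  }
  ## alpha = beta = 0 with all-ones codes: only the (vanishing) regularizer
  ones <- list(matrix(1, 3, 4))
  perfect <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(as.numeric(total_objective(list(perfect), list(perfect),
                                          ones, c(1, 2, 1),
                                          alpha = 0, beta = 0)), 0)
})

test_that("analytic gradients of J2 and the regularizer match finite differences", {
  for (seed in c(4, 9)) {
    codes <- random_codes(2, 4, 3, seed = seed)
    classes <- with_seed_test(seed, sample(1:2, 4, replace = TRUE))
    g <- manifold_preserving_grad(codes, classes, tau = 0.7)
    fd <- fd_grad_list(function(cs) manifold_preserving_loss(cs, classes,
                                                             tau = 0.7), codes)
    rel <- abs(unlist(g) - unlist(fd)) / pmax(abs(unlist(fd)), 1e-6)
    expect_lt(max(rel), 1e-4)
    for (form in c("literal", "magnitude")) {
      gq <- quantization_grad(codes, form = form)
      fdq <- fd_grad_list(function(cs) quantization_regularizer(cs, form = form),
                          codes)
      expect_lt(max(abs(unlist(gq) - unlist(fdq))), 1e-6)
    }
  }
})

test_that("the pair-loss fixed point is the log golden ratio", {
  ## independent closed form: u = e^s solves u^2 - u - 1 = 0
  expect_equal(theorem_fixed_point(), log((1 + sqrt(5)) / 2),
               tolerance = 1e-12)
  s <- theorem_fixed_point()
  expect_equal(log1p(exp(s)), 2 * s, tolerance = 1e-12)
})

test_that("J2 relates to the Laplacian embedding objective near the fixed point", {
  ## probe: when every off-diagonal pair similarity is forced to the fixed
  ## point s*, the pair loss equals 2 s* = s* + s*, mirroring the
  ## (1/2)*S*||H_i - H_j||^2 + constant structure of the embedding objective
  s_star <- theorem_fixed_point()
  expect_equal(similarity_pair_loss(s_star, FALSE), 2 * s_star,
               tolerance = 1e-10)
})
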