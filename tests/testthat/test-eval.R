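test_that("gallery ranking follows cosine with stable index tie-breaks", {
  gallery <- rbind(c(1, 1), c(1, -1), c(-1, -1))
  expect_equal(rank_gallery(c(1, 1), gallery), c(1, 2, 3))
  ## the query itself ranks first
  g2 <- rbind(c(1, -1), c(1, 1), c(-1, 1))
  expect_equal(rank_gallery(c(1, 1), g2)[1], 2)
  ## ties broken by ascending gallery index
  g3 <- rbind(c(1, -1), c(-1, 1), c(1, 1))
  ord <- rank_gallery(c(1, 1), g3)
  expect_equal(ord, c(3, 1, 2))
  expect_error(rank_gallery(c(0.5, 1), gallery), "binary")
  expect_error(rank_gallery(c(1, 1, 1), gallery), "match")
})

test_that("cosine and Hamming produce identical rankings for binary codes", {
  q <- random_pm1(100, 8, seed = 31)
  g <- random_pm1(60, 8, seed = 32)
  for (i in seq_len(nrow(q))) {
    expect_identical(rank_gallery(q[i, ], g, "cosine"),
                     rank_gallery(q[i, ], g, "hamming"))
  }
})

test_that("average precision matches its definition on hand cases", {
  expect_equal(average_precision(c(1, 0)), 1)
  expect_equal(average_precision(c(1, 0, 1, 0)), (1 + 2 / 3) / 2)
  expect_equal(average_precision(rep(1, 5)), 1)
  expect_warning(ap0 <- average_precision(c(0, 0)), "no relevant")
  expect_equal(ap0, 0)
  expect_error(average_precision(numeric(0)), "empty")
  expect_error(average_precision(c(1, 2)), "0/1")
  ## brute-force oracle on random relevance vectors
  for (s in 1:5) {
    rel <- with_seed_test(s, sample(c(0, 1), 20, replace = TRUE, prob = c(0.7, 0.3)))
    if (sum(rel) == 0) rel[1] <- 1
    expect_equal(average_precision(rel), oracle_ap(rel))
  }
})

test_that("mAP and precision@k equal naive per-query loops", {
  for (s in 1:3) {
    qc <- random_pm1(12, 6, seed = 40 + s)
    gc <- random_pm1(25, 6, seed = 50 + s)
    ql <- with_seed_test(60 + s, sample(1:3, 12, replace = TRUE))
    gl <- with_seed_test(70 + s, sample(1:3, 25, replace = TRUE))
    expect_equal(mean_average_precision(qc, ql, gc, gl),
                 oracle_map(qc, ql, gc, gl))
    ## precision@k oracle
    curve <- precision_at_k_curve(qc, ql, gc, gl)
    brute <- rowMeans(sapply(seq_len(nrow(qc)), function(i) {
      ord <- rank_gallery(qc[i, ], gc)
      rel <- as.numeric(gl[ord] == ql[i])
      cumsum(rel) / seq_along(rel)
    }))
    expect_equal(curve, brute)
    expect_true(all(curve >= 0 & curve <= 1))
  }
  ## single query equals its own AP
  qc <- random_pm1(1, 6, seed = 80); gc <- random_pm1(10, 6, seed = 81)
  gl <- rep(1:2, 5)
  ord <- rank_gallery(qc[1, ], gc)
  expect_equal(mean_average_precision(qc, 1L, gc, gl),
               average_precision(as.numeric(gl[ord] == 1)))
})

test_that("random codes score chance-level mAP near the class prior", {
  qc <- random_pm1(200, 16, seed = 90)
  gc <- random_pm1(200, 16, seed = 91)
  labs <- rep(1:2, each = 100)
  m <- mean_average_precision(qc, labs, gc, labs)
  expect_lt(abs(m - 0.5), 0.05)
  ## label shuffling a structured code set also collapses to the prior
  codes <- do.call(rbind, lapply(1:2, function(c) {
    matrix(rep(c(rep(1, 8), rep(-1, 8)) * (-1)^c, 100), 100, 16, byrow = TRUE)
  }))
  shuffled <- with_seed_test(92, sample(rep(1:2, each = 100)))
  m2 <- mean_average_precision(codes, shuffled, codes, shuffled)
  expect_lt(abs(m2 - 0.5), 0.05)
})

test_that("cross-modal evaluation reports both directions and their mean", {
  d <- generate_paired_data(n_subjects = 40, n_classes = 2, input_dim = 32,
                            seed = 9)
  ctrl <- mmhash_control(pretrain_encoder_iters = 40,
                         pretrain_decoder_iters = 30, iterations = 60,
                         seed = 9)
  fit <- mmhash(d, bits = 8, control = ctrl)
  rep <- cross_modal_eval(fit, d)
  expect_named(rep$tasks, c("1->2", "2->1"))
  expect_equal(rep$average,
               (rep$tasks[["1->2"]]$map + rep$tasks[["2->1"]]$map) / 2)
  expect_true(all(vapply(rep$tasks, `[[`, numeric(1), "map") >= 0))
  expect_length(rep$tasks[["1->2"]]$precision_curve, 40)
  expect_output(print(rep), "Average")
  ## modalities that are identical copies give symmetric mAP
  d2 <- d; d2$samples[[2]] <- d2$samples[[1]]
  m <- mmhash_model(2, 32, 8, 6, 2, seed = 1)
  ## hand-tie the encoders so both modalities share weights
  for (suffix in c("W1", "b1", "W2", "b2")) {
    m$params[[paste0("enc2.", suffix)]] <- m$params[[paste0("enc1.", suffix)]]
  }
  rep2 <- cross_modal_eval(m, d2)
  expect_equal(rep2$tasks[["1->2"]]$map, rep2$tasks[["2->1"]]$map)
})
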