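## Independent scalar oracles used to cross-check the vectorized code paths.

## Entry-by-entry multi-manifold similarity: cosine on the diagonal blocks,
## heat-kernel modified distance off the diagonal.
oracle_multi_manifold <- function(codes, classes, tau = 1, swap = FALSE) {
  M <- length(codes)
  n <- nrow(codes[[1]])
  S <- matrix(NA_real_, M * n, M * n)
  for (m in seq_len(M)) for (mn in seq_len(M)) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      a <- codes[[m]][i, ]; b <- codes[[mn]][j, ]
      S[(m - 1) * n + i, (mn - 1) * n + j] <- if (m == mn) {
        sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
      } else {
        heterogeneous_pair_similarity(a, b, classes[i] == classes[j],
                                      tau = tau, swap = swap)
      }
    }
  }
  S
}

## Naive per-query average precision from first principles.
oracle_ap <- function(rel) {
  R <- sum(rel)
  if (R == 0) return(0)
  hits <- 0; acc <- 0
  for (k in seq_along(rel)) {
    if (rel[k] == 1) {
      hits <- hits + 1
      acc <- acc + hits / k
    }
  }
  acc / R
}

oracle_map <- function(qc, ql, gc, gl) {
  mean(vapply(seq_len(nrow(qc)), function(i) {
    sim <- vapply(seq_len(nrow(gc)), function(j) {
      sum(qc[i, ] * gc[j, ]) / (sqrt(sum(qc[i, ]^2)) * sqrt(sum(gc[j, ]^2)))
    }, numeric(1))
    ord <- order(-sim, seq_along(sim))
    oracle_ap(as.numeric(gl[ord] == ql[i]))
  }, numeric(1)))
}

## Central finite differences of f at a list of matrices.
fd_grad_list <- function(f, codes, eps = 1e-6) {
  lapply(seq_along(codes), function(m) {
    g <- codes[[m]] * 0
    for (i in seq_along(g)) {
      cp <- codes; cm <- codes
      cp[[m]][i] <- cp[[m]][i] + eps
      cm[[m]][i] <- cm[[m]][i] - eps
      g[i] <- (f(cp) - f(cm)) / (2 * eps)
    }
    g
  })
}

## Random relaxed codes away from the tanh saturation boundaries.
random_codes <- function(M, n, K, seed = 1, lim = 0.9) {
  with_seed_test(seed, lapply(seq_len(M), function(m) {
    matrix(stats::runif(n * K, -lim, lim), n, K)
  }))
}

random_pm1 <- function(n, K, seed = 1) {
  with_seed_test(seed, matrix(sample(c(-1, 1), n * K, replace = TRUE), n, K))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

## The fixed desk-scale study conditions used by end-to-end tests.
desk_dataset <- function() generate_paired_data(seed = 7)
desk_fit <- function(data, ...) mmhash(data, bits = 16, ...)
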