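#' Multi-semantic consistency loss
#'
#' Sums, over modalities and samples, the Euclidean norms
#' \eqn{\|y_i^m-\ell_i\| + \|r_i^m-\ell_i\| + \|y_i^m-r_i^m\|}, where
#' \eqn{y_i^m} is the encoder-stage class prediction, \eqn{r_i^m} the
#' decoder-stage prediction and \eqn{\ell_i} the one-hot label. The loss is
#' zero exactly when every prediction equals its label.
#'
#' @param y,r lists of M prediction matrices (N x C, rows are probability
#'   vectors) from the encoder- and decoder-stage attention branches.
#' @param labels class labels (vector or one-hot matrix) of the N subjects.
#' @return a single non-negative number (sum reduction, as defined).
#' @export
semantic_consistency_loss <- function(y, r, labels) {
  if (!is.list(y)) y <- list(y)
  if (!is.list(r)) r <- list(r)
  if (length(y) != length(r)) {
    stop("y and r must cover the same number of modalities", call. = FALSE)
  }
  n <- nrow(y[[1]])
  C <- ncol(y[[1]])
  L <- one_hot(as_class_index(labels, n), C)
  total <- 0
  for (m in seq_along(y)) {
    ym <- as.matrix(y[[m]]); rm_ <- as.matrix(r[[m]])
    if (!all(dim(ym) == c(n, C)) || !all(dim(rm_) == c(n, C))) {
      stop("prediction matrices must all be N x C", call. = FALSE)
    }
    total <- total + sum(row_norms(ym - L)) + sum(row_norms(rm_ - L)) +
      sum(row_norms(ym - rm_))
  }
  total
}

#' Per-pair similarity-preserving loss term
#'
#' \eqn{\log(1 + e^s) - I \cdot s}: the contribution of one ordered
#' modality/sample pair with similarity s and same-label indicator I. Always
#' non-negative, since \eqn{\log(1+e^s) \ge \max(0, s)}.
#'
#' @param s similarity value(s).
#' @param same_label logical indicator(s) I.
#' @return per-pair loss value(s).
#' @export
similarity_pair_loss <- function(s, same_label) {
  log1p(exp(s)) - as.numeric(same_label) * s
}

#' Multi-manifold similarity-preserving loss
#'
#' The negative-log-likelihood-style pairwise loss
#' \deqn{J_2 = \sum_{m,n}\sum_{i,j} \log(1 + e^{S_M(h_i^m, h_j^n)}) -
#'   I(\ell_i,\ell_j)\, S_M(h_i^m, h_j^n)}
#' over all ordered modality/sample pairs, where \eqn{S_M} is the
#' multi-manifold similarity and \eqn{I} the same-label indicator. Every
#' per-pair term is non-negative since \eqn{\log(1+e^s) \ge \max(0, s)}.
#'
#' Self-pairs (m = n, i = j) have constant similarity 1 and are included by
#' default, exactly as the double sums are written; they add a constant
#' offset with zero gradient. Set `include_self = FALSE` to drop them when
#' reporting.
#'
#' @param codes list of M relaxed or binary code matrices (N x K).
#' @inheritParams heterogeneous_similarity
#' @param include_self logical; keep the i = j, m = n terms (default TRUE).
#' @return a single non-negative number.
#' @export
manifold_preserving_loss <- function(codes, labels, tau = 1, swap = FALSE,
                                     include_self = TRUE) {
  codes <- check_code_list(codes)
  n <- nrow(codes[[1]])
  M <- length(codes)
  cls <- as_class_index(labels, n)
  S <- multi_manifold_similarity(codes, cls, tau = tau, swap = swap)
  I <- matrix(outer(cls, cls, "=="), n, n)
  Ifull <- do.call(rbind, rep(list(do.call(cbind, rep(list(I), M))), M))
  terms <- similarity_pair_loss(S, Ifull)
  if (!include_self) {
    diag(terms) <- 0
  }
  sum(terms)
}

#' Gradient of the multi-manifold similarity-preserving loss
#'
#' Analytic gradient of [manifold_preserving_loss()] with respect to every
#' relaxed code entry, used by the fine-tuning stage and checked against
#' central finite differences in the test suite. At non-differentiable points
#' (coincident codes, d = 0) the subgradient 0 is used.
#'
#' @inheritParams manifold_preserving_loss
#' @return a list of M gradient matrices matching `codes` in shape.
#' @export
manifold_preserving_grad <- function(codes, labels, tau = 1, swap = FALSE) {
  codes <- check_code_list(codes)
  M <- length(codes)
  n <- nrow(codes[[1]])
  cls <- as_class_index(labels, n)
  same <- outer(cls, cls, "==")
  grads <- lapply(codes, function(x) x * 0)
  for (m in seq_len(M)) {
    A <- codes[[m]]
    ## homogeneous block: S = cosine; both ordered pairs (i,j),(j,i) counted
    nrm <- row_norms(A)
    if (any(nrm == 0)) stop("zero-norm code row", call. = FALSE)
    U <- A / nrm
    Cs <- tcrossprod(U)
    G <- stats::plogis(Cs) - same
    diag(G) <- 0          # self-pair similarity is constant
    W <- 2 * G            # S symmetric: (i,j) and (j,i) contribute equally
    rs <- rowSums(W * Cs)
    grads[[m]] <- grads[[m]] + (W %*% U - rs * U) / nrm
    ## heterogeneous blocks: each ordered (m, n) pair handled once, with
    ## gradient flowing to both sides
    for (mn in seq_len(M)) {
      if (mn == m) next
      B <- codes[[mn]]
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      d <- sqrt(pmax(d2, 0))
      e <- exp(-d)
      sm <- if (isTRUE(swap)) !same else same
      D2 <- ifelse(sm, 1 - e, e)
      S <- exp(-D2 / tau)
      G <- stats::plogis(S) - same
      dS_dd <- (-S / tau) * ifelse(sm, e, -e)
      coef <- ifelse(d > 0, G * dS_dd / d, 0)
      grads[[m]] <- grads[[m]] + rowSums(coef) * A - coef %*% B
      grads[[mn]] <- grads[[mn]] + colSums(coef) * B - crossprod(coef, A)
    }
  }
  grads
}

#' Laplacian-embedding reference loss
#'
#' The graph-embedding objective
#' \eqn{\sum_{m,n}\sum_{i,j} \tfrac12 S_{ij}\|H_i^m - H_j^n\|^2} with
#' \eqn{H = h/\|h\|} row-normalized codes — the Laplacian-eigenmaps form that
#' the similarity-preserving loss reduces to at its fixed point
#' \eqn{\log(1+e^s) = 2s} (see [theorem_fixed_point()]). Provided as a
#' numerical probe, not as a training objective.
#'
#' @param codes list of M code matrices (N x K), no zero rows.
#' @param similarity a symmetric MN x MN weight matrix in modality-major
#'   order, e.g. from [multi_manifold_similarity()].
#' @return a single non-negative number.
#' @export
laplacian_embedding_loss <- function(codes, similarity) {
  codes <- check_code_list(codes)
  n <- nrow(codes[[1]])
  M <- length(codes)
  S <- as.matrix(similarity)
  if (!all(dim(S) == M * n)) {
    stop("similarity must be MN x MN (", M * n, "); got ",
         paste(dim(S), collapse = " x "), call. = FALSE)
  }
  if (max(abs(S - t(S))) > 1e-8) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  H <- do.call(rbind, lapply(codes, normalize_rows))
  d2 <- outer(rowSums(H^2), rowSums(H^2), "+") - 2 * tcrossprod(H)
  sum(0.5 * S * pmax(d2, 0))
}

#' Quantization regularizer
#'
#' Pushes relaxed codes toward valid binary values. Two forms:
#' \describe{
#'   \item{`"literal"`}{\eqn{\|h - \mathbf{1}\|_1}, the distance of each code
#'     to the all-ones vector, exactly as the objective prints it. Note this
#'     drives every bit toward +1.}
#'   \item{`"magnitude"`}{\eqn{\||h| - \mathbf{1}\|_1}, the distance of the
#'     bit magnitudes to 1 — the usual quantization penalty, sign-agnostic.}
#' }
#' `count = "once"` sums one term per code (so a single all-(-1) code of
#' length K scores 2K under the literal form); `count = "pairwise"`
#' reproduces the printed double sum over (m, n, i, j), which multiplies each
#' per-code term by 2MN.
#'
#' @param codes list of M code matrices (N x K), or a single matrix.
#' @param form `"literal"` or `"magnitude"`.
#' @param count `"once"` (per code) or `"pairwise"` (printed multiplicity).
#' @return a single non-negative number.
#' @export
quantization_regularizer <- function(codes, form = c("literal", "magnitude"),
                                     count = c("once", "pairwise")) {
  form <- match.arg(form)
  count <- match.arg(count)
  if (!is.list(codes)) codes <- list(codes)
  codes <- check_code_list(codes)
  per_code <- vapply(codes, function(h) {
    if (form == "literal") sum(abs(h - 1)) else sum(abs(abs(h) - 1))
  }, numeric(1))
  mult <- if (count == "pairwise") 2 * length(codes) * nrow(codes[[1]]) else 1
  mult * sum(per_code)
}

#' Gradient of the quantization regularizer
#'
#' Elementwise subgradient of [quantization_regularizer()] with respect to
#' the relaxed codes (0 at the kinks).
#'
#' @inheritParams quantization_regularizer
#' @return a list of M gradient matrices matching `codes` in shape.
#' @export
quantization_grad <- function(codes, form = c("literal", "magnitude"),
                              count = c("once", "pairwise")) {
  form <- match.arg(form)
  count <- match.arg(count)
  if (!is.list(codes)) codes <- list(codes)
  codes <- check_code_list(codes)
  mult <- if (count == "pairwise") 2 * length(codes) * nrow(codes[[1]]) else 1
  lapply(codes, function(h) {
    g <- if (form == "literal") sign(h - 1) else sign(abs(h) - 1) * sign(h)
    mult * g
  })
}

#' Total training objective
#'
#' \eqn{J = \alpha J_1 + \beta J_2 + \mathrm{reg}}, combining the
#' multi-semantic consistency loss, the multi-manifold similarity-preserving
#' loss and the quantization regularizer. `alpha = 0` gives the
#' similarity-only ablation variant; `beta = 0` the consistency-only variant.
#'
#' @inheritParams semantic_consistency_loss
#' @inheritParams manifold_preserving_loss
#' @inheritParams quantization_regularizer
#' @param alpha,beta non-negative weights of the consistency and
#'   similarity-preserving terms.
#' @return a single number; attribute `"components"` carries the named parts.
#' @export
total_objective <- function(y, r, codes, labels, alpha = 0.3, beta = 1,
                            tau = 1, swap = FALSE,
                            form = c("literal", "magnitude"),
                            count = c("once", "pairwise")) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0", call. = FALSE)
  j1 <- if (alpha > 0) semantic_consistency_loss(y, r, labels) else 0
  j2 <- if (beta > 0) manifold_preserving_loss(codes, labels, tau, swap) else 0
  reg <- quantization_regularizer(codes, form = form, count = count)
  structure(alpha * j1 + beta * j2 + reg,
            components = c(J1 = j1, J2 = j2, reg = reg))
}

#' Fixed point of the similarity-preserving pair term
#'
#' Solves \eqn{\log(1 + e^s) = 2s} numerically. Substituting \eqn{u = e^s}
#' turns the condition into \eqn{u^2 - u - 1 = 0}, so the root is the log of
#' the golden ratio, \eqn{\ln((1+\sqrt 5)/2) \approx 0.4812118}. At this
#' similarity value the pairwise loss coincides with the Laplacian-embedding
#' objective (manifold-preserving invariance).
#'
#' @param tol convergence tolerance for the root search.
#' @return the root of `log(1 + exp(s)) - 2 s` on `(0, 1)`.
#' @export
theorem_fixed_point <- function(tol = 1e-14) {
  stats::uniroot(function(s) log1p(exp(s)) - 2 * s, c(0.1, 1),
                 tol = tol)$root
}
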