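#' Euclidean distance between two code vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return the non-negative l2 norm of `a - b`.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("code vectors differ in length: ", length(a), " vs ", length(b),
         call. = FALSE)
  }
  sqrt(sum((a - b)^2))
}

#' Modified distance between two hash codes
#'
#' Squashes the Euclidean distance \eqn{d(a,b)} into \eqn{[0,1)} with a branch
#' chosen by the label relation: \eqn{\sqrt{1-e^{-d}}} for a same-label pair
#' (small when the codes agree) and \eqn{\sqrt{e^{-d}}} for a different-label
#' pair (large when the codes agree). This is the distance that feeds the heat
#' kernel in [heterogeneous_similarity()].
#'
#' As printed, the different-label branch approaches 1 as \eqn{d \to \infty}
#' and \eqn{\sqrt{e^{0}} = 1} at \eqn{d = 0} — i.e. it *decreases* with
#' growing code distance. `swap` exchanges the two branches for
#' experimentation; the default follows the published formula literally.
#'
#' @param a,b numeric code vectors of equal length.
#' @param same_label logical; do the two samples share a class label?
#' @param swap logical; exchange the same/different-label branches.
#' @return a single value in `[0, 1]`.
#' @examples
#' modified_distance(c(1, -1, 1), c(1, -1, 1), same_label = TRUE)   # 0
#' modified_distance(c(1, 1), c(1, 1), same_label = FALSE)          # 1
#' @export
modified_distance <- function(a, b, same_label, swap = FALSE) {
  if (length(a) != length(b)) {
    stop("code vectors differ in length: ", length(a), " vs ", length(b),
         call. = FALSE)
  }
  d <- sqrt(sum((a - b)^2))
  if (isTRUE(swap)) same_label <- !same_label
  if (isTRUE(same_label)) sqrt(1 - exp(-d)) else sqrt(exp(-d))
}

#' Heat-kernel similarity of a heterogeneous code pair
#'
#' \eqn{S_H(a, b) = \exp(-D^2(a,b)/\tau)} where \eqn{D} is the
#' label-dependent [modified_distance()] and \eqn{\tau > 0} the heat kernel
#' constant. Values lie in \eqn{(0, 1]}: same-label pairs reach 1 at
#' \eqn{d = 0} and decay towards \eqn{e^{-1/\tau}}; different-label pairs
#' start at \eqn{e^{-1/\tau}} at \eqn{d = 0}.
#'
#' @inheritParams modified_distance
#' @param tau positive heat kernel constant.
#' @return a single value in `(0, 1]`.
#' @export
heterogeneous_pair_similarity <- function(a, b, same_label, tau = 1, swap = FALSE) {
  stopifnot_scalar_pos(tau, "tau")
  D <- modified_distance(a, b, same_label, swap = swap)
  exp(-D^2 / tau)
}

#' Heterogeneous manifold similarity matrix
#'
#' Pairwise heat-kernel similarities between all samples of one modality and
#' all samples of another. Entry \eqn{(i, j)} compares code \eqn{i} of
#' modality m with code \eqn{j} of modality n, using the shared (strongly
#' paired) labels to pick the modified-distance branch. Swapping the two code
#' matrices transposes the result.
#'
#' @param codes_m,codes_n N x K numeric code matrices of two different
#'   modalities (rows are samples).
#' @param labels class labels of the N subjects — an integer/factor vector or
#'   a one-hot matrix; identical across modalities under strong pairing.
#' @inheritParams heterogeneous_pair_similarity
#' @return an N x N matrix with entries in `(0, 1]`.
#' @export
heterogeneous_similarity <- function(codes_m, codes_n, labels, tau = 1,
                                     swap = FALSE) {
  stopifnot_scalar_pos(tau, "tau")
  codes_m <- as.matrix(codes_m)
  codes_n <- as.matrix(codes_n)
  if (ncol(codes_m) != ncol(codes_n)) {
    stop("code matrices differ in K: ", ncol(codes_m), " vs ", ncol(codes_n),
         call. = FALSE)
  }
  n <- nrow(codes_m)
  if (nrow(codes_n) != n) {
    stop("code matrices differ in N: ", n, " vs ", nrow(codes_n), call. = FALSE)
  }
  cls <- as_class_index(labels, n)
  d2 <- outer(rowSums(codes_m^2), rowSums(codes_n^2), "+") -
    2 * tcrossprod(codes_m, codes_n)
  d <- sqrt(pmax(d2, 0))
  e <- exp(-d)
  same <- outer(cls, cls, "==")
  if (isTRUE(swap)) same <- !same
  D2 <- ifelse(same, 1 - e, e)
  exp(-D2 / tau)
}

#' Homogeneous manifold similarity matrix (cosine)
#'
#' Pairwise cosine similarity between all codes of one modality: symmetric,
#' unit diagonal, entries in `[-1, 1]`. Rows with zero norm are rejected
#' explicitly (cosine is undefined there).
#'
#' @param codes N x K numeric code matrix.
#' @return an N x N symmetric matrix with unit diagonal.
#' @export
homogeneous_similarity <- function(codes) {
  u <- normalize_rows(as.matrix(codes))
  s <- tcrossprod(u)
  diag(s) <- 1
  pmin(pmax(s, -1), 1)
}

#' Multi-manifold similarity block matrix
#'
#' Assembles the MN x MN similarity over all modality/sample pairs in
#' modality-major order: diagonal blocks are homogeneous (cosine)
#' similarities within a modality, off-diagonal blocks are heterogeneous
#' heat-kernel similarities between modalities. The result is symmetric.
#'
#' @param codes list of M code matrices (one per modality), all N x K.
#' @inheritParams heterogeneous_similarity
#' @return an MN x MN matrix of class `multi_manifold_similarity` with
#'   attributes `n_modalities`, `n_samples` and `tau`. Row/column `(m-1)*N + i`
#'   corresponds to sample i of modality m.
#' @examples
#' codes <- list(matrix(c(1, 1, -1, 1), 2), matrix(c(1, -1, -1, 1), 2))
#' S <- multi_manifold_similarity(codes, labels = c(1, 2))
#' isSymmetric(unclass(S))
#' @export
multi_manifold_similarity <- function(codes, labels, tau = 1, swap = FALSE) {
  codes <- check_code_list(codes)
  M <- length(codes)
  n <- nrow(codes[[1]])
  cls <- as_class_index(labels, n)
  S <- matrix(NA_real_, M * n, M * n)
  idx <- function(m) ((m - 1L) * n + 1L):(m * n)
  for (m in seq_len(M)) {
    S[idx(m), idx(m)] <- homogeneous_similarity(codes[[m]])
    if (m < M) {
      for (mn in seq(m + 1L, M)) {
        blk <- heterogeneous_similarity(codes[[m]], codes[[mn]], cls,
                                        tau = tau, swap = swap)
        S[idx(m), idx(mn)] <- blk
        S[idx(mn), idx(m)] <- t(blk)
      }
    }
  }
  structure(S, n_modalities = M, n_samples = n, tau = tau,
            class = c("multi_manifold_similarity", "matrix", "array"))
}
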