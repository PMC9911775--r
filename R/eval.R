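#' Rank a gallery against one query code
#'
#' Orders gallery indices by decreasing cosine similarity to the query (or
#' increasing Hamming distance — identical orderings for fixed-length
#' \eqn{\pm 1} codes, since \eqn{\cos = (K - 2\,\mathrm{Ham})/K}). Ties are
#' broken by ascending gallery index.
#'
#' @param query a binary code vector (entries -1/+1).
#' @param gallery an N x K binary code matrix.
#' @param metric `"cosine"` or `"hamming"`.
#' @param binary require binary codes (default TRUE; evaluation is defined
#'   on binarized codes — set FALSE to rank relaxed codes by cosine).
#' @return an integer permutation of `seq_len(nrow(gallery))`.
#' @export
rank_gallery <- function(query, gallery, metric = c("cosine", "hamming"),
                         binary = TRUE) {
  metric <- match.arg(metric)
  gallery <- as.matrix(gallery)
  if (length(query) != ncol(gallery)) {
    stop("query length ", length(query), " does not match gallery K = ",
         ncol(gallery), call. = FALSE)
  }
  if (binary && (!is_pm1(query) || !is_pm1(gallery))) {
    stop("codes must be binary (-1/+1); binarize first or set binary = FALSE",
         call. = FALSE)
  }
  if (metric == "hamming") {
    key <- colSums(query != t(gallery))            # ascending distance
    order(key, seq_len(nrow(gallery)))
  } else {
    sim <- as.vector(gallery %*% query) /
      (row_norms(gallery) * sqrt(sum(query^2)))
    order(-sim, seq_len(nrow(gallery)))
  }
}

#' Average precision of a ranked relevance list
#'
#' \eqn{AP = \frac1R \sum_{k:\ \mathrm{rel}_k = 1} \mathrm{prec}@k} over the
#' full returned list (no rank cutoff), where R is the number of relevant
#' items. A query with no relevant item in the gallery scores 0 (with a
#' warning).
#'
#' @param ranked_relevance 0/1 (or logical) vector in rank order.
#' @return a value in `[0, 1]`.
#' @examples
#' average_precision(c(1, 0, 1, 0))  # (1 + 2/3) / 2
#' @export
average_precision <- function(ranked_relevance) {
  rel <- as.numeric(ranked_relevance)
  if (!length(rel)) stop("empty ranked list", call. = FALSE)
  if (!all(rel %in% c(0, 1))) stop("relevance must be 0/1", call. = FALSE)
  R <- sum(rel)
  if (R == 0) {
    warning("query has no relevant gallery item; AP = 0")
    return(0)
  }
  prec <- cumsum(rel) / seq_along(rel)
  sum(prec[rel == 1]) / R
}

#' Mean average precision over a query set
#'
#' Relevance is same-class membership. Each query ranks the full gallery
#' (all returned results) and the per-query average precisions are averaged.
#'
#' @param query_codes,gallery_codes binary code matrices.
#' @param query_labels,gallery_labels class labels for the two sets.
#' @param metric ranking metric, see [rank_gallery()].
#' @param binary require binarized codes (default TRUE).
#' @param map_at optional rank cutoff; `NULL` (default) evaluates the full
#'   list.
#' @return mAP in `[0, 1]`.
#' @export
mean_average_precision <- function(query_codes, query_labels, gallery_codes,
                                   gallery_labels,
                                   metric = c("cosine", "hamming"),
                                   binary = TRUE, map_at = NULL) {
  metric <- match.arg(metric)
  query_codes <- as.matrix(query_codes)
  gallery_codes <- as.matrix(gallery_codes)
  ql <- as_class_index(query_labels, nrow(query_codes))
  gl <- as_class_index(gallery_labels, nrow(gallery_codes))
  aps <- vapply(seq_len(nrow(query_codes)), function(i) {
    ord <- rank_gallery(query_codes[i, ], gallery_codes, metric,
                        binary = binary)
    rel <- as.numeric(gl[ord] == ql[i])
    if (!is.null(map_at)) rel <- rel[seq_len(min(map_at, length(rel)))]
    if (sum(rel) == 0) 0 else average_precision(rel)
  }, numeric(1))
  mean(aps)
}

#' Precision@k curve
#'
#' For each cutoff k = 1..gallery size, the mean over queries of the
#' fraction of relevant items among the top k returned.
#'
#' @inheritParams mean_average_precision
#' @return numeric vector of length `nrow(gallery_codes)`.
#' @export
precision_at_k_curve <- function(query_codes, query_labels, gallery_codes,
                                 gallery_labels,
                                 metric = c("cosine", "hamming"),
                                 binary = TRUE) {
  metric <- match.arg(metric)
  query_codes <- as.matrix(query_codes)
  gallery_codes <- as.matrix(gallery_codes)
  ql <- as_class_index(query_labels, nrow(query_codes))
  gl <- as_class_index(gallery_labels, nrow(gallery_codes))
  G <- nrow(gallery_codes)
  acc <- numeric(G)
  for (i in seq_len(nrow(query_codes))) {
    ord <- rank_gallery(query_codes[i, ], gallery_codes, metric,
                        binary = binary)
    rel <- as.numeric(gl[ord] == ql[i])
    acc <- acc + cumsum(rel) / seq_len(G)
  }
  acc / nrow(query_codes)
}

#' Cross-modal retrieval evaluation of a trained model
#'
#' Encodes and binarizes the test split, then evaluates every ordered
#' modality pair as a retrieval task (query one modality, rank the full
#' opposite-modality test set). For two modalities this is the familiar
#' M->P / P->M / Average layout.
#'
#' @param object a fitted [mmhash()] model (or an `mmhash_model`).
#' @param data a paired test dataset.
#' @param metric ranking metric.
#' @param binarize binarize the relaxed codes before evaluation (default
#'   TRUE; this is a hashing evaluation).
#' @return an object of class `retrieval_report`: per-task mAP and
#'   precision@k curves plus their average mAP.
#' @export
cross_modal_eval <- function(object, data, metric = c("cosine", "hamming"),
                             binarize = TRUE) {
  metric <- match.arg(metric)
  model <- if (inherits(object, "mmhash")) object$model else object
  data <- as_paired(data)
  if (length(data$samples) != model$n_modalities || model$n_modalities < 2) {
    stop("need a test split covering all (>= 2) model modalities",
         call. = FALSE)
  }
  codes <- mm_decode(model, mm_encode(model, data$samples))
  if (binarize) codes <- binarize_codes(codes)
  M <- length(codes)
  tasks <- list()
  for (m in seq_len(M)) for (n in seq_len(M)) {
    if (m == n) next
    key <- sprintf("%d->%d", m, n)
    tasks[[key]] <- list(
      map = mean_average_precision(codes[[m]], data$classes, codes[[n]],
                                   data$classes, metric, binary = binarize),
      precision_curve = precision_at_k_curve(codes[[m]], data$classes,
                                             codes[[n]], data$classes,
                                             metric, binary = binarize))
  }
  structure(list(tasks = tasks,
                 average = mean(vapply(tasks, `[[`, numeric(1), "map")),
                 metric = metric, binarized = binarize,
                 n_queries = length(data$classes)),
            class = "retrieval_report")
}

#' @export
print.retrieval_report <- function(x, digits = 4, ...) {
  cat("Cross-modal retrieval (", x$metric, ", ",
      if (x$binarized) "binary" else "relaxed", " codes, ", x$n_queries,
      " queries per task)\n", sep = "")
  for (nm in names(x$tasks)) {
    cat(sprintf("  task %-6s mAP = %.*f\n", nm, digits, x$tasks[[nm]]$map))
  }
  cat(sprintf("  Average    mAP = %.*f\n", digits, x$average))
  invisible(x)
}
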