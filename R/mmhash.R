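#' Fit a consistency-preserving cross-modal hashing model
#'
#' The main entry point: builds the asymmetric hash auto-encoder and runs the
#' three-stage training schedule (encoder pre-training, decoder pre-training,
#' joint fine-tuning) on a strongly paired multi-modal dataset, returning a
#' fitted model whose binary codes support cross-modal retrieval.
#'
#' The objective combines a multi-semantic consistency loss (encoder- and
#' decoder-stage class predictions pulled to the one-hot labels and to each
#' other, weight `alpha`), a multi-manifold similarity-preserving loss over
#' the heat-kernel/cosine block similarity of the relaxed codes (weight
#' `beta`), and a quantization penalty pushing codes toward \eqn{\pm 1}.
#' Setting `alpha = 0` or `beta = 0` trains the two published ablation
#' variants.
#'
#' @param data a `paired_mmdata` (see [generate_paired_data()]) or a list
#'   with elements `samples` (list of M N x Z matrices) and `classes`.
#' @param bits hash code length K.
#' @param feature_dim encoder output dimension D (< Z).
#' @param hidden_dim encoder hidden width.
#' @param control an [mmhash_control()]; its hyper-parameters drive all three
#'   stages.
#' @param model_seed seed for parameter initialization (batch order is
#'   seeded by `control$seed`).
#' @param log_file optional TSV training-log path.
#' @param ... passed to [mmhash_control()] when `control` is missing.
#' @return an object of class `mmhash` with elements `model`, `history`,
#'   `control`, `data_dims` and `call`. Methods: `print`, `summary`,
#'   `predict`, `plot`, `coef`.
#' @examples
#' d <- generate_paired_data(n_subjects = 40, n_classes = 2, seed = 1)
#' fit <- mmhash(d, bits = 8, iterations = 30,
#'               pretrain_encoder_iters = 20, pretrain_decoder_iters = 20)
#' fit
#' codes <- predict(fit, d, type = "codes")
#' @export
mmhash <- function(data, bits = 16, feature_dim = 16, hidden_dim = 64,
                   control = NULL, model_seed = NULL, log_file = NULL, ...) {
  cl <- match.call()
  data <- as_paired(data)
  if (is.null(control)) control <- mmhash_control(...)
  model <- mmhash_model(n_modalities = length(data$samples),
                        input_dim = ncol(data$samples[[1]]),
                        feature_dim = feature_dim, code_bits = bits,
                        n_classes = ncol(data$onehot),
                        hidden_dim = hidden_dim,
                        seed = model_seed %||% control$seed)
  trained <- mm_train(model, data, control, log_file = log_file)
  structure(list(model = trained$model, history = trained$history,
                 control = control,
                 data_dims = c(n = length(data$classes),
                               M = length(data$samples),
                               Z = ncol(data$samples[[1]]),
                               C = ncol(data$onehot)),
                 call = cl),
            class = "mmhash")
}

#' @export
print.mmhash <- function(x, ...) {
  cat("Cross-modal hashing fit\n")
  cat("  call: "); print(x$call)
  cat(sprintf("  data: %d subjects, %d modalities, Z = %d, %d classes\n",
              x$data_dims["n"], x$data_dims["M"], x$data_dims["Z"],
              x$data_dims["C"]))
  cat(sprintf("  codes: %d bits | alpha = %g, beta = %g, tau = %g\n",
              x$model$code_bits, x$control$alpha, x$control$beta,
              x$control$tau))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final training loss: %.4f (%d iterations over 3 stages)\n",
                last$total, nrow(x$history)))
  }
  invisible(x)
}

#' @export
summary.mmhash <- function(object, ...) {
  h <- object$history
  stage_tab <- if (nrow(h)) {
    do.call(rbind, lapply(split(h, factor(h$stage, unique(h$stage))),
                          function(s) data.frame(stage = s$stage[1],
                                                 iterations = nrow(s),
                                                 first_loss = s$total[1],
                                                 last_loss = s$total[nrow(s)])))
  } else data.frame()
  out <- list(fit = object, stages = stage_tab,
              param_counts = model_param_counts(object$model))
  class(out) <- "summary.mmhash"
  out
}

#' @export
print.summary.mmhash <- function(x, ...) {
  print(x$fit)
  cat("  parameters: encoder", x$param_counts[["encoder"]],
      "per modality; decoder", x$param_counts[["decoder"]],
      "; SPAB heads", x$param_counts[["spab"]], "\n")
  if (nrow(x$stages)) {
    cat("  training stages:\n")
    print(x$stages, row.names = FALSE)
  }
  invisible(x)
}

#' Predict hash codes, features or classes for new paired data
#'
#' @param object a fitted [mmhash()] model.
#' @param newdata a paired dataset (or list of M sample matrices).
#' @param type `"codes"` (binarized, the default), `"relaxed"`, `"features"`,
#'   or `"class"` (decoder-stage class predictions).
#' @param ... ignored.
#' @return list of M matrices of the requested quantity.
#' @export
predict.mmhash <- function(object, newdata,
                           type = c("codes", "relaxed", "features", "class"),
                           ...) {
  type <- match.arg(type)
  samples <- if (is.list(newdata) && !is.null(newdata$samples)) {
    newdata$samples
  } else newdata
  f <- mm_encode(object$model, samples)
  if (type == "features") return(f)
  h <- mm_decode(object$model, f)
  switch(type,
         relaxed = h,
         codes = binarize_codes(h),
         class = spab_predict(object$model, "decoder", h))
}

#' @export
coef.mmhash <- function(object, ...) object$model$params

#' Plot training loss history
#'
#' Draws the per-iteration total loss with stage boundaries; optionally the
#' individual loss components of the fine-tuning stage.
#'
#' @param x a fitted [mmhash()] model.
#' @param component `"total"`, `"J1"`, `"J2"` or `"reg"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mmhash <- function(x, component = "total", ...) {
  h <- x$history
  if (!nrow(h)) stop("no training history to plot", call. = FALSE)
  val <- h[[component]]
  graphics::plot(h$iteration, val, type = "l", xlab = "iteration",
                 ylab = component, ...)
  bounds <- cumsum(rle(h$stage)$lengths)
  graphics::abline(v = bounds[-length(bounds)] + 0.5, lty = 2, col = "grey")
  invisible(x)
}
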