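#' Build the asymmetric hash auto-encoder
#'
#' Constructs the network: one encoder per modality (pseudo-Siamese —
#' identical architecture, unshared weights), a single light fully-connected
#' decoder shared across modalities mapping features to relaxed codes in
#' (-1, 1) via tanh, and two semantics-preserving attention branches — a
#' linear softmax head on the features (encoder stage) and one on the codes
#' (decoder stage). Initialization is deterministic given `seed`.
#'
#' The default backbone is a 2-layer MLP on flat inputs; the encoder always
#' holds more parameters than the decoder (architectural asymmetry).
#'
#' @param n_modalities number of modalities M (>= 1).
#' @param input_dim flat input dimension Z per sample.
#' @param feature_dim encoder output dimension D; must satisfy D < Z.
#' @param code_bits hash code length K (>= 1).
#' @param n_classes number of classes C (>= 2).
#' @param hidden_dim encoder hidden-layer width.
#' @param backbone backbone family; only `"mlp"` is implemented (convolutional
#'   backbones belong to GPU-scale image experiments outside this package's
#'   scope).
#' @param seed integer seed for parameter initialization.
#' @return an object of class `mmhash_model`: a flat named parameter list
#'   plus the architecture description.
#' @examples
#' m <- mmhash_model(2, input_dim = 64, feature_dim = 16, code_bits = 8,
#'                   n_classes = 2, seed = 0)
#' @export
mmhash_model <- function(n_modalities, input_dim, feature_dim = 16,
                         code_bits = 16, n_classes, hidden_dim = 32,
                         backbone = "mlp", seed = 1) {
  if (n_modalities < 1) stop("need at least one modality", call. = FALSE)
  if (feature_dim >= input_dim) {
    stop("feature_dim (D = ", feature_dim, ") must be smaller than input_dim ",
         "(Z = ", input_dim, "): the encoder is a compression", call. = FALSE)
  }
  if (code_bits < 1) stop("code_bits must be >= 1", call. = FALSE)
  if (n_classes < 2) stop("need at least two classes", call. = FALSE)
  backbone <- match.arg(backbone, c("mlp", "tiny_cnn", "alexnet_like"))
  if (backbone != "mlp") {
    stop("backbone '", backbone, "' is not implemented; use 'mlp'",
         call. = FALSE)
  }
  init <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
  params <- with_seed(seed, {
    p <- list()
    for (m in seq_len(n_modalities)) {
      p[[sprintf("enc%d.W1", m)]] <- init(input_dim, hidden_dim)
      p[[sprintf("enc%d.b1", m)]] <- numeric(hidden_dim)
      p[[sprintf("enc%d.W2", m)]] <- init(hidden_dim, feature_dim)
      p[[sprintf("enc%d.b2", m)]] <- numeric(feature_dim)
    }
    p[["dec.W"]] <- init(feature_dim, code_bits)
    p[["dec.b"]] <- numeric(code_bits)
    p[["spabE.W"]] <- init(feature_dim, n_classes)
    p[["spabE.b"]] <- numeric(n_classes)
    p[["spabD.W"]] <- init(code_bits, n_classes)
    p[["spabD.b"]] <- numeric(n_classes)
    p
  })
  structure(list(params = params,
                 n_modalities = n_modalities, input_dim = input_dim,
                 feature_dim = feature_dim, code_bits = code_bits,
                 n_classes = n_classes, hidden_dim = hidden_dim,
                 backbone = backbone, seed = seed),
            class = "mmhash_model")
}

#' @export
print.mmhash_model <- function(x, ...) {
  cat("Asymmetric hash auto-encoder (", x$backbone, " backbone)\n", sep = "")
  cat(sprintf("  modalities: %d | Z = %d -> D = %d -> K = %d bits | C = %d classes\n",
              x$n_modalities, x$input_dim, x$feature_dim, x$code_bits,
              x$n_classes))
  np <- model_param_counts(x)
  cat(sprintf("  parameters: encoder %d per modality, decoder %d, SPAB %d\n",
              np[["encoder"]], np[["decoder"]], np[["spab"]]))
  invisible(x)
}

model_param_counts <- function(model) {
  p <- model$params
  enc <- sum(vapply(p[grep("^enc1\\.", names(p))], length, integer(1)))
  dec <- sum(vapply(p[grep("^dec\\.", names(p))], length, integer(1)))
  spab <- sum(vapply(p[grep("^spab", names(p))], length, integer(1)))
  c(encoder = enc, decoder = dec, spab = spab)
}

check_batch <- function(model, batch) {
  if (!is.list(batch)) batch <- list(batch)
  if (length(batch) != model$n_modalities) {
    stop("batch has ", length(batch), " modalities; model expects ",
         model$n_modalities, call. = FALSE)
  }
  batch <- lapply(batch, function(x) {
    x <- as.matrix(x)
    if (ncol(x) != model$input_dim) {
      stop("sample dimension ", ncol(x), " does not match input_dim ",
           model$input_dim, call. = FALSE)
    }
    x
  })
  batch
}

#' Encode a multi-modal batch into features
#'
#' Runs each modality's samples through its own encoder only (unshared
#' weights).
#'
#' @param model an [mmhash_model()].
#' @param batch list of M sample matrices (N x Z).
#' @return list of M feature matrices (N x D).
#' @export
mm_encode <- function(model, batch) {
  batch <- check_batch(model, batch)
  p <- model$params
  lapply(seq_along(batch), function(m) {
    a1 <- tanh(sweep(batch[[m]] %*% p[[sprintf("enc%d.W1", m)]], 2,
                     p[[sprintf("enc%d.b1", m)]], "+"))
    sweep(a1 %*% p[[sprintf("enc%d.W2", m)]], 2,
          p[[sprintf("enc%d.b2", m)]], "+")
  })
}

#' Decode features into relaxed hash codes
#'
#' The shared light fully-connected decoder maps D-dimensional features into
#' Hamming space through tanh, giving relaxed codes strictly inside (-1, 1).
#'
#' @param model an [mmhash_model()].
#' @param features list of M feature matrices (N x D), or one matrix.
#' @return list of M relaxed code matrices (N x K) (or one matrix, matching
#'   the input form).
#' @export
mm_decode <- function(model, features) {
  single <- !is.list(features)
  if (single) features <- list(features)
  p <- model$params
  out <- lapply(features, function(f) {
    f <- as.matrix(f)
    if (ncol(f) != model$feature_dim) {
      stop("feature dimension ", ncol(f), " does not match D = ",
           model$feature_dim, call. = FALSE)
    }
    tanh(sweep(f %*% p[["dec.W"]], 2, p[["dec.b"]], "+"))
  })
  if (single) out[[1]] else out
}

#' Class predictions from a semantics-preserving attention branch
#'
#' The encoder-stage branch takes D-dimensional features; the decoder-stage
#' branch takes K-dimensional relaxed codes. Both are linear softmax heads,
#' so every output row is a probability vector.
#'
#' @param model an [mmhash_model()].
#' @param stage `"encoder"` or `"decoder"`.
#' @param input an N x D (encoder stage) or N x K (decoder stage) matrix, or
#'   a list of such matrices (one per modality).
#' @return matrix (or list of matrices) of N x C class probabilities.
#' @export
spab_predict <- function(model, stage = c("encoder", "decoder"), input) {
  stage <- match.arg(stage)
  single <- !is.list(input)
  if (single) input <- list(input)
  p <- model$params
  want <- if (stage == "encoder") model$feature_dim else model$code_bits
  W <- if (stage == "encoder") p[["spabE.W"]] else p[["spabD.W"]]
  b <- if (stage == "encoder") p[["spabE.b"]] else p[["spabD.b"]]
  out <- lapply(input, function(x) {
    x <- as.matrix(x)
    if (ncol(x) != want) {
      stop(stage, "-stage branch expects ", want, " columns, got ", ncol(x),
           call. = FALSE)
    }
    softmax_rows(sweep(x %*% W, 2, b, "+"))
  })
  if (single) out[[1]] else out
}

#' Binarize relaxed codes
#'
#' Sign function with the fixed tie rule `sign(0) = +1`, mapping relaxed
#' codes in `[-1, 1]` to binary codes in `{-1, +1}`. Idempotent.
#'
#' @param codes a matrix or list of matrices of relaxed codes.
#' @return binary code matrix (or list), entries exactly -1 or +1.
#' @export
binarize_codes <- function(codes) {
  f <- function(x) {
    out <- ifelse(x >= 0, 1, -1)
    dimnames(out) <- dimnames(x)
    out
  }
  if (is.list(codes)) lapply(codes, f) else f(as.matrix(codes))
}

#' Full forward pass
#'
#' Composes encode, decode and both attention branches; the returned pieces
#' feed [total_objective()] directly.
#'
#' @param model an [mmhash_model()].
#' @param batch list of M sample matrices (N x Z).
#' @return a list with elements `features`, `codes` (relaxed), `y`
#'   (encoder-stage predictions) and `r` (decoder-stage predictions), each a
#'   list of M matrices.
#' @export
mm_forward <- function(model, batch) {
  f <- mm_encode(model, batch)
  h <- mm_decode(model, f)
  list(features = f, codes = h,
       y = spab_predict(model, "encoder", f),
       r = spab_predict(model, "decoder", h))
}
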