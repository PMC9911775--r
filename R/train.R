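#' Training control parameters
#'
#' Collects the optimization hyper-parameters for the three-stage schedule.
#' The desk-scale defaults (learning rate 1e-3, a few hundred iterations per
#' stage) suit the small MLP backbone and the bundled synthetic data; the
#' `"adni2"` and `"oasis3"` presets set the published recipe (batch size 20,
#' 500 iterations, initial learning rate 1e-6, alpha/beta as selected on each
#' dataset), which assumes a large CNN backbone.
#'
#' @param batch_size samples per optimization step.
#' @param learning_rate Adam step size.
#' @param iterations fine-tuning steps.
#' @param pretrain_encoder_iters,pretrain_decoder_iters steps for the two
#'   pre-training stages.
#' @param alpha,beta non-negative weights of the consistency (J1) and
#'   similarity-preserving (J2) losses. `alpha = 0` trains the
#'   similarity-only variant, `beta = 0` the consistency-only variant.
#' @param tau heat kernel constant of the similarity module.
#' @param quantization quantization penalty form: `"magnitude"` (default;
#'   sign-agnostic \eqn{\||h|-1\|_1}, compatible with the \eqn{\{-1,1\}^K}
#'   code space) or `"literal"` (the printed \eqn{\|h-1\|_1}).
#' @param swap_distance_branches experimental branch swap in the modified
#'   distance (see [modified_distance()]).
#' @param seed RNG seed controlling batch order (and nothing else).
#' @param preset `NULL`, `"desk"`, `"adni2"` or `"oasis3"`.
#' @return a list of class `mmhash_control`.
#' @export
mmhash_control <- function(batch_size = 20, learning_rate = 1e-3,
                           iterations = 200, pretrain_encoder_iters = 150,
                           pretrain_decoder_iters = 100, alpha = 0.3,
                           beta = 1, tau = 1,
                           quantization = c("magnitude", "literal"),
                           swap_distance_branches = FALSE, seed = 7,
                           preset = NULL) {
  quantization <- match.arg(quantization)
  ctrl <- list(batch_size = batch_size, learning_rate = learning_rate,
               iterations = iterations,
               pretrain_encoder_iters = pretrain_encoder_iters,
               pretrain_decoder_iters = pretrain_decoder_iters,
               alpha = alpha, beta = beta, tau = tau,
               quantization = quantization,
               swap_distance_branches = swap_distance_branches, seed = seed)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("desk", "adni2", "oasis3"))
    if (preset == "adni2") {
      ctrl[c("alpha", "beta", "batch_size", "iterations", "learning_rate")] <-
        list(0.3, 1, 20, 500, 1e-6)
    } else if (preset == "oasis3") {
      ctrl[c("alpha", "beta", "batch_size", "iterations", "learning_rate")] <-
        list(0.1, 1, 20, 500, 1e-6)
    }
  }
  with(ctrl, {
    if (batch_size < 1 || iterations < 0 || pretrain_encoder_iters < 0 ||
        pretrain_decoder_iters < 0) {
      stop("iteration counts must be >= 0 and batch_size >= 1", call. = FALSE)
    }
    if (learning_rate <= 0 || tau <= 0) {
      stop("learning_rate and tau must be > 0", call. = FALSE)
    }
    if (alpha < 0 || beta < 0) stop("alpha, beta must be >= 0", call. = FALSE)
  })
  class(ctrl) <- "mmhash_control"
  ctrl
}

## ---- internal: gradient engine -------------------------------------------

## Row-normalized difference with subgradient 0 at coincident rows.
unit_diff <- function(a, b) {
  d <- a - b
  n <- row_norms(d)
  nz <- n > 0
  d[nz, ] <- d[nz, , drop = FALSE] / n[nz]
  d
}

softmax_backward <- function(p, g) p * (g - rowSums(g * p))

## Forward pass with cached hidden activations, loss of the given stage, and
## parameter gradients. Stages: "encoder" (sum ||y - l||, encoder + SPAB_E),
## "decoder" (sum ||r - l|| + reg, decoder + SPAB_D), "finetune" (full
## objective, all parameters).
mm_stage_gradients <- function(model, batch, cls, control, stage) {
  p <- model$params
  M <- model$n_modalities
  L <- one_hot(cls, model$n_classes)
  A1 <- F <- H <- Y <- R <- vector("list", M)
  for (m in seq_len(M)) {
    A1[[m]] <- tanh(sweep(batch[[m]] %*% p[[sprintf("enc%d.W1", m)]], 2,
                          p[[sprintf("enc%d.b1", m)]], "+"))
    F[[m]] <- sweep(A1[[m]] %*% p[[sprintf("enc%d.W2", m)]], 2,
                    p[[sprintf("enc%d.b2", m)]], "+")
    H[[m]] <- tanh(sweep(F[[m]] %*% p[["dec.W"]], 2, p[["dec.b"]], "+"))
    Y[[m]] <- softmax_rows(sweep(F[[m]] %*% p[["spabE.W"]], 2,
                                 p[["spabE.b"]], "+"))
    R[[m]] <- softmax_rows(sweep(H[[m]] %*% p[["spabD.W"]], 2,
                                 p[["spabD.b"]], "+"))
  }

  alpha <- control$alpha; beta <- control$beta
  dY <- lapply(Y, function(x) x * 0)
  dR <- lapply(R, function(x) x * 0)
  dH <- lapply(H, function(x) x * 0)
  j1 <- j2 <- reg <- NA_real_

  if (stage == "encoder") {
    j1 <- sum(vapply(seq_len(M), function(m) sum(row_norms(Y[[m]] - L)),
                     numeric(1)))
    loss <- j1
    for (m in seq_len(M)) dY[[m]] <- unit_diff(Y[[m]], L)
  } else if (stage == "decoder") {
    j1 <- sum(vapply(seq_len(M), function(m) sum(row_norms(R[[m]] - L)),
                     numeric(1)))
    reg <- quantization_regularizer(H, form = control$quantization)
    loss <- j1 + reg
    gq <- quantization_grad(H, form = control$quantization)
    for (m in seq_len(M)) {
      dR[[m]] <- unit_diff(R[[m]], L)
      dH[[m]] <- gq[[m]]
    }
  } else {
    j1 <- semantic_consistency_loss(Y, R, cls)
    j2 <- if (beta > 0) {
      manifold_preserving_loss(H, cls, tau = control$tau,
                               swap = control$swap_distance_branches)
    } else 0
    reg <- quantization_regularizer(H, form = control$quantization)
    loss <- alpha * j1 + beta * j2 + reg
    if (alpha > 0) {
      for (m in seq_len(M)) {
        dY[[m]] <- alpha * (unit_diff(Y[[m]], L) + unit_diff(Y[[m]], R[[m]]))
        dR[[m]] <- alpha * (unit_diff(R[[m]], L) - unit_diff(Y[[m]], R[[m]]))
      }
    }
    gq <- quantization_grad(H, form = control$quantization)
    if (beta > 0) {
      gm <- manifold_preserving_grad(H, cls, tau = control$tau,
                                     swap = control$swap_distance_branches)
      for (m in seq_len(M)) dH[[m]] <- beta * gm[[m]] + gq[[m]]
    } else {
      for (m in seq_len(M)) dH[[m]] <- gq[[m]]
    }
  }

  ## backward
  g <- list()
  add <- function(name, val) {
    g[[name]] <<- if (is.null(g[[name]])) val else g[[name]] + val
  }
  for (m in seq_len(M)) {
    dF <- F[[m]] * 0
    if (stage != "encoder") {
      dZr <- softmax_backward(R[[m]], dR[[m]])
      add("spabD.W", crossprod(H[[m]], dZr))
      add("spabD.b", colSums(dZr))
      dHm <- dH[[m]] + tcrossprod(dZr, p[["spabD.W"]])
      dZd <- dHm * (1 - H[[m]]^2)
      add("dec.W", crossprod(F[[m]], dZd))
      add("dec.b", colSums(dZd))
      dF <- dF + tcrossprod(dZd, p[["dec.W"]])
    }
    if (stage != "decoder") {
      dZy <- softmax_backward(Y[[m]], dY[[m]])
      add("spabE.W", crossprod(F[[m]], dZy))
      add("spabE.b", colSums(dZy))
      dF <- dF + tcrossprod(dZy, p[["spabE.W"]])
      dA1 <- tcrossprod(dF, p[[sprintf("enc%d.W2", m)]])
      dZ1 <- dA1 * (1 - A1[[m]]^2)
      add(sprintf("enc%d.W2", m), crossprod(A1[[m]], dF))
      add(sprintf("enc%d.b2", m), colSums(dF))
      add(sprintf("enc%d.W1", m), crossprod(batch[[m]], dZ1))
      add(sprintf("enc%d.b1", m), colSums(dZ1))
    }
  }
  list(loss = loss, J1 = j1, J2 = j2, reg = reg, grads = g)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * (state$m[[nm]] %||% (g * 0)) + (1 - beta1) * g
    state$v[[nm]] <- beta2 * (state$v[[nm]] %||% (g * 0)) + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## One optimization stage over seeded batches; returns updated model + history.
run_stage <- function(model, data, control, stage, iters, iter_offset = 0) {
  if (iters == 0) {
    return(list(model = model,
                history = data.frame(iteration = integer(), stage = character(),
                                     J1 = numeric(), J2 = numeric(),
                                     reg = numeric(), total = numeric())))
  }
  n <- nrow(data$samples[[1]])
  if (n == 0) stop("dataset is empty", call. = FALSE)
  bs <- min(control$batch_size, n)
  state <- list(m = list(), v = list(), t = 0)
  hist <- vector("list", iters)
  pool <- integer(0)
  for (it in seq_len(iters)) {
    ## epoch-wise sampling without replacement; same subjects across modalities
    if (length(pool) < bs) pool <- sample.int(n)
    take <- pool[seq_len(bs)]
    pool <- pool[-seq_len(bs)]
    batch <- lapply(data$samples, function(x) x[take, , drop = FALSE])
    res <- mm_stage_gradients(model, batch, data$classes[take], control, stage)
    upd <- adam_step(model$params, res$grads, state, control$learning_rate)
    model$params <- upd$params
    state <- upd$state
    hist[[it]] <- data.frame(iteration = iter_offset + it, stage = stage,
                             J1 = res$J1, J2 = res$J2, reg = res$reg,
                             total = res$loss)
  }
  list(model = model, history = do.call(rbind, hist))
}

#' Pre-train the encoders
#'
#' Stage 1: optimizes encoder and encoder-stage attention-branch parameters
#' against the encoder classification term \eqn{\sum\|y-\ell\|}; the decoder
#' and its branch are untouched.
#'
#' @param model an [mmhash_model()].
#' @param data a paired dataset (see [generate_paired_data()]).
#' @param control an [mmhash_control()].
#' @return list with the updated `model` and the stage `history` data frame.
#' @export
pretrain_encoder <- function(model, data, control = mmhash_control()) {
  with_seed(control$seed, run_stage(model, as_paired(data), control, "encoder",
                                    control$pretrain_encoder_iters))
}

#' Pre-train the decoder
#'
#' Stage 2: optimizes decoder and decoder-stage attention-branch parameters
#' against \eqn{\sum\|r-\ell\|} plus the quantization penalty, with the
#' encoders frozen.
#'
#' @inheritParams pretrain_encoder
#' @return list with the updated `model` and the stage `history` data frame.
#' @export
pretrain_decoder <- function(model, data, control = mmhash_control()) {
  with_seed(control$seed + 1L,
            run_stage(model, as_paired(data), control, "decoder",
                      control$pretrain_decoder_iters))
}

#' Fine-tune the full model
#'
#' Stage 3: optimizes all parameters jointly against the total objective
#' \eqn{\alpha J_1 + \beta J_2 + \mathrm{reg}} with Adam.
#'
#' @inheritParams pretrain_encoder
#' @return list with the updated `model` and the stage `history` data frame.
#' @export
finetune <- function(model, data, control = mmhash_control()) {
  with_seed(control$seed + 2L,
            run_stage(model, as_paired(data), control, "finetune",
                      control$iterations))
}

#' Run the full three-stage training schedule
#'
#' Executes encoder pre-training, decoder pre-training and fine-tuning in
#' order, concatenating the per-iteration loss histories. Optionally appends
#' the history to a TSV training log.
#'
#' @inheritParams pretrain_encoder
#' @param log_file optional path; the history is written as TSV
#'   (iteration, stage, J1, J2, reg, total).
#' @return list with the trained `model` and full `history`.
#' @export
mm_train <- function(model, data, control = mmhash_control(),
                     log_file = NULL) {
  data <- as_paired(data)
  s1 <- pretrain_encoder(model, data, control)
  s2 <- pretrain_decoder(s1$model, data, control)
  s3 <- finetune(s2$model, data, control)
  hist <- rbind(s1$history, s2$history, s3$history)
  if (nrow(hist)) hist$iteration <- seq_len(nrow(hist))
  if (!is.null(log_file)) {
    utils::write.table(hist, log_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(model = s3$model, history = hist)
}
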