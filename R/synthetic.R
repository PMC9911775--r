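#' Generate a strongly paired multi-modal synthetic dataset
#'
#' Emulates the statistical structure of paired neuroimaging modalities:
#' every subject has one sample per modality, all sharing one class label
#' (strong pairing). Subjects of class c share a latent center on a
#' q-dimensional patch; each modality applies its own fixed random smooth
#' map (linear part plus a sinusoidal bend) from the latent patch into the
#' Z-dimensional input space, then adds Gaussian noise. Modalities therefore
#' live on different sub-manifolds while sharing subject latents and labels.
#' No imaging physics is simulated.
#'
#' @param n_subjects number of subjects N.
#' @param n_modalities number of modalities M.
#' @param n_classes number of classes C (subjects are balanced across
#'   classes by construction).
#' @param input_dim observed dimension Z per modality.
#' @param manifold_dim intrinsic latent dimension q (< Z).
#' @param noise_sd Gaussian observation noise standard deviation.
#' @param class_separation minimum pairwise distance between latent class
#'   centers (the difficulty knob: larger separates classes more).
#' @param within_sd within-class latent spread.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return an object of class `paired_mmdata`: list with `samples` (list of
#'   M N x Z matrices), `classes` (integer class index per subject),
#'   `onehot` (N x C), `subject_ids`, and the generating configuration.
#' @examples
#' d <- generate_paired_data(n_subjects = 30, seed = 1)
#' d
#' @export
generate_paired_data <- function(n_subjects = 150, n_modalities = 2,
                                 n_classes = 3, input_dim = 64,
                                 manifold_dim = 4, noise_sd = 0.1,
                                 class_separation = 4, within_sd = 0.5,
                                 seed = 7) {
  if (n_subjects < n_classes) stop("need at least one subject per class",
                                   call. = FALSE)
  if (manifold_dim >= input_dim) stop("manifold_dim must be < input_dim",
                                      call. = FALSE)
  if (noise_sd < 0 || class_separation <= 0) {
    stop("noise_sd must be >= 0 and class_separation > 0", call. = FALSE)
  }
  with_seed(seed, {
    N <- n_subjects; C <- n_classes; q <- manifold_dim; Z <- input_dim
    ## balanced class counts: floor(N/C) or ceiling(N/C) each
    counts <- rep(N %/% C, C) + c(rep(1L, N %% C), rep(0L, C - N %% C))
    classes <- sample(rep.int(seq_len(C), counts))
    centers <- matrix(stats::rnorm(C * q), C, q)
    if (C > 1) {
      dmin <- min(stats::dist(centers))
      centers <- centers * (class_separation / dmin)
    }
    latents <- centers[classes, , drop = FALSE] +
      matrix(stats::rnorm(N * q, sd = within_sd), N, q)
    samples <- lapply(seq_len(n_modalities), function(m) {
      A <- matrix(stats::rnorm(Z * q, sd = 1 / sqrt(q)), Z, q)
      B <- matrix(stats::rnorm(Z * q, sd = 1 / sqrt(q)), Z, q)
      W <- matrix(stats::rnorm(q * q), q, q)
      phase <- stats::runif(q, 0, 2 * pi)
      x <- tcrossprod(latents, A) +
        0.5 * tcrossprod(sin(sweep(tcrossprod(latents, W), 2, phase, "+")), B)
      x + matrix(stats::rnorm(N * Z, sd = noise_sd), N, Z)
    })
    structure(list(samples = samples, classes = classes,
                   onehot = one_hot(classes, C),
                   subject_ids = sprintf("S%04d", seq_len(N)),
                   config = list(n_subjects = N, n_modalities = n_modalities,
                                 n_classes = C, input_dim = Z,
                                 manifold_dim = q, noise_sd = noise_sd,
                                 class_separation = class_separation,
                                 within_sd = within_sd, seed = seed)),
              class = "paired_mmdata")
  })
}

#' @export
print.paired_mmdata <- function(x, ...) {
  cat(sprintf("Paired multi-modal dataset: %d subjects x %d modalities, Z = %d, %d classes\n",
              length(x$classes), length(x$samples), ncol(x$samples[[1]]),
              ncol(x$onehot)))
  cat("  class counts:", paste(tabulate(x$classes, ncol(x$onehot)),
                               collapse = " / "), "\n")
  invisible(x)
}

#' Subset a paired dataset by subjects
#'
#' Keeps strong pairing: the same subjects are taken from every modality.
#'
#' @param x a `paired_mmdata` object.
#' @param i subject indices.
#' @param ... ignored.
#' @return a `paired_mmdata` with the selected subjects.
#' @export
`[.paired_mmdata` <- function(x, i, ...) {
  structure(list(samples = lapply(x$samples, function(s) s[i, , drop = FALSE]),
                 classes = x$classes[i],
                 onehot = x$onehot[i, , drop = FALSE],
                 subject_ids = x$subject_ids[i],
                 config = x$config),
            class = "paired_mmdata")
}

## Accept a paired_mmdata or a bare list(samples, classes) and validate
## strong pairing invariants.
as_paired <- function(data) {
  if (inherits(data, "paired_mmdata")) return(data)
  if (is.list(data) && !is.null(data$samples) && !is.null(data$classes)) {
    samples <- lapply(data$samples, as.matrix)
    n <- nrow(samples[[1]])
    if (any(vapply(samples, nrow, integer(1)) != n)) {
      stop("all modalities must contain the same subjects (strong pairing)",
           call. = FALSE)
    }
    cls <- as_class_index(data$classes, n)
    return(structure(list(samples = samples, classes = cls,
                          onehot = one_hot(cls),
                          subject_ids = data$subject_ids %||%
                            sprintf("S%04d", seq_len(n)),
                          config = data$config %||% list()),
                     class = "paired_mmdata"))
  }
  stop("`data` must be a paired_mmdata or a list(samples = <list of matrices>, classes = <labels>)",
       call. = FALSE)
}

#' Subject-level stratified train/test split
#'
#' Splits a paired dataset at the subject level (a subject's modalities never
#' straddle the split), stratified by class with a seeded shuffle. The total
#' training size is `round(N * train_fraction)`; per-class allocations use
#' largest-remainder rounding so class proportions are preserved within one
#' subject.
#'
#' @param data a `paired_mmdata` (or compatible list).
#' @param train_fraction fraction of subjects assigned to training
#'   (default 0.8, the 8/2 convention).
#' @param seed RNG seed for the shuffle.
#' @return list with `train` and `test` paired datasets.
#' @export
split_paired_data <- function(data, train_fraction = 0.8, seed = 1) {
  data <- as_paired(data)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  cls <- data$classes
  if (any(tabulate(cls) > 0 & tabulate(cls) < 2)) {
    stop("every class needs >= 2 subjects to stratify the split",
         call. = FALSE)
  }
  n <- length(cls)
  target <- round(n * train_fraction)
  counts <- tabulate(cls, max(cls))
  exact <- counts * train_fraction
  base <- floor(exact)
  rem <- target - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  train_idx <- with_seed(seed, {
    unlist(lapply(seq_along(counts), function(c) {
      members <- which(cls == c)
      if (!length(members)) return(integer(0))
      sample(members)[seq_len(base[c])]
    }))
  })
  train_idx <- sort(train_idx)
  list(train = data[train_idx], test = data[setdiff(seq_len(n), train_idx)])
}
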