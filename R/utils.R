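## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

row_norms <- function(x) sqrt(rowSums(x^2))

## Row-wise x/||x|| with an explicit error on zero rows: downstream cosine and
## Laplacian computations are undefined there and must not emit silent NaNs.
normalize_rows <- function(x, what = "code") {
  n <- row_norms(x)
  if (any(n == 0)) {
    stop("degenerate input: ", what, " row(s) ",
         paste(which(n == 0), collapse = ", "),
         " have zero norm; cosine similarity is undefined", call. = FALSE)
  }
  x / n
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

is_pm1 <- function(x) all(x == 1 | x == -1)

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a single positive number", call. = FALSE)
  }
}

## Coerce labels (factor / integer / one-hot matrix) to 1-based class indices.
as_class_index <- function(labels, n = NULL) {
  if (is.matrix(labels)) {
    if (any(rowSums(labels) != 1) || !all(labels %in% c(0, 1))) {
      stop("one-hot label matrix must have exactly one 1 per row", call. = FALSE)
    }
    labels <- max.col(labels)
  }
  if (is.factor(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  if (!is.null(n) && length(labels) != n) {
    stop("labels have length ", length(labels), ", expected ", n, call. = FALSE)
  }
  if (any(is.na(labels)) || any(labels < 1L)) {
    stop("labels must be positive class indices (or a factor / one-hot matrix)",
         call. = FALSE)
  }
  labels
}

## One-hot encode 1-based class indices into an N x C 0/1 matrix.
one_hot <- function(class_index, n_classes = max(class_index)) {
  out <- matrix(0, length(class_index), n_classes)
  out[cbind(seq_along(class_index), class_index)] <- 1
  out
}

## Atomic write: write to a sibling temp file, then rename into place, so an
## interrupted run never leaves a truncated table behind.
write_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path, call. = FALSE)
  invisible(path)
}

check_code_list <- function(codes) {
  if (!is.list(codes) || length(codes) < 1L) {
    stop("`codes` must be a non-empty list of per-modality code matrices",
         call. = FALSE)
  }
  codes <- lapply(codes, as.matrix)
  dims <- vapply(codes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all modalities must share the same N and K; got N = ",
         paste(dims[1, ], collapse = "/"), ", K = ",
         paste(dims[2, ], collapse = "/"), call. = FALSE)
  }
  codes
}
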