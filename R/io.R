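#' Write hash codes to a TSV table
#'
#' Serializes binary codes as a plain-text table with header
#' `subject_id  modality  class  b1..bK` (0-based modality indices). Codes
#' from several modalities can be stacked in one table; each
#' (subject, modality) pair must be unique. Writes are atomic
#' (temp-file-then-rename).
#'
#' @param codes a binary code matrix (N x K), or a list of M matrices (one
#'   per modality, modalities numbered 0..M-1).
#' @param classes class labels of the N subjects.
#' @param subject_ids character subject identifiers.
#' @param path output file path.
#' @param modality modality index (0-based) when `codes` is a single matrix.
#' @return the path, invisibly.
#' @export
write_hash_table <- function(codes, classes, subject_ids, path,
                             modality = 0L) {
  if (!is.list(codes)) {
    codes <- stats::setNames(list(as.matrix(codes)), NULL)
    modalities <- modality
  } else {
    codes <- lapply(codes, as.matrix)
    modalities <- seq_along(codes) - 1L
  }
  K <- unique(vapply(codes, ncol, integer(1)))
  if (length(K) != 1) stop("all code matrices must share K", call. = FALSE)
  n <- unique(vapply(codes, nrow, integer(1)))
  if (length(n) != 1) stop("all code matrices must share N", call. = FALSE)
  cls <- as_class_index(classes, n)
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n) stop("need one subject_id per row",
                                     call. = FALSE)
  if (anyDuplicated(subject_ids)) {
    stop("duplicate subject_id within a modality", call. = FALSE)
  }
  for (h in codes) {
    if (n > 0 && !is_pm1(h)) {
      stop("codes must be binary (-1/+1); binarize before writing",
           call. = FALSE)
    }
  }
  header <- paste(c("subject_id", "modality", "class",
                    paste0("b", seq_len(K))), collapse = "\t")
  rows <- unlist(lapply(seq_along(codes), function(j) {
    h <- codes[[j]]
    if (!nrow(h)) return(character(0))
    apply(cbind(subject_ids, modalities[j], cls, h), 1, paste,
          collapse = "\t")
  }))
  write_atomic(c(header, rows), path)
  invisible(path)
}

#' Read a hash-code TSV table
#'
#' Validates the header, the fixed arity and the -1/+1 bit values; malformed
#' rows are reported with their line number.
#'
#' @param path a file written by [write_hash_table()].
#' @return list with `codes` (N_rows x K integer matrix), `modality`,
#'   `classes` and `subject_ids` vectors (one entry per row).
#' @export
read_hash_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 4 || !identical(header[1:3],
                                       c("subject_id", "modality", "class")) ||
      !all(grepl("^b[0-9]+$", header[-(1:3)]))) {
    stop("malformed header in ", path,
         "; expected subject_id\\tmodality\\tclass\\tb1..bK", call. = FALSE)
  }
  K <- length(header) - 3L
  body <- lines[-1]
  n <- length(body)
  codes <- matrix(NA_integer_, n, K)
  modality <- integer(n); classes <- integer(n); ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != K + 3L) {
      stop("line ", i + 1L, ": expected ", K + 3L, " fields, found ",
           length(f), call. = FALSE)
    }
    ids[i] <- f[1]
    modality[i] <- as.integer(f[2])
    classes[i] <- as.integer(f[3])
    bits <- suppressWarnings(as.integer(f[-(1:3)]))
    if (any(is.na(bits)) || !all(bits %in% c(-1L, 1L))) {
      stop("line ", i + 1L, ": hash bits must be -1 or +1", call. = FALSE)
    }
    codes[i, ] <- bits
  }
  if (anyDuplicated(paste(ids, modality))) {
    stop("duplicate (subject_id, modality) pair in ", path, call. = FALSE)
  }
  list(codes = codes, modality = modality, classes = classes,
       subject_ids = ids)
}

#' Extract a 2-D slice from a NIfTI volume
#'
#' Reads a 3-D volume, takes one slice along the chosen axis (by default the
#' middle slice, 0-based index `floor((depth - 1)/2)`), min-max normalizes
#' intensities to `[0, 1]` and optionally resizes to a target shape by
#' bilinear interpolation. Requires the RNifti package.
#'
#' @param volume_path path to a readable NIfTI file.
#' @param axis slice axis (1, 2 or 3).
#' @param index 0-based slice index, or `"middle"`.
#' @param target_shape optional `c(rows, cols)` output shape.
#' @return the slice matrix with attribute `"metadata"` recording source,
#'   axis and index.
#' @export
extract_slice <- function(volume_path, axis = 3, index = "middle",
                          target_shape = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("extract_slice needs the RNifti package", call. = FALSE)
  }
  vol <- tryCatch(as.array(RNifti::readNifti(volume_path)),
                  error = function(e) stop("could not read NIfTI volume ",
                                           volume_path, ": ",
                                           conditionMessage(e),
                                           call. = FALSE))
  if (length(dim(vol)) < 3) stop("expected a 3-D volume", call. = FALSE)
  if (length(dim(vol)) > 3) vol <- array(vol, dim(vol)[1:3])
  depth <- dim(vol)[axis]
  idx0 <- if (identical(index, "middle")) (depth - 1L) %/% 2L else {
    as.integer(index)
  }
  if (idx0 < 0 || idx0 >= depth) {
    stop("slice index ", idx0, " out of range [0, ", depth - 1L, "]",
         call. = FALSE)
  }
  sl <- switch(axis,
               vol[idx0 + 1L, , ],
               vol[, idx0 + 1L, ],
               vol[, , idx0 + 1L])
  rng <- range(sl)
  sl <- if (rng[2] > rng[1]) (sl - rng[1]) / (rng[2] - rng[1]) else sl * 0
  if (!is.null(target_shape)) sl <- resize_bilinear(sl, target_shape)
  structure(sl, metadata = list(source = volume_path, axis = axis,
                                index = idx0))
}

## Plain bilinear resampling of a matrix onto a new grid.
resize_bilinear <- function(x, shape) {
  nr <- shape[1]; nc <- shape[2]
  if (nr == nrow(x) && nc == ncol(x)) return(x)
  ri <- if (nr == 1) 1 else seq(1, nrow(x), length.out = nr)
  ci <- if (nc == 1) 1 else seq(1, ncol(x), length.out = nc)
  r0 <- pmin(floor(ri), nrow(x) - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(ci), ncol(x) - 1L); c0 <- pmax(c0, 1L)
  fr <- ri - r0; fc <- ci - c0
  if (nrow(x) == 1) { r0 <- rep(1L, nr); fr <- rep(0, nr) }
  if (ncol(x) == 1) { c0 <- rep(1L, nc); fc <- rep(0, nc) }
  top <- x[r0, c0, drop = FALSE] * (1 - fc)[col(matrix(0, nr, nc))] +
    x[r0, pmin(c0 + 1L, ncol(x)), drop = FALSE] * fc[col(matrix(0, nr, nc))]
  bot <- x[pmin(r0 + 1L, nrow(x)), c0, drop = FALSE] *
    (1 - fc)[col(matrix(0, nr, nc))] +
    x[pmin(r0 + 1L, nrow(x)), pmin(c0 + 1L, ncol(x)), drop = FALSE] *
    fc[col(matrix(0, nr, nc))]
  top * (1 - fr)[row(matrix(0, nr, nc))] + bot * fr[row(matrix(0, nr, nc))]
}

#' Write a paired dataset as TSV files
#'
#' One file per modality (`modality<m>.tsv`, 0-based), each row
#' `subject_id  class  z1..zZ`, the input format of the command-line
#' training tool.
#'
#' @param data a `paired_mmdata`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_paired_tsv <- function(data, dir) {
  data <- as_paired(data)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Z <- ncol(data$samples[[1]])
  header <- paste(c("subject_id", "class", paste0("z", seq_len(Z))),
                  collapse = "\t")
  for (m in seq_along(data$samples)) {
    rows <- apply(cbind(data$subject_ids, data$classes,
                        format(data$samples[[m]], digits = 10,
                               scientific = TRUE, trim = TRUE)),
                  1, paste, collapse = "\t")
    write_atomic(c(header, rows),
                 file.path(dir, sprintf("modality%d.tsv", m - 1L)))
  }
  invisible(dir)
}

#' Read a paired dataset from TSV files
#'
#' Inverse of [write_paired_tsv()]: reads every `modality*.tsv` in a
#' directory and checks strong pairing (same subjects and labels in every
#' file, same order).
#'
#' @param dir directory containing `modality<m>.tsv` files.
#' @return a `paired_mmdata`.
#' @export
read_paired_tsv <- function(dir) {
  files <- sort(list.files(dir, pattern = "^modality[0-9]+\\.tsv$",
                           full.names = TRUE))
  if (!length(files)) stop("no modality*.tsv files in ", dir, call. = FALSE)
  tabs <- lapply(files, utils::read.delim, check.names = FALSE)
  ids <- tabs[[1]]$subject_id
  cls <- tabs[[1]]$class
  for (t in tabs[-1]) {
    if (!identical(t$subject_id, ids) || !identical(t$class, cls)) {
      stop("modality files disagree on subjects/labels (strong pairing ",
           "violated)", call. = FALSE)
    }
  }
  samples <- lapply(tabs, function(t) {
    as.matrix(t[, grep("^z[0-9]+$", names(t)), drop = FALSE])
  })
  as_paired(list(samples = samples, classes = cls, subject_ids = ids))
}
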