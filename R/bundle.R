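#' Construct a validated probability matrix
#'
#' A probability matrix holds one classifier's predicted class probabilities:
#' one row per sample, one column per class, rows summing to 1. This is the
#' shape of a softmax output layer serialized to text.
#'
#' @param values numeric N x C matrix of non-negative entries.
#' @param class_names character vector of C class names; defaults to the
#'   column names of `values`.
#' @param sample_ids character vector of N sample identifiers; defaults to the
#'   row names of `values`, or `"s1" ... "sN"`.
#' @param renormalize if `TRUE`, each row is divided by its sum before
#'   validation (useful for softmax outputs serialized at low precision).
#' @return an object of class `"probability_matrix"`: the numeric matrix with
#'   `dimnames` set to `list(sample_ids, class_names)`.
#' @export
probability_matrix <- function(values, class_names = colnames(values),
                               sample_ids = rownames(values),
                               renormalize = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("probability matrix entries must be numeric")
  n <- nrow(values); c <- ncol(values)
  if (n < 1L) stop("probability matrix needs at least one row")
  if (c < 2L) stop("probability matrix needs at least two classes")
  if (is.null(class_names)) class_names <- paste0("class", seq_len(c) - 1L)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  class_names <- as.character(class_names)
  sample_ids <- as.character(sample_ids)
  if (length(class_names) != c) stop("class_names length must equal ncol(values)")
  if (length(sample_ids) != n) stop("sample_ids length must equal nrow(values)")
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (anyNA(values)) stop("probability matrix contains missing values")
  if (any(values < 0)) stop("negative probability entries")
  rs <- rowSums(values)
  if (renormalize) {
    if (any(rs == 0)) stop("cannot renormalize a row with sum 0")
    values <- values / rs
  } else {
    # ingest tolerance 1e-3: serialized softmax rows rarely sum to 1 exactly
    bad <- which(abs(rs - 1) > 1e-3)
    if (length(bad)) {
      stop(sprintf("row %d sums to %.6f, outside [1-1e-3, 1+1e-3]; use renormalize = TRUE",
                   bad[1L], rs[bad[1L]]))
    }
    values <- values / rs  # enforce exact row-stochasticity internally
  }
  if (any(values > 1)) stop("probability entries above 1")
  dimnames(values) <- list(sample_ids, class_names)
  structure(values, class = c("probability_matrix", "matrix", "array"))
}

#' Read a probability matrix from CSV
#'
#' File dialect: comma-delimited with a mandatory header row; first column
#' `sample_id`, remaining columns one per class, named by the class.
#'
#' @param path path to the CSV file.
#' @inheritParams probability_matrix
#' @return a `probability_matrix`.
#' @export
read_probability_matrix <- function(path, renormalize = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expected a sample_id column plus >= 2 class columns in ", path)
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      stop(sprintf("non-numeric cell in column '%s' of %s", names(vals)[j], path))
    }
  }
  probability_matrix(as.matrix(vals), class_names = names(vals),
                     sample_ids = ids, renormalize = renormalize)
}

#' Write a probability matrix to CSV
#'
#' Inverse of [read_probability_matrix()]; values are written at full double
#' precision so a read/write round-trip is lossless to ~1e-16 relative error.
#'
#' @param m a `probability_matrix`.
#' @param path output path.
#' @export
write_probability_matrix <- function(m, path) {
  stopifnot(inherits(m, "probability_matrix"))
  df <- data.frame(sample_id = rownames(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- format(m[, j], digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read ground-truth (or predicted) labels
#'
#' Accepts either the two-column `sample_id,label` dialect (preferred, header
#' required) or a bare one-integer-per-line file, in which case ids are taken
#' to be implicit row numbers `s1 ... sN`.
#'
#' @param path path to the labels file.
#' @param n_classes number of classes C; if `NULL`, inferred as
#'   `max(label) + 1`.
#' @return a list with components `labels` (integer vector, values in
#'   `[0, C)`), `sample_ids` (character) and `n_classes`.
#' @export
read_labels <- function(path, n_classes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("sample_id", first, fixed = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    labels <- df[[2L]]
  } else {
    labels <- utils::read.csv(path, header = FALSE)[[1L]]
    ids <- paste0("s", seq_along(labels))
  }
  if (!is.numeric(labels) || any(labels != floor(labels))) {
    stop("labels must be integers")
  }
  labels <- as.integer(labels)
  if (any(labels < 0)) stop("negative label")
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  if (any(labels >= n_classes)) stop("label out of range [0, C)")
  list(labels = labels, sample_ids = ids, n_classes = as.integer(n_classes))
}

#' Bundle aligned per-model probability matrices with ground truth
#'
#' A model bundle is the unit the fusion and optimizer functions operate on:
#' K probability matrices over identical samples and classes, plus the true
#' labels. Matrices are re-ordered by sample id to the order of `sample_ids`
#' (or of the first matrix); class columns must already agree — column
#' misalignment is treated as an error, never silently fixed.
#'
#' @param matrices named list of K `probability_matrix` objects (K >= 2).
#' @param labels integer vector of true class indices in `[0, C)`, aligned to
#'   `sample_ids`.
#' @param sample_ids optional character vector giving the target row order;
#'   defaults to the row order of the first matrix.
#' @return an object of class `"model_bundle"`: list with `matrices`,
#'   `labels`, `class_names`, `sample_ids`, `n_models`, `n_samples`,
#'   `n_classes`.
#' @export
model_bundle <- function(matrices, labels, sample_ids = NULL) {
  if (!is.list(matrices) || length(matrices) < 2L) {
    stop("a model bundle needs at least 2 probability matrices")
  }
  if (is.null(names(matrices)) || any(names(matrices) == "")) {
    names(matrices) <- paste0("model_", seq_along(matrices))
  }
  for (m in matrices) {
    if (!inherits(m, "probability_matrix")) stop("all matrices must be probability_matrix objects")
  }
  cls <- colnames(matrices[[1L]])
  if (is.null(sample_ids)) sample_ids <- rownames(matrices[[1L]])
  sample_ids <- as.character(sample_ids)
  nms <- names(matrices)
  matrices <- lapply(nms, function(nm) {
    m <- matrices[[nm]]
    if (!identical(colnames(m), cls)) {
      stop("class names of '", nm, "' differ from the first model's (no silent column reordering)")
    }
    missing_ids <- setdiff(sample_ids, rownames(m))
    if (length(missing_ids)) {
      stop("sample id '", missing_ids[1L], "' absent from model '", nm, "'")
    }
    if (nrow(m) != length(sample_ids)) stop("model '", nm, "' has extra sample ids")
    m <- m[sample_ids, , drop = FALSE]  # `[` drops the S3 class; restore it
    structure(m, class = c("probability_matrix", "matrix", "array"))
  })
  names(matrices) <- nms
  labels <- as.integer(labels)
  n <- length(sample_ids); c <- length(cls)
  if (length(labels) != n) stop("labels length does not match sample count")
  if (any(labels < 0 | labels >= c)) stop("label out of range [0, C)")
  out <- list(matrices = matrices, labels = labels, class_names = cls,
              sample_ids = sample_ids, n_models = length(matrices),
              n_samples = n, n_classes = c)
  class(out) <- "model_bundle"
  out
}

#' Read and assemble a model bundle from files
#'
#' @param matrix_paths character vector of >= 2 probability-matrix CSV paths.
#' @param labels_path path to the labels file (see [read_labels()]).
#' @param renormalize passed to [read_probability_matrix()].
#' @param model_names optional names for the models; defaults to the file
#'   base names without extension.
#' @return a `model_bundle` with rows aligned to the labels file's order.
#' @export
read_bundle <- function(matrix_paths, labels_path, renormalize = FALSE,
                        model_names = NULL) {
  if (length(matrix_paths) < 2L) stop("need at least 2 matrix paths for fusion")
  if (is.null(model_names)) {
    model_names <- sub("\\.[^.]*$", "", basename(matrix_paths))
  }
  mats <- lapply(matrix_paths, read_probability_matrix, renormalize = renormalize)
  names(mats) <- model_names
  lab <- read_labels(labels_path, n_classes = ncol(mats[[1L]]))
  model_bundle(mats, labels = lab$labels, sample_ids = lab$sample_ids)
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("Model bundle: %d models, %d samples, %d classes\n",
              x$n_models, x$n_samples, x$n_classes))
  nms <- names(x$matrices)
  if (is.null(nms)) nms <- paste0("model_", seq_len(x$n_models))
  for (k in seq_len(x$n_models)) {
    acc <- mean(predict_classes(x$matrices[[k]]) == x$labels)
    cat(sprintf("  %-12s standalone accuracy %.4f\n", nms[k], acc))
  }
  invisible(x)
}

#' Write labels in the `sample_id,label` dialect
#' @param labels integer vector of class indices.
#' @param path output path.
#' @param sample_ids optional ids; default `s1..sN`.
#' @export
write_labels <- function(labels, path, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(labels))
  utils::write.csv(data.frame(sample_id = sample_ids, label = as.integer(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write fusion weights as `model_name,weight` lines
#' @param weights numeric simplex weight vector, optionally named.
#' @param path output path.
#' @export
write_weights <- function(weights, path) {
  if (length(weights) == 0L) stop("empty weight vector")
  validate_weights(weights, k = length(weights))
  nms <- names(weights)
  if (is.null(nms)) nms <- paste0("model_", seq_along(weights))
  writeLines(paste(nms, format(weights, digits = 17, trim = TRUE), sep = ","), path)
  invisible(path)
}

#' Read fusion weights written by [write_weights()]
#' @param path path to the weights CSV.
#' @return named numeric weight vector on the simplex.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  w <- as.numeric(df[[2L]])
  names(w) <- as.character(df[[1L]])
  validate_weights(w, k = length(w))
  w
}
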