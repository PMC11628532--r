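# Small in-code fixtures shared across test files.

# probability_matrix from a plain numeric matrix given as rows
pm <- function(..., class_names = NULL, sample_ids = NULL) {
  m <- rbind(...)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(ncol(m)) - 1L)
  probability_matrix(m, class_names = class_names, sample_ids = sample_ids)
}

# two-model bundle from two row-lists and labels
tiny_bundle <- function(m1, m2, labels) {
  model_bundle(list(model_1 = m1, model_2 = m2), labels = labels)
}

# write a probability matrix CSV by hand (independent of write_probability_matrix)
write_pm_csv <- function(rows, path, ids = NULL, classes = NULL) {
  C <- length(rows[[1L]])
  if (is.null(classes)) classes <- paste0("class", seq_len(C) - 1L)
  if (is.null(ids)) ids <- paste0("s", seq_along(rows))
  lines <- c(paste(c("sample_id", classes), collapse = ","),
             vapply(seq_along(rows), function(i)
               paste(c(ids[i], format(rows[[i]], digits = 17, trim = TRUE)),
                     collapse = ","), ""))
  writeLines(lines, path)
  path
}

# one-hot probability matrix on given labels (rows exactly on the vertices)
one_hot <- function(labels, C) {
  m <- matrix(0, length(labels), C)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  probability_matrix(m, class_names = paste0("class", 0:(C - 1L)))
}
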