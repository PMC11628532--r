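#' Validate a fusion weight vector
#'
#' Fusion weights live on the probability simplex: each in `[0, 1]`, summing
#' to 1 within 1e-9. Weights are validated, never silently renormalized —
#' producing simplex weights is the optimizer's job, and fusion should fail
#' loudly on anything else.
#'
#' @param weights numeric vector of candidate weights.
#' @param k expected number of models.
#' @param tol simplex tolerance on the sum.
#' @return the weights, invisibly, if valid; otherwise an error.
#' @export
validate_weights <- function(weights, k, tol = 1e-9) {
  if (!is.numeric(weights)) stop("weights must be numeric")
  if (length(weights) != k) stop(sprintf("expected %d weights, got %d", k, length(weights)))
  if (anyNA(weights)) stop("missing weight")
  if (any(weights < 0) || any(weights > 1)) stop("weights must lie in [0, 1]")
  if (abs(sum(weights) - 1) > tol) {
    stop(sprintf("weights sum to %.12f, off the simplex beyond tolerance %g", sum(weights), tol))
  }
  invisible(weights)
}

#' Weighted average fusion of classifier probabilities
#'
#' Computes the entrywise convex combination `sum_k w_k * P_k` of the K
#' per-model probability matrices. Because the weights are on the simplex and
#' each matrix is row-stochastic, the fused matrix is row-stochastic too.
#'
#' @param bundle a [model_bundle()].
#' @param weights numeric simplex weight vector of length `bundle$n_models`.
#'   If named, names must match the bundle's model names in order.
#' @return fused `probability_matrix`.
#' @export
fuse_weighted <- function(bundle, weights) {
  stopifnot(inherits(bundle, "model_bundle"))
  validate_weights(weights, k = bundle$n_models)
  nms <- names(bundle$matrices)
  if (!is.null(names(weights)) && !is.null(nms) &&
      !identical(names(weights), nms)) {
    stop("weight names do not match the bundle's model names/order")
  }
  fused <- weights[1L] * unclass(bundle$matrices[[1L]])
  for (k in seq_len(bundle$n_models)[-1L]) {
    fused <- fused + weights[k] * unclass(bundle$matrices[[k]])
  }
  structure(fused, class = c("probability_matrix", "matrix", "array"))
}

#' Simple (equal-weight) average fusion
#'
#' Entrywise mean of the K matrices: identical to [fuse_weighted()] with all
#' weights `1/K`.
#'
#' @inheritParams fuse_weighted
#' @return fused `probability_matrix`.
#' @export
fuse_average <- function(bundle) {
  stopifnot(inherits(bundle, "model_bundle"))
  fuse_weighted(bundle, rep(1 / bundle$n_models, bundle$n_models))
}

#' Hard class predictions from a probability matrix
#'
#' Per-row argmax, with ties broken deterministically toward the lowest class
#' index.
#'
#' @param m a `probability_matrix` (or plain numeric matrix).
#' @return integer vector of 0-based class indices.
#' @export
predict_classes <- function(m) {
  m <- unclass(as.matrix(m))
  max.col(m, ties.method = "first") - 1L
}
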