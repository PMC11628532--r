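#' Compare fusion weight settings on one bundle
#'
#' Evaluates a list of weighting schemes — the string `"equal"` (simple
#' average), the string `"ga"` (weights selected by [ga_fuse()]), or an
#' explicit numeric simplex weight vector — on the same bundle, and tabulates
#' accuracy, support-weighted precision/recall/F1 and top-k accuracy for
#' each. This is the benchmarking table one builds when deciding whether
#' optimized weights beat fixed or equal ones.
#'
#' @param bundle a [model_bundle()].
#' @param settings non-empty list of settings as above.
#' @param config [ga_config()] used for any `"ga"` entries.
#' @param seed seed for any `"ga"` entries.
#' @param topk k for the top-k column (default 3).
#' @return data frame with one row per setting: `setting`, one `w_*` column
#'   per model, `accuracy`, `precision`, `recall`, `f1`,
#'   `top_<k>_accuracy`.
#' @export
compare_weightings <- function(bundle, settings, config = ga_config(),
                               seed = NULL, topk = 3L) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (!is.list(settings) || length(settings) == 0L) stop("empty settings list")
  k <- bundle$n_models
  topk <- min(as.integer(topk), bundle$n_classes)
  rows <- lapply(seq_along(settings), function(i) {
    s <- settings[[i]]
    if (is.character(s) && length(s) == 1L && s == "equal") {
      w <- rep(1 / k, k); label <- "equal"
    } else if (is.character(s) && length(s) == 1L && s == "ga") {
      fit <- ga_fuse(bundle, config, seed = seed)
      w <- unname(coef(fit)); label <- "ga"
    } else if (is.numeric(s)) {
      validate_weights(s, k = k)
      w <- as.numeric(s)
      # "/"-separated so the label stays a single field in unquoted CSV output
      label <- paste0("(", paste(format(w, digits = 4, trim = TRUE), collapse = "/"), ")")
    } else {
      stop("setting must be \"equal\", \"ga\", or a numeric weight vector")
    }
    fused <- fuse_weighted(bundle, w)
    rep_ <- evaluate_predictions(fused, bundle$labels, ks = c(1L, topk), warn = FALSE)
    out <- data.frame(setting = label, stringsAsFactors = FALSE)
    for (j in seq_len(k)) out[[paste0("w_", j)]] <- w[j]
    out$accuracy <- rep_$accuracy
    out$precision <- rep_$aggregated["weighted", "precision"]
    out$recall <- rep_$aggregated["weighted", "recall"]
    out$f1 <- rep_$aggregated["weighted", "f1"]
    out[[paste0("top_", topk, "_accuracy")]] <- rep_$top_k[[paste0("top_", topk)]]
    out
  })
  do.call(rbind, rows)
}
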