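#' Simulation scenario for synthetic classifier outputs
#'
#' Describes a population of N samples over C classes and K imperfect
#' classifiers whose softmax-like outputs are emitted as Dirichlet rows:
#' concentration `sharpness` (kappa) on the class the model "intends" to
#' predict and 1 elsewhere, so for large kappa the row's argmax is the
#' intended class with high probability. Each model intends the true class
#' with its configured accuracy; a wrong intended class is drawn from
#' `confusion_bias`. `error_correlation` (rho) couples the models'
#' correct/incorrect events through a shared latent uniform: with
#' probability rho the same uniform is thresholded by every model's
#' accuracy (errors co-occur as much as the marginals allow), otherwise
#' each model draws independently.
#'
#' @param n_samples number of samples N.
#' @param n_classes number of classes C (default 44, a realistic many-class
#'   medical-imaging setting; tests use small C for speed).
#' @param class_priors length-C simplex of class frequencies (default
#'   uniform).
#' @param model_accuracies length-K vector of intended-class accuracies in
#'   `(0, 1]`. An informative model lies strictly between 1/C and 1; the
#'   endpoints model a chance-level classifier (1/C) and a perfect one (1).
#' @param sharpness Dirichlet concentration kappa > 0 on the intended class.
#' @param error_correlation rho in `[0, 1]`.
#' @param confusion_bias how a wrong intended class is drawn given the true
#'   class: `NULL` (uniform over the C-1 wrong classes), a single C x C
#'   row-stochastic matrix shared by all models, or a list of K such
#'   matrices. Diagonal entries must be 0.
#' @param seed integer seed used by [simulate_bundle()].
#' @return a list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_samples, n_classes = 44L,
                            class_priors = NULL,
                            model_accuracies = c(0.8, 0.8),
                            sharpness = 50, error_correlation = 0,
                            confusion_bias = NULL, seed = NULL) {
  n_samples <- as.integer(n_samples); n_classes <- as.integer(n_classes)
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (is.null(class_priors)) class_priors <- rep(1 / n_classes, n_classes)
  if (length(class_priors) != n_classes || any(class_priors < 0) ||
      abs(sum(class_priors) - 1) > 1e-9) {
    stop("class_priors must be a length-C simplex")
  }
  if (any(model_accuracies <= 0) || any(model_accuracies > 1)) {
    stop("model_accuracies must lie in (0, 1]")
  }
  if (sharpness <= 0) stop("sharpness must be positive")
  if (error_correlation < 0 || error_correlation > 1) stop("error_correlation must be in [0, 1]")
  k <- length(model_accuracies)
  check_bias <- function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == n_classes)) stop("confusion_bias must be C x C")
    if (any(m < 0)) stop("confusion_bias entries must be non-negative")
    if (any(abs(diag(m)) > 0)) stop("confusion_bias diagonal must be 0")
    if (any(abs(rowSums(m) - 1) > 1e-9)) stop("confusion_bias rows must sum to 1")
    m
  }
  if (!is.null(confusion_bias)) {
    confusion_bias <- if (is.list(confusion_bias)) {
      if (length(confusion_bias) != k) stop("need one confusion_bias per model")
      lapply(confusion_bias, check_bias)
    } else {
      rep(list(check_bias(confusion_bias)), k)
    }
  }
  structure(list(n_samples = n_samples, n_classes = n_classes,
                 class_priors = class_priors,
                 model_accuracies = model_accuracies, sharpness = sharpness,
                 error_correlation = error_correlation,
                 confusion_bias = confusion_bias, seed = seed),
            class = "scenario_config")
}

#' Simulate a bundle of correlated imperfect classifier outputs
#'
#' For each sample a true label is drawn from the class priors. For each
#' model a correct/incorrect event fires with the model's accuracy — with
#' probability rho the event is driven by a uniform shared across models,
#' otherwise by an independent one. The intended class is the true label on
#' a correct event, else a wrong class drawn from the model's confusion
#' bias (uniform over wrong classes by default). The emitted probability row
#' is a Dirichlet draw with concentration kappa on the intended class and 1
#' on every other class. Fully reproducible given the seed.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed; overrides `config$seed` when given.
#' @return a [model_bundle()] with models named `model_1 ... model_K`.
#' @export
simulate_bundle <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- config$n_samples; C <- config$n_classes
  k <- length(config$model_accuracies)
  y <- sample.int(C, n, replace = TRUE, prob = config$class_priors) - 1L
  shared_u <- stats::runif(n)
  use_shared <- stats::runif(n) < config$error_correlation
  ids <- paste0("s", seq_len(n))
  mats <- vector("list", k)
  for (m in seq_len(k)) {
    acc <- config$model_accuracies[m]
    own_u <- stats::runif(n)
    u <- ifelse(use_shared, shared_u, own_u)
    correct <- u < acc
    intended <- y
    wrong_idx <- which(!correct)
    if (length(wrong_idx)) {
      bias <- if (!is.null(config$confusion_bias)) config$confusion_bias[[m]] else NULL
      intended[wrong_idx] <- vapply(wrong_idx, function(i) {
        if (is.null(bias)) {
          wrongs <- (0:(C - 1L))[-(y[i] + 1L)]
          wrongs[sample.int(length(wrongs), 1L)]
        } else {
          sample.int(C, 1L, prob = bias[y[i] + 1L, ]) - 1L
        }
      }, integer(1L))
    }
    # Dirichlet(kappa on intended, 1 elsewhere) via gamma draws
    g <- matrix(stats::rgamma(n * C, shape = 1), nrow = n)
    g[cbind(seq_len(n), intended + 1L)] <- stats::rgamma(n, shape = config$sharpness)
    vals <- g / rowSums(g)
    mats[[m]] <- probability_matrix(vals,
                                    class_names = paste0("class", 0:(C - 1L)),
                                    sample_ids = ids)
  }
  names(mats) <- paste0("model_", seq_len(k))
  model_bundle(mats, labels = y, sample_ids = ids)
}

#' Canonical complementary-error scenario
#'
#' Two models of equal marginal accuracy 0.80 over N = 500 samples and
#' C = 5 classes, with independent errors (rho = 0) routed to disjoint
#' wrong-class pairs: model 1 confuses class c with c+1 or c+2 (mod 5),
#' model 2 with c+3 or c+4 (mod 5). Sharpness kappa = 50 keeps rows soft
#' enough that fusion arithmetic matters. Because the two models err on
#' (mostly) different samples, an interior fusion weight can beat either
#' model alone — the regime where weight optimization is informative.
#'
#' @param seed integer seed stored in the config.
#' @return a [scenario_config()].
#' @export
scenario_s1 <- function(seed = NULL) {
  C <- 5L
  shift_bias <- function(shifts) {
    b <- matrix(0, C, C)
    for (cl in 0:(C - 1L)) {
      for (s in shifts) b[cl + 1L, ((cl + s) %% C) + 1L] <- 1 / length(shifts)
    }
    b
  }
  scenario_config(n_samples = 500L, n_classes = C,
                  model_accuracies = c(0.80, 0.80),
                  sharpness = 50, error_correlation = 0,
                  confusion_bias = list(shift_bias(c(1L, 2L)),
                                        shift_bias(c(3L, 4L))),
                  seed = seed)
}

#' Write a simulated bundle to CSV files
#'
#' Writes `model_1.csv ... model_K.csv` and `labels.csv` in the package's
#' CSV dialect into `outdir`.
#'
#' @param bundle a [model_bundle()].
#' @param outdir output directory (created if missing).
#' @return character vector of the files written, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  nms <- names(bundle$matrices)
  if (is.null(nms)) nms <- paste0("model_", seq_len(bundle$n_models))
  paths <- character(0)
  for (k in seq_len(bundle$n_models)) {
    p <- file.path(outdir, paste0(nms[k], ".csv"))
    write_probability_matrix(bundle$matrices[[k]], p)
    paths <- c(paths, p)
  }
  lp <- file.path(outdir, "labels.csv")
  write_labels(bundle$labels, lp, sample_ids = bundle$sample_ids)
  invisible(c(paths, lp))
}
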