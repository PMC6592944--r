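# Classifier configuration, stratified cross-validation and method
# comparison on shared splits.

#' Classifier configuration
#'
#' @param kind `"nn"` (multilayer perceptron, 50-50-100 ReLU hidden layers
#'   with a sigmoid output by default) or `"svm"` (RBF kernel, scores taken
#'   from the decision function).
#' @param nn_hidden Hidden layer sizes for the network.
#' @param l2_lambda L2 regularization strength for the network.
#' @param epochs,learning_rate,batch_size Network training schedule (minibatch
#'   Adam).
#' @param class_weighting Weight both classifiers' losses by inverse class
#'   frequency (default `TRUE`): the SVM via `class.weights`, the network by
#'   per-observation weights on the cross-entropy loss.
#' @param svm_cost SVM cost parameter.
#' @param standardize Center/scale features before fitting (training
#'   statistics reused at prediction). Positional features already bounded in
#'   `[-1, 1]` can be used raw (`FALSE`) so cross-column magnitude
#'   comparisons are preserved.
#' @param threshold Score threshold for the F1 decision; defaults to 0.5 on
#'   the probability scale for the network and 0 for SVM decision values.
#' @param seed Integer seed for model fitting.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(kind = c("nn", "svm"),
                              nn_hidden = c(50L, 50L, 100L),
                              l2_lambda = 1e-3, epochs = 300L,
                              learning_rate = 0.01, batch_size = 32L,
                              class_weighting = TRUE, svm_cost = 1,
                              standardize = TRUE, threshold = NULL,
                              seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(threshold)) threshold <- if (kind == "nn") 0.5 else 0
  structure(list(kind = kind, nn_hidden = as.integer(nn_hidden),
                 l2_lambda = l2_lambda, epochs = .check_count(epochs,
                                                              "epochs", 1L),
                 learning_rate = learning_rate, batch_size = batch_size,
                 class_weighting = isTRUE(class_weighting),
                 svm_cost = svm_cost, standardize = isTRUE(standardize),
                 threshold = threshold,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Fit a configured classifier
#'
#' Features are standardized internally (training means and standard
#' deviations are stored and reused at prediction time); constant columns
#' are left unscaled.
#'
#' @param x Feature matrix.
#' @param y Binary labels (0/1).
#' @param config A [classifier_config()].
#' @return Object of class `rwov_classifier`.
#' @export
fit_classifier <- function(x, y, config = classifier_config()) {
  x <- as.matrix(x)
  y <- .binary_labels(y)
  if (config$standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(x))
    scl <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, `/`)
  if (config$kind == "nn") {
    w <- if (config$class_weighting) {
      tb <- table(factor(y, levels = c(0L, 1L)))
      (length(y) / (2 * as.numeric(tb)))[y + 1L]
    } else NULL
    model <- mlp_train(xs, y, hidden = config$nn_hidden,
                       l2 = config$l2_lambda, lr = config$learning_rate,
                       epochs = config$epochs, batch_size = config$batch_size,
                       weights = w, seed = config$seed)
  } else {
    yf <- factor(y, levels = c(0L, 1L))
    cw <- if (config$class_weighting) {
      tb <- table(yf)
      stats::setNames(length(y) / (2 * as.numeric(tb)), names(tb))
    } else NULL
    model <- with_seed(config$seed, {
      e1071::svm(xs, yf, kernel = "radial", cost = config$svm_cost,
                 class.weights = cw, scale = FALSE)
    })
  }
  structure(list(model = model, config = config, center = ctr, scale = scl),
            class = "rwov_classifier")
}

#' Score new observations with a fitted classifier
#'
#' Returns class-1 probabilities for the network and oriented decision
#' values (positive = class 1) for the SVM.
#'
#' @param object An `rwov_classifier` from [fit_classifier()].
#' @param x Feature matrix.
#' @return Numeric score vector.
#' @export
predict_scores <- function(object, x) {
  stopifnot(inherits(object, "rwov_classifier"))
  xs <- sweep(sweep(as.matrix(x), 2L, object$center), 2L, object$scale, `/`)
  if (object$config$kind == "nn") return(mlp_predict(object$model, xs))
  pr <- stats::predict(object$model, xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # colname "A/B" means dv > 0 favors class A
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  if (first == "1") as.numeric(dv) else -as.numeric(dv)
}

#' Stratified fold assignment
#'
#' Observations of each class are shuffled and distributed so that fold
#' sizes differ by at most one and class proportions are preserved to within
#' one observation per fold. Two methods evaluated with the same labels and
#' seed receive identical splits, which is what makes paired AUC comparisons
#' valid.
#'
#' @param labels Binary labels; every class must have at least `n_folds`
#'   members.
#' @param n_folds Number of folds (default 3).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
make_folds <- function(labels, n_folds = 3L, seed = 1L) {
  labels <- .binary_labels(labels)
  n_folds <- .check_count(n_folds, "n_folds", 2L)
  if (any(table(labels) < n_folds))
    stop("stratification error: a class has fewer members than folds",
         call. = FALSE)
  fold <- integer(length(labels))
  with_seed(seed, {
    sizes <- integer(n_folds)
    for (cl in c(1L, 0L)) {
      idx <- sample(which(labels == cl))
      base <- length(idx) %/% n_folds
      rem <- length(idx) %% n_folds
      per <- rep(base, n_folds)
      if (rem > 0L) {
        grow <- order(sizes, seq_len(n_folds))[seq_len(rem)]
        per[grow] <- per[grow] + 1L
      }
      f <- rep(seq_len(n_folds), times = per)
      fold[idx] <- f
      sizes <- sizes + per
    }
  })
  fold
}

#' Cross-validated evaluation of a feature matrix
#'
#' Stratified k-fold cross-validation of one binary task: the configured
#' classifier is refit on each training fold (with a fold-specific derived
#' seed) and scores the held-out fold. Reported F1 and AUC are means over
#' folds; the pooled out-of-fold scores and the fold assignment are kept so
#' that several feature sets can be compared on identical splits with
#' [compare_methods()].
#'
#' @param features m x p feature matrix.
#' @param labels Binary labels (0/1, logical, or 2-level factor).
#' @param config A [classifier_config()].
#' @param n_folds Number of folds (default 3).
#' @param seed Seed controlling the split and the per-fold fits.
#' @param bootstrap Also compute 95\% percentile bootstrap intervals for the
#'   pooled out-of-fold F1 and AUC.
#' @param B Bootstrap resamples when `bootstrap = TRUE`.
#' @return Object of class `rwov_eval`: per-fold metrics, mean `f1` and
#'   `auc`, `folds`, pooled out-of-fold `scores`, `labels`, and optional
#'   `f1_ci`/`auc_ci`.
#' @export
cross_validate <- function(features, labels, config = classifier_config(),
                           n_folds = 3L, seed = 1L, bootstrap = FALSE,
                           B = 1000L) {
  features <- as.matrix(features)
  labels <- .binary_labels(labels)
  stopifnot(nrow(features) == length(labels))
  folds <- make_folds(labels, n_folds, seed)
  scores <- numeric(length(labels))
  fm <- data.frame(fold = seq_len(n_folds), f1 = NA_real_, auc = NA_real_)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    cfg <- config
    cfg$seed <- config$seed + 1000L * f
    fit <- fit_classifier(features[tr, , drop = FALSE], labels[tr], cfg)
    s <- predict_scores(fit, features[!tr, , drop = FALSE])
    scores[!tr] <- s
    fm$f1[f] <- .f1_from_scores(s, labels[!tr], config$threshold)
    fm$auc[f] <- auc_score(s, labels[!tr])
  }
  out <- structure(list(fold_metrics = fm, f1 = mean(fm$f1),
                        auc = mean(fm$auc), folds = folds, scores = scores,
                        labels = labels, config = config,
                        threshold = config$threshold, seed = seed),
                   class = "rwov_eval")
  if (bootstrap) {
    out$auc_ci <- bootstrap_ci(scores, labels, "auc", B = B, seed = seed)
    out$f1_ci <- bootstrap_ci(scores, labels, "f1", B = B, seed = seed,
                              threshold = config$threshold)
  }
  out
}

#' @export
print.rwov_eval <- function(x, ...) {
  cat("Cross-validated evaluation (", length(unique(x$folds)), " folds, ",
      x$config$kind, ")\n", sep = "")
  cat(sprintf("  mean F1  = %.3f\n  mean AUC = %.3f\n", x$f1, x$auc))
  if (!is.null(x$auc_ci))
    cat(sprintf("  AUC 95%% CI (%.3f, %.3f); F1 95%% CI (%.3f, %.3f)\n",
                x$auc_ci$lower, x$auc_ci$upper,
                x$f1_ci$lower, x$f1_ci$upper))
  print(x$fold_metrics, row.names = FALSE)
  invisible(x)
}

#' Compare two evaluated methods by DeLong's test
#'
#' Both evaluations must come from [cross_validate()] runs on the same
#' labels with the same split (same `seed`), so the pooled out-of-fold
#' scores form a paired design.
#'
#' @param eval_a,eval_b `rwov_eval` objects.
#' @return The [delong_compare()] `htest`.
#' @export
compare_methods <- function(eval_a, eval_b) {
  stopifnot(inherits(eval_a, "rwov_eval"), inherits(eval_b, "rwov_eval"))
  if (!identical(eval_a$folds, eval_b$folds) ||
      !identical(eval_a$labels, eval_b$labels))
    stop("evaluations were not made on identical splits/labels",
         call. = FALSE)
  delong_compare(eval_a$scores, eval_b$scores, eval_a$labels)
}
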