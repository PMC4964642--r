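# classification: Gaussian discriminant analysis of TS vs MS with
# homology-grouped k-fold cross-validation and MCC reporting

#' Assemble a labelled dataset
#'
#' @param ids protein identifiers (unique).
#' @param features data.frame or matrix of numeric features, one row per
#'   protein.
#' @param labels factor or character with exactly the two levels `TS`, `MS`.
#' @param groups homology-group identifiers (homologous proteins share a
#'   group and are never split across CV folds); singletons allowed.
#' @return Object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(ids, features, labels, groups = ids) {
  features <- as.data.frame(features)
  n <- length(ids)
  if (anyDuplicated(ids)) stopf("ids must be unique")
  if (nrow(features) != n || length(labels) != n || length(groups) != n)
    stopf("ids, features, labels, groups must all have %d entries", n)
  if (!all(vapply(features, is.numeric, logical(1))))
    stopf("all features must be numeric")
  if (anyNA(features)) stopf("missing feature values are not allowed")
  labels <- factor(as.character(labels), levels = c("MS", "TS"))
  if (anyNA(labels)) stopf("labels must be 'TS' or 'MS'")
  if (nlevels(droplevels(labels)) < 2L) stopf("both labels must be present")
  rownames(features) <- ids
  structure(list(ids = as.character(ids), features = features,
                 labels = labels, groups = as.character(groups)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labelled dataset: %d proteins (%d MS, %d TS), %d features, %d homology groups\n",
              length(x$ids), sum(x$labels == "MS"), sum(x$labels == "TS"),
              ncol(x$features), length(unique(x$groups))))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; +1 is a
#' perfect prediction, 0 no better than random, -1 total disagreement.  If
#' any factor of the denominator is zero the coefficient is defined as 0
#' (standard convention).
#'
#' @param tp,tn,fp,fn confusion counts (nonnegative, not all zero).
#' @return MCC in `[-1, 1]`.
#' @export
matthews_cc <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stopf("confusion counts must be >= 0")
  if (sum(counts) == 0) stopf("MCC undefined: all confusion counts are zero")
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den2)
}

#' Fit a Gaussian discriminant classifier
#'
#' Class-conditional Gaussians with priors taken from training frequencies;
#' `mode = "linear"` pools the covariance across classes (Fisher/LDA
#' boundary), `mode = "quadratic"` keeps per-class covariances (QDA, the
#' default).  A ridge of `1e-9` times the mean feature variance is added to
#' each covariance so near-singular small folds remain invertible.
#'
#' @param train a [labeled_dataset()].
#' @param feature_names which feature columns to use (default: all).
#' @param mode `"quadratic"` (default) or `"linear"`.
#' @return Object of class `fold_da` with `predict` and `print` methods.
#' @export
fit_discriminant <- function(train, feature_names = names(train$features),
                             mode = c("quadratic", "linear")) {
  stopifnot(inherits(train, "labeled_dataset"))
  mode <- match.arg(mode)
  miss <- setdiff(feature_names, names(train$features))
  if (length(miss))
    stopf("unknown feature(s): %s", paste(miss, collapse = ", "))
  X <- as.matrix(train$features[, feature_names, drop = FALSE])
  y <- droplevels(train$labels)
  if (any(table(y) < 2L)) stopf("need at least 2 training samples per class")

  classes <- levels(y)
  d <- ncol(X)
  stats_by_class <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    list(mean = colMeans(Xi), cov = stats::cov(Xi), n = nrow(Xi))
  })
  names(stats_by_class) <- classes
  if (mode == "linear") {
    pool <- Reduce(`+`, lapply(stats_by_class, function(s) s$cov * (s$n - 1)))
    pool <- pool / (nrow(X) - length(classes))
    for (cl in classes) stats_by_class[[cl]]$cov <- pool
  }
  ridge <- 1e-9 * mean(vapply(stats_by_class, function(s) mean(diag(s$cov)),
                              numeric(1)))
  for (cl in classes) {
    S <- stats_by_class[[cl]]$cov + diag(ridge + 1e-300, d)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) stopf("singular covariance for class %s after regularization", cl)
    stats_by_class[[cl]]$chol <- ch
    stats_by_class[[cl]]$logdet <- 2 * sum(log(diag(ch)))
  }
  priors <- as.numeric(table(y)[classes]) / nrow(X)
  structure(list(mode = mode, classes = classes,
                 feature_names = feature_names,
                 class_stats = stats_by_class,
                 priors = stats::setNames(priors, classes)),
            class = "fold_da")
}

#' @export
print.fold_da <- function(x, ...) {
  cat(sprintf("%s discriminant on (%s); priors: %s\n",
              if (x$mode == "linear") "Linear" else "Quadratic",
              paste(x$feature_names, collapse = ", "),
              paste(sprintf("%s %.2f", x$classes, x$priors), collapse = ", ")))
  invisible(x)
}

#' Predict folding-state labels
#'
#' @param object a fitted [fit_discriminant()] model.
#' @param newdata data.frame (or [labeled_dataset()]) with the model's
#'   feature columns.
#' @param type `"class"` (default) or `"posterior"`.
#' @param ... unused.
#' @return Factor of predicted labels, or a posterior-probability matrix.
#' @export
predict.fold_da <- function(object, newdata, type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$features
  X <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  logp <- vapply(object$classes, function(cl) {
    s <- object$class_stats[[cl]]
    z <- backsolve(s$chol, t(X) - s$mean, transpose = TRUE)
    -0.5 * colSums(z^2) - 0.5 * s$logdet + log(object$priors[[cl]])
  }, numeric(nrow(X)))
  logp <- matrix(logp, nrow = nrow(X),
                 dimnames = list(NULL, object$classes))
  if (type == "posterior") {
    m <- apply(logp, 1, max)
    p <- exp(logp - m)
    return(p / rowSums(p))
  }
  factor(object$classes[max.col(logp, ties.method = "first")],
         levels = c("MS", "TS"))
}

# deal homology groups into k folds: random group order, each group goes to
# the currently smallest fold (by protein count)
assign_group_folds <- function(groups, k) {
  gs <- unique(groups)
  sizes <- as.integer(table(factor(groups, levels = gs)))
  ord <- sample.int(length(gs))
  fold_of_group <- integer(length(gs))
  fold_sizes <- integer(k)
  for (gi in ord) {
    f <- which.min(fold_sizes)
    fold_of_group[gi] <- f
    fold_sizes[f] <- fold_sizes[f] + sizes[gi]
  }
  fold_of_group[match(groups, gs)]
}

#' Homology-grouped k-fold cross-validation
#'
#' Repeats a k-fold cross-validation `n_resamplings` times with re-randomised
#' fold assignment.  Homologous proteins (same `groups` entry) are always
#' placed in the same fold, so performance is never inflated by training on a
#' test protein's homolog.  Within each resampling the confusion counts are
#' pooled over the k test folds (positive class: TS); the report carries the
#' mean and standard deviation over resamplings of the overall accuracy,
#' per-class accuracies and MCC.
#'
#' @param data a [labeled_dataset()].
#' @param feature_names feature subset (single observables up to quadruples).
#' @param k number of folds (default 10).
#' @param n_resamplings number of re-randomised repetitions (default 10000).
#' @param mode passed to [fit_discriminant()].
#' @param seed integer seed; the report is bit-reproducible from it.
#' @return Object of class `fold_cv_report`.
#' @export
grouped_kfold_cv <- function(data, feature_names = names(data$features),
                             k = 10L, n_resamplings = 10000L,
                             mode = c("quadratic", "linear"), seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"))
  mode <- match.arg(mode)
  n_groups <- length(unique(data$groups))
  if (n_groups < k)
    stopf("need at least k = %d homology groups, have %d", k, n_groups)
  n <- length(data$ids)
  y <- data$labels

  acc <- num_ms <- num_ts <- mcc <- numeric(n_resamplings)
  conf <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  with_seed(seed, {
    for (r in seq_len(n_resamplings)) {
      folds <- assign_group_folds(data$groups, k)
      pred <- factor(rep(NA_character_, n), levels = c("MS", "TS"))
      for (f in seq_len(k)) {
        test <- folds == f
        if (!any(test)) next
        train <- labeled_dataset(data$ids[!test],
                                 data$features[!test, , drop = FALSE],
                                 y[!test], data$groups[!test])
        model <- fit_discriminant(train, feature_names, mode)
        pred[test] <- predict(model, data$features[test, , drop = FALSE])
      }
      tp <- sum(pred == "TS" & y == "TS")
      tn <- sum(pred == "MS" & y == "MS")
      fp <- sum(pred == "TS" & y == "MS")
      fn <- sum(pred == "MS" & y == "TS")
      conf <- conf + c(tp, tn, fp, fn)
      acc[r] <- 100 * (tp + tn) / n
      num_ms[r] <- 100 * tn / sum(y == "MS")
      num_ts[r] <- 100 * tp / sum(y == "TS")
      mcc[r] <- matthews_cc(tp, tn, fp, fn)
    }
  })
  msd <- function(v) c(mean = mean(v), sd = stats::sd(v))
  structure(list(feature_names = feature_names, mode = mode, k = k,
                 n_resamplings = n_resamplings, seed = seed,
                 overall_accuracy = msd(acc),
                 per_class_accuracy = list(MS = msd(num_ms), TS = msd(num_ts)),
                 mcc = msd(mcc),
                 confusion_totals = conf,
                 n_proteins = n),
            class = "fold_cv_report")
}

#' @export
print.fold_cv_report <- function(x, ...) {
  pm <- function(v, digits = 2) sprintf("%.*f ± %.*f", digits, v["mean"], digits, v["sd"])
  cat(sprintf("Grouped %d-fold CV (%s discriminant, %d resamplings, seed %d)\n",
              x$k, x$mode, x$n_resamplings, x$seed))
  cat(sprintf("  features: %s\n", paste(x$feature_names, collapse = ", ")))
  cat(sprintf("  overall accuracy: %s %%\n", pm(x$overall_accuracy)))
  cat(sprintf("  MS accuracy:      %s %%\n", pm(x$per_class_accuracy$MS)))
  cat(sprintf("  TS accuracy:      %s %%\n", pm(x$per_class_accuracy$TS)))
  cat(sprintf("  MCC:              %s\n", pm(x$mcc)))
  invisible(x)
}

#' Serialise a CV report to a JSON-ready list
#'
#' @param report a `fold_cv_report`.
#' @return Nested list mirroring the report fields.
#' @export
report_to_list <- function(report) {
  stopifnot(inherits(report, "fold_cv_report"))
  list(features = report$feature_names,
       mode = report$mode, k = report$k,
       n_resamplings = report$n_resamplings, seed = report$seed,
       overall_accuracy = as.list(report$overall_accuracy),
       per_class_accuracy = lapply(report$per_class_accuracy, as.list),
       mcc = as.list(report$mcc),
       confusion_totals = as.list(report$confusion_totals),
       n_proteins = report$n_proteins)
}
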