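# Classifier protocol: stratified 10-fold cross-validation; per-fold
# descriptor selection by absolute Pearson (point-biserial) correlation
# with the 0/1 label; three learner families (CART decision tree, random
# forest, PLS regression with a 0.5 cut on the predicted label); balanced
# accuracy as the performance metric, pooled over out-of-fold predictions.

#' Stratified cross-validation folds
#'
#' Partitions indices into `k` folds so that each fold's class counts are
#' within one compound of the global class ratio and fold sizes differ by
#' at most one.
#'
#' @param labels 0/1 vector.
#' @param k number of folds.
#' @param seed seed for the random assignment.
#' @return list of `k` disjoint integer index vectors covering all indices.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1) {
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (any(table(labels) < k)) {
    stop("each class must have at least k = ", k, " members")
  }
  with_seed(seed, {
    folds <- vector("list", k)
    totals <- numeric(k)
    # larger class first so remainders can be placed to even out fold sizes
    for (cl in classes[order(-tabulate(match(labels, classes)))]) {
      idx <- sample(which(labels == cl))
      n_c <- length(idx)
      base <- n_c %/% k
      rem <- n_c %% k
      per_fold <- rep(base, k)
      if (rem > 0) {
        extra <- order(totals, stats::runif(k))[seq_len(rem)]
        per_fold[extra] <- per_fold[extra] + 1L
      }
      pos <- 0
      for (f in seq_len(k)) {
        if (per_fold[f] > 0) {
          folds[[f]] <- c(folds[[f]], idx[pos + seq_len(per_fold[f])])
          pos <- pos + per_fold[f]
        }
      }
      totals <- totals + per_fold
    }
    lapply(folds, sort)
  })
}

#' Select descriptors by correlation with the class label
#'
#' Ranks descriptors by absolute Pearson correlation with the 0/1 label,
#' computed on the training data only. Constant (zero-variance) descriptors
#' are never selected; ties break by ascending descriptor index. When fewer
#' than `n` usable descriptors exist, all are returned with a warning.
#'
#' @param features numeric matrix (rows = compounds).
#' @param labels 0/1 vector.
#' @param n number of descriptors wanted.
#' @return integer column indices in rank order (strongest first).
#' @export
select_descriptors <- function(features, labels, n) {
  if (n < 1) stop("n must be >= 1")
  r <- suppressWarnings(as.vector(stats::cor(features, as.numeric(labels))))
  usable <- which(!is.na(r))
  if (!length(usable)) stop("no usable (non-constant) descriptors")
  if (length(usable) < n) {
    warning("only ", length(usable), " usable descriptors; selecting all")
    n <- length(usable)
  }
  usable[order(-abs(r[usable]), usable)][seq_len(n)]
}

#' Descriptor budget for a learner
#'
#' Decision trees and random forests use one tenth of the training-set size;
#' PLS scans a fixed grid of descriptor counts (with the component count
#' separately capped at one tenth of the number of data points).
#'
#' @param method `"decision_tree"`, `"random_forest"` or `"pls"`.
#' @param n_train training-set size (ignored for PLS).
#' @param pls_grid descriptor-count grid for PLS.
#' @return integer budget, or the grid for PLS.
#' @export
descriptor_budget <- function(method, n_train,
                              pls_grid = c(5, 10, 20, 50)) {
  if (method == "pls") return(pls_grid)
  floor(n_train / 10)
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity of a binary classification.
#'
#' @param y_true,y_pred 0/1 vectors of equal length.
#' @return value in \[0, 1\]; `NA` with a warning when a class is absent
#'   from `y_true`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!length(y_true)) stop("empty input")
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (!all(c(0L, 1L) %in% y_true)) {
    warning("a class is absent from y_true; balanced accuracy undefined")
    return(NA_real_)
  }
  sens <- mean(y_pred[y_true == 1L] == 1L)
  spec <- mean(y_pred[y_true == 0L] == 0L)
  (sens + spec) / 2
}

# Fast data.frame view of a numeric matrix (columns already validly named).
.df_view <- function(x) {
  structure(lapply(seq_len(ncol(x)), function(j) x[, j]),
            names = colnames(x), class = "data.frame",
            row.names = .set_row_names(nrow(x)))
}

.fit_predict <- function(method, x_train, y_train, x_test, rf_ntree,
                         pls_ncomp) {
  switch(method,
    decision_tree = {
      nm <- make.names(colnames(x_train), unique = TRUE)
      colnames(x_train) <- nm
      colnames(x_test) <- nm
      d <- .df_view(x_train)
      d$.y <- factor(y_train, levels = c(0, 1))
      m <- rpart::rpart(.y ~ ., data = d, method = "class",
                        control = rpart::rpart.control(
                          xval = 0, maxcompete = 0, maxsurrogate = 0))
      as.integer(as.character(
        stats::predict(m, .df_view(x_test), type = "class")))
    },
    random_forest = {
      m <- randomForest::randomForest(x_train,
                                      factor(y_train, levels = c(0, 1)),
                                      ntree = rf_ntree)
      as.integer(as.character(stats::predict(m, x_test)))
    },
    pls = {
      ncomp <- max(1L, min(pls_ncomp, ncol(x_train), nrow(x_train) - 1L))
      m <- NULL
      while (is.null(m) && ncomp >= 1L) {
        m <- tryCatch(
          mixOmics::pls(x_train, as.numeric(y_train), ncomp = ncomp,
                        mode = "regression"),
          error = function(e) NULL)
        # NIPALS diverges when ncomp exceeds the effective rank of the
        # selected block (common with collinear binary keys): drop a
        # component and refit
        if (is.null(m)) ncomp <- ncomp - 1L
      }
      if (is.null(m)) stop("PLS fit failed at every component count")
      pred <- stats::predict(m, x_test)$predict[, 1, ncomp]
      if (anyNA(pred)) stop("PLS prediction undefined")
      # fitted label >= 0.5 is assigned class 1
      as.integer(pred >= 0.5)
    })
}

# One full cross-validation pass at a fixed per-fold descriptor budget.
.cv_pass <- function(method, features, labels, folds, budget, rf_ntree,
                     pls_ncomp, seed) {
  n <- length(labels)
  preds <- rep(NA_integer_, n)
  selected <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    b <- if (is.null(budget)) floor(length(train) / 10) else budget
    sel <- suppressWarnings(
      select_descriptors(features[train, , drop = FALSE], labels[train], b))
    selected[[f]] <- colnames(features)[sel]
    fit_seed <- if (method == "random_forest") derive_seed(seed, 100 + f)
    preds[test] <- with_seed(fit_seed, {
      .fit_predict(method, features[train, sel, drop = FALSE], labels[train],
                   features[test, sel, drop = FALSE], rf_ntree, pls_ncomp)
    })
  }
  list(predictions = preds, selected = selected)
}

#' Cross-validate a classifier on a modelling dataset
#'
#' Runs the full protocol for one learner: stratified folds, per-fold
#' descriptor selection against the training labels only, fit, and
#' prediction of the held-out compounds. For PLS the descriptor grid
#' (5, 10, 20, 50) is scanned and the best cross-validated balanced
#' accuracy is reported (ties go to the smaller count); the number of PLS
#' components is capped at one tenth of the number of data points.
#'
#' @param dataset a [build_dataset()] result that passed the size gate.
#' @param method `"decision_tree"`, `"random_forest"` or `"pls"`.
#' @param k number of folds.
#' @param seed master seed; folds and forest seeds derive from it.
#' @param pls_grid descriptor-count grid for PLS.
#' @param rf_ntree trees per random forest.
#' @return list of class `model_run`: `method`, `balanced_accuracy` (pooled
#'   over out-of-fold predictions), `mean_fold_ba`, `predictions` (named),
#'   `folds`, `selected` (descriptor names per fold), `pls_n_descriptors`
#'   (PLS only), `k`, `seed`.
#' @export
cross_validate <- function(dataset, method = c("decision_tree",
                                               "random_forest", "pls"),
                           k = 10, seed = 1, pls_grid = c(5, 10, 20, 50),
                           rf_ntree = 100) {
  method <- match.arg(method)
  if (isTRUE(dataset$too_small)) {
    stop("dataset below the minimum size gate (", dataset$min_n, ")")
  }
  y <- unname(dataset$labels)
  X <- dataset$features
  storage.mode(X) <- "double"
  folds <- stratified_folds(y, k, derive_seed(seed, 1))
  pls_ncomp <- floor(length(y) / 10)
  run_one <- function(budget) {
    .cv_pass(method, X, y, folds, budget, rf_ntree, pls_ncomp, seed)
  }
  grid_value <- NULL
  if (method == "pls") {
    grid <- sort(pls_grid)
    passes <- lapply(grid, run_one)
    bas <- vapply(passes, function(p) balanced_accuracy(y, p$predictions),
                  numeric(1))
    best <- which.max(bas)  # ties resolve to the smallest grid value
    pass <- passes[[best]]
    grid_value <- grid[best]
  } else {
    pass <- run_one(NULL)
  }
  fold_bas <- vapply(folds, function(f) {
    suppressWarnings(balanced_accuracy(y[f], pass$predictions[f]))
  }, numeric(1))
  structure(list(
    method = method,
    balanced_accuracy = balanced_accuracy(y, pass$predictions),
    mean_fold_ba = mean(fold_bas, na.rm = TRUE),
    predictions = stats::setNames(pass$predictions, dataset$compounds),
    folds = folds, selected = pass$selected,
    pls_n_descriptors = grid_value, k = k, seed = seed),
    class = "model_run")
}

#' @export
print.model_run <- function(x, ...) {
  cat(sprintf("%s, %d-fold CV: balanced accuracy %.3f (per-fold mean %.3f)\n",
              x$method, x$k, x$balanced_accuracy, x$mean_fold_ba))
  if (!is.null(x$pls_n_descriptors)) {
    cat("  PLS descriptor count:", x$pls_n_descriptors, "\n")
  }
  invisible(x)
}

#' Balanced-accuracy distribution over re-seeded random forests
#'
#' Rebuilds the cross-validated random-forest model `n_models` times under
#' different seeds (the screening protocol uses 100), giving the
#' distribution of balanced accuracies that the RF significance machinery
#' compares against y-randomised counterparts.
#'
#' @param dataset a [build_dataset()] result.
#' @param n_models number of re-seeded models.
#' @param k folds.
#' @param seed master seed; per-model seeds derive from it.
#' @param rf_ntree trees per forest.
#' @return numeric vector of `n_models` balanced accuracies.
#' @export
rf_distribution <- function(dataset, n_models = 100, k = 10, seed = 1,
                            rf_ntree = 100) {
  vapply(seq_len(n_models), function(i) {
    cross_validate(dataset, "random_forest", k = k,
                   seed = derive_seed(seed, 1000 + i),
                   rf_ntree = rf_ntree)$balanced_accuracy
  }, numeric(1))
}

#' Descriptor importance from whole-dataset random forests
#'
#' Fits `n_models` re-seeded random forests to the whole dataset (no
#' cross-validation), with descriptors selected once on the full data, and
#' averages the class-specific permutation importances. Two rankings are
#' returned, one per prediction direction.
#'
#' @param dataset a [build_dataset()] result.
#' @param n_models number of forests to average over.
#' @param seed master seed.
#' @param rf_ntree trees per forest.
#' @return data.frame `descriptor`, `importance_a`, `importance_b`,
#'   `rank_a`, `rank_b`, ordered by `rank_a`; class a/b = less toxic in
#'   `vehicle_a`/`vehicle_b`.
#' @export
descriptor_importance <- function(dataset, n_models = 100, seed = 1,
                                  rf_ntree = 100) {
  y <- unname(dataset$labels)
  X <- dataset$features
  storage.mode(X) <- "double"
  sel <- select_descriptors(X, y, floor(length(y) / 10))
  Xs <- X[, sel, drop = FALSE]
  fy <- factor(y, levels = c(0, 1))
  acc <- matrix(0, ncol(Xs), 2, dimnames = list(colnames(Xs), c("0", "1")))
  for (i in seq_len(n_models)) {
    m <- with_seed(derive_seed(seed, i), {
      randomForest::randomForest(Xs, fy, ntree = rf_ntree,
                                 importance = TRUE)
    })
    acc <- acc + randomForest::importance(m)[, c("0", "1"), drop = FALSE]
  }
  acc <- acc / n_models
  out <- data.frame(descriptor = rownames(acc),
                    importance_a = acc[, "0"], importance_b = acc[, "1"],
                    stringsAsFactors = FALSE)
  out$rank_a <- rank(-out$importance_a, ties.method = "first")
  out$rank_b <- rank(-out$importance_b, ties.method = "first")
  out <- out[order(out$rank_a), ]
  rownames(out) <- NULL
  out
}
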