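#' @keywords internal
standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl,
       apply = function(M) sweep(sweep(M, 2L, ctr), 2L, scl, `/`))
}

as_feature_matrix <- function(features) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("non-finite feature values")
  X
}

rbf_kernel <- function(X, Y, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

#' One-vs-rest Gaussian-kernel SVM
#'
#' Trains one binary soft-margin SVM per class (that class positive, all
#' others negative); each binary subproblem is solved in the dual, whose
#' optimum satisfies the KKT feasibility conditions `0 <= alpha_i <= C` and
#' `sum(alpha_i y_i) = 0`. Prediction evaluates the package's own decision
#' function `f_m(x) = sum_i alpha_i^m y_i K(x, x_i) + b_m` for every class m
#' and takes the maximum. Features are standardized internally (train
#' statistics stored).
#'
#' @param features Numeric matrix / data frame of predictors (rows = samples).
#' @param labels Class labels (coerced to factor; >= 2 classes).
#' @param C Penalty parameter (> 0), default 1.
#' @param kernel_width RBF `gamma`; default `1 / (n_features * mean feature
#'   variance)` computed on the standardized features.
#' @param seed Integer seed (solver is deterministic; kept for interface
#'   symmetry).
#' @return An object of class `svm_ovr` with per-class support vectors, dual
#'   coefficients `alpha_i y_i` and bias.
#' @export
train_svm <- function(features, labels, C = 1, kernel_width = NULL, seed = 1L) {
  X <- as_feature_matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least two classes")
  std <- standardizer(X)
  Xs <- std$apply(X)
  if (is.null(kernel_width)) {
    v <- mean(apply(Xs, 2L, stats::var))
    kernel_width <- 1 / (ncol(Xs) * max(v, .Machine$double.eps))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(derive_seed(seed, 11L))
  per_class <- lapply(levels(y), function(cl) {
    yb <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    fit <- e1071::svm(Xs, yb, kernel = "radial", gamma = kernel_width,
                      cost = C, scale = FALSE)
    # libsvm orients the binary decision by order of appearance in the data,
    # not by factor level; flip so positive decision always means `cl`
    dv <- attr(stats::predict(fit, Xs[1, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
    flip <- identical(colnames(dv), "neg/pos")
    sgn <- if (flip) -1 else 1
    list(class = cl, sv = fit$SV, coefs = sgn * as.numeric(fit$coefs),
         rho = sgn * fit$rho)
  })
  names(per_class) <- levels(y)
  structure(list(classes = levels(y), models = per_class, C = C,
                 gamma = kernel_width, center = std$center,
                 scale = std$scale, n = nrow(Xs)),
            class = "svm_ovr")
}

#' Per-class decision values of a one-vs-rest SVM
#'
#' Evaluates `f_m(x) = sum_i (alpha_i^m y_i) K(x, x_i) + b_m` directly from
#' the stored dual coefficients.
#'
#' @param object An `svm_ovr` model.
#' @param features New samples (rows).
#' @return Matrix, rows = samples, one column per class.
#' @export
svm_decision_values <- function(object, features) {
  X <- as_feature_matrix(features)
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, `/`)
  vals <- vapply(object$models, function(m) {
    K <- rbf_kernel(Xs, m$sv, object$gamma)
    as.numeric(K %*% m$coefs - m$rho)
  }, numeric(nrow(Xs)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  colnames(vals) <- object$classes
  vals
}

#' @export
predict.svm_ovr <- function(object, newdata, ...) {
  vals <- svm_decision_values(object, newdata)
  factor(object$classes[max.col(vals, ties.method = "first")],
         levels = object$classes)
}

#' KKT feasibility audit of a fitted one-vs-rest SVM
#'
#' For each binary subproblem checks the dual constraints: every multiplier
#' `alpha_i = |alpha_i y_i|` lies in `[0, C]` and `sum(alpha_i y_i) = 0`.
#'
#' @param model An `svm_ovr`.
#' @param tol Feasibility tolerance, default 1e-6.
#' @return Tibble: `class`, `n_sv`, `max_alpha`, `sum_alpha_y`, `feasible`.
#' @export
kkt_audit <- function(model, tol = 1e-6) {
  purrr::map_dfr(model$models, function(m) {
    alpha <- abs(m$coefs)
    tibble::tibble(
      class = m$class, n_sv = length(alpha),
      max_alpha = max(alpha), sum_alpha_y = sum(m$coefs),
      feasible = max(alpha) <= model$C + tol && abs(sum(m$coefs)) <= tol
    )
  })
}

#' Random-forest classifier with explicit majority voting
#'
#' Fits a bagged forest and predicts by the package's own majority vote over
#' per-tree votes; an even split is broken deterministically in favor of the
#' lowest class index (factor-level order).
#'
#' @inheritParams train_svm
#' @param n_trees Number of trees, default 200.
#' @return Object of class `rf_vote`.
#' @export
train_random_forest <- function(features, labels, n_trees = 200L, seed = 1L) {
  X <- as_feature_matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least two classes")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(derive_seed(seed, 23L))
  fit <- randomForest::randomForest(X, y, ntree = n_trees)
  structure(list(forest = fit, classes = levels(y), n_trees = n_trees),
            class = "rf_vote")
}

#' @export
predict.rf_vote <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  votes <- stats::predict(object$forest, X, type = "vote", norm.votes = FALSE)
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L,
                                           dimnames = list(NULL, object$classes))
  # majority vote; which.max/max.col "first" = lowest class index on ties
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

#' Backpropagation neural network
#'
#' A plain multilayer feedforward network (tanh hidden units, softmax output)
#' trained by full-batch gradient descent on the cross-entropy loss — forward
#' propagation, then backpropagation of errors, repeated for `epochs`
#' iterations. Deterministic given `seed`; the per-epoch loss trajectory is
#' stored. With `epochs = 0` the model predicts from its random
#' initialization. Divergence (non-finite loss) is an error.
#'
#' @inheritParams train_svm
#' @param hidden_sizes Integer vector of hidden-layer widths, default 32.
#' @param epochs Training iterations, default 200.
#' @param learning_rate Gradient step size, default 0.1.
#' @return Object of class `bpnn` with weight matrices, training-loss
#'   history, standardization parameters and class levels.
#' @export
train_bpnn <- function(features, labels, hidden_sizes = 32L, epochs = 200L,
                       learning_rate = 0.1, seed = 1L) {
  X <- as_feature_matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least two classes")
  std <- standardizer(X)
  Xs <- std$apply(X)
  n <- nrow(Xs); k <- nlevels(y)
  Y <- matrix(0, n, k); Y[cbind(seq_len(n), as.integer(y))] <- 1
  sizes <- c(ncol(Xs), hidden_sizes, k)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(derive_seed(seed, 31L))
  W <- lapply(seq_len(length(sizes) - 1L), function(l) {
    matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = 1 / sqrt(sizes[l])),
           sizes[l], sizes[l + 1L])
  })
  b <- lapply(sizes[-1L], function(s) numeric(s))
  forward <- function(Xin) {
    acts <- list(Xin)
    L <- length(W)
    for (l in seq_len(L - 1L)) {
      acts[[l + 1L]] <- tanh(sweep(acts[[l]] %*% W[[l]], 2L, b[[l]], `+`))
    }
    z <- sweep(acts[[L]] %*% W[[L]], 2L, b[[L]], `+`)
    z <- z - apply(z, 1L, max)
    p <- exp(z); p <- p / rowSums(p)
    acts[[L + 1L]] <- p
    acts
  }
  loss_history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    acts <- forward(Xs)
    P <- acts[[length(acts)]]
    loss <- -mean(log(pmax(P[cbind(seq_len(n), as.integer(y))], 1e-300)))
    if (!is.finite(loss)) stop("BPNN training diverged (non-finite loss)")
    loss_history[e] <- loss
    delta <- (P - Y) / n
    for (l in rev(seq_along(W))) {
      gW <- crossprod(acts[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(W[[l]])) * (1 - acts[[l]]^2)
      }
      W[[l]] <- W[[l]] - learning_rate * gW
      b[[l]] <- b[[l]] - learning_rate * gb
    }
  }
  structure(list(weights = W, biases = b, classes = levels(y),
                 center = std$center, scale = std$scale,
                 loss_history = loss_history, epochs = epochs,
                 learning_rate = learning_rate,
                 hidden_sizes = hidden_sizes,
                 forward = NULL),
            class = "bpnn")
}

bpnn_probs <- function(object, X) {
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, `/`)
  a <- Xs
  L <- length(object$weights)
  for (l in seq_len(L - 1L)) {
    a <- tanh(sweep(a %*% object$weights[[l]], 2L, object$biases[[l]], `+`))
  }
  z <- sweep(a %*% object$weights[[L]], 2L, object$biases[[L]], `+`)
  z <- z - apply(z, 1L, max)
  p <- exp(z)
  p / rowSums(p)
}

#' @export
predict.bpnn <- function(object, newdata, ...) {
  P <- bpnn_probs(object, as_feature_matrix(newdata))
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' Stratified train/test split
#'
#' Random, seeded, disjoint and exhaustive split; with `stratified = TRUE`
#' (default) the train fraction is applied within each class, preserving
#' class proportions to within one sample.
#'
#' @param data A data frame / tibble of samples.
#' @param labels Class labels (same length as `nrow(data)`); used for
#'   stratification.
#' @param train_fraction Fraction in (0, 1), default 0.8.
#' @param seed Integer seed.
#' @param stratified Stratify by class (default TRUE; every class then needs
#'   at least 2 samples).
#' @return List with `train` and `test` (row-subsets of `data`) and the
#'   corresponding `train_labels`, `test_labels`.
#' @export
split_data <- function(data, labels, train_fraction = 0.8, seed = 1L,
                       stratified = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie in (0, 1)")
  }
  y <- factor(labels)
  stopifnot(length(y) == nrow(data))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(derive_seed(seed, 47L))
  if (stratified) {
    if (any(table(y) < 2L)) {
      stop("every class needs at least 2 samples for a stratified split")
    }
    idx_train <- unlist(lapply(levels(y), function(cl) {
      rows <- which(y == cl)
      # keep every class represented on both sides of the split
      n_take <- min(length(rows) - 1L, max(1L, round(train_fraction * length(rows))))
      sample(rows, n_take)
    }))
  } else {
    n_take <- min(nrow(data) - 1L, max(1L, round(train_fraction * nrow(data))))
    idx_train <- sample(nrow(data), n_take)
  }
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(nrow(data)), idx_train)
  list(train = data[idx_train, , drop = FALSE],
       test = data[idx_test, , drop = FALSE],
       train_labels = y[idx_train], test_labels = y[idx_test])
}

#' Evaluate a classifier on a test set
#'
#' Accuracy plus macro-averaged recall and F1 (equal class weight), and the
#' confusion matrix with true classes as rows.
#'
#' @param model A fitted `svm_ovr`, `rf_vote` or `bpnn` (anything with a
#'   `predict` method returning labels).
#' @param features Test predictors.
#' @param labels True test labels.
#' @return Object of class `classification_report`: `accuracy`, `recall`,
#'   `f1`, `averaging = "macro"`, `confusion`, `classes`.
#' @export
evaluate <- function(model, features, labels) {
  if (nrow(as_feature_matrix(features)) == 0L) stop("empty test set")
  cls <- model$classes
  truth <- factor(labels, levels = cls)
  if (anyNA(truth)) stop("test labels outside the model's class vocabulary")
  pred <- factor(stats::predict(model, features), levels = cls)
  cm <- table(truth = truth, predicted = pred)
  acc <- sum(diag(cm)) / sum(cm)
  present <- rowSums(cm) > 0
  rec_per <- diag(cm)[present] / rowSums(cm)[present]
  prec_den <- colSums(cm)[present]
  prec_per <- ifelse(prec_den > 0, diag(cm)[present] / prec_den, 0)
  f1_per <- ifelse(prec_per + rec_per > 0,
                   2 * prec_per * rec_per / (prec_per + rec_per), 0)
  structure(list(accuracy = acc, recall = mean(rec_per), f1 = mean(f1_per),
                 averaging = "macro", confusion = unclass(cm), classes = cls),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> accuracy %.4f | macro recall %.4f | macro F1 %.4f\n",
    x$accuracy, x$recall, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Short movement labels
#'
#' The conventional abbreviations: CE (close eyes), PL (purse lips), RE
#' (raise eyebrows), LCM (lift mouth corners), FR (frown); intensities N / F.
#'
#' @param action,intensity Label vectors.
#' @return Character vector like `"CE_N"`.
#' @export
short_label <- function(action, intensity = NULL) {
  ab <- c(raise_eyebrows = "RE", frown = "FR", close_eyes = "CE",
          purse_lips = "PL", lift_mouth_corners = "LCM")
  base <- ifelse(action %in% names(ab), ab[action], action)
  if (is.null(intensity)) return(unname(base))
  paste0(base, "_", toupper(substr(intensity, 1, 1)))
}

#' Movement-recognition benchmark
#'
#' Runs the five-class (forceful only) or ten-class (action x intensity) task
#' on an epoch feature matrix: stratified 80/20 split, then one fitted model
#' and test-set report per requested classifier.
#'
#' @param feature_matrix Tibble from [extract_feature_matrix()] with `action`
#'   and `intensity` columns plus the feature columns.
#' @param task `"five_class"` (forceful epochs, action labels) or
#'   `"ten_class"` (all epochs, action-intensity labels).
#' @param classifiers Subset of `c("rf", "svm", "bpnn")`.
#' @param train_fraction Train fraction for the split, default 0.8.
#' @param stratified Stratify the split by class (default TRUE).
#' @param seed Integer seed governing split and classifier fits.
#' @param bpnn_epochs Training epochs for the BPNN entry, default 400.
#' @return A tibble with one row per classifier: `task`, `classifier`,
#'   `accuracy`, `recall`, `f1`, `averaging`, and list columns `report`
#'   (the full `classification_report`) and `model`.
#' @export
run_benchmark <- function(feature_matrix, task = c("five_class", "ten_class"),
                          classifiers = c("rf", "svm", "bpnn"),
                          train_fraction = 0.8, stratified = TRUE, seed = 1L,
                          bpnn_epochs = 400L) {
  task <- match.arg(task)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  fm <- tibble::as_tibble(feature_matrix)
  stopifnot(all(c("action", "intensity") %in% names(fm)))
  if (task == "five_class") {
    if (!any(fm$intensity == "forceful")) {
      stop("five_class task needs forceful-intensity epochs")
    }
    fm <- dplyr::filter(fm, .data$intensity == "forceful")
    lab <- short_label(fm$action)
  } else {
    if (length(unique(fm$intensity)) < 2L) {
      stop("ten_class task needs both intensities")
    }
    lab <- short_label(fm$action, fm$intensity)
  }
  X <- fm[, feature_columns(fm), drop = FALSE]
  sp <- split_data(X, lab, train_fraction, seed = seed,
                   stratified = stratified)
  trainers <- list(
    rf = function() train_random_forest(sp$train, sp$train_labels, seed = seed),
    svm = function() train_svm(sp$train, sp$train_labels, seed = seed),
    bpnn = function() train_bpnn(sp$train, sp$train_labels, seed = seed,
                                 epochs = bpnn_epochs)
  )
  purrr::map_dfr(classifiers, function(clf) {
    model <- trainers[[clf]]()
    rep <- evaluate(model, sp$test, sp$test_labels)
    tibble::tibble(task = task, classifier = clf, accuracy = rep$accuracy,
                   recall = rep$recall, f1 = rep$f1,
                   averaging = rep$averaging,
                   report = list(rep), model = list(model))
  })
}
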