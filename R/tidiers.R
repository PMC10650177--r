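#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an unmixing fit
#'
#' One row per (component, channel) weight of the full unmixing map.
#'
#' @param x An `unmixing_result`.
#' @param ... Unused.
#' @return A tibble: `component`, `channel`, `weight`.
#' @method tidy unmixing_result
#' @export
tidy.unmixing_result <- function(x, ...) {
  W <- x$W
  tibble::tibble(
    component = rep(seq_len(nrow(W)), times = ncol(W)),
    channel = rep(seq_len(ncol(W)), each = nrow(W)),
    weight = as.vector(W)
  )
}

#' @rdname tidy.unmixing_result
#' @return `glance()`: one-row tibble with `n_components`, `converged`,
#'   `iterations`, `tol`.
#' @method glance unmixing_result
#' @export
glance.unmixing_result <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, converged = x$converged,
                 iterations = x$iterations, tol = x$tol)
}

#' Tidy a classification report
#'
#' Per-class test counts, recall, precision and F1 from the confusion matrix.
#'
#' @param x A `classification_report`.
#' @param ... Unused.
#' @return A tibble with one row per class.
#' @method tidy classification_report
#' @export
tidy.classification_report <- function(x, ...) {
  cm <- x$confusion
  n_test <- rowSums(cm)
  rec <- ifelse(n_test > 0, diag(cm) / n_test, NA_real_)
  prec_den <- colSums(cm)
  prec <- ifelse(prec_den > 0, diag(cm) / prec_den, 0)
  f1 <- ifelse(!is.na(rec) & prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  tibble::tibble(class = x$classes, n_test = as.integer(n_test),
                 recall = rec, precision = prec, f1 = f1)
}

#' @rdname tidy.classification_report
#' @method glance classification_report
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, recall = x$recall, f1 = x$f1,
                 averaging = x$averaging)
}

#' Tidy a one-vs-rest SVM
#'
#' The per-class dual summary (the KKT audit view).
#'
#' @param x An `svm_ovr`.
#' @param ... Unused.
#' @return A tibble: `class`, `n_sv`, `max_alpha`, `sum_alpha_y`, `feasible`.
#' @method tidy svm_ovr
#' @export
tidy.svm_ovr <- function(x, ...) kkt_audit(x)

#' @rdname tidy.svm_ovr
#' @method glance svm_ovr
#' @export
glance.svm_ovr <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes), C = x$C, gamma = x$gamma,
                 n_train = x$n)
}

#' Tidy a BPNN fit
#'
#' The per-epoch training-loss trajectory.
#'
#' @param x A `bpnn`.
#' @param ... Unused.
#' @return A tibble: `epoch`, `loss`.
#' @method tidy bpnn
#' @export
tidy.bpnn <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @rdname tidy.bpnn
#' @method glance bpnn
#' @export
glance.bpnn <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    hidden = paste(x$hidden_sizes, collapse = "x"),
    epochs = x$epochs, learning_rate = x$learning_rate,
    final_loss = if (x$epochs > 0) x$loss_history[x$epochs] else NA_real_
  )
}

#' Tidy a mixing model
#'
#' @param x A `mixing_model`.
#' @param ... Unused.
#' @return A tibble: `electrode`, `source`, `coefficient`.
#' @method tidy mixing_model
#' @export
tidy.mixing_model <- function(x, ...) {
  A <- x$matrix
  tibble::tibble(
    electrode = rep(x$electrode_labels, times = ncol(A)),
    source = rep(x$source_labels, each = nrow(A)),
    coefficient = as.vector(A)
  )
}
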