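#' One-vs-rest linear support vector classifier
#'
#' Multiclass linear SVC built from K binary linear SVMs (class vs rest),
#' fitted with [e1071::svm()] (cost `C`, no rescaling: inputs are already
#' standardized). Prediction is by the largest one-vs-rest decision value;
#' the per-class weight vectors are exposed for recursive feature
#' elimination, where a gene's importance is its sum of squared weights
#' across classes.
#'
#' @param x Samples-by-features numeric matrix.
#' @param y Class labels (coerced to factor).
#' @param cost SVM regularization strength.
#' @return A list of class `lsvc` with `weights` (features x classes),
#'   `intercepts`, `classes`, `features`.
#' @export
lsvc_fit <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  y <- factor(y)
  classes <- levels(y)
  stopifnot(length(classes) >= 2, nrow(x) == length(y))
  p <- ncol(x)
  w <- matrix(0, p, length(classes),
              dimnames = list(colnames(x), classes))
  b <- setNames(numeric(length(classes)), classes)
  for (k in seq_along(classes)) {
    yk <- factor(y == classes[k], levels = c(FALSE, TRUE))
    fit <- e1071::svm(x, yk, kernel = "linear", scale = FALSE, cost = cost)
    wk <- as.numeric(t(fit$coefs) %*% fit$SV)
    bk <- -fit$rho
    # orient the decision value so positive means "this class"
    dec <- x %*% wk + bk
    if (mean(dec[yk == "TRUE"]) < mean(dec[yk == "FALSE"])) {
      wk <- -wk
      bk <- -bk
    }
    w[, k] <- wk
    b[k] <- bk
  }
  structure(list(weights = w, intercepts = b, classes = classes,
                 features = colnames(x)),
            class = "lsvc")
}

#' Predict classes with a fitted `lsvc`
#'
#' @param object A fitted [lsvc_fit()] model.
#' @param newdata Samples-by-features matrix with the model's features
#'   (matched by name when available).
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.lsvc <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata))) {
    newdata <- newdata[, object$features, drop = FALSE]
  }
  scores <- newdata %*% object$weights +
    matrix(object$intercepts, nrow(newdata), length(object$intercepts),
           byrow = TRUE)
  object$classes[max.col(scores, ties.method = "first")]
}

# Feature importance for RFE: sum over classes of squared weights.
lsvc_importance <- function(object) {
  rowSums(object$weights^2)
}

#' Mean stratified k-fold cross-validated accuracy of a linear SVC
#'
#' @param x Samples-by-features matrix.
#' @param y Class labels.
#' @param folds Number of folds.
#' @param seed Seed for the stratified fold assignment.
#' @param cost SVM cost.
#' @return Mean over folds of the held-out accuracy.
#' @export
lsvc_cv_accuracy <- function(x, y, folds = 3L, seed = 1L, cost = 1) {
  x <- as.matrix(x)
  y <- factor(y)
  fold <- stratified_folds(y, folds, seed)
  accs <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L || !any(!tr)) return(NA_real_)
    fit <- lsvc_fit(x[tr, , drop = FALSE], y[tr], cost = cost)
    mean(predict(fit, x[!tr, , drop = FALSE]) == as.character(y[!tr]))
  }, numeric(1))
  mean(accs, na.rm = TRUE)
}
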